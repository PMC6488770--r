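#' The nine condensed identity-by-descent states
#'
#' Each state is a set partition of the four gene copies (a1, a2, b1, b2) of
#' a diploid pair into IBD blocks; gene copies in the same block are identical
#' by descent.  Within-individual blocks encode inbreeding.  Returned as a
#' list of integer vectors of length 4 giving the block index of each slot,
#' ordered J1..J9.
#'
#' @return list of 9 integer block assignments.
#' @examples
#' statePartitions()[[7]]  # {a1 b1}{a2 b2}
#' @export
statePartitions <- function() {
  list(
    J1 = c(1L, 1L, 1L, 1L),  # {a1 a2 b1 b2}
    J2 = c(1L, 1L, 2L, 2L),  # {a1 a2}{b1 b2}
    J3 = c(1L, 1L, 1L, 2L),  # {a1 a2 b1}{b2}
    J4 = c(1L, 1L, 2L, 3L),  # {a1 a2}{b1}{b2}
    J5 = c(1L, 2L, 1L, 1L),  # {a1 b1 b2}{a2}
    J6 = c(1L, 2L, 3L, 3L),  # {a1}{a2}{b1 b2}
    J7 = c(1L, 2L, 1L, 2L),  # {a1 b1}{a2 b2}
    J8 = c(1L, 2L, 1L, 3L),  # {a1 b1}{a2}{b2}
    J9 = c(1L, 2L, 3L, 4L)   # {a1}{a2}{b1}{b2}
  )
}

# Allele assignments to the blocks of one partition: each IBD block carries a
# single allele drawn independently with frequency f (allele 1) or 1 - f
# (allele 0).  Returns, per assignment, the implied ordered genotype pair and
# the exponents (k ones out of nb blocks) of the weight f^k (1-f)^(nb-k).
.blockAssignments <- function(blocks) {
  nb <- max(blocks)
  out <- vector("list", 2^nb)
  for (a in seq_len(2^nb) - 1L) {
    allele <- as.integer(bitwAnd(bitwShiftL(1L, seq_len(nb) - 1L), a) > 0L)
    slot <- allele[blocks]
    out[[a + 1L]] <- list(gA = slot[1] + slot[2], gB = slot[3] + slot[4],
                          k = sum(allele), nb = nb)
  }
  out
}

.assignmentTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(statePartitions(), .blockAssignments)
    cache
  }
})

#' Genotype-pair prior under each condensed IBD state
#'
#' Probability \eqn{P(G_a, G_b \mid f, X = m)} of every ordered genotype pair
#' for the nine condensed IBD states, at allele frequency \code{f} of the
#' counted allele.  Each state's distribution is generated from its set
#' partition: every IBD block draws one allele independently (frequency
#' \code{f} for allele 1), and the genotypes are the allele counts this
#' induces.  With called genotypes these are the classical identity-state
#' genotype-pair probabilities of Anderson and Weir.
#'
#' @param f allele frequency, strictly inside (0, 1).
#' @return numeric array 9 x 3 x 3; \code{[m, gA + 1, gB + 1]} is the
#'   probability of genotypes \code{gA} in individual a and \code{gB} in b
#'   under state m.  Each 3 x 3 slice sums to 1.
#' @examples
#' p <- genotypePairPrior(0.7)
#' p["J7", "1", "1"]  # 2 * 0.7 * 0.3
#' @export
genotypePairPrior <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f >= 1)
    stop("allele frequency must be a single value strictly inside (0, 1)")
  tab <- .assignmentTable()
  out <- array(0, c(9, 3, 3),
               dimnames = list(paste0("J", 1:9), 0:2, 0:2))
  for (m in 1:9) {
    for (as in tab[[m]]) {
      out[m, as$gA + 1L, as$gB + 1L] <- out[m, as$gA + 1L, as$gB + 1L] +
        f^as$k * (1 - f)^(as$nb - as$k)
    }
  }
  out
}

#' Per-site emission probabilities under the nine IBD states
#'
#' For every site l and state m computes
#' \eqn{e_{lm} = \sum_{g,h} P(D_a \mid g)\, P(D_b \mid h)\,
#' P(g, h \mid f_l, X = m)}, i.e. the probability of the observed sequencing
#' data of both individuals given the IBD state, with genotype uncertainty
#' integrated out through the genotype likelihoods.  The output inherits the
#' (arbitrary) per-site scale of the input likelihoods.
#'
#' @param glA,glB numeric L x 3 genotype-likelihood matrices for the two
#'   individuals (columns: genotypes 0, 1, 2).
#' @param f numeric vector of L allele frequencies in (0, 1).
#' @return numeric L x 9 matrix of emissions, columns J1..J9.
#' @examples
#' e <- pairEmissions(matrix(1/3, 1, 3), matrix(1/3, 1, 3), 0.4)
#' stopifnot(all(abs(e - 1/9) < 1e-12))
#' @export
pairEmissions <- function(glA, glB, f) {
  glA <- as.matrix(glA); glB <- as.matrix(glB)
  L <- length(f)
  if (nrow(glA) != L || nrow(glB) != L || ncol(glA) != 3 || ncol(glB) != 3)
    stop("GL matrices must be L x 3 with L matching the frequency vector")
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("allele frequencies must lie strictly inside (0, 1); filter sites first")
  badA <- rowSums(glA) == 0
  badB <- rowSums(glB) == 0
  if (any(badA | badB))
    stop("all-zero genotype-likelihood row(s) at site(s): ",
         paste(utils::head(which(badA | badB), 5), collapse = ", "))
  tab <- .assignmentTable()
  # powers of f and 1-f up to the largest block count
  fp <- cbind(1, f, f^2, f^3, f^4)
  qp <- cbind(1, 1 - f, (1 - f)^2, (1 - f)^3, (1 - f)^4)
  E <- matrix(0, L, 9, dimnames = list(NULL, paste0("J", 1:9)))
  for (m in 1:9) {
    acc <- numeric(L)
    for (as in tab[[m]]) {
      acc <- acc + fp[, as$k + 1L] * qp[, as$nb - as$k + 1L] *
        glA[, as$gA + 1L] * glB[, as$gB + 1L]
    }
    E[, m] <- acc
  }
  E
}

#' Composite log-likelihood of a Jacquard vector
#'
#' \eqn{\ell(J) = \sum_l \log \sum_m J_m e_{lm}} over unlinked biallelic
#' sites.  The function is concave in J (log of a linear function), so the
#' maximiser over the simplex is a global optimum.
#'
#' @param j numeric vector of 9 coefficients on the probability simplex.
#' @param E numeric L x 9 emission matrix from \code{\link{pairEmissions}}.
#' @return the log-likelihood (scale depends on the GL scale by an additive
#'   constant that does not affect maximisation).
#' @export
pairLogLik <- function(j, E) {
  .checkSimplex(j, 9)
  d <- as.vector(E %*% j)
  if (any(d <= 0)) {
    bad <- which(d <= 0)
    stop("degenerate site(s) with zero total emission under J: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  sum(log(d))
}

.checkSimplex <- function(j, n) {
  if (length(j) != n || any(j < -.SIMPLEX_TOL) ||
      abs(sum(j) - 1) > 1e-6)
    stop("coefficient vector must be ", n, " non-negative values summing to 1")
  invisible(TRUE)
}
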
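#' Estimate the pairwise 2D site frequency spectrum by EM
#'
#' Maximises \eqn{\sum_l \log \sum_{g,h} s_{gh}\, P(D_a \mid g)\,
#' P(D_b \mid h)} over the 9-cell probability simplex, i.e. the joint
#' genotype-class distribution of the pair integrated over genotype
#' uncertainty.  No population allele frequencies are needed.  The EM update
#' is the posterior mean of the per-site genotype-pair indicators and is run
#' through the same SQUAREM acceleration (with identical fallback rules) as
#' the Jacquard estimator.  The default start is uniform (1/9 per cell), so
#' the fit is deterministic; \code{seed} only seeds additional random
#' restarts when \code{nRestarts > 1}.
#'
#' @param glA,glB L x 3 genotype-likelihood matrices for the pair.
#' @param tol absolute log-likelihood convergence tolerance (default 1e-9).
#' @param maxIter maximum accepted cycles (default 5000).
#' @param nRestarts extra random Dirichlet starts beyond the uniform one
#'   (default 1, i.e. uniform start only).
#' @param seed integer seed for random restarts.
#' @param accelerate use SQUAREM acceleration (default \code{TRUE}).
#' @return An \linkS4class{Sfs2D}.  When every site is uninformative (all
#'   likelihood rows flat) the start point is returned with \code{flat = TRUE}.
#' @examples
#' gA <- matrix(c(1, 0, 0), 10, 3, byrow = TRUE)   # certain homozygote 0
#' gB <- matrix(c(0, 1, 0), 10, 3, byrow = TRUE)   # certain heterozygote
#' sfsMatrix(estimate2dSfs(gA, gB))                # point mass at (0, 1)
#' @export
estimate2dSfs <- function(glA, glB, tol = 1e-9, maxIter = 5000L,
                          nRestarts = 1L, seed = 1L, accelerate = TRUE) {
  glA <- as.matrix(glA); glB <- as.matrix(glB)
  if (nrow(glA) != nrow(glB))
    stop("GL tables have mismatched lengths: ", nrow(glA), " vs ", nrow(glB))
  stopifnot(ncol(glA) == 3, ncol(glB) == 3, nrow(glA) >= 1)
  # per-site likelihood of each of the 9 ordered genotype pairs, normalised
  # per site for numerical stability (the MLE is scale-invariant)
  K <- matrix(0, nrow(glA), 9)
  for (h in 0:2) for (g in 0:2)
    K[, g + 1L + 3L * h] <- glA[, g + 1L] * glB[, h + 1L]
  mx <- apply(K, 1, max)
  if (any(mx <= 0))
    stop("all-zero genotype-likelihood row(s) at site(s): ",
         paste(utils::head(which(mx <= 0), 5), collapse = ", "))
  K <- K / mx
  uniform <- rep(1 / 9, 9)
  flat <- all(abs(K - K[, 1]) < 1e-12)
  if (flat) {
    return(new("Sfs2D", sfs = .sfsToMatrix(uniform),
               loglik = .mixLogLik(uniform, K), nIter = 0L,
               converged = TRUE, flat = TRUE))
  }
  starts <- list(uniform)
  if (nRestarts > 1)
    starts <- c(starts, .withSeed(seed, replicate(nRestarts - 1L,
                                                  .rdirichlet1(9),
                                                  simplify = FALSE)))
  best <- NULL
  for (s in starts) {
    fit <- .emOptimize(s, K, tol, maxIter, accelerate)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  new("Sfs2D", sfs = .sfsToMatrix(best$j), loglik = best$loglik,
      nIter = best$nIter, converged = best$converged, flat = FALSE)
}

# cell vector is ordered (gA, gB) = (0,0),(1,0),(2,0),(0,1),... i.e. gA fast;
# reshape so rows index individual a's genotype
.sfsToMatrix <- function(s) {
  matrix(s, 3, 3, byrow = FALSE)
}
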
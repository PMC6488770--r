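# Run expr with a private, reproducible RNG stream; the caller's RNG state
# is untouched.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from a base seed and a stream index.
.childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 69069 + 12345 * as.double(k)) %% 2147483647)
}

.rdirichlet1 <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

#' One plain EM step for a mixture over the probability simplex
#'
#' The condensed-state mixture update
#' \eqn{J'_m = L^{-1} \sum_l J_m e_{lm} / \sum_{m'} J_{m'} e_{lm'}}; the
#' posterior mean of the per-site state indicators.  Also the update for the
#' 2D-SFS when \code{E} holds the 9 genotype-pair likelihood products.
#'
#' @param j current mixture weights (simplex vector matching \code{ncol(E)}).
#' @param E L x M per-site component likelihood matrix.
#' @return list with \code{j} (updated weights) and \code{loglik}
#'   (log-likelihood of the \emph{input} weights, a free by-product).
#' @export
emStep <- function(j, E) {
  .checkSimplex(j, ncol(E))
  d <- as.vector(E %*% j)
  if (any(d <= 0)) {
    stop("degenerate site(s) with zero weighted emission: ",
         paste(utils::head(which(d <= 0), 5), collapse = ", "))
  }
  # J'_m = j_m L^{-1} sum_l E[l,m] / d_l: two matrix-vector products
  jn <- j * as.vector(crossprod(E, 1 / d)) / nrow(E)
  list(j = jn / sum(jn), loglik = sum(log(d)))
}

# Project a proposal onto the simplex by flooring at eps and renormalising;
# returns NULL when the proposal is too far outside to be trusted.
.projectSimplex <- function(j, eps = 1e-12) {
  if (any(!is.finite(j))) return(NULL)
  j <- pmax(j, eps)
  j / sum(j)
}

#' One SQUAREM-accelerated EM cycle
#'
#' Squared iterative (SqS3) extrapolation: from two plain EM steps
#' \eqn{J^{(1)} = EM(J)}, \eqn{J^{(2)} = EM(J^{(1)})} form
#' \eqn{r = J^{(1)} - J}, \eqn{v = J^{(2)} - J^{(1)} - r} and step length
#' \eqn{\alpha = -\lVert r\rVert / \lVert v\rVert \le -1}, and propose the
#' extrapolation \eqn{J - 2\alpha r + \alpha^2 v}, projected back to the
#' simplex by flooring at 1e-12 and renormalising.  A proposal that leaves
#' the simplex or does not improve on \eqn{J^{(2)}} triggers step-halving of
#' \eqn{\alpha} toward \eqn{-1}; if no backtracked proposal improves, the
#' cycle falls back to the plain double step \eqn{J^{(2)}}.  Either way the
#' log-likelihood never decreases, preserving EM's monotone ascent.
#'
#' @inheritParams emStep
#' @return list with \code{j}, \code{loglik} (log-likelihood of the returned
#'   weights) and \code{accelerated} (logical).
#' @export
squaremStep <- function(j, E) {
  s1 <- emStep(j, E)
  s2 <- emStep(s1$j, E)
  j2 <- s2$j
  ll2 <- .mixLogLik(j2, E)
  r <- s1$j - j
  v <- j2 - s1$j - r
  nv <- sqrt(sum(v * v))
  nr <- sqrt(sum(r * r))
  if (nv < 1e-14 || nr < 1e-14)
    return(list(j = j2, loglik = ll2, accelerated = FALSE))
  alpha <- max(-nr / nv, -64)  # step-length cap for numerical safety
  for (bt in 1:5) {
    if (alpha >= -1) break
    jp <- .projectSimplex(j - 2 * alpha * r + alpha^2 * v)
    if (!is.null(jp)) {
      llp <- .mixLogLik(jp, E)
      if (is.finite(llp) && llp >= ll2)
        return(list(j = jp, loglik = llp, accelerated = TRUE))
    }
    alpha <- (alpha - 1) / 2
  }
  list(j = j2, loglik = ll2, accelerated = FALSE)
}

.mixLogLik <- function(j, E) {
  d <- as.vector(E %*% j)
  if (any(d <= 0)) return(-Inf)
  sum(log(d))
}

# Core optimiser shared by the Jacquard estimator and the 2D-SFS: maximises
# sum_l log sum_m j_m E[l, m] over the simplex from a given start.
.emOptimize <- function(start, E, tol, maxIter, accelerate = TRUE) {
  j <- start
  ll <- .mixLogLik(j, E)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    st <- if (accelerate) squaremStep(j, E) else emStep(j, E)
    if (!accelerate) st$loglik <- .mixLogLik(st$j, E)
    if (st$loglik < ll - 1e-9)  # ascent guard; fallback logic should prevent this
      stop("log-likelihood decreased during EM; numerical failure")
    dll <- st$loglik - ll
    j <- st$j
    ll <- st$loglik
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  list(j = j, loglik = ll, nIter = it, converged = converged)
}

#' Maximum-likelihood Jacquard coefficients from pair emissions
#'
#' Runs \code{nRestarts} accelerated-EM optimisations from independent
#' uniform-Dirichlet start points on the simplex, keeps the best, then
#' examines the boundary of the parameter space: coefficients within
#' \code{boundaryTol} of 0 are clamped to exactly 0 (and the vector
#' renormalised); the clamped solution is kept when its log-likelihood is not
#' worse than the unclamped one by more than \code{tol}.  Deterministic given
#' \code{seed}.  Because the composite log-likelihood is concave in J, every
#' start converges to the same optimal value; restarts guard the stopping
#' rule, and on a non-identifiable optimal face different starts may stop at
#' different coefficient vectors of equal likelihood.
#'
#' @param E L x 9 emission matrix from \code{\link{pairEmissions}}.
#' @param tol absolute log-likelihood convergence tolerance (default 1e-9).
#' @param maxIter maximum accepted cycles per start (default 5000).
#' @param nRestarts number of random start points (default 5).
#' @param seed integer seed controlling the start points.
#' @param accelerate use SQUAREM acceleration (default \code{TRUE}).
#' @param boundaryTol clamp threshold for boundary examination (default 1e-5).
#' @return A \linkS4class{JacquardEstimate}.
#' @examples
#' f <- runif(200, 0.1, 0.9)
#' gA <- t(sapply(f, function(p) as.numeric(1:3 == sample(3, 1))))
#' est <- estimateJacquard(pairEmissions(gA, gA, f), seed = 1)
#' @export
estimateJacquard <- function(E, tol = 1e-9, maxIter = 5000L, nRestarts = 5L,
                             seed = 1L, accelerate = TRUE,
                             boundaryTol = 1e-5) {
  stopifnot(is.matrix(E), ncol(E) == 9, nrow(E) >= 1, tol > 0, maxIter >= 1,
            nRestarts >= 1)
  starts <- .withSeed(seed, replicate(nRestarts, .rdirichlet1(9),
                                      simplify = FALSE))
  best <- NULL
  nIterTotal <- 0L
  for (s in starts) {
    fit <- .emOptimize(s, E, tol, maxIter, accelerate)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # boundary examination: clamp near-zero coefficients and re-evaluate
  j <- best$j
  near0 <- j < boundaryTol
  if (any(near0) && !all(near0)) {
    jc <- ifelse(near0, 0, j)
    jc <- jc / sum(jc)
    llc <- .mixLogLik(jc, E)
    if (llc >= best$loglik - tol) {
      best$j <- jc
      best$loglik <- llc
    }
  }
  new("JacquardEstimate", j = unname(best$j), loglik = best$loglik,
      nIter = best$nIter, converged = best$converged,
      nSitesUsed = nrow(E), seed = as.integer(seed),
      boundary = unname(best$j < boundaryTol))
}

#' Estimate the Jacquard coefficients for one pair from GLs and frequencies
#'
#' Convenience wrapper: filters sites whose frequency is outside (0, 1)
#' (reported via a message), builds the emission matrix and runs
#' \code{\link{estimateJacquard}}.  Sites where either individual has a flat
#' likelihood row carry no information but are harmless and retained.
#'
#' @param glA,glB L x 3 genotype-likelihood matrices.
#' @param freq numeric vector of L allele frequencies.
#' @param ... passed to \code{\link{estimateJacquard}}.
#' @return A \linkS4class{JacquardEstimate}.
#' @export
estimatePair <- function(glA, glB, freq, ...) {
  keep <- is.finite(freq) & freq > 0 & freq < 1
  if (!any(keep)) stop("no sites with frequency strictly inside (0, 1)")
  if (any(!keep))
    message(sum(!keep), " site(s) dropped: frequency outside (0, 1)")
  E <- pairEmissions(as.matrix(glA)[keep, , drop = FALSE],
                     as.matrix(glB)[keep, , drop = FALSE], freq[keep])
  estimateJacquard(E, ...)
}

#' Site-level bootstrap confidence intervals for all pair statistics
#'
#' Resamples sites with replacement (L draws per replicate), re-estimates the
#' Jacquard vector and, when \code{ibs = TRUE}, the pairwise 2D-SFS on each
#' replicate, and returns percentile intervals for every summary statistic.
#' Deterministic given \code{seed}.
#'
#' @inheritParams estimatePair
#' @param nBoot number of bootstrap replicates (default 200).
#' @param level two-sided confidence level in (0, 1) (default 0.95).
#' @param seed integer seed; replicate r uses a seed derived from it.
#' @param ibs also bootstrap the IBS statistics R0, R1, King (default
#'   \code{TRUE}).
#' @param ... passed to \code{\link{estimateJacquard}} (and the SFS EM).
#' @return data.frame with columns \code{statistic}, \code{point},
#'   \code{lower}, \code{upper}; attributes \code{nBoot}, \code{level},
#'   \code{seed}.
#' @export
bootstrapPair <- function(glA, glB, freq, nBoot = 200L, level = 0.95,
                          seed = 1L, ibs = TRUE, ...) {
  stopifnot(nBoot >= 1, level > 0, level < 1)
  glA <- as.matrix(glA); glB <- as.matrix(glB)
  keep <- is.finite(freq) & freq > 0 & freq < 1
  glA <- glA[keep, , drop = FALSE]; glB <- glB[keep, , drop = FALSE]
  freq <- freq[keep]
  L <- length(freq)
  E <- pairEmissions(glA, glB, freq)
  statsOf <- function(Esub, gA, gB) {
    est <- estimateJacquard(Esub, seed = seed, ...)
    s <- ibdStats(est@j)
    if (ibs) {
      sfs <- estimate2dSfs(gA, gB)
      s <- c(s, ibsStats(sfs))
    }
    s
  }
  point <- statsOf(E, glA, glB)
  reps <- matrix(NA_real_, nBoot, length(point),
                 dimnames = list(NULL, names(point)))
  for (r in seq_len(nBoot)) {
    idx <- .withSeed(.childSeed(seed, r),
                     sample.int(L, L, replace = TRUE))
    reps[r, ] <- statsOf(E[idx, , drop = FALSE],
                         glA[idx, , drop = FALSE], glB[idx, , drop = FALSE])
  }
  a <- (1 - level) / 2
  qs <- apply(reps, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE,
              names = FALSE)
  out <- data.frame(statistic = names(point), point = unname(point),
                    lower = qs[1, ], upper = qs[2, ], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "nBoot") <- as.integer(nBoot)
  attr(out, "level") <- level
  attr(out, "seed") <- as.integer(seed)
  out
}
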
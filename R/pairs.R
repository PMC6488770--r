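#' Estimate relatedness for many pairs of individuals
#'
#' Runs the Jacquard estimator (and, by default, the 2D-SFS IBS statistics)
#' for every requested pair and assembles the per-pair results table.  Work
#' is distributed over \code{threads} workers pair-by-pair; every pair uses a
#' seed derived from \code{seed} and its position in the (fixed) pair order,
#' and rows are collected in that order, so results are bit-identical for any
#' worker count.
#'
#' @param x a \linkS4class{GenotypeLikelihoods}.
#' @param freq per-site allele frequencies; defaults to the frequencies
#'   attached to \code{x}.
#' @param pairs two-column matrix or data.frame of sample identifiers;
#'   default all unordered pairs.
#' @param seed integer base seed.
#' @param nRestarts,tol,maxIter passed to \code{\link{estimateJacquard}}.
#' @param ibs also estimate the 2D-SFS and IBS statistics (default
#'   \code{TRUE}).
#' @param threads number of worker processes (forked; values > 1 change wall
#'   time only, never results).
#' @param verbose log one structured line per pair (default \code{TRUE}).
#' @return data.frame, one row per pair, following the output column
#'   contract of \code{\link{pairResultRow}}.
#' @export
relatePairs <- function(x, freq = NULL, pairs = NULL, seed = 1L,
                        nRestarts = 5L, tol = 1e-9, maxIter = 5000L,
                        ibs = TRUE, threads = 1L, verbose = TRUE) {
  stopifnot(is(x, "GenotypeLikelihoods"))
  if (is.null(freq)) freq <- alleleFreq(x)
  if (!length(freq))
    stop("no allele frequencies: supply freq= or attach them to the input")
  if (length(freq) != nSites(x))
    stop("frequency vector has ", length(freq), " entries but input has ",
         nSites(x), " sites")
  ids <- sampleIds(x)
  if (is.null(pairs)) {
    if (length(ids) < 2) stop("need at least two individuals")
    cmb <- utils::combn(ids, 2)
    pairs <- data.frame(ida = cmb[1, ], idb = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (ncol(pairs) < 2) stop("pairs needs two id columns")
    names(pairs)[1:2] <- c("ida", "idb")
    unknown <- setdiff(unique(c(pairs$ida, pairs$idb)), ids)
    if (length(unknown))
      stop("unknown sample id(s) in pairs: ", paste(unknown, collapse = ", "))
  }
  if (nrow(pairs) == 0) {
    out <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(.RESULT_COLS))),
      .RESULT_COLS)
    return(out)
  }
  onePair <- function(k) {
    ida <- pairs$ida[k]; idb <- pairs$idb[k]
    pseed <- .childSeed(seed, k)
    glA <- glMatrix(x, ida); glB <- glMatrix(x, idb)
    est <- suppressMessages(
      estimatePair(glA, glB, freq, tol = tol, maxIter = maxIter,
                   nRestarts = nRestarts, seed = pseed))
    sfs <- if (ibs) estimate2dSfs(glA, glB, tol = tol, maxIter = maxIter)
           else NULL
    pairResultRow(ida, idb, est, sfs)
  }
  ks <- seq_len(nrow(pairs))
  rows <- if (threads > 1L) {
    parallel::mclapply(ks, onePair, mc.cores = threads,
                       mc.preschedule = TRUE)
  } else lapply(ks, onePair)
  failed <- vapply(rows, function(r) !is.data.frame(r), logical(1))
  if (any(failed))
    stop("pair estimation failed: ",
         paste(utils::head(unlist(lapply(rows[failed], as.character)), 2),
               collapse = "; "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (verbose) {
    for (k in ks)
      message(sprintf(
        "pair %s-%s: L=%d iter=%d loglik=%.4f converged=%s seed=%d",
        out$ida[k], out$idb[k], out$nSites[k], out$nIter[k], out$loglik[k],
        out$converged[k], out$seed[k]))
  }
  out
}

#' Per-pair 2D-SFS and IBS statistics for many pairs
#'
#' @inheritParams relatePairs
#' @return data.frame with ida, idb, the nine SFS cells A..I (row-major,
#'   rows = individual a's genotype), R0, R1, King, loglik, nIter, converged.
#' @export
sfsPairs <- function(x, pairs = NULL, tol = 1e-9, maxIter = 5000L,
                     threads = 1L) {
  stopifnot(is(x, "GenotypeLikelihoods"))
  ids <- sampleIds(x)
  if (is.null(pairs)) {
    if (length(ids) < 2) stop("need at least two individuals")
    cmb <- utils::combn(ids, 2)
    pairs <- data.frame(ida = cmb[1, ], idb = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("ida", "idb")
  }
  cells <- LETTERS[1:9]
  if (nrow(pairs) == 0) {
    out <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 17)),
                           c("ida", "idb", cells, "R0", "R1", "King",
                             "loglik", "nIter", "converged"))
    return(out)
  }
  onePair <- function(k) {
    sfs <- estimate2dSfs(glMatrix(x, pairs$ida[k]),
                         glMatrix(x, pairs$idb[k]),
                         tol = tol, maxIter = maxIter)
    m <- sfs@sfs
    row <- data.frame(ida = pairs$ida[k], idb = pairs$idb[k],
                      stringsAsFactors = FALSE)
    # A..I row-major over (a-genotype rows, b-genotype columns)
    row <- cbind(row, stats::setNames(as.list(as.vector(t(m))), cells))
    cbind(row, as.list(ibsStats(sfs)),
          data.frame(loglik = sfs@loglik, nIter = sfs@nIter,
                     converged = sfs@converged))
  }
  ks <- seq_len(nrow(pairs))
  rows <- if (threads > 1L) parallel::mclapply(ks, onePair,
                                               mc.cores = threads)
          else lapply(ks, onePair)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
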
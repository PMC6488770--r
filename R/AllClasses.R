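#' @import methods
NULL

.SIMPLEX_TOL <- 1e-8

#' Per-site genotype likelihoods for a set of individuals
#'
#' Container for biallelic per-site genotype likelihoods
#' \eqn{P(D \mid G = 0, 1, 2)} for one or more diploid individuals, where the
#' genotype counts copies of the allele whose population frequency is carried
#' in \code{freq} (the second-listed allele of the source file).  Likelihood
#' scale is arbitrary per site; readers and the simulator normalise each row
#' to maximum 1.
#'
#' @slot gl list of numeric L x 3 matrices, one per individual, columns
#'   ordered as genotypes 0, 1, 2.
#' @slot siteIds character vector of L site identifiers (e.g. "chr_pos").
#' @slot sampleIds character vector naming the individuals.
#' @slot freq numeric vector of L population allele frequencies for the
#'   counted allele, or a zero-length vector when frequencies are not loaded.
#'
#' @examples
#' gl <- GenotypeLikelihoods(
#'   gl = list(a = matrix(1, 2, 3), b = matrix(1, 2, 3)),
#'   siteIds = c("1_1", "1_2"), freq = c(0.2, 0.5))
#' nSites(gl)
#' @export
setClass("GenotypeLikelihoods",
  representation(gl = "list", siteIds = "character",
                 sampleIds = "character", freq = "numeric"))

setValidity("GenotypeLikelihoods", function(object) {
  msg <- character()
  L <- length(object@siteIds)
  if (length(object@gl) != length(object@sampleIds))
    msg <- c(msg, "one GL matrix per sample is required")
  for (i in seq_along(object@gl)) {
    m <- object@gl[[i]]
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != L)
      msg <- c(msg, sprintf("GL matrix %d is not L x 3", i))
    else if (any(m < 0) || any(!is.finite(m)))
      msg <- c(msg, sprintf("GL matrix %d has negative or non-finite entries", i))
    else if (any(rowSums(m) == 0))
      msg <- c(msg, sprintf("GL matrix %d has an all-zero row", i))
  }
  if (length(object@freq) && length(object@freq) != L)
    msg <- c(msg, "freq length differs from number of sites")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeLikelihoods object
#'
#' @param gl list of L x 3 matrices (one per individual); names become sample
#'   identifiers unless \code{sampleIds} is given.
#' @param siteIds site identifiers; defaults to \code{"site1"...}.
#' @param sampleIds sample identifiers.
#' @param freq optional numeric vector of per-site allele frequencies.
#' @return A \linkS4class{GenotypeLikelihoods} object.
#' @export
GenotypeLikelihoods <- function(gl, siteIds = NULL, sampleIds = NULL,
                                freq = numeric()) {
  gl <- lapply(gl, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  L <- if (length(gl)) nrow(gl[[1]]) else 0L
  if (is.null(siteIds)) siteIds <- paste0("site", seq_len(L))
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(names(gl))) names(gl)
                 else paste0("ind", seq_along(gl))
  names(gl) <- NULL
  new("GenotypeLikelihoods", gl = gl, siteIds = as.character(siteIds),
      sampleIds = as.character(sampleIds), freq = as.numeric(freq))
}

#' @describeIn GenotypeLikelihoods-class number of sites
#' @param x,object a \code{GenotypeLikelihoods} object
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setMethod("nSites", "GenotypeLikelihoods", function(x) length(x@siteIds))

#' @describeIn GenotypeLikelihoods-class number of individuals
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "GenotypeLikelihoods", function(x) length(x@gl))

#' @describeIn GenotypeLikelihoods-class sample identifiers
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "GenotypeLikelihoods", function(x) x@sampleIds)

#' @describeIn GenotypeLikelihoods-class site identifiers
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @export
setMethod("siteIds", "GenotypeLikelihoods", function(x) x@siteIds)

#' @describeIn GenotypeLikelihoods-class per-site allele frequencies
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @export
setMethod("alleleFreq", "GenotypeLikelihoods", function(x) x@freq)

#' Extract one individual's L x 3 genotype-likelihood matrix
#'
#' @param x a \linkS4class{GenotypeLikelihoods} object
#' @param sample sample identifier or index
#' @return numeric L x 3 matrix.
#' @export
glMatrix <- function(x, sample) {
  stopifnot(is(x, "GenotypeLikelihoods"))
  if (is.character(sample)) {
    i <- match(sample, x@sampleIds)
    if (is.na(i)) stop("unknown sample: ", sample)
  } else i <- as.integer(sample)
  x@gl[[i]]
}

setMethod("show", "GenotypeLikelihoods", function(object) {
  cat(sprintf("GenotypeLikelihoods: %d sites, %d individuals%s\n",
              nSites(object), nSamples(object),
              if (length(object@freq)) ", frequencies attached" else ""))
  cat("  samples:", paste(utils::head(object@sampleIds, 6), collapse = ", "),
      if (nSamples(object) > 6) "..." else "", "\n")
})

#' Maximum-likelihood estimate of the condensed Jacquard coefficients
#'
#' Result of the accelerated-EM optimisation for one pair of individuals.
#'
#' @slot j numeric vector of 9 coefficients J1..J9 on the probability simplex.
#' @slot loglik composite log-likelihood at the estimate.
#' @slot nIter number of accepted EM/SQUAREM cycles of the best start.
#' @slot converged logical; \code{FALSE} if \code{maxIter} was exhausted.
#' @slot nSitesUsed number of sites entering the likelihood.
#' @slot seed integer seed that makes the run reproducible.
#' @slot boundary logical vector of 9; \code{TRUE} where the coefficient was
#'   clamped to the simplex boundary (estimate within tolerance of 0).
#' @export
setClass("JacquardEstimate",
  representation(j = "numeric", loglik = "numeric", nIter = "integer",
                 converged = "logical", nSitesUsed = "integer",
                 seed = "integer", boundary = "logical"))

setValidity("JacquardEstimate", function(object) {
  msg <- character()
  if (length(object@j) != 9) msg <- c(msg, "j must have length 9")
  else {
    if (any(object@j < -.SIMPLEX_TOL) || any(object@j > 1 + .SIMPLEX_TOL))
      msg <- c(msg, "coefficients outside [0, 1]")
    if (abs(sum(object@j) - 1) > .SIMPLEX_TOL)
      msg <- c(msg, "coefficients do not sum to 1")
  }
  if (length(object@boundary) != 9) msg <- c(msg, "boundary must have length 9")
  if (length(msg)) msg else TRUE
})

#' @describeIn JacquardEstimate-class the estimated coefficient vector
#' @param x,object a \code{JacquardEstimate}
#' @export
setGeneric("jacquard", function(x) standardGeneric("jacquard"))

#' @export
setMethod("jacquard", "JacquardEstimate", function(x) {
  stats::setNames(x@j, paste0("J", 1:9))
})

#' @export
setMethod("logLik", "JacquardEstimate", function(object, ...) {
  structure(object@loglik, df = 8, nobs = object@nSitesUsed, class = "logLik")
})

setMethod("show", "JacquardEstimate", function(object) {
  cat("JacquardEstimate (9 condensed identity coefficients)\n")
  print(round(jacquard(object), 4))
  s <- ibdStats(object@j)
  cat(sprintf("  rab = %.4f  Fa = %.4f  Fb = %.4f  theta = %.4f\n",
              s[["rab"]], s[["Fa"]], s[["Fb"]], s[["theta"]]))
  cat(sprintf("  loglik = %.4f over %d sites; %d iterations; %s\n",
              object@loglik, object@nSitesUsed, object@nIter,
              if (object@converged) "converged" else "NOT converged"))
  if (any(object@boundary))
    cat("  on boundary:", paste(paste0("J", which(object@boundary)),
                                collapse = " "), "\n")
})

#' Pairwise two-dimensional site frequency spectrum
#'
#' EM estimate of the 3 x 3 joint genotype-class distribution of a pair of
#' individuals, rows indexing individual a's genotype (0, 1, 2 copies of the
#' counted allele) and columns individual b's.  Cells are labelled A..I
#' row-major, so E is the double-heterozygote cell and C, G the
#' opposite-homozygote cells.
#'
#' @slot sfs numeric 3 x 3 matrix on the simplex.
#' @slot loglik log-likelihood at the estimate.
#' @slot nIter accepted EM cycles.
#' @slot converged logical.
#' @slot flat logical; \code{TRUE} when the data carried no information and
#'   the start point was returned.
#' @export
setClass("Sfs2D",
  representation(sfs = "matrix", loglik = "numeric", nIter = "integer",
                 converged = "logical", flat = "logical"))

setValidity("Sfs2D", function(object) {
  msg <- character()
  if (!all(dim(object@sfs) == c(3, 3))) msg <- c(msg, "sfs must be 3 x 3")
  else {
    if (any(object@sfs < -.SIMPLEX_TOL)) msg <- c(msg, "negative cells")
    if (abs(sum(object@sfs) - 1) > .SIMPLEX_TOL) msg <- c(msg, "cells do not sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Sfs2D-class the 3 x 3 spectrum matrix
#' @param x,object an \code{Sfs2D}
#' @export
setGeneric("sfsMatrix", function(x) standardGeneric("sfsMatrix"))

#' @export
setMethod("sfsMatrix", "Sfs2D", function(x) {
  m <- x@sfs
  dimnames(m) <- list(a = 0:2, b = 0:2)
  m
})

setMethod("show", "Sfs2D", function(object) {
  cat("Sfs2D: pairwise 2D site frequency spectrum\n")
  print(round(sfsMatrix(object), 4))
  s <- ibsStats(object)
  cat(sprintf("  R0 = %.4f  R1 = %.4f  King = %.4f  (loglik %.4f, %d iter)\n",
              s[["R0"]], s[["R1"]], s[["King"]], object@loglik, object@nIter))
})

#' Diploid pedigree for gene dropping and exact identity coefficients
#'
#' Individuals are stored in topological order (parents before children);
#' founders carry parent index 0.  Selfing is not supported.
#'
#' @slot id character identifiers.
#' @slot father integer index of the father (0 for founders).
#' @slot mother integer index of the mother (0 for founders).
#' @export
setClass("Pedigree",
  representation(id = "character", father = "integer", mother = "integer"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msg <- character()
  if (length(object@father) != n || length(object@mother) != n)
    msg <- c(msg, "id, father, mother must have equal length")
  if (anyDuplicated(object@id)) msg <- c(msg, "duplicated individual ids")
  both <- (object@father == 0L) == (object@mother == 0L)
  if (!all(both)) msg <- c(msg, "individuals must have two parents or none")
  idx <- seq_len(n)
  if (any(object@father > n | object@mother > n | object@father < 0L |
          object@mother < 0L))
    msg <- c(msg, "parent index out of range")
  else {
    if (any(object@father >= idx & object@father > 0L) ||
        any(object@mother >= idx & object@mother > 0L))
      msg <- c(msg, "parents must precede children (topological order)")
    nf <- object@father > 0L
    if (any(object@father[nf] == object@mother[nf]))
      msg <- c(msg, "selfing is not supported")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Pedigree
#'
#' @param id character identifiers, parents listed before their children.
#' @param father,mother identifiers (or \code{"0"}/\code{0}/\code{NA} for
#'   founders) of each individual's parents.
#' @return A \linkS4class{Pedigree}.
#' @examples
#' ped <- pedigree(c("f1", "f2", "kid"), c("0", "0", "f1"), c("0", "0", "f2"))
#' @export
pedigree <- function(id, father, mother) {
  id <- as.character(id)
  toIdx <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p == "0" | p == ""] <- NA
    i <- match(p, id)
    bad <- !is.na(p) & is.na(i)
    if (any(bad))
      stop("unknown parent id(s): ", paste(unique(p[bad]), collapse = ", "))
    i[is.na(i)] <- 0L
    as.integer(i)
  }
  new("Pedigree", id = id, father = toIdx(father), mother = toIdx(mother))
}

#' @describeIn Pedigree-class number of individuals
#' @param x,object a \code{Pedigree}
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @export
setMethod("nIndividuals", "Pedigree", function(x) length(x@id))

#' @describeIn Pedigree-class founder identifiers
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @export
setMethod("founders", "Pedigree", function(x) x@id[x@father == 0L])

setMethod("show", "Pedigree", function(object) {
  cat(sprintf("Pedigree: %d individuals (%d founders)\n",
              nIndividuals(object), length(founders(object))))
  df <- as.data.frame(object)
  print(utils::head(df, 10))
  if (nrow(df) > 10) cat("  ...\n")
})

#' @export
setMethod("as.data.frame", "Pedigree", function(x, ...) {
  data.frame(id = x@id,
             father = ifelse(x@father == 0L, "0", x@id[pmax(x@father, 1L)]),
             mother = ifelse(x@mother == 0L, "0", x@id[pmax(x@mother, 1L)]),
             stringsAsFactors = FALSE)
})
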
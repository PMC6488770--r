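#' Read a beagle-style genotype-likelihood table
#'
#' Whitespace-separated text (optionally gzip-compressed): a header line,
#' then one row per site with a marker id, two allele codes, and three
#' likelihood columns per individual (genotypes 0, 1, 2 copies of the
#' second-listed allele).  Values may be linear-scale likelihoods or log10
#' likelihoods; negative entries trigger automatic log10 interpretation.
#' Every row is normalised to maximum 1 on read.
#'
#' @param path file path (".gz" accepted).
#' @param scale \code{"auto"} (default), \code{"linear"} or \code{"log10"}.
#' @return A \linkS4class{GenotypeLikelihoods} (no frequencies attached).
#' @seealso \code{\link{readFrequencies}}, \code{\link{writeBeagleGL}}
#' @export
readBeagleGL <- function(path, scale = c("auto", "linear", "log10")) {
  scale <- match.arg(scale)
  nf <- utils::count.fields(path, comment.char = "")
  if (length(nf) < 2) stop("beagle file has no data rows: ", path)
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged beagle file: row ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  if (nf[1] < 6 || (nf[1] - 3) %% 3 != 0)
    stop("beagle file must have 3 site columns plus 3 columns per ",
         "individual; got ", nf[1], " columns")
  hdr <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  tab <- utils::read.table(path, header = FALSE, skip = 1,
                           colClasses = c("character", "character",
                                          "character",
                                          rep("numeric", nf[1] - 3)))
  nInd <- (nf[1] - 3) %/% 3
  vals <- as.matrix(tab[, -(1:3), drop = FALSE])
  if (any(!is.finite(vals)))
    stop("non-numeric or non-finite genotype likelihood in ", path)
  if (scale == "auto") scale <- if (any(vals < 0)) "log10" else "linear"
  if (scale == "log10") vals <- 10^vals
  if (any(vals < 0)) stop("negative linear-scale likelihoods in ", path)
  sampleNames <- hdr[seq(4, length(hdr), by = 3)]
  if (anyDuplicated(sampleNames) || any(sampleNames == ""))
    sampleNames <- paste0("ind", seq_len(nInd))
  gl <- lapply(seq_len(nInd), function(i) {
    m <- vals[, (3 * i - 2):(3 * i), drop = FALSE]
    mx <- apply(m, 1, max)
    if (any(mx == 0))
      stop("all-zero likelihood row for individual ", i, " at site row ",
           which(mx == 0)[1])
    m / mx
  })
  names(gl) <- sampleNames
  GenotypeLikelihoods(gl, siteIds = tab[[1]], sampleIds = sampleNames)
}

#' Write genotype likelihoods in beagle format
#'
#' @param x a \linkS4class{GenotypeLikelihoods} or a named list of L x 3
#'   matrices.
#' @param path output path; a ".gz" suffix writes gzip-compressed text.
#' @param alleles two allele codes written for every site (beagle
#'   convention: 0 = A, 1 = C, 2 = G, 3 = T); genotypes count copies of the
#'   second.
#' @param digits significant digits (default 6).
#' @return the path, invisibly.
#' @export
writeBeagleGL <- function(x, path, alleles = c(0, 1), digits = 6) {
  if (!is(x, "GenotypeLikelihoods")) x <- GenotypeLikelihoods(x)
  L <- nSites(x)
  cols <- list(marker = siteIds(x), allele1 = rep(alleles[1], L),
               allele2 = rep(alleles[2], L))
  for (i in seq_len(nSamples(x))) {
    m <- glMatrix(x, i)
    for (g in 1:3)
      cols[[length(cols) + 1L]] <- formatC(m[, g], digits = digits,
                                           format = "g")
  }
  hdr <- c("marker", "allele1", "allele2",
           rep(sampleIds(x), each = 3))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a plain-text allele-frequency file
#'
#' One numeric frequency per line, in the same order as the sites of the
#' genotype-likelihood input.  Frequencies of exactly 0 or 1 are tolerated
#' here (the estimator drops those sites with a message); values outside
#' [0, 1] or non-numeric lines are errors.
#'
#' @param path file path.
#' @param nExpected optional expected number of sites; a mismatch is an
#'   error naming both lengths.
#' @return numeric vector of frequencies.
#' @export
readFrequencies <- function(path, nExpected = NULL) {
  f <- tryCatch(scan(path, what = numeric(), quiet = TRUE),
                error = function(e) stop("non-numeric frequency file ",
                                         path, ": ", conditionMessage(e)))
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("frequencies must lie in [0, 1]: ", path)
  if (!is.null(nExpected) && length(f) != nExpected)
    stop("frequency file has ", length(f), " entries but ", nExpected,
         " sites were loaded")
  f
}

#' Read genotype likelihoods from a VCF
#'
#' Loads biallelic single-nucleotide records carrying the \code{PL}
#' (phred-scaled, \eqn{10^{-x/10}}) or \code{GL} (log10-scaled,
#' \eqn{10^{x}}) FORMAT field and converts them to linear-scale likelihoods
#' normalised to maximum 1 per site.  Multi-allelic and non-SNV records are
#' skipped and counted (message).  Missing per-sample values become flat
#' rows.  Genotypes count copies of the ALT allele, so frequencies supplied
#' alongside must refer to ALT; with \code{afFromInfo = TRUE} the INFO/AF
#' tag is attached as the frequency vector.
#'
#' @param path VCF file (plain or bgzip; convert BCF with
#'   \code{bcftools view} first).
#' @param tag \code{"PL"} or \code{"GL"}.
#' @param afFromInfo attach INFO/AF as the per-site frequency vector.
#' @return A \linkS4class{GenotypeLikelihoods}; site ids are
#'   \code{"chrom_pos"}.
#' @export
readVcfGL <- function(path, tag = c("PL", "GL"), afFromInfo = FALSE) {
  tag <- match.arg(tag)
  vcf <- VariantAnnotation::readVcf(path)
  if (!tag %in% rownames(VariantAnnotation::geno(
        VariantAnnotation::header(vcf))))
    stop("FORMAT tag ", tag, " absent from ", path)
  snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  nSkip <- sum(!snv)
  if (nSkip > 0)
    message(nSkip, " multi-allelic or non-SNV record(s) skipped")
  vcf <- vcf[snv, ]
  L <- length(snv) - nSkip
  if (L == 0) stop("no biallelic SNV records in ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  sites <- paste(as.character(GenomeInfoDb::seqnames(rr)),
                 BiocGenerics::start(rr), sep = "_")
  raw <- VariantAnnotation::geno(vcf)[[tag]]
  samples <- colnames(raw)
  toLinear <- function(x) {
    if (tag == "PL") 10^(-x / 10) else 10^x
  }
  getTriple <- function(site, smp) {
    v <- if (is.list(raw)) raw[[site, smp]] else raw[site, smp, ]
    v <- suppressWarnings(as.numeric(v))
    if (length(v) != 3 || any(is.na(v))) rep(1, 3) else toLinear(v)
  }
  gl <- lapply(seq_along(samples), function(smp) {
    m <- t(vapply(seq_len(L), function(site) getTriple(site, smp),
                  numeric(3)))
    m / apply(m, 1, max)
  })
  names(gl) <- samples
  freq <- numeric()
  if (afFromInfo) {
    af <- VariantAnnotation::info(vcf)$AF
    if (is.null(af)) stop("INFO/AF tag absent from ", path)
    freq <- vapply(seq_len(L), function(i) {
      v <- if (is.list(af)) af[[i]] else af[i]
      as.numeric(v[1])
    }, numeric(1))
  }
  GenotypeLikelihoods(gl, siteIds = sites, sampleIds = samples, freq = freq)
}

#' Write a per-pair results table
#'
#' Tab-separated, one row per pair, deterministic column order (the output
#' contract of \code{\link{pairResultRow}}), floats at 6 significant digits.
#'
#' @param rows data.frame of stacked \code{\link{pairResultRow}} rows.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeResults <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  missing <- setdiff(.RESULT_COLS, names(rows))
  if (length(missing))
    stop("result table lacks column(s): ", paste(missing, collapse = ", "))
  out <- rows[, .RESULT_COLS]
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- formatC(out[[nm]], digits = 6, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
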
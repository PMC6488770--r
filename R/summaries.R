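#' IBD-based relatedness summaries from a Jacquard vector
#'
#' Linear combinations of the condensed identity coefficients:
#' \itemize{
#'   \item \code{rab}: relatedness, \eqn{J_1 + J_7 + 0.75(J_3 + J_5) + 0.5 J_8}
#'     (proportion of homologous alleles IBD)
#'   \item \code{Fa}, \code{Fb}: per-individual inbreeding coefficients,
#'     \eqn{J_1+J_2+J_3+J_4} and \eqn{J_1+J_2+J_5+J_6}
#'   \item \code{theta}: kinship, \eqn{J_1 + 0.5(J_3+J_5+J_7) + 0.25 J_8}
#'   \item \code{F12} = \eqn{J_1 + 0.5 J_3}; \code{F21} = \eqn{J_1 + 0.5 J_5}
#'   \item \code{fraternity} = \eqn{J_2 + J_7}; \code{identity} = \eqn{J_1};
#'     \code{zygosity} = \eqn{J_1 + J_2 + J_7}
#'   \item \code{ibd23} = \eqn{J_1+J_2+J_3+J_5+J_7 + 0.5(J_4+J_6+J_8)};
#'     \code{Fdiff} = \eqn{0.5(J_4 - J_6)}
#' }
#' On diallelic markers the nine coefficients are not always individually
#' identifiable, but \code{rab}, \code{Fa}, \code{Fb}, \code{theta},
#' \code{ibd23} and \code{Fdiff} are invariant across equally likely
#' solutions.
#'
#' @param j numeric vector of 9 coefficients on the simplex, or a
#'   \linkS4class{JacquardEstimate}.
#' @return named numeric vector of the 11 statistics.
#' @examples
#' ibdStats(c(0, 0, 0, 0, 0, 0, 0, 0.25, 0.75))["rab"]  # first cousins: 0.125
#' @export
ibdStats <- function(j) {
  if (is(j, "JacquardEstimate")) j <- j@j
  j <- unname(j)
  .checkSimplex(j, 9)
  c(rab        = j[1] + j[7] + 0.75 * (j[3] + j[5]) + 0.5 * j[8],
    Fa         = j[1] + j[2] + j[3] + j[4],
    Fb         = j[1] + j[2] + j[5] + j[6],
    theta      = j[1] + 0.5 * (j[3] + j[5] + j[7]) + 0.25 * j[8],
    F12        = j[1] + 0.5 * j[3],
    F21        = j[1] + 0.5 * j[5],
    fraternity = j[2] + j[7],
    identity   = j[1],
    zygosity   = j[1] + j[2] + j[7],
    ibd23      = j[1] + j[2] + j[3] + j[5] + j[7] +
                 0.5 * (j[4] + j[6] + j[8]),
    Fdiff      = 0.5 * (j[4] - j[6]))
}

#' IBS statistics from the pairwise 2D site frequency spectrum
#'
#' With the 3 x 3 spectrum labelled A..I row-major (rows: individual a's
#' genotype 0, 1, 2; columns: individual b's), E is the double-heterozygote
#' cell and C, G the opposite-homozygote cells, and
#' \deqn{R_0 = (C+G)/E, \quad R_1 = E/(B+D+H+F+C+G),}
#' \deqn{King = [E - 2(C+G)] / (B+D+H+F+2E).}
#' These statistics need no population allele frequencies and assume the two
#' individuals are not inbred.  An undefined ratio (zero denominator) is
#' returned as \code{NaN} rather than an error so that tabulation over many
#' pairs can continue.
#'
#' @param s a \linkS4class{Sfs2D} or a non-negative 3 x 3 matrix (any positive
#'   scale; the statistics are scale-invariant).
#' @return named numeric vector \code{R0}, \code{R1}, \code{King}.
#' @examples
#' s <- matrix(c(4, 1, 0, 1, 2, 1, 0, 1, 4), 3, 3) / 14
#' ibsStats(s)
#' @export
ibsStats <- function(s) {
  if (is(s, "Sfs2D")) s <- s@sfs
  s <- as.matrix(s)
  stopifnot(all(dim(s) == c(3, 3)), all(s >= 0))
  B <- s[1, 2]; C <- s[1, 3]
  D <- s[2, 1]; E <- s[2, 2]; F <- s[2, 3]
  G <- s[3, 1]; H <- s[3, 2]
  safe <- function(num, den) if (den <= 0) NaN else num / den
  c(R0   = safe(C + G, E),
    R1   = safe(E, B + D + H + F + C + G),
    King = safe(E - 2 * (C + G), B + D + H + F + 2 * E))
}

# Column contract for per-pair result tables.
.RESULT_COLS <- c("ida", "idb", paste0("J", 1:9),
                  "rab", "Fa", "Fb", "theta", "F12", "F21", "fraternity",
                  "identity", "zygosity", "ibd23", "Fdiff",
                  "R0", "R1", "King",
                  "loglik", "nSites", "nIter", "converged", "seed")

#' Assemble the result row for one pair
#'
#' @param ida,idb sample identifiers.
#' @param est a \linkS4class{JacquardEstimate}.
#' @param sfs optional \linkS4class{Sfs2D}; when absent the IBS columns are
#'   \code{NA}.
#' @return one-row data.frame following the output column contract
#'   (J1..J9, rab, Fa, Fb, theta, F12, F21, fraternity, identity, zygosity,
#'   ibd23, Fdiff, R0, R1, King, loglik, nSites, nIter, converged, seed).
#' @export
pairResultRow <- function(ida, idb, est, sfs = NULL) {
  j <- as.list(stats::setNames(est@j, paste0("J", 1:9)))
  ibd <- as.list(ibdStats(est@j))
  ibs <- if (is.null(sfs)) list(R0 = NA_real_, R1 = NA_real_, King = NA_real_)
         else as.list(ibsStats(sfs))
  df <- data.frame(ida = ida, idb = idb, stringsAsFactors = FALSE)
  df <- cbind(df, j, ibd, ibs,
              data.frame(loglik = est@loglik, nSites = est@nSitesUsed,
                         nIter = est@nIter, converged = est@converged,
                         seed = est@seed))
  df[, .RESULT_COLS]
}
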
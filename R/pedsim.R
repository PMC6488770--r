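#' Read a pedigree from a tab-separated trio file
#'
#' Expected format: one header line, then one row per individual with columns
#' \code{id}, \code{father}, \code{mother}; \code{0} marks a founder parent.
#' Rows must list parents before children.
#'
#' @param path file path.
#' @return A \linkS4class{Pedigree}.
#' @seealso \code{\link{writePedigree}}
#' @export
readPedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 3)
    stop("pedigree file needs columns id, father, mother: ", path)
  pedigree(df[[1]], df[[2]], df[[3]])
}

#' Write a pedigree as a tab-separated trio file
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param path output path.
#' @export
writePedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The three built-in validation pedigrees
#'
#' Fixed pedigrees used to validate the estimator, each defining an analysis
#' pair (attribute \code{pair}):
#' \describe{
#'   \item{Scenario 1}{a grandparental founder couple (gf, gm) with two
#'     children p1, p2; a = p1 x founder, b = p2 x founder.  Pair (a, b):
#'     outbred first cousins, expected (J8, J9) = (0.25, 0.75), R = 0.125.}
#'   \item{Scenario 2}{as Scenario 1 on a's side, but b = gf x p2, a
#'     father-daughter mating, so b's parents are related as parent-child and
#'     F_b = 0.25.  Pair (a, b): expected (J5, J6, J8, J9) =
#'     (0.0625, 0.1875, 0.375, 0.375), R = 0.234375.}
#'   \item{Scenario 3}{b as in Scenario 2 (now individual 1); d2 = p2 x
#'     founder and a2 = p1 x d2, an uncle-niece mating (kinship 1/8,
#'     equivalent to grandparent-grandchild), so F_a2 = 0.125.  Pair (b, a2):
#'     R = 0.3828125, F1 = 0.25, F2 = 0.125.}
#' }
#'
#' @param scenario 1, 2 or 3.
#' @return A \linkS4class{Pedigree} with attribute \code{pair}, the character
#'   ids of the analysis pair (individual 1 first).
#' @examples
#' ped <- scenarioPedigree(1)
#' expectedJacquard(ped, attr(ped, "pair")[1], attr(ped, "pair")[2])
#' @export
scenarioPedigree <- function(scenario) {
  scenario <- as.integer(scenario)
  ped <- switch(as.character(scenario),
    "1" = {
      p <- pedigree(
        id     = c("gf", "gm", "s1", "s2", "p1", "p2", "a", "b"),
        father = c("0",  "0",  "0",  "0",  "gf", "gf", "p1", "p2"),
        mother = c("0",  "0",  "0",  "0",  "gm", "gm", "s1", "s2"))
      attr(p, "pair") <- c("a", "b"); p
    },
    "2" = {
      p <- pedigree(
        id     = c("gf", "gm", "s1", "p1", "p2", "a", "b"),
        father = c("0",  "0",  "0",  "gf", "gf", "p1", "gf"),
        mother = c("0",  "0",  "0",  "gm", "gm", "s1", "p2"))
      attr(p, "pair") <- c("a", "b"); p
    },
    "3" = {
      p <- pedigree(
        id     = c("gf", "gm", "s1", "p1", "p2", "b", "d2", "a2"),
        father = c("0",  "0",  "0",  "gf", "gf", "gf", "p2", "p1"),
        mother = c("0",  "0",  "0",  "gm", "gm", "p2", "s1", "d2"))
      attr(p, "pair") <- c("b", "a2"); p
    },
    stop("scenario must be 1, 2 or 3"))
  ped
}

#' Sample site allele frequencies with a minor-allele-frequency filter
#'
#' L independent draws from Uniform(maf, 1 - maf) — applying the MAF filter
#' at sampling time, equivalent in distribution to post-hoc rejection.
#'
#' @param L number of sites.
#' @param maf minor-allele-frequency cutoff in (0, 0.5).
#' @param seed integer seed.
#' @return numeric vector of L frequencies.
#' @export
sampleFrequencies <- function(L, maf = 0.1, seed = 1L) {
  stopifnot(L >= 1, maf > 0, maf < 0.5)
  .withSeed(seed, stats::runif(L, maf, 1 - maf))
}

#' Gene dropping: simulate genotypes down a pedigree with IBD bookkeeping
#'
#' Founders receive Hardy-Weinberg genotypes (two independent Bernoulli(f_l)
#' draws per site) and two globally unique ancestral-allele labels; each
#' non-founder inherits, independently per site, one uniformly chosen allele
#' (with its label) from each parent.  Sites are unlinked: no linkage
#' disequilibrium is modelled.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param freq numeric vector of L allele frequencies in (0, 1).
#' @param seed integer seed.
#' @return list with \code{genotypes} (L x N integer matrix of counts of
#'   allele 1, columns named by individual), \code{labels} (per-individual
#'   list of L x 2 integer founder-allele label matrices), \code{freq}, and
#'   \code{ped}.
#' @export
geneDrop <- function(ped, freq, seed = 1L) {
  stopifnot(is(ped, "Pedigree"), all(freq > 0 & freq < 1))
  validObject(ped)
  L <- length(freq)
  n <- nIndividuals(ped)
  .withSeed(seed, {
    alleles <- vector("list", n)  # L x 2 matrices of 0/1
    labels <- vector("list", n)   # L x 2 matrices of founder-allele ids
    for (i in seq_len(n)) {
      fa <- ped@father[i]; mo <- ped@mother[i]
      if (fa == 0L) {
        alleles[[i]] <- cbind(stats::rbinom(L, 1L, freq),
                              stats::rbinom(L, 1L, freq))
        labels[[i]] <- cbind(rep.int(2L * i - 1L, L), rep.int(2L * i, L))
      } else {
        pickF <- stats::rbinom(L, 1L, 0.5) + 1L
        pickM <- stats::rbinom(L, 1L, 0.5) + 1L
        iF <- cbind(seq_len(L), pickF)
        iM <- cbind(seq_len(L), pickM)
        alleles[[i]] <- cbind(alleles[[fa]][iF], alleles[[mo]][iM])
        labels[[i]] <- cbind(labels[[fa]][iF], labels[[mo]][iM])
      }
    }
    genotypes <- vapply(alleles, function(a) a[, 1] + a[, 2], integer(L))
    if (L == 1L) genotypes <- matrix(genotypes, 1L, n)
    colnames(genotypes) <- ped@id
    names(labels) <- ped@id
    list(genotypes = genotypes, labels = labels, freq = freq, ped = ped)
  })
}

# condensed IBD state (1..9) of a pair given the four allele labels
.condensedState <- function(a1, a2, b1, b2) {
  ia <- a1 == a2; ib <- b1 == b2
  m11 <- a1 == b1; m12 <- a1 == b2; m21 <- a2 == b1; m22 <- a2 == b2
  ncross <- m11 + m12 + m21 + m22
  st <- integer(length(a1))
  st[ia & ib & m11] <- 1L
  st[ia & ib & !m11] <- 2L
  st[ia & !ib & (m11 | m12)] <- 3L
  st[ia & !ib & !(m11 | m12)] <- 4L
  st[!ia & ib & (m11 | m21)] <- 5L
  st[!ia & ib & !(m11 | m21)] <- 6L
  st[!ia & !ib & ncross == 2L] <- 7L
  st[!ia & !ib & ncross == 1L] <- 8L
  st[!ia & !ib & ncross == 0L] <- 9L
  st
}

#' Realised condensed IBD state at every site for a pair
#'
#' Reads the founder-allele labels of a \code{\link{geneDrop}} result and
#' classifies each site into one of the nine condensed identity states.
#'
#' @param drop result of \code{\link{geneDrop}}.
#' @param a,b individual identifiers.
#' @return integer vector of states 1..9, one per site.
#' @export
ibdStates <- function(drop, a, b) {
  la <- drop$labels[[a]]; lb <- drop$labels[[b]]
  if (is.null(la) || is.null(lb)) stop("unknown individual id")
  .condensedState(la[, 1], la[, 2], lb[, 1], lb[, 2])
}

#' Simulate sequencing reads and genotype likelihoods
#'
#' Per site and individual the read depth is Poisson(\code{depth}); each read
#' samples one of the two chromosomes uniformly and is mis-read with
#' probability \code{error}.  The genotype likelihood of hypothesis g is the
#' product over reads of the per-read probability
#' \eqn{c_g (1-e) + (1 - c_g) e} with \eqn{c_g = g/2} the chance the read's
#' true base is allele 1.  Sites with zero reads yield a flat row.  Rows are
#' normalised to maximum 1.
#'
#' @param genotypes integer vector (one individual) or L x N matrix of
#'   genotypes 0/1/2, e.g. \code{geneDrop(...)$genotypes}.
#' @param depth mean sequencing depth (Poisson parameter), >= 0.
#' @param error symmetric per-base error rate in [0, 0.5).
#' @param seed integer seed.
#' @return for a vector input an L x 3 GL matrix; for a matrix input a named
#'   list of L x 3 GL matrices.
#' @export
simulateGL <- function(genotypes, depth = 4, error = 0.001, seed = 1L) {
  stopifnot(depth >= 0, error >= 0, error < 0.5)
  if (is.matrix(genotypes)) {
    nm <- colnames(genotypes)
    out <- lapply(seq_len(ncol(genotypes)), function(i)
      simulateGL(genotypes[, i], depth, error, .childSeed(seed, i)))
    names(out) <- nm
    return(out)
  }
  g <- as.integer(genotypes)
  stopifnot(all(g %in% 0:2))
  L <- length(g)
  .withSeed(seed, {
    k <- stats::rpois(L, depth)
    pAlt <- g / 2 * (1 - error) + (1 - g / 2) * error
    nAlt <- stats::rbinom(L, k, pAlt)
    gl <- matrix(1, L, 3)
    for (hyp in 0:2) {
      p <- hyp / 2 * (1 - error) + (1 - hyp / 2) * error
      # 0^0 = 1 handles the boundary hypotheses at error = 0
      gl[, hyp + 1L] <- p^nAlt * (1 - p)^(k - nAlt)
    }
    gl / apply(gl, 1, max)
  })
}

#' Exact condensed Jacquard coefficients from a pedigree
#'
#' Enumerates every meiosis outcome of the pedigree (each non-founder draws
#' one of two alleles from each parent: \eqn{2^{2n}} equiprobable
#' transmission patterns for n non-founders), tracks founder-allele labels,
#' classifies the pair's four alleles into the nine condensed identity states
#' and averages.  Exact, not Monte Carlo.  A self-pair (\code{a == b}) is
#' allowed and yields J7 = 1 for an outbred individual.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param a,b individual identifiers (may be equal).
#' @param maxMeioses enumeration budget; pedigrees with more than this many
#'   meioses (2 per non-founder) raise an error suggesting Monte Carlo gene
#'   dropping via \code{\link{geneDrop}} + \code{\link{ibdStates}}.
#' @return named numeric vector J1..J9 summing to 1.
#' @examples
#' ped <- scenarioPedigree(1)
#' expectedJacquard(ped, "a", "b")  # (J8, J9) = (0.25, 0.75)
#' @export
expectedJacquard <- function(ped, a, b, maxMeioses = 20L) {
  stopifnot(is(ped, "Pedigree"))
  validObject(ped)
  ia <- match(a, ped@id); ib <- match(b, ped@id)
  if (is.na(ia) || is.na(ib)) stop("unknown individual id(s)")
  nonf <- which(ped@father != 0L)
  nm <- 2L * length(nonf)
  if (nm > maxMeioses)
    stop("pedigree has ", nm, " meioses, above the enumeration budget of ",
         maxMeioses, "; use geneDrop() + ibdStates() for a Monte Carlo estimate")
  npat <- 2^nm
  lab1 <- vector("list", nIndividuals(ped))
  lab2 <- vector("list", nIndividuals(ped))
  mcol <- 0L
  pat <- seq_len(npat) - 1L
  for (i in seq_len(nIndividuals(ped))) {
    fa <- ped@father[i]; mo <- ped@mother[i]
    if (fa == 0L) {
      lab1[[i]] <- rep.int(2L * i - 1L, npat)
      lab2[[i]] <- rep.int(2L * i, npat)
    } else {
      c1 <- bitwAnd(pat, bitwShiftL(1L, mcol)) > 0L
      c2 <- bitwAnd(pat, bitwShiftL(1L, mcol + 1L)) > 0L
      mcol <- mcol + 2L
      lab1[[i]] <- ifelse(c1, lab2[[fa]], lab1[[fa]])
      lab2[[i]] <- ifelse(c2, lab2[[mo]], lab1[[mo]])
    }
  }
  st <- .condensedState(lab1[[ia]], lab2[[ia]], lab1[[ib]], lab2[[ib]])
  stats::setNames(tabulate(st, 9) / npat, paste0("J", 1:9))
}

#' Simulate a full validation dataset for one scenario
#'
#' Draws site frequencies, gene-drops the scenario pedigree, simulates
#' sequencing for the analysis pair and packages the genotype likelihoods
#' with the true frequencies, true genotypes and the exact pedigree-expected
#' Jacquard coefficients.
#'
#' @param scenario 1, 2 or 3, or a \linkS4class{Pedigree} with a
#'   \code{pair} attribute.
#' @param nSites number of unlinked biallelic sites.
#' @param depth mean sequencing depth.
#' @param error per-base error rate.
#' @param maf minor-allele-frequency cutoff for the frequency draw.
#' @param seed integer seed; frequency draw, gene drop and read simulation
#'   use derived sub-seeds.
#' @return list with \code{gl} (a \linkS4class{GenotypeLikelihoods} for the
#'   pair, frequencies attached), \code{genotypes} (true genotypes of the
#'   pair), \code{expectedJ} (exact coefficients), \code{ped}, \code{pair}.
#' @export
simulateScenario <- function(scenario, nSites = 10000L, depth = 4,
                             error = 0.001, maf = 0.1, seed = 1L) {
  ped <- if (is(scenario, "Pedigree")) scenario else scenarioPedigree(scenario)
  pair <- attr(ped, "pair")
  if (is.null(pair) || length(pair) != 2)
    stop("pedigree must carry a 'pair' attribute of two individual ids")
  freq <- sampleFrequencies(nSites, maf, .childSeed(seed, 1L))
  drop <- geneDrop(ped, freq, .childSeed(seed, 2L))
  g <- drop$genotypes[, pair, drop = FALSE]
  gl <- simulateGL(g, depth, error, .childSeed(seed, 3L))
  glo <- GenotypeLikelihoods(gl, siteIds = paste0("1_", seq_len(nSites)),
                             sampleIds = pair, freq = freq)
  list(gl = glo, genotypes = g,
       expectedJ = expectedJacquard(ped, pair[1], pair[2]),
       ped = ped, pair = pair)
}
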
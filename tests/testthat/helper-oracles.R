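# Independent brute-force oracles and small fixture builders.

# The nine condensed states written out as set partitions of the four gene
# slots, independent of the package's internal encoding.
oraclePartitions <- list(
  J1 = list(c("a1", "a2", "b1", "b2")),
  J2 = list(c("a1", "a2"), c("b1", "b2")),
  J3 = list(c("a1", "a2", "b1"), c("b2")),
  J4 = list(c("a1", "a2"), c("b1"), c("b2")),
  J5 = list(c("a1", "b1", "b2"), c("a2")),
  J6 = list(c("a1"), c("a2"), c("b1", "b2")),
  J7 = list(c("a1", "b1"), c("a2", "b2")),
  J8 = list(c("a1", "b1"), c("a2"), c("b2")),
  J9 = list(c("a1"), c("a2"), c("b1"), c("b2"))
)

# Brute force genotype-pair distribution for one state: enumerate all 2^4
# allele assignments to the slots, keep those constant within each IBD
# block, and weight by one frequency factor per distinct block.
oraclePairPrior <- function(f) {
  out <- array(0, c(9, 3, 3))
  slots <- c("a1", "a2", "b1", "b2")
  grid <- expand.grid(a1 = 0:1, a2 = 0:1, b1 = 0:1, b2 = 0:1)
  for (m in 1:9) {
    blocks <- oraclePartitions[[m]]
    for (r in seq_len(nrow(grid))) {
      al <- as.integer(grid[r, slots])
      names(al) <- slots
      ok <- all(vapply(blocks,
                       function(bl) length(unique(al[bl])) == 1L,
                       logical(1)))
      if (!ok) next
      w <- prod(vapply(blocks,
                       function(bl) if (al[bl[1]] == 1L) f else 1 - f,
                       numeric(1)))
      gA <- al["a1"] + al["a2"]; gB <- al["b1"] + al["b2"]
      out[m, gA + 1L, gB + 1L] <- out[m, gA + 1L, gB + 1L] + w
    }
  }
  out
}

# one-hot genotype-likelihood row(s) for called genotypes
oneHotGL <- function(g) {
  m <- matrix(0, length(g), 3)
  m[cbind(seq_along(g), g + 1L)] <- 1
  m
}

randomGL <- function(L, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(L * 3, 0.01, 1), L, 3)
  m / apply(m, 1, max)
}

# a pedigree of unrelated founders plus one trio, reused across tests
trioPedigree <- function() {
  ped <- pedigree(c("f1", "f2", "f3", "kid"),
                  c("0", "0", "0", "f1"),
                  c("0", "0", "0", "f2"))
  ped
}

simulatePairData <- function(pairIds, nSites, depth, error = 0.001,
                             maf = 0.1, seed = 1, ped = trioPedigree()) {
  attr(ped, "pair") <- pairIds
  simulateScenario(ped, nSites = nSites, depth = depth, error = error,
                   maf = maf, seed = seed)
}
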
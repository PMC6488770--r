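test_that("pedigree validity catches malformed structures", {
  expect_error(pedigree(c("a", "b"), c("0", "a"), c("0", "0")),
               "two parents or none")
  expect_error(pedigree(c("a", "b", "c"), c("0", "0", "b"), c("0", "0", "b")),
               "selfing")
  expect_error(new("Pedigree", id = c("kid", "dad", "mum"),
                   father = c(2L, 0L, 0L), mother = c(3L, 0L, 0L)),
               "topological")
  expect_error(pedigree("a", "ghost", "b"), "unknown parent")
})

test_that("pedigrees round-trip through the trio file format", {
  ped <- scenarioPedigree(3)
  path <- withr::local_tempfile(fileext = ".ped")
  writePedigree(ped, path)
  ped2 <- readPedigree(path)
  expect_identical(ped2@id, ped@id)
  expect_identical(ped2@father, ped@father)
  expect_identical(ped2@mother, ped@mother)
})

test_that("sampled frequencies respect the MAF filter and the seed", {
  f <- sampleFrequencies(5000, maf = 0.1, seed = 3)
  expect_true(all(f > 0.1 & f < 0.9))
  expect_identical(f, sampleFrequencies(5000, maf = 0.1, seed = 3))
  f2 <- sampleFrequencies(100000, maf = 0.05, seed = 4)
  expect_lt(abs(mean(f2) - 0.5), 0.01)
})

test_that("founder genotypes are Hardy-Weinberg and children inherit IBD", {
  ped <- trioPedigree()
  L <- 100000
  drop <- geneDrop(ped, rep(0.5, L), seed = 5)
  het <- mean(drop$genotypes[, "f1"] == 1L)
  expect_lt(abs(het - 0.5), 0.01)
  # a parent and child share at least one IBD allele everywhere
  st <- ibdStates(drop, "f1", "kid")
  expect_true(all(st %in% c(1L, 3L, 5L, 7L, 8L)))
  # two founders are never IBD
  expect_true(all(ibdStates(drop, "f1", "f3") == 9L))
})

test_that("realised IBD proportions converge to the exact coefficients", {
  ped <- scenarioPedigree(1)
  L <- 500000
  drop <- geneDrop(ped, sampleFrequencies(L, 0.1, seed = 6), seed = 6)
  prop <- tabulate(ibdStates(drop, "a", "b"), 9) / L
  expect_lt(max(abs(prop - expectedJacquard(ped, "a", "b"))), 0.005)
})

test_that("exact coefficients at the degenerate corners", {
  ped <- trioPedigree()
  # two founders: J9 = 1
  expect_equal(unname(expectedJacquard(ped, "f1", "f3")),
               c(0, 0, 0, 0, 0, 0, 0, 0, 1))
  # outbred self-pair: J7 = 1
  expect_equal(unname(expectedJacquard(ped, "kid", "kid")),
               c(0, 0, 0, 0, 0, 0, 1, 0, 0))
  # parent-offspring: J8 = 1
  expect_equal(unname(expectedJacquard(ped, "f1", "kid")),
               c(0, 0, 0, 0, 0, 0, 0, 1, 0))
})

test_that("exact coefficients reproduce the three validation scenarios", {
  ped1 <- scenarioPedigree(1)
  j1 <- expectedJacquard(ped1, "a", "b")
  expect_equal(unname(j1), c(0, 0, 0, 0, 0, 0, 0, 0.25, 0.75))
  expect_equal(ibdStats(j1)[["rab"]], 0.125)

  ped2 <- scenarioPedigree(2)
  j2 <- expectedJacquard(ped2, "a", "b")
  expect_equal(unname(j2),
               c(0, 0, 0, 0, 0.0625, 0.1875, 0, 0.375, 0.375))
  expect_equal(ibdStats(j2)[["Fb"]], 0.25)
  expect_equal(round(ibdStats(j2)[["rab"]], 2), 0.23)

  ped3 <- scenarioPedigree(3)
  j3 <- expectedJacquard(ped3, "b", "a2")
  expect_equal(unname(j3),
               c(1 / 64, 1 / 64, 6 / 64, 8 / 64, 4 / 64, 2 / 64, 4 / 64,
                 24 / 64, 14 / 64))
  expect_equal(ibdStats(j3)[["rab"]], 0.3828125)
  expect_equal(ibdStats(j3)[["Fa"]], 0.25)
  expect_equal(ibdStats(j3)[["Fb"]], 0.125)
})

test_that("gene-drop realisations agree with the Monte-Carlo view of the exact oracle", {
  ped <- scenarioPedigree(2)
  L <- 200000
  drop <- geneDrop(ped, sampleFrequencies(L, 0.1, seed = 8), seed = 8)
  prop <- tabulate(ibdStates(drop, "a", "b"), 9) / L
  expect_lt(max(abs(prop - expectedJacquard(ped, "a", "b"))), 0.01)
})

test_that("the enumeration budget guards deep pedigrees", {
  # 11 non-founders = 22 meioses > default budget of 20
  ids <- c("f1", "f2", paste0("k", 1:11))
  fa <- c("0", "0", "f1", rep("f1", 10))
  mo <- c("0", "0", "f2", paste0("k", 1:10))
  ped <- pedigree(ids, fa, mo)
  expect_error(expectedJacquard(ped, "k10", "k11", maxMeioses = 20),
               "budget")
})

test_that("simulated likelihoods behave at the edges of the read model", {
  # zero depth: flat rows
  gl0 <- simulateGL(rep(1L, 50), depth = 0, error = 0.001, seed = 9)
  expect_equal(gl0, matrix(1, 50, 3))
  # no error, homozygous reference with reads: opposite homozygote excluded
  set.seed(10)
  gl <- simulateGL(rep(0L, 2000), depth = 4, error = 0, seed = 10)
  covered <- rowSums(gl) < 3  # rows with at least one read
  expect_true(any(covered))
  expect_true(all(gl[covered, 3] == 0))
  expect_true(all(gl[, 1] == 1))  # truth always has maximal likelihood here
})

test_that("realised depth matches the Poisson mean", {
  L <- 50000
  # error-free homozygous truth: the heterozygote hypothesis scores 0.5 per
  # read, so the read count is recoverable as log2 of that likelihood
  gl <- simulateGL(rep(0L, L), depth = 4, error = 0, seed = 11)
  k <- log(gl[, 2]) / log(0.5)
  expect_lt(abs(mean(k) - 4), 0.05)
})

test_that("scenario simulation is reproducible and carries the truth", {
  s1 <- simulateScenario(2, nSites = 500, depth = 4, seed = 12)
  s2 <- simulateScenario(2, nSites = 500, depth = 4, seed = 12)
  expect_identical(glMatrix(s1$gl, 1), glMatrix(s2$gl, 1))
  expect_identical(alleleFreq(s1$gl), alleleFreq(s2$gl))
  expect_equal(unname(s1$expectedJ),
               c(0, 0, 0, 0, 0.0625, 0.1875, 0, 0.375, 0.375))
  expect_identical(sampleIds(s1$gl), c("a", "b"))
})

test_that("GL normalisation downstream does not change the estimate", {
  sim <- simulatePairData(c("f1", "kid"), nSites = 2000, depth = 4,
                          seed = 13)
  glA <- glMatrix(sim$gl, 1)
  set.seed(14)
  sc <- stats::runif(nrow(glA), 0.2, 5)
  a <- estimatePair(glA, glMatrix(sim$gl, 2), alleleFreq(sim$gl),
                    nRestarts = 1, seed = 2)
  b <- estimatePair(glA * sc, glMatrix(sim$gl, 2), alleleFreq(sim$gl),
                    nRestarts = 1, seed = 2)
  expect_equal(a@j, b@j, tolerance = 1e-6)
})
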
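test_that("EM leaves the weights unchanged on uninformative emissions", {
  E <- matrix(stats::runif(30, 0.5, 2), 30, 9)
  E <- E[, rep(1, 9)]  # rows constant across states
  set.seed(1)
  j <- stats::rexp(9); j <- j / sum(j)
  st <- emStep(j, E)
  expect_equal(st$j, j, tolerance = 1e-12)
})

test_that("a single site yields the normalised posterior product", {
  e <- pairEmissions(randomGL(1, 5), randomGL(1, 6), 0.3)
  set.seed(2)
  j <- stats::rexp(9); j <- j / sum(j)
  st <- emStep(j, e)
  expect_equal(st$j, as.vector(j * e[1, ]) / sum(j * e[1, ]),
               tolerance = 1e-12)
})

test_that("EM and SQUAREM cycles never decrease the log-likelihood", {
  set.seed(3)
  worstEm <- worstSq <- 0
  for (k in 1:1000) {
    L <- sample(3:30, 1)
    E <- matrix(stats::rexp(L * 9), L, 9)
    j <- stats::rexp(9); j <- j / sum(j)
    ll0 <- pairLogLik(j, E)
    st <- emStep(j, E)
    worstEm <- min(worstEm, pairLogLik(st$j, E) - ll0)
    sq <- squaremStep(j, E)
    worstSq <- min(worstSq, sq$loglik - ll0)
  }
  expect_gte(worstEm, -1e-10)
  expect_gte(worstSq, -1e-10)
})

test_that("a fixed point of EM is a fixed point of the accelerated cycle", {
  # J9 = 1 with data from unrelated individuals reaches a vertex fixed point
  e <- pairEmissions(oneHotGL(c(0L, 1L, 2L)), oneHotGL(c(2L, 1L, 0L)),
                     c(0.5, 0.5, 0.5))
  j <- c(rep(0, 8), 1)
  st <- squaremStep(j, e)
  expect_equal(st$j, j, tolerance = 1e-9)
})

test_that("estimates stay on the simplex through acceleration and clamping", {
  set.seed(4)
  for (k in 1:20) {
    sim <- simulatePairData(c("f1", "kid"), nSites = 300, depth = 2,
                            seed = 400 + k)
    est <- estimatePair(glMatrix(sim$gl, 1), glMatrix(sim$gl, 2),
                        alleleFreq(sim$gl), nRestarts = 2, seed = k)
    expect_true(all(est@j >= 0))
    expect_equal(sum(est@j), 1, tolerance = 1e-8)
    expect_equal(est@loglik,
                 pairLogLik(est@j + 1e-300, # guard exact zeros
                            pairEmissions(glMatrix(sim$gl, 1),
                                          glMatrix(sim$gl, 2),
                                          alleleFreq(sim$gl))),
                 tolerance = 1e-6)
  }
})

test_that("restarts with the same seed are bit-identical", {
  sim <- simulatePairData(c("f1", "kid"), nSites = 500, depth = 4, seed = 7)
  E <- pairEmissions(glMatrix(sim$gl, 1), glMatrix(sim$gl, 2),
                     alleleFreq(sim$gl))
  a <- estimateJacquard(E, seed = 42, nRestarts = 3)
  b <- estimateJacquard(E, seed = 42, nRestarts = 3)
  expect_identical(a@j, b@j)
  expect_identical(a@loglik, b@loglik)
})

test_that("accelerated and plain EM reach the same maximised log-likelihood", {
  # identifiable only up to a known flat direction in coefficient space, so
  # the optimum is compared through its value and the invariant statistics
  inv <- c("rab", "Fa", "Fb", "theta", "ibd23", "Fdiff")
  for (k in 1:10) {
    sim <- simulateScenario((k %% 3) + 1, nSites = 800, depth = 16,
                            error = 0.001, maf = 0.1, seed = 500 + k)
    E <- pairEmissions(glMatrix(sim$gl, 1), glMatrix(sim$gl, 2),
                       alleleFreq(sim$gl))
    a <- estimateJacquard(E, seed = k, nRestarts = 1, tol = 1e-12)
    b <- estimateJacquard(E, seed = k, nRestarts = 1, tol = 1e-12,
                          accelerate = FALSE, maxIter = 500000L)
    expect_lt(abs(a@loglik - b@loglik), 1e-6)
    expect_lt(max(abs(ibdStats(a@j)[inv] - ibdStats(b@j)[inv])), 1e-3)
  }
})

test_that("acceleration reduces the median iteration count", {
  nit <- matrix(NA_real_, 20, 2)
  for (k in 1:20) {
    sim <- simulateScenario(2, nSites = 1000, depth = 8, error = 0.001,
                            maf = 0.1, seed = 600 + k)
    E <- pairEmissions(glMatrix(sim$gl, 1), glMatrix(sim$gl, 2),
                       alleleFreq(sim$gl))
    a <- estimateJacquard(E, seed = k, nRestarts = 1, tol = 1e-9)
    b <- estimateJacquard(E, seed = k, nRestarts = 1, tol = 1e-9,
                          accelerate = FALSE, maxIter = 100000L)
    nit[k, ] <- c(a@nIter, b@nIter)
  }
  expect_lt(stats::median(nit[, 1]), stats::median(nit[, 2]))
})

test_that("the unrelated-pair estimate drives J9 toward 1", {
  sim <- simulatePairData(c("f1", "f3"), nSites = 30000, depth = 4,
                          seed = 11)
  est <- estimatePair(glMatrix(sim$gl, 1), glMatrix(sim$gl, 2),
                      alleleFreq(sim$gl), nRestarts = 1, seed = 1)
  expect_gt(est@j[9], 0.95)
  expect_true(est@converged)
})

test_that("sites with frequency outside (0,1) are dropped with a message", {
  sim <- simulatePairData(c("f1", "f3"), nSites = 100, depth = 4, seed = 12)
  f <- alleleFreq(sim$gl)
  f[c(3, 50)] <- c(0, 1)
  expect_message(
    est <- estimatePair(glMatrix(sim$gl, 1), glMatrix(sim$gl, 2), f,
                        nRestarts = 1, seed = 1),
    "dropped")
  expect_equal(est@nSitesUsed, 98L)
})

test_that("boundary coefficients are clamped to exact zero", {
  sim <- simulatePairData(c("f1", "f3"), nSites = 20000, depth = 8,
                          seed = 13)
  est <- estimatePair(glMatrix(sim$gl, 1), glMatrix(sim$gl, 2),
                      alleleFreq(sim$gl), nRestarts = 1, seed = 1)
  expect_true(any(est@j == 0))
  expect_identical(unname(est@boundary), est@j < 1e-5)
})

test_that("bootstrap intervals behave at the degenerate corners", {
  # identical sites replicated: every resample is the same dataset
  glA <- oneHotGL(rep(1L, 40)); glB <- oneHotGL(rep(1L, 40))
  f <- rep(0.5, 40)
  ci <- bootstrapPair(glA, glB, f, nBoot = 8, seed = 5, nRestarts = 1,
                      ibs = FALSE)
  expect_true(all(abs(ci$upper - ci$lower) < 1e-9))
  # n_boot = 1: both ends equal that replicate's value
  sim <- simulatePairData(c("f1", "kid"), nSites = 200, depth = 4, seed = 14)
  ci1 <- bootstrapPair(glMatrix(sim$gl, 1), glMatrix(sim$gl, 2),
                       alleleFreq(sim$gl), nBoot = 1, seed = 5,
                       nRestarts = 1, ibs = FALSE)
  expect_equal(ci1$lower, ci1$upper, tolerance = 1e-12)
})

test_that("bootstrap is deterministic given the seed and covers the truth", {
  sim <- simulatePairData(c("f1", "kid"), nSites = 2000, depth = 8,
                          seed = 15)
  ci <- bootstrapPair(glMatrix(sim$gl, 1), glMatrix(sim$gl, 2),
                      alleleFreq(sim$gl), nBoot = 30, seed = 9,
                      nRestarts = 1, ibs = FALSE)
  ci2 <- bootstrapPair(glMatrix(sim$gl, 1), glMatrix(sim$gl, 2),
                       alleleFreq(sim$gl), nBoot = 30, seed = 9,
                       nRestarts = 1, ibs = FALSE)
  expect_identical(ci, ci2)
  expect_true(all(ci$lower <= ci$upper))
  # parent-offspring relatedness 0.5 should sit inside a widened interval
  rab <- ci[ci$statistic == "rab", ]
  expect_gt(0.5, rab$lower - 0.05)
  expect_lt(0.5, rab$upper + 0.05)
})
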
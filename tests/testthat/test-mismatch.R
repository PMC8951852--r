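test_that("mismatch distribution matches pair enumeration", {
  same <- hapAlignment(rep("ACGT", 4), populations = "p")
  expect_equal(mismatchDistribution(same), 1)
  # pairwise differences {1, 1, 2}
  tri <- hapAlignment(c("AAAA", "AAAT", "AATA"), populations = "p")
  expect_equal(mismatchDistribution(tri), c(0, 2 / 3, 1 / 3))
  for (s in 1:10) {
    a <- randAlignment(sample(3:8, 1), sample(5:20, 1), seed = 600 + s)
    obs <- mismatchDistribution(a)
    expect_equal(obs, orc_mismatch(alignmentMatrix(a)))
    expect_equal(sum(obs), 1)
  }
  expect_error(mismatchDistribution(hapAlignment("AAAA", populations = "p")),
               "n >= 2")
})

test_that("expected mismatch reduces to known limits and sums to one", {
  # tau = 0: geometric equilibrium with theta0
  th <- 2.5
  e <- expectedMismatch(0, th, 50, 40)
  j <- 0:39
  direct <- th^j / (th + 1)^(j + 1)
  expect_equal(e[1:39], direct[1:39], tolerance = 1e-9)
  expect_equal(sum(e), 1, tolerance = 1e-12)
  # theta0 = 0, huge theta1: Poisson-like peak near tau
  e2 <- expectedMismatch(6, 0, 1e6, 40)
  expect_equal(e2[1:30], dpois(0:29, 6), tolerance = 1e-3)
  expect_true((which.max(e2) - 1) %in% c(5, 6))   # Poisson(6) modes tie
  # general parameters: normalized
  expect_equal(sum(expectedMismatch(4, 1, 100, 25)), 1, tolerance = 1e-6)
  expect_error(expectedMismatch(-1, 1, 1, 5), "nonnegative")
})

test_that("raggedness matches its definition", {
  expect_equal(raggedness(c(1, 0)), 1)
  expect_equal(raggedness(rep(0.2, 5)), 0)
  smooth <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  spiky <- c(0.4, 0, 0.2, 0, 0.4)
  expect_lt(raggedness(smooth), raggedness(spiky))
  for (s in 1:5) {
    x <- runif(8); x <- x / sum(x)
    expect_equal(raggedness(x), orc_hri(x))
  }
  expect_error(raggedness(numeric()), "non-empty")
})

test_that("sudden-expansion fit recovers exact model spectra and is deterministic", {
  obs <- expectedMismatch(4, 1, 100, 25)
  fit <- fitSuddenExpansion(obs)
  expect_lt(fit@ssd, 1e-8)
  expect_equal(fit@tau, 4, tolerance = 0.1)
  # equilibrium input: tau fitted near zero (or a fit that reproduces the
  # equilibrium shape with negligible SSD)
  eq <- expectedMismatch(0, 3, 3, 20)
  feq <- fitSuddenExpansion(eq)
  expect_lt(feq@ssd, 1e-6)
  # determinism
  a <- randAlignment(10, 25, seed = 9)
  f1 <- fitSuddenExpansion(mismatchDistribution(a))
  f2 <- fitSuddenExpansion(mismatchDistribution(a))
  expect_identical(f1@tau, f2@tau)
  expect_identical(f1@ssd, f2@ssd)
  # degenerate single-class observed
  fdeg <- fitSuddenExpansion(1)
  expect_equal(fdeg@tau, 0)
})

test_that("bootstrap p-values are seeded, sane for model-true data", {
  sim <- simulateExpansion(simConfig(nPerPop = 30, model = "expansion",
                                     theta0 = 1, theta1 = 100, tau = 4,
                                     seed = 88))
  a <- sim$alignment
  fit <- fitSuddenExpansion(mismatchDistribution(a))
  b1 <- expansionBootstrapP(a, fit, reps = 60, seed = 7)
  b2 <- expansionBootstrapP(a, fit, reps = 60, seed = 7)
  expect_identical(b1@pSSD, b2@pSSD)
  expect_identical(b1@pHri, b2@pHri)
  # data generated under the fitted model should rarely be rejected
  expect_gt(b1@pSSD, 0.05)
  expect_error(expansionBootstrapP(a, fit, reps = 0), "reps")
})

test_that("bootstrap p-values are roughly uniform under the fitted model", {
  # reduced-scale calibration: datasets drawn from a fixed expansion model,
  # each fitted and bootstrapped; the resulting p_SSD should not concentrate
  set.seed(314)
  ps <- vapply(1:40, function(r) {
    sim <- simulateExpansion(simConfig(nPerPop = 20, model = "expansion",
                                       theta0 = 0.5, theta1 = 50, tau = 4,
                                       seed = 7000 + r))
    a <- sim$alignment
    fit <- fitSuddenExpansion(mismatchDistribution(a), refine = FALSE)
    expansionBootstrapP(a, fit, reps = 50, seed = 100 + r)@pSSD
  }, 0)
  # no mass collapse at 0 (anti-conservative) and a healthy spread
  expect_lt(mean(ps <= 0.05), 0.2)
  expect_gt(stats::sd(ps), 0.1)
})
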
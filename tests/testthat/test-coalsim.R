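test_that("theta = 0 gives a monomorphic sample; seeds give identical bytes", {
  sim <- simulateConstant(simConfig(nPerPop = 10, theta = 0, seed = 3))
  expect_equal(segregatingSites(sim$alignment), 0L)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  s1 <- simulateConstant(simConfig(nPerPop = 15, theta = 5, seed = 99))
  s2 <- simulateConstant(simConfig(nPerPop = 15, theta = 5, seed = 99))
  writeHapAlignment(s1$alignment, f1)
  writeHapAlignment(s2$alignment, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("constant-model S tracks the Watterson expectation", {
  # homogeneous rates: E[S] = a1 * theta under infinite sites; recurrent
  # hits at 328 finite sites leave a ~6% deficit, inside this 10% band
  S <- vapply(1:300, function(r)
    segregatingSites(simulateConstant(
      simConfig(nPerPop = 20, theta = 5, gammaShape = Inf,
                seed = 10000 + r))$alignment), 0L)
  a1 <- sum(1 / 1:19)
  expect_equal(mean(S), a1 * 5, tolerance = 0.1)
})

test_that("simulated mutations respect the 10:1 transition bias", {
  ts <- 0; tv <- 0
  for (r in 1:25) {
    sim <- simulateConstant(simConfig(nPerPop = 2, L = 3000, theta = 30,
                                      gammaShape = Inf, seed = 20000 + r))
    m <- alignmentMatrix(sim$alignment)
    d <- m[1, ] != m[2, ]
    pair <- paste0(pmin(m[1, d], m[2, d]), pmax(m[1, d], m[2, d]))
    ts <- ts + sum(pair %in% c("AG", "CT"))
    tv <- tv + sum(!pair %in% c("AG", "CT"))
  }
  expect_equal(ts / (ts + tv), 10 / 11, tolerance = 0.05)
})

test_that("tau = 0 expansion is statistically indistinguishable from constant size", {
  Sconst <- vapply(1:200, function(r)
    segregatingSites(simulateConstant(
      simConfig(nPerPop = 12, theta = 3, seed = 30000 + r))$alignment), 0L)
  Sexp <- vapply(1:200, function(r)
    segregatingSites(simulateExpansion(
      simConfig(nPerPop = 12, model = "expansion", theta0 = 3, theta1 = 3,
                tau = 0, seed = 40000 + r))$alignment), 0L)
  expect_equal(mean(Sexp), mean(Sconst), tolerance = 0.12)
})

test_that("expansion datasets show the unimodal mismatch signature", {
  modes <- vapply(1:40, function(r) {
    sim <- simulateExpansion(simConfig(nPerPop = 50, model = "expansion",
                                       theta0 = 1, theta1 = 100, tau = 4,
                                       seed = 50000 + r))
    obs <- mismatchDistribution(sim$alignment)
    which.max(obs) - 1
  }, 0)
  # mode concentrates near tau = 4
  expect_gte(mean(modes >= 2 & modes <= 7), 0.6)
})

test_that("island model: panmixia limit and migration-ordered differentiation", {
  meanPhi <- function(Nm, reps, seed0) {
    mean(vapply(1:reps, function(r) {
      sim <- simulateIsland(simConfig(nPerPop = 8, nPops = 4,
                                      model = "island", theta = 2, Nm = Nm,
                                      seed = seed0 + r))
      pm <- phistMatrix(sim$alignment, distanceConfig(method = "raw"),
                        perms = 0)
      mean(pm@phist[upper.tri(pm@phist)])
    }, 0))
  }
  hi <- meanPhi(1e6, 10, 60000)
  expect_lt(abs(hi), 0.05)
  lo1 <- meanPhi(0.1, 15, 61000)
  lo2 <- meanPhi(1, 15, 62000)
  lo3 <- meanPhi(10, 15, 63000)
  expect_gt(lo1, lo2)
  expect_gt(lo2, lo3)
})

test_that("hierarchical structure is detectable by AMOVA on the true grouping", {
  # crossGroupFactor 0.1 * 4/15 makes the total cross-group migrant flow
  # (15 cross targets) ten-fold lower than the total within-group flow
  # (4 within targets) for 5 demes per group
  hits <- 0
  for (r in 1:12) {
    sim <- simulateHierarchical(nPerPop = 10, popsPerCell = 5, theta = 2,
                                Nm = 10, crossGroupFactor = 0.1 * 4 / 15,
                                seed = 70000 + r)
    res <- amovaTwoLevel(sim$alignment,
                         groupingSchemes(sim$metadata, "Region2")$Region2,
                         distanceConfig(method = "raw"), perms = 200,
                         seed = r)
    if (!is.na(res@pvals[["ct"]]) && res@pvals[["ct"]] <= 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 10)
})

test_that("writeSimulation emits the seqdata input dialect", {
  sim <- simulateIsland(simConfig(nPerPop = 4, nPops = 3, model = "island",
                                  theta = 2, Nm = 1, seed = 8))
  pre <- tempfile()
  files <- writeSimulation(sim, pre)
  a <- readHapAlignment(paste0(pre, ".fasta"), coordStart = 1L)
  expect_equal(nSamples(a), 12L)
  expect_equal(sort(unique(samplePopulations(a))),
               sort(sim$metadata$population_id))
  md <- read.table(paste0(pre, "_meta.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(md), 3L)
})
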
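.mkMultiPop <- function(sizes, L = 25, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  a <- randAlignment(n, L)
  a@populations <- rep(sprintf("p%d", seq_along(sizes)), sizes)
  a
}

test_that("AMOVA matches the brute-force nested decomposition", {
  for (s in 1:10) {
    a <- .mkMultiPop(c(3, 3, 2, 2), seed = 1200 + s)
    scheme <- setNames(c("g1", "g1", "g2", "g2"), sprintf("p%d", 1:4))
    res <- amovaTwoLevel(a, scheme, distanceConfig(method = "raw"), perms = 0)
    orc <- orc_amova(orc_d2raw(alignmentMatrix(a)),
                     samplePopulations(a), scheme)
    expect_equal(unname(res@sigma2), unname(orc$sigma2), tolerance = 1e-9)
    expect_equal(unname(res@phi), unname(orc$phi), tolerance = 1e-9)
  }
})

test_that("the Phi identity (1-ST) = (1-CT)(1-SC) holds to 1e-9", {
  for (s in 1:10) {
    a <- .mkMultiPop(c(4, 3, 3, 2, 2), seed = 1300 + s)
    scheme <- setNames(c("g1", "g1", "g2", "g2", "g3"), sprintf("p%d", 1:5))
    res <- amovaTwoLevel(a, scheme, distanceConfig(method = "raw"), perms = 0)
    expect_equal(1 - res@phi[["st"]],
                 (1 - res@phi[["ct"]]) * (1 - res@phi[["sc"]]),
                 tolerance = 1e-9)
    expect_equal(sum(res@pct), 100, tolerance = 1e-9)
  }
})

test_that("complete between-group differentiation gives Phi_CT = 1, Phi_SC = 0", {
  a <- hapAlignment(c(rep("AAAA", 4), rep("TTTT", 4)),
                    populations = rep(c("p1", "p2", "p3", "p4"), each = 2))
  scheme <- setNames(c("g1", "g1", "g2", "g2"), sprintf("p%d", 1:4))
  res <- amovaTwoLevel(a, scheme, distanceConfig(method = "raw"), perms = 0)
  expect_equal(res@phi[["ct"]], 1)
  expect_equal(res@phi[["sc"]], 0)
  expect_equal(res@phi[["st"]], 1)
})

test_that("one-group AMOVA equals the pairwise Phi-ST decomposition", {
  a <- .mkMultiPop(c(5, 6), seed = 1400)
  scheme <- setNames(c("g1", "g1"), c("p1", "p2"))
  res <- amovaTwoLevel(a, scheme, distanceConfig(method = "raw"), perms = 0)
  pp <- pairwisePhist(a, "p1", "p2", distanceConfig(method = "raw"), perms = 0)
  expect_equal(res@phi[["st"]], pp$phist, tolerance = 1e-9)
})

test_that("components are invariant to population and sequence ordering", {
  a <- .mkMultiPop(c(3, 4, 3), seed = 1500)
  scheme <- setNames(c("g1", "g2", "g2"), sprintf("p%d", 1:3))
  res1 <- amovaTwoLevel(a, scheme, distanceConfig(method = "raw"), perms = 0)
  idx <- sample(nSamples(a))
  b <- hapAlignment(alignmentMatrix(a)[idx, ],
                    populations = samplePopulations(a)[idx])
  res2 <- amovaTwoLevel(b, scheme, distanceConfig(method = "raw"), perms = 0)
  expect_equal(res1@sigma2, res2@sigma2, tolerance = 1e-9)
  expect_equal(res1@phi, res2@phi, tolerance = 1e-9)
})

test_that("permutation p-values are seeded and grouping schemes validated", {
  a <- .mkMultiPop(c(4, 4, 4, 4), seed = 1600)
  scheme <- setNames(c("g1", "g1", "g2", "g2"), sprintf("p%d", 1:4))
  r1 <- amovaTwoLevel(a, scheme, distanceConfig(method = "raw"),
                      perms = 100, seed = 11)
  r2 <- amovaTwoLevel(a, scheme, distanceConfig(method = "raw"),
                      perms = 100, seed = 11)
  expect_identical(r1@pvals, r2@pvals)
  expect_true(all(r1@pvals > 0 & r1@pvals <= 1))
  # missing population in the scheme is a hard error naming it
  expect_error(amovaTwoLevel(a, scheme[-2], perms = 0), "p2")
  # single-population group is flagged
  sch3 <- setNames(c("g1", "g1", "g1", "g2"), sprintf("p%d", 1:4))
  r3 <- amovaTwoLevel(a, sch3, distanceConfig(method = "raw"), perms = 0)
  expect_match(r3@flags, "single population")
})

test_that("runAllSchemes reproduces single-scheme results and true structure ranks higher", {
  sim <- simulateHierarchical(nPerPop = 8, popsPerCell = 2, theta = 2,
                              Nm = 5, crossGroupFactor = 0.05, seed = 42)
  a <- sim$alignment
  md <- sim$metadata
  schemes <- groupingSchemes(md, c("Region2", "Lifestyle1"))
  res <- runAllSchemes(a, schemes, distanceConfig(method = "raw"),
                       perms = 50, seed = 5)
  single <- amovaTwoLevel(a, schemes$Region2, distanceConfig(method = "raw"),
                          perms = 50, seed = (5 + 1) %% .Machine$integer.max,
                          schemeName = "Region2")
  expect_equal(res$Region2@phi, single@phi, tolerance = 1e-12)
  # the generative grouping (Region2) explains more among-group variance
  # than the orthogonal lifestyle labels
  expect_gt(res$Region2@phi[["ct"]], res$Lifestyle1@phi[["ct"]])
  tab <- amovaTable(res)
  expect_equal(nrow(tab), 2L)
})
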
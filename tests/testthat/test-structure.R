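test_that("K2P gamma distance matches direct evaluation and its limits", {
  expect_equal(k2pGammaDistance("ACGT", "ACGT"), 0)
  # P = 0.1, Q = 0.05 on L = 20: 2 transitions, 1 transversion
  si <- c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C",
          "G", "T", "A", "C", "G", "T", "A", "C", "G", "T")
  sj <- si; sj[1] <- "G"; sj[2] <- "T"; sj[3] <- "C"
  expect_equal(k2pGammaDistance(si, sj, distanceConfig(gammaShape = 0.4)),
               orc_k2p_gamma(0.1, 0.05, 0.4), tolerance = 1e-12)
  # enormous shape approximates the uncorrected K2P distance
  big <- k2pGammaDistance(si, sj, distanceConfig(gammaShape = 1e6))
  uncorr <- -log(1 - 2 * 0.1 - 0.05) / 2 - log(1 - 2 * 0.05) / 4
  expect_equal(big, uncorr, tolerance = 1e-4)
  # saturation errors
  sat_i <- rep("A", 4); sat_j <- rep("G", 4)
  expect_error(k2pGammaDistance(sat_i, sat_j), "saturated")
  expect_error(k2pGammaDistance("ACG", "AC"), "equal length")
})

test_that("pairwiseDistances agrees with per-pair calls", {
  a <- randAlignment(6, 30, mutRate = 0.03, seed = 50)
  m <- alignmentMatrix(a)
  d <- pairwiseDistances(a)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(d[i, j], k2pGammaDistance(m[i, ], m[j, ]), tolerance = 1e-12)
  draw <- pairwiseDistances(a, distanceConfig(method = "raw"))
  expect_equal(draw[2, 5], sum(m[2, ] != m[5, ]))
  expect_true(isSymmetric(d))
})

test_that("pairwise Phi-ST matches the brute-force decomposition", {
  for (s in 1:10) {
    a <- randAlignment(9, 20, seed = 700 + s)
    pops <- rep(c("p1", "p2"), c(4, 5))
    a@populations <- pops
    r <- pairwisePhist(a, "p1", "p2", distanceConfig(method = "raw"),
                       perms = 0)
    orc <- orc_phist(orc_d2raw(alignmentMatrix(a)), pops)
    expect_equal(r$phist, orc$phist, tolerance = 1e-10)
  }
})

test_that("Phi-ST hits its boundary cases", {
  # fixed different haplotypes: complete differentiation
  a <- hapAlignment(c("AAAA", "AAAA", "TTTT", "TTTT"),
                    populations = c("p1", "p1", "p2", "p2"))
  r <- pairwisePhist(a, "p1", "p2", distanceConfig(method = "raw"), perms = 50,
                     seed = 1)
  expect_equal(r$phist, 1)
  # identical monomorphic populations
  b <- hapAlignment(rep("AAAA", 4), populations = c("p1", "p1", "p2", "p2"))
  rb <- pairwisePhist(b, "p1", "p2", perms = 10, seed = 1)
  expect_equal(rb$phist, 0)
  expect_equal(rb$p, 1)
  # panmictic pool: near-zero Phi-ST on average
  phis <- vapply(1:30, function(s) {
    x <- randAlignment(12, 40, seed = 8000 + s)
    x@populations <- rep(c("p1", "p2"), 6)
    pairwisePhist(x, "p1", "p2", distanceConfig(method = "raw"),
                  perms = 0)$phist
  }, 0)
  expect_lt(abs(mean(phis)), 0.05)
})

test_that("Phi-ST is invariant to sample order within populations", {
  a <- randAlignment(10, 25, seed = 31)
  a@populations <- rep(c("p1", "p2"), each = 5)
  r1 <- pairwisePhist(a, "p1", "p2", perms = 0)
  idx <- c(sample(1:5), sample(6:10))
  b <- hapAlignment(alignmentMatrix(a)[idx, ],
                    populations = a@populations[idx])
  r2 <- pairwisePhist(b, "p1", "p2", perms = 0)
  expect_equal(r1$phist, r2$phist, tolerance = 1e-12)
})

test_that("linearization clips, transforms and preserves order", {
  expect_equal(linearizePhist(0), 0)
  expect_equal(linearizePhist(0.5), -log(0.5))
  expect_equal(linearizePhist(-0.2), 0)
  x <- c(0.1, 0.3, 0.05, 0.6)
  expect_equal(order(linearizePhist(x)), order(x))
  expect_warning(out <- linearizePhist(1), "Inf")
  expect_true(is.infinite(out))
})

test_that("phistMatrix is symmetric with zero diagonal and seeded p-values", {
  sim <- simulateIsland(simConfig(nPerPop = 6, nPops = 4, model = "island",
                                  theta = 2, Nm = 1, seed = 12))
  pm1 <- phistMatrix(sim$alignment, distanceConfig(method = "raw"),
                     perms = 50, seed = 3)
  pm2 <- phistMatrix(sim$alignment, distanceConfig(method = "raw"),
                     perms = 50, seed = 3)
  expect_identical(pm1@phist, pm2@phist)
  expect_identical(pm1@pvals, pm2@pvals)
  expect_equal(diag(pm1@phist), setNames(rep(0, 4), pm1@populations))
  expect_equal(pm1@phist, t(pm1@phist))
})

test_that("NMDS embeds exact 2-D configurations with near-zero stress", {
  set.seed(2)
  pts <- matrix(rnorm(16), 8, 2)
  d <- dist(pts)
  ord <- nmdsOrdination(as.matrix(d), restarts = 10, seed = 5)
  expect_lt(ord$stress, 1e-3)
  # more dimensions never fit worse
  ord3 <- nmdsOrdination(as.matrix(dist(matrix(rnorm(45), 9, 5))),
                         dims = 3, restarts = 10, seed = 5)
  ord2 <- nmdsOrdination(as.matrix(dist(matrix(rnorm(45), 9, 5))),
                         dims = 2, restarts = 10, seed = 5)
  # refit the same matrix for a clean comparison
  m <- as.matrix(dist(matrix(rnorm(45, 1), 9, 5)))
  s2 <- nmdsOrdination(m, dims = 2, restarts = 10, seed = 7)$stress
  s3 <- nmdsOrdination(m, dims = 3, restarts = 10, seed = 7)$stress
  expect_lte(s3, s2 + 1e-6)
  expect_identical(nmdsOrdination(m, restarts = 5, seed = 9)$stress,
                   nmdsOrdination(m, restarts = 5, seed = 9)$stress)
  expect_error(nmdsOrdination(matrix(0, 2, 2)), "at least 3")
})

test_that("Kruskal-Wallis wrapper matches a hand rank computation", {
  # textbook three-group example
  vals <- c(27, 2, 4, 18, 7, 9, 1, 5, 11, 12, 17, 58)
  grp <- rep(c("a", "b", "c"), each = 4)
  kw <- kruskalWallisGroups(vals, grp)
  rk <- rank(vals)
  n <- length(vals)
  Hraw <- 12 / (n * (n + 1)) *
    sum(tapply(rk, grp, function(r) sum(r)^2 / length(r))) - 3 * (n + 1)
  expect_equal(kw$H, Hraw, tolerance = 1e-10)   # no ties here
  expect_equal(kw$p, pchisq(Hraw, 2, lower.tail = FALSE), tolerance = 1e-10)
  # identical multisets: p near 1; identical values: exactly (H=0, p=1)
  same <- kruskalWallisGroups(rep(5, 8), rep(c("a", "b"), 4))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  expect_error(kruskalWallisGroups(1:4, rep("a", 4)), "2 groups")
})

test_that("kruskalWallisTable lays out schemes by indices", {
  md <- makeMeta(sprintf("p%d", 1:8))
  stats <- data.frame(population_id = md$population_id,
                      H = runif(8), pi = runif(8))
  tab <- kruskalWallisTable(stats, md, schemes = c("region1", "lifestyle1"),
                            indices = c("H", "pi"))
  expect_equal(dim(tab), c(2L, 2L))
  expect_true(all(tab >= 0 & tab <= 1, na.rm = TRUE))
  bad <- stats; bad$population_id[1] <- "nope"
  expect_error(kruskalWallisTable(bad, md), "missing")
})
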
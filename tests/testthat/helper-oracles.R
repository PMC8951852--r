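# Independent brute-force oracles: every statistic re-derived from its
# definition with explicit loops, sharing no code with the package
# implementations.

orc_k <- function(m) {
  n <- nrow(m)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + sum(m[i, ] != m[j, ])
  s / (n * (n - 1) / 2)
}

# unbiased gene diversity = fraction of unordered pairs with different
# haplotypes (equivalent to n(1 - sum p^2)/(n-1))
orc_H <- function(haps) {
  n <- length(haps)
  cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (haps[i] != haps[j]) cnt <- cnt + 1
  cnt / (n * (n - 1) / 2)
}

orc_S <- function(m) {
  s <- 0
  for (j in seq_len(ncol(m))) if (length(unique(m[, j])) > 1) s <- s + 1
  s
}

orc_tajD <- function(m) {
  n <- nrow(m)
  S <- orc_S(m)
  if (S == 0) return(NA_real_)
  k <- orc_k(m)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# unsigned Stirling numbers of the first kind as coefficients of the rising
# factorial polynomial x(x+1)...(x+n-1); exact for small n
orc_stirling <- function(n) {
  p <- 1
  for (m_ in 0:(n - 1)) p <- c(0, p) + m_ * c(p, 0)
  p  # p[k+1] = |S_n^k|
}

orc_fs <- function(m) {
  n <- nrow(m)
  k <- orc_k(m)
  if (k <= 0) return(NA_real_)
  haps <- apply(m, 1, paste, collapse = "")
  K <- length(unique(haps))
  st <- orc_stirling(n)
  probs <- vapply(1:n, function(j) st[j + 1] * k^j, 0) / prod(k + 0:(n - 1))
  Sp <- sum(probs[K:n])
  Sp <- min(max(Sp, 1e-300), 1 - 1e-15)
  log(Sp / (1 - Sp))
}

orc_singletons <- function(m) {
  n <- nrow(m)
  U <- integer(n)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    for (al in names(tab)[tab == 1]) U[m[, j] == al] <- U[m[, j] == al] + 1L
  }
  U
}

orc_r2 <- function(m) {
  n <- nrow(m)
  S <- orc_S(m)
  if (S == 0) return(NA_real_)
  k <- orc_k(m)
  U <- orc_singletons(m)
  sqrt(sum((U - k / 2)^2) / n) / S
}

orc_mismatch <- function(m) {
  n <- nrow(m)
  diffs <- integer(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diffs <- c(diffs, sum(m[i, ] != m[j, ]))
  tab <- tabulate(diffs + 1L, nbins = max(diffs) + 1L)
  tab / sum(tab)
}

orc_hri <- function(x) {
  s <- 0
  if (length(x) > 1) for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  s
}

orc_k2p_gamma <- function(P, Q, a) {
  (a / 2) * ((1 - 2 * P - Q)^(-1 / a) - 1) + (a / 4) * ((1 - 2 * Q)^(-1 / a) - 1)
}

# one-level variance decomposition of squared distances, explicit loops
orc_phist <- function(d2, popOf) {
  popOf <- as.character(popOf)
  pops <- unique(popOf)
  N <- length(popOf)
  P <- length(pops)
  sstot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) sstot <- sstot + d2[i, j]
  sstot <- sstot / N
  sswp <- 0
  np <- numeric(P)
  for (p in seq_len(pops_len <- P)) {
    idx <- which(popOf == pops[p])
    np[p] <- length(idx)
    acc <- 0
    if (length(idx) > 1)
      for (i in 1:(length(idx) - 1)) for (j in (i + 1):length(idx))
        acc <- acc + d2[idx[i], idx[j]]
    sswp <- sswp + acc / np[p]
  }
  ssap <- sstot - sswp
  s2c <- sswp / (N - P)
  nc <- (N - sum(np^2) / N) / (P - 1)
  s2a <- (ssap / (P - 1) - s2c) / nc
  list(phist = s2a / (s2a + s2c), s2a = s2a, s2c = s2c)
}

# two-level decomposition, explicit loops
orc_amova <- function(d2, popOf, grpOfPop) {
  popOf <- as.character(popOf)
  pops <- unique(popOf)
  grpOf <- grpOfPop[pops]
  grps <- unique(grpOf)
  N <- length(popOf)
  P <- length(pops)
  G <- length(grps)
  indGrp <- grpOf[match(popOf, pops)]
  ssIn <- function(idx, w) {
    acc <- 0
    if (length(idx) > 1)
      for (i in 1:(length(idx) - 1)) for (j in (i + 1):length(idx))
        acc <- acc + d2[idx[i], idx[j]]
    acc / w
  }
  sstot <- ssIn(1:N, N)
  np <- vapply(pops, function(p) sum(popOf == p), 0)
  Ng <- vapply(grps, function(g) sum(indGrp == g), 0)
  sswp <- sum(vapply(pops, function(p) ssIn(which(popOf == p), sum(popOf == p)), 0))
  sswg <- sum(vapply(grps, function(g) ssIn(which(indGrp == g), sum(indGrp == g)), 0))
  ssag <- sstot - sswg
  ssapwg <- sswg - sswp
  s2c <- sswp / (N - P)
  sA <- sum(vapply(grps, function(g) sum(np[grpOf == g]^2) / Ng[g], 0))
  nb <- (N - sA) / (P - G)
  s2b <- (ssapwg / (P - G) - s2c) / nb
  nprime <- (sA - sum(np^2) / N) / (G - 1)
  ndprime <- (N - sum(Ng^2) / N) / (G - 1)
  s2a <- (ssag / (G - 1) - s2c - nprime * s2b) / ndprime
  tot <- s2a + s2b + s2c
  list(sigma2 = c(s2a, s2b, s2c),
       phi = c(ct = s2a / tot,
               sc = if (s2b + s2c != 0) s2b / (s2b + s2c) else 0,
               st = (s2a + s2b) / tot))
}

# raw pairwise difference matrix by loops
orc_d2raw <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])^2
  }
  d
}
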
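.logadd <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log of unsigned Stirling numbers of the first kind |S_n^k|, k = 0..n
# via |S_{m+1}^k| = m |S_m^k| + |S_m^{k-1}|, kept in log space
.logStirlingFirst <- function(n) {
  row <- c(-Inf, 0)                      # n = 1: |S_1^1| = 1
  if (n >= 2) for (m in 1:(n - 1))
    row <- .logadd(log(m) + c(row, -Inf), c(-Inf, row))
  row                                    # row[k + 1] = log|S_n^k|
}

.tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' D = (k - S/a1) / sqrt(e1 S + e2 S(S-1)) comparing the mean pairwise
#' differences k with the Watterson estimate S/a1.  Returns NA (the
#' undefined-result flag) when the sample is monomorphic.
#'
#' @param a a \linkS4class{HapAlignment} restricted to one population (n >= 4)
#' @return D, or NA when S = 0
#' @export
tajimasD <- function(a) {
  n <- nSamples(a)
  if (n < 4L) stop("Tajima's D requires n >= 4")
  S <- segregatingSites(a)
  if (S == 0L) return(NA_real_)
  k <- meanPairwiseDifferences(a)
  tc <- .tajimaConstants(n)
  (k - S / tc$a1) / sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
}

.fuFsFromKk <- function(khat, K, n) {
  if (!is.finite(khat) || khat <= 0) return(NA_real_)
  lgS <- .logStirlingFirst(n)
  lth <- log(khat)
  lrf <- sum(log(khat + 0:(n - 1)))
  lp <- lgS[(1:n) + 1L] + (1:n) * lth - lrf
  m <- max(lp[K:n])
  lSp <- m + log(sum(exp(lp[K:n] - m)))
  Sp <- min(max(exp(lSp), 1e-300), 1 - 1e-15)
  log(Sp / (1 - Sp))
}

#' Fu's Fs
#'
#' Fs = ln(S'/(1 - S')) with S' = P(K >= K_obs | theta = k), the Ewens
#' sampling-formula probability (via unsigned Stirling numbers of the first
#' kind, evaluated in log space) of observing at least the sampled number of
#' distinct haplotypes given theta estimated by the mean pairwise
#' differences.  Strongly negative values indicate an excess of haplotypes,
#' the classic expansion signal.  The one-tailed convention means the 5%
#' significance level corresponds to a p-value below 2%.
#'
#' @param a a \linkS4class{HapAlignment} restricted to one population
#' @return Fs, or NA when the sample is monomorphic (k = 0)
#' @export
fusFs <- function(a) {
  n <- nSamples(a)
  if (n < 2L) stop("Fu's Fs requires n >= 2")
  khat <- meanPairwiseDifferences(a)
  K <- length(collapseHaplotypes(a)[[1L]]@counts)
  .fuFsFromKk(khat, K, n)
}

# per-sequence folded singleton counts: an allele carried by exactly one
# sequence at a segregating column counts toward that sequence
.singletonCounts <- function(a) {
  n <- nSamples(a)
  U <- integer(n)
  cnt <- .alleleCountMatrix(a@seqs)
  seg <- colSums(cnt > 0) > 1L
  for (b in .DNA_ALPHABET) {
    cols <- which(seg & cnt[b, ] == 1L)
    if (!length(cols)) next
    hit <- which(a@seqs[, cols, drop = FALSE] == b, arr.ind = TRUE)
    U <- U + tabulate(hit[, "row"], n)
  }
  U
}

#' Ramos-Onsins and Rozas R2
#'
#' R2 = sqrt(mean((U_i - k/2)^2)) / S, where U_i is the number of singleton
#' mutations carried by sequence i (folded definition: the minority sequence
#' at a site where one sequence differs from all others).  Low values
#' indicate an excess of singletons relative to pairwise diversity, as
#' expected after population growth.
#'
#' @param a a \linkS4class{HapAlignment} restricted to one population
#' @return R2 >= 0, or NA when S = 0
#' @export
r2Statistic <- function(a) {
  n <- nSamples(a)
  if (n < 2L) stop("R2 requires n >= 2")
  S <- segregatingSites(a)
  if (S == 0L) return(NA_real_)
  k <- meanPairwiseDifferences(a)
  U <- .singletonCounts(a)
  sqrt(mean((U - k / 2)^2)) / S
}

#' Simulate the coalescent null distribution of the neutrality statistics
#'
#' Constant-size coalescent genealogies with mutations either placed
#' uniformly on the genealogy conditioned on a fixed number of segregating
#' sites (\code{conditionOn = "S"}, the default, matching common
#' Arlequin/DnaSP practice) or as a Poisson process at rate theta/2 per
#' lineage (\code{conditionOn = "theta"}).  Infinite-sites mutation.
#'
#' @param n sample size
#' @param S segregating sites to condition on (\code{conditionOn = "S"})
#' @param theta scaled mutation rate (\code{conditionOn = "theta"})
#' @param reps number of replicates
#' @param seed integer seed (R RNG); NULL leaves the RNG state alone
#' @param conditionOn "S" or "theta"
#' @return data.frame with columns S, D, Fs, R2 (\code{reps} rows)
#' @export
simulateNullNeutrality <- function(n, S = NULL, theta = NULL, reps = 1000L,
                                   seed = NULL,
                                   conditionOn = c("S", "theta")) {
  conditionOn <- match.arg(conditionOn)
  if (!is.null(seed)) set.seed(seed)
  if (conditionOn == "S") {
    if (is.null(S) || S < 0) stop("conditioning on S requires S >= 0")
    m <- .cpp_null_neutrality(n, as.integer(S), 0, as.integer(reps), TRUE)
  } else {
    if (is.null(theta) || theta < 0) stop("conditioning on theta requires theta >= 0")
    m <- .cpp_null_neutrality(n, 0L, theta, as.integer(reps), FALSE)
  }
  as.data.frame(m)
}

#' Empirical p-value of a neutrality statistic
#'
#' Lower-tail empirical p-value against the constant-size coalescent null:
#' p = (#\{sim <= obs\} + 1)/(reps + 1).  D, Fs and R2 all reject in the
#' lower tail under demographic expansion.
#'
#' @param statistic one of "D", "Fs", "R2"
#' @param observed the observed statistic (NA gives an NA p-value)
#' @param n sample size
#' @param S observed segregating sites (null conditioned on S by default)
#' @param reps simulation replicates
#' @param seed integer seed
#' @param conditionOn "S" (default) or "theta"
#' @param theta required when \code{conditionOn = "theta"}
#' @return empirical p-value in (0, 1]
#' @export
neutralityPValues <- function(statistic = c("D", "Fs", "R2"), observed, n, S,
                              reps = 10000L, seed = NULL,
                              conditionOn = c("S", "theta"), theta = NULL) {
  statistic <- match.arg(statistic)
  if (is.na(observed)) return(NA_real_)
  sim <- simulateNullNeutrality(n, S = S, theta = theta, reps = reps,
                                seed = seed, conditionOn = match.arg(conditionOn))
  x <- sim[[statistic]]
  x <- x[!is.na(x)]
  (sum(x <= observed) + 1) / (length(x) + 1)
}

#' Per-population neutrality-test table
#'
#' @param a a multi-population \linkS4class{HapAlignment}
#' @param reps null-simulation replicates per population
#' @param seed master seed; per-population seeds are derived from it
#' @return data.frame with population_id, n, S, D, pD, Fs, pFs, R2, pR2,
#'   reps, seed
#' @export
neutralityTable <- function(a, reps = 1000L, seed = 1L) {
  pops <- unique(a@populations)
  rows <- lapply(seq_along(pops), function(i) {
    ap <- subsetPopulations(a, pops[i])
    n <- nSamples(ap)
    S <- segregatingSites(ap)
    D <- if (n >= 4L) tajimasD(ap) else NA_real_
    Fs <- fusFs(ap)
    R2 <- r2Statistic(ap)
    sd_i <- (seed + i) %% .Machine$integer.max
    ps <- vapply(list(c("D", D), c("Fs", Fs), c("R2", R2)), function(z) {
      obs <- as.numeric(z[2L])
      if (is.na(obs) || S == 0L) return(NA_real_)
      neutralityPValues(z[1L], obs, n, S, reps = reps, seed = sd_i)
    }, 0)
    data.frame(population_id = pops[i], n = n, S = S,
               D = D, pD = ps[1L], Fs = Fs, pFs = ps[2L],
               R2 = R2, pR2 = ps[3L], reps = reps, seed = sd_i)
  })
  do.call(rbind, rows)
}
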
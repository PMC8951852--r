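#' Observed mismatch distribution
#'
#' Relative frequencies of the pairwise-difference classes 0..d, where d is
#' the largest difference observed among the n(n-1)/2 unordered pairs.
#'
#' @param a a \linkS4class{HapAlignment} restricted to one population (n >= 2)
#' @return numeric vector x0..xd summing to 1
#' @export
mismatchDistribution <- function(a) {
  n <- nSamples(a)
  if (n < 2L) stop("mismatch distribution requires n >= 2")
  d <- .pairwiseDiffMatrix(a)
  diffs <- d[upper.tri(d)]
  tab <- tabulate(diffs + 1L, nbins = max(diffs) + 1L)
  tab / sum(tab)
}

# equilibrium spectrum F_j(theta) = theta^j / (theta+1)^(j+1), j = 0..d
.equilibriumMismatch <- function(theta, d) {
  j <- 0:d
  if (theta == 0) return(as.numeric(j == 0))
  exp(j * log(theta) - (j + 1) * log(theta + 1))
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' The classical pairwise-difference expectation for a population that
#' jumped from scaled size theta0 to theta1 at mutational time tau before
#' the present:
#' F_j = Fhat_j(theta1) +
#'       exp(-tau (theta1 + 1)/theta1) *
#'       sum_{i=0}^{j} (tau^i / i!) (Fhat_{j-i}(theta0) - Fhat_{j-i}(theta1)),
#' with Fhat the geometric equilibrium spectrum.  At tau = 0 it reduces to
#' the equilibrium spectrum with parameter theta0; for theta0 = 0 and large
#' theta1 it approaches a Poisson peak at tau.  Mass beyond class d is
#' folded into the last class so the vector sums to exactly 1.
#'
#' @param tau expansion time in mutational units (>= 0)
#' @param theta0,theta1 pre-/post-expansion scaled sizes (>= 0)
#' @param d largest difference class
#' @return probability vector over classes 0..d
#' @export
expectedMismatch <- function(tau, theta0, theta1, d) {
  if (any(c(tau, theta0, theta1) < 0) || !all(is.finite(c(tau, theta0, theta1))))
    stop("tau, theta0 and theta1 must be finite and nonnegative")
  f1 <- .equilibriumMismatch(theta1, d)
  f0 <- .equilibriumMismatch(theta0, d)
  if (tau == 0) {
    f <- f0
  } else {
    pref <- if (theta1 > 0) -tau * (theta1 + 1) / theta1 else -Inf
    i <- 0:d
    w <- exp(pref + i * log(tau) - lgamma(i + 1))
    delta <- f0 - f1
    conv <- vapply(0:d, function(j) sum(w[1:(j + 1)] * delta[(j + 1):1]), 0)
    f <- f1 + conv
  }
  f <- pmax(f, 0)
  f[d + 1L] <- max(1 - sum(f[seq_len(d)]), 0)
  f / sum(f)
}

#' Harpending's raggedness index
#'
#' Hri = sum_{i=1}^{d} (x_i - x_{i-1})^2 over the observed classes 0..d
#' (no padding beyond the observed support).  Smooth unimodal spectra give
#' low values; multimodal "ragged" spectra give high values.
#'
#' @param observed mismatch relative-frequency vector
#' @return Hri >= 0
#' @export
raggedness <- function(observed) {
  if (!length(observed)) stop("observed must be non-empty")
  if (length(observed) == 1L) return(0)
  sum(diff(observed)^2)
}

# vectorised SSD over a tau grid for fixed (theta0, theta1); the
# convolution over classes is a product with an upper-triangular Toeplitz
# matrix of the equilibrium-spectrum difference
.ssdGrid <- function(obs, taus, theta0, theta1) {
  d <- length(obs) - 1L
  f1 <- .equilibriumMismatch(theta1, d)
  f0 <- .equilibriumMismatch(theta0, d)
  delta <- f0 - f1
  pref <- if (theta1 > 0) -(theta1 + 1) / theta1 else -Inf
  i <- 0:d
  ltau <- ifelse(taus > 0, log(taus), -Inf)
  W <- exp(taus * pref + outer(ltau, i) - rep(lgamma(i + 1), each = length(taus)))
  W[taus == 0, ] <- 0                   # tau = 0 handled via f0 directly
  # Tmat[a+1, b+1] = delta[b - a + 1] for b >= a (upper-triangular Toeplitz)
  Tmat <- matrix(0, d + 1L, d + 1L)
  for (a in i) Tmat[a + 1L, (a:d) + 1L] <- delta[1:(d - a + 1L)]
  FF <- matrix(f1, length(taus), d + 1L, byrow = TRUE) + W %*% Tmat
  FF[taus == 0, ] <- matrix(f0, sum(taus == 0), d + 1L, byrow = TRUE)
  FF[FF < 0] <- 0
  FF[, d + 1L] <- pmax(1 - rowSums(FF[, seq_len(d), drop = FALSE]), 0)
  FF <- FF / rowSums(FF)
  colSums((t(FF) - obs)^2)
}

#' Fit the sudden-expansion model by least squares
#'
#' Minimises SSD = sum_j (x_j - F_j)^2 over (tau, theta0, theta1) with a
#' coarse grid start (tau in 0..20 by 0.5, theta0 and theta1 log-spaced)
#' followed by Nelder-Mead refinement (derivative-free, tolerance 1e-8 on
#' SSD).  The fit is deterministic.
#'
#' @param observed mismatch probability vector (classes 0..d)
#' @param refine run the local refinement after the grid (default TRUE)
#' @return a \linkS4class{MismatchFit} (bootstrap p-values NA)
#' @export
fitSuddenExpansion <- function(observed, refine = TRUE) {
  if (abs(sum(observed) - 1) > 1e-6)
    stop("observed must be a probability vector")
  d <- length(observed) - 1L
  if (d == 0L) {                         # degenerate: single class
    fit <- c(tau = 0, theta0 = 0, theta1 = 0)
    expd <- expectedMismatch(0, 0, 0, 0)
    return(methods::new("MismatchFit", observed = observed, expected = expd,
                        tau = 0, theta0 = 0, theta1 = 0,
                        ssd = sum((observed - expd)^2),
                        hri = raggedness(observed),
                        pSSD = NA_real_, pHri = NA_real_,
                        reps = 0L, seed = NA_integer_))
  }
  taus <- seq(0, 20, by = 0.5)
  th0s <- c(0, 10^seq(-2, 1, length.out = 7))
  best <- c(Inf, 0, 0, 0)
  for (t0 in th0s) {
    th1s <- 10^seq(log10(max(t0, 0.05)), 3, length.out = 8)
    for (t1 in th1s) {
      ssds <- .ssdGrid(observed, taus, t0, t1)
      i <- which.min(ssds)
      if (ssds[i] < best[1L]) best <- c(ssds[i], taus[i], t0, t1)
    }
  }
  par <- best[2:4]
  ssd <- best[1L]
  if (refine) {
    obj <- function(p) {
      if (any(p < 0) || p[2L] > p[3L] + 1e-9) return(1e6)
      sum((observed - expectedMismatch(p[1L], p[2L], p[3L], d))^2)
    }
    opt <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 2000))
    if (opt$value < ssd) { par <- pmax(opt$par, 0); ssd <- opt$value }
  }
  expd <- expectedMismatch(par[1L], par[2L], par[3L], d)
  methods::new("MismatchFit", observed = observed, expected = expd,
               tau = par[1L], theta0 = par[2L], theta1 = par[3L],
               ssd = ssd, hri = raggedness(observed),
               pSSD = NA_real_, pHri = NA_real_,
               reps = 0L, seed = NA_integer_)
}

#' Parametric-bootstrap p-values for SSD and raggedness
#'
#' Simulates \code{reps} coalescent datasets of the same sample size and
#' sequence length under the fitted sudden-expansion model, refits the
#' model to each, and reports the upper-tail fractions
#' p = #\{statistic_sim >= statistic_obs\} / reps for both SSD and Hri
#' (Arlequin's goodness-of-fit scheme).
#'
#' @param a the \linkS4class{HapAlignment} (one population) the fit came from
#' @param fit a \linkS4class{MismatchFit}
#' @param reps bootstrap replicates (default 1000)
#' @param seed integer seed
#' @return the fit with \code{pSSD}, \code{pHri}, \code{reps}, \code{seed}
#'   filled in
#' @export
expansionBootstrapP <- function(a, fit, reps = 1000L, seed = 1L) {
  if (reps < 1L) stop("reps must be >= 1")
  n <- nSamples(a)
  L <- nSites(a)
  set.seed(seed)
  theta0 <- max(fit@theta0, 1e-6)
  theta1 <- max(fit@theta1, theta0)
  cnt_ssd <- 0L
  cnt_hri <- 0L
  for (r in seq_len(reps)) {
    sim <- simulateExpansion(simConfig(nPerPop = n, L = L, model = "expansion",
                                       theta0 = theta0, theta1 = theta1,
                                       tau = fit@tau,
                                       seed = sample.int(2^31 - 1, 1)))
    obs_r <- mismatchDistribution(sim$alignment)
    fit_r <- fitSuddenExpansion(obs_r, refine = FALSE)
    if (fit_r@ssd >= fit@ssd) cnt_ssd <- cnt_ssd + 1L
    if (fit_r@hri >= fit@hri) cnt_hri <- cnt_hri + 1L
  }
  methods::initialize(fit, pSSD = cnt_ssd / reps, pHri = cnt_hri / reps,
                      reps = as.integer(reps), seed = as.integer(seed))
}

#' Per-population mismatch / expansion table
#'
#' @param a a multi-population \linkS4class{HapAlignment}
#' @param reps bootstrap replicates per population (0 to skip p-values)
#' @param seed master seed
#' @return data.frame with population_id, tau, theta0, theta1, SSD, pSSD,
#'   Hri, pHri
#' @export
mismatchTable <- function(a, reps = 1000L, seed = 1L) {
  pops <- unique(a@populations)
  rows <- lapply(seq_along(pops), function(i) {
    ap <- subsetPopulations(a, pops[i])
    if (nSamples(ap) < 2L)
      return(data.frame(population_id = pops[i], tau = NA_real_,
                        theta0 = NA_real_, theta1 = NA_real_, SSD = NA_real_,
                        pSSD = NA_real_, Hri = NA_real_, pHri = NA_real_))
    fit <- fitSuddenExpansion(mismatchDistribution(ap))
    if (reps > 0L)
      fit <- expansionBootstrapP(ap, fit, reps = reps,
                                 seed = (seed + i) %% .Machine$integer.max)
    data.frame(population_id = pops[i], tau = fit@tau, theta0 = fit@theta0,
               theta1 = fit@theta1, SSD = fit@ssd, pSSD = fit@pSSD,
               Hri = fit@hri, pHri = fit@pHri)
  })
  do.call(rbind, rows)
}
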
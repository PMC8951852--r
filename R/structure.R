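#' Distance model configuration
#'
#' The study's distance settings: Kimura two-parameter model with gamma
#' rate-heterogeneity correction (shape 0.4) and a transition/transversion
#' ratio of 10/1.  The ts/tv ratio parameterises the finite-sites simulator
#' and optional mutation weighting; the K2P estimator itself estimates the
#' transition and transversion fractions from the data.  Setting
#' \code{method = "raw"} uses plain numbers of differences instead.
#'
#' @param gammaShape gamma shape parameter a (> 0); \code{Inf} gives the
#'   uncorrected K2P distance
#' @param tstv transition/transversion ratio (simulation / weighting)
#' @param method "k2p_gamma" or "raw"
#' @return a list of class \code{distanceConfig}
#' @export
distanceConfig <- function(gammaShape = 0.4, tstv = 10,
                           method = c("k2p_gamma", "raw")) {
  if (gammaShape <= 0) stop("gammaShape must be > 0")
  structure(list(gammaShape = gammaShape, tstv = tstv,
                 method = match.arg(method)),
            class = "distanceConfig")
}

#' Gamma-corrected Kimura two-parameter distance between two sequences
#'
#' d = (a/2) [(1 - 2P - Q)^(-1/a) - 1] + (a/4) [(1 - 2Q)^(-1/a) - 1], with
#' P and Q the transition and transversion difference fractions and a the
#' gamma shape.  As a grows the uncorrected K2P distance
#' -ln(1-2P-Q)/2 - ln(1-2Q)/4 is recovered.
#'
#' @param seqI,seqJ character vectors (or strings) of equal length over
#'   A,C,G,T
#' @param cfg a \code{\link{distanceConfig}}
#' @return distance >= 0 (substitutions per site)
#' @export
k2pGammaDistance <- function(seqI, seqJ, cfg = distanceConfig()) {
  if (length(seqI) == 1L) seqI <- strsplit(seqI, "")[[1L]]
  if (length(seqJ) == 1L) seqJ <- strsplit(seqJ, "")[[1L]]
  if (length(seqI) != length(seqJ)) stop("sequences must have equal length")
  L <- length(seqI)
  diffs <- seqI != seqJ
  ts <- diffs & ((seqI == "A" & seqJ == "G") | (seqI == "G" & seqJ == "A") |
                 (seqI == "C" & seqJ == "T") | (seqI == "T" & seqJ == "C"))
  P <- sum(ts) / L
  Q <- (sum(diffs) - sum(ts)) / L
  .k2pGammaFromPQ(P, Q, cfg$gammaShape)
}

.k2pGammaFromPQ <- function(P, Q, a) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0))
    stop("K2P distance saturated (1-2P-Q or 1-2Q nonpositive) for a pair ",
         "with P = ", max(P), ", Q = ", max(Q))
  if (is.infinite(a)) return(-log(w1) / 2 - log(w2) / 4)
  (a / 2) * (w1^(-1 / a) - 1) + (a / 4) * (w2^(-1 / a) - 1)
}

#' All pairwise sequence distances within an alignment
#'
#' @param a a \linkS4class{HapAlignment}
#' @param cfg a \code{\link{distanceConfig}}
#' @return symmetric n x n matrix of distances ("raw": numbers of
#'   differences; "k2p_gamma": substitutions per site)
#' @export
pairwiseDistances <- function(a, cfg = distanceConfig()) {
  seqs <- a@seqs
  L <- ncol(seqs)
  ind <- .seqIndicator(seqs)
  names(ind) <- c("A", "C", "G", "T")
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  nd <- L - matches
  if (cfg$method == "raw") {
    diag(nd) <- 0
    return(nd)
  }
  tsmat <- ind$A %*% t(ind$G) + ind$G %*% t(ind$A) +
    ind$C %*% t(ind$T) + ind$T %*% t(ind$C)
  P <- tsmat / L
  Q <- (nd - tsmat) / L
  d <- matrix(0, nrow(seqs), nrow(seqs))
  up <- upper.tri(d)
  d[up] <- .k2pGammaFromPQ(P[up], Q[up], cfg$gammaShape)
  d <- d + t(d)
  d
}

#' Pairwise Phi-ST between two populations
#'
#' One-level variance decomposition of squared inter-haplotype distances
#' (sums of squares from pairwise squared distances), with an empirical
#' p-value from permuting individuals between the two populations:
#' p = (#\{perm >= obs\} + 1)/(perms + 1).
#'
#' @param a a \linkS4class{HapAlignment} containing (at least) both
#'   populations
#' @param popI,popJ population labels
#' @param cfg a \code{\link{distanceConfig}}
#' @param perms permutation count (0 skips the test)
#' @param seed integer seed
#' @return list with \code{phist}, \code{p}, \code{sigma2} (among, within)
#' @export
pairwisePhist <- function(a, popI, popJ, cfg = distanceConfig(),
                          perms = 10000L, seed = 1L) {
  ap <- subsetPopulations(a, c(popI, popJ))
  if (min(table(ap@populations)) < 2L)
    stop("both populations need >= 2 samples")
  d2 <- pairwiseDistances(ap, cfg)^2
  if (all(d2 == 0))                       # identical monomorphic populations
    return(list(phist = 0, p = 1, sigma2 = c(among = 0, within = 0)))
  popIdx <- as.integer(factor(ap@populations, levels = c(popI, popJ))) - 1L
  set.seed(seed)
  res <- .cpp_phist_pair(d2, popIdx, as.integer(perms))
  list(phist = res$phist, p = res$p,
       sigma2 = c(among = res$sigma2[1L], within = res$sigma2[2L]))
}

#' Reynolds-style linearization of Phi-ST
#'
#' -ln(1 - Phi), with negative estimates clipped to 0 before the transform
#' (negative values are sampling noise) and Phi = 1 flagged as Inf.
#'
#' @param phi numeric vector or matrix of Phi-ST values (< 1)
#' @return transformed values; Inf where phi = 1
#' @export
linearizePhist <- function(phi) {
  out <- -log1p(-pmax(phi, 0))
  if (any(is.infinite(out)))
    warning("Phi-ST of 1 linearizes to Inf; flagged")
  if (is.matrix(phi)) out <- matrix(out, nrow(phi), ncol(phi),
                                    dimnames = dimnames(phi))
  out
}

#' Matrix of pairwise Phi-ST over all populations
#'
#' @param a a multi-population \linkS4class{HapAlignment} (every population
#'   >= 2 samples)
#' @param cfg a \code{\link{distanceConfig}}
#' @param perms permutations per pair (0 skips p-values)
#' @param seed master seed; per-pair seeds derived from it
#' @return a \linkS4class{PhistMatrix}
#' @export
phistMatrix <- function(a, cfg = distanceConfig(), perms = 10000L, seed = 1L) {
  pops <- unique(a@populations)
  k <- length(pops)
  phi <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  idx <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    idx <- idx + 1L
    r <- pairwisePhist(a, pops[i], pops[j], cfg, perms,
                       seed = (seed + idx) %% .Machine$integer.max)
    phi[i, j] <- phi[j, i] <- r$phist
    pv[i, j] <- pv[j, i] <- r$p
  }
  lin <- linearizePhist(phi)
  diag(lin) <- 0
  methods::new("PhistMatrix", populations = pops, phist = phi, pvals = pv,
               linearized = lin, perms = as.integer(perms),
               seed = as.integer(seed), method = cfg$method)
}

#' Nonmetric multidimensional scaling of a population distance matrix
#'
#' Kruskal stress-1 NMDS (via \code{vegan::metaMDS} with random restarts)
#' on the linearized Phi-ST matrix (or any symmetric nonnegative matrix).
#'
#' @param m a \linkS4class{PhistMatrix}, \code{dist}, or symmetric matrix
#' @param dims embedding dimensions (default 2)
#' @param restarts random restarts (default 50)
#' @param seed integer seed (NMDS is stochastic in its starts)
#' @return list with \code{coordinates} (populations x dims), \code{stress}
#'   (Kruskal stress-1, 0..1 scale), \code{seed}, \code{restarts},
#'   \code{converged}
#' @export
nmdsOrdination <- function(m, dims = 2L, restarts = 50L, seed = 1L) {
  if (methods::is(m, "PhistMatrix")) m <- stats::as.dist(m@linearized)
  if (is.matrix(m)) m <- stats::as.dist(m)
  if (attr(m, "Size") < 3L) stop("NMDS needs at least 3 populations")
  set.seed(seed)
  fit <- vegan::metaMDS(m, k = dims, trymax = restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE,
                        weakties = TRUE)
  list(coordinates = vegan::scores(fit), stress = fit$stress,
       seed = seed, restarts = restarts, converged = fit$converged)
}

#' Kruskal-Wallis comparison of a per-population index across groups
#'
#' Rank-based H with tie correction and the chi-square approximation on
#' g - 1 degrees of freedom (via \code{stats::kruskal.test}).  All-identical
#' values give H = 0, p = 1.
#'
#' @param values numeric vector (one value per population)
#' @param groups group label per value (>= 2 non-empty groups)
#' @return list with \code{H}, \code{df}, \code{p}
#' @export
kruskalWallisGroups <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Kruskal-Wallis table across indices and grouping schemes
#'
#' Reproduces the study's table layout: one row per grouping scheme, one
#' column of p-values per diversity/demography index.
#'
#' @param stats data.frame with a \code{population_id} column plus numeric
#'   index columns
#' @param meta metadata data.frame (see \code{\link{readSampleMetadata}})
#' @param schemes metadata columns to group by
#' @param indices index columns of \code{stats} to test
#' @return data.frame of p-values (schemes x indices)
#' @export
kruskalWallisTable <- function(stats, meta,
                               schemes = c("region1", "lifestyle1", "language",
                                           "region2", "lifestyle2"),
                               indices = intersect(c("H", "pi", "k", "pFs",
                                                     "pHri", "pSSD"),
                                                   names(stats))) {
  m <- match(stats$population_id, meta$population_id)
  if (anyNA(m))
    stop("populations missing from metadata: ",
         paste(stats$population_id[is.na(m)], collapse = ", "))
  out <- matrix(NA_real_, length(schemes), length(indices),
                dimnames = list(schemes, indices))
  for (s in schemes) for (ix in indices) {
    g <- meta[[s]][m]
    if (length(unique(g)) >= 2L)
      out[s, ix] <- kruskalWallisGroups(stats[[ix]], g)$p
  }
  as.data.frame(out)
}
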
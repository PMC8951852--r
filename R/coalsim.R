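#' Simulation configuration
#'
#' Time is measured in units of N generations (N the present haploid
#' population size per deme), so a pair of lineages within a deme coalesces
#' at rate 1, each lineage mutates at rate theta/2 (theta = 2Nu per
#' sequence), and each lineage emigrates at total rate Nm.  The
#' sudden-expansion model changes size from theta0 to theta1 at scaled time
#' tau/theta1 before the present, which makes the simulator's tau identical
#' to the mismatch model's mutational-units tau.
#'
#' @param nPerPop samples per population
#' @param nPops number of populations (island model)
#' @param L sequence length in sites (default 328, the masked HVS-1 window)
#' @param model "constant", "expansion" or "island"
#' @param theta scaled mutation rate (constant / island, per deme)
#' @param theta0,theta1,tau sudden-expansion parameters
#' @param Nm scaled migrants per generation (island model)
#' @param tstv transition/transversion ratio of the finite-sites mutation
#'   model (default 10)
#' @param gammaShape shape of the per-site gamma rate heterogeneity
#'   (default 0.4); \code{Inf} disables heterogeneity (uniform rates)
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output
#' @param groupOf optional per-population group labels (hierarchical
#'   structure); cross-group migration is scaled by \code{crossGroupFactor}
#' @param crossGroupFactor multiplier (< 1 reduces) on migration between
#'   populations in different groups
#' @return a list of class \code{simConfig}
#' @export
simConfig <- function(nPerPop, nPops = 1L, L = 328L,
                      model = c("constant", "expansion", "island"),
                      theta = 5, theta0 = 1, theta1 = 100, tau = 4,
                      Nm = 1, tstv = 10, gammaShape = 0.4, seed = 1L,
                      groupOf = NULL, crossGroupFactor = 1) {
  model <- match.arg(model)
  if (L < 1L) stop("L must be >= 1")
  if (any(c(theta, theta0, theta1, tau, Nm) < 0)) stop("rates must be >= 0")
  if (!is.finite(gammaShape) && !is.infinite(gammaShape))
    stop("gammaShape must be positive or Inf")
  if (model == "island" && nPops < 2L) stop("island model needs nPops >= 2")
  structure(list(nPerPop = as.integer(nPerPop), nPops = as.integer(nPops),
                 L = as.integer(L), model = model, theta = theta,
                 theta0 = theta0, theta1 = theta1, tau = tau, Nm = Nm,
                 tstv = tstv, gammaShape = gammaShape,
                 seed = as.integer(seed), groupOf = groupOf,
                 crossGroupFactor = crossGroupFactor),
            class = "simConfig")
}

# single-population coalescent genealogy with piecewise-constant relative
# size: relSize = 1 for t < boundary, relSize = shrink for t >= boundary
# (boundary = Inf for constant size).  Returns parent pointers, node times.
.simGenealogy <- function(n, boundary = Inf, shrink = 1) {
  m <- 2L * n - 1L
  parent <- integer(m)
  times <- numeric(m)
  active <- 1:n
  t <- 0
  nxt <- n + 1L
  rel <- 1
  while (length(active) > 1L) {
    k <- length(active)
    repeat {
      dt <- stats::rexp(1L, rate = k * (k - 1) / 2 / rel)
      if (t < boundary && t + dt > boundary) {
        t <- boundary
        rel <- shrink
      } else {
        t <- t + dt
        break
      }
    }
    pair <- sample(k, 2L)
    a <- active[pair[1L]]; b <- active[pair[2L]]
    parent[a] <- nxt; parent[b] <- nxt
    times[nxt] <- t
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, times = times, n = n)
}

# structured (island-model) coalescent: demeOf per sample, per-lineage total
# emigration rate Nm, target weights scaled by crossGroupFactor across groups.
# In the strong-migration regime (Nm >= 1e4) lineage locations mix orders of
# magnitude faster than they coalesce, so the genealogy is simulated as a
# single panmictic coalescent scaled to the metapopulation size, which is the
# exact strong-migration limit.
.simGenealogyIsland <- function(nPerPop, nPops, Nm, groupIdx, crossFactor) {
  if (Nm >= 1e4) {
    gen <- .simGenealogy(nPerPop * nPops)
    gen$times <- gen$times * nPops     # metapopulation coalescent timescale
    return(gen)
  }
  n <- nPerPop * nPops
  m <- 2L * n - 1L
  parent <- integer(m)
  times <- numeric(m)
  deme <- rep(seq_len(nPops), each = nPerPop)  # deme of each active lineage
  lin <- 1:n
  lindeme <- deme
  t <- 0
  nxt <- n + 1L
  # per-source-deme emigration rate and target weights
  wmat <- matrix(1, nPops, nPops)
  for (i in seq_len(nPops)) for (j in seq_len(nPops)) {
    if (i == j) wmat[i, j] <- 0
    else if (groupIdx[i] != groupIdx[j]) wmat[i, j] <- crossFactor
  }
  base <- Nm / (nPops - 1)
  migRateDeme <- base * rowSums(wmat)
  while (length(lin) > 1L) {
    kd <- tabulate(lindeme, nPops)
    coalRates <- kd * (kd - 1) / 2
    migRates <- migRateDeme[lindeme]
    tot <- sum(coalRates) + sum(migRates)
    t <- t + stats::rexp(1L, rate = tot)
    if (stats::runif(1L) * tot < sum(coalRates)) {
      d <- sample.int(nPops, 1L, prob = coalRates)
      idx <- which(lindeme == d)
      pair <- idx[sample(length(idx), 2L)]
      a <- lin[pair[1L]]; b <- lin[pair[2L]]
      parent[a] <- nxt; parent[b] <- nxt
      times[nxt] <- t
      lin <- c(lin[-pair], nxt)
      lindeme <- c(lindeme[-pair], d)
      nxt <- nxt + 1L
    } else {
      i <- sample.int(length(lin), 1L, prob = migRates)
      lindeme[i] <- sample.int(nPops, 1L, prob = wmat[lindeme[i], ])
    }
  }
  list(parent = parent, times = times, n = n)
}

# drop mutations on a genealogy and evolve sequences under the finite-sites
# model: per-site gamma rates, transition with prob tstv/(tstv+1)
.mutateGenealogy <- function(gen, theta, L, tstv, gammaShape, fixedS = NULL) {
  n <- gen$n
  m <- 2L * n - 1L
  root <- m
  blen <- numeric(m)
  nonroot <- seq_len(m - 1L)
  blen[nonroot] <- gen$times[gen$parent[nonroot]] - gen$times[nonroot]
  Ltot <- sum(blen)
  M <- if (is.null(fixedS)) stats::rpois(1L, theta / 2 * Ltot) else fixedS
  rates <- if (is.finite(gammaShape))
    stats::rgamma(L, shape = gammaShape, rate = gammaShape) else rep(1, L)
  bases <- c("A", "C", "G", "T")
  rootSeq <- sample(bases, L, replace = TRUE)
  seqs <- matrix("", n, L)
  if (M > 0) {
    branch <- sample.int(m - 1L, M, replace = TRUE, prob = blen[nonroot])
    site <- sample.int(L, M, replace = TRUE, prob = rates)
    mtime <- gen$times[branch] + stats::runif(M) * blen[branch]
    isTs <- stats::runif(M) < tstv / (tstv + 1)
    tvPick <- stats::runif(M)
    byBranch <- split(seq_len(M), branch)
  } else byBranch <- list()
  tsMap <- c(A = "G", G = "A", C = "T", T = "C")
  tvMap <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  children <- split(nonroot, gen$parent[nonroot])
  apply_branch <- function(sq, v) {
    idx <- byBranch[[as.character(v)]]
    if (!is.null(idx)) {
      for (i in idx[order(mtime[idx], decreasing = TRUE)]) {
        b <- sq[site[i]]
        sq[site[i]] <- if (isTs[i]) tsMap[[b]]
                       else tvMap[[b]][1L + (tvPick[i] > 0.5)]
      }
    }
    sq
  }
  stack <- list(list(node = root, seq = rootSeq))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top$node
    if (v <= n) seqs[v, ] <- top$seq
    else for (ch in children[[as.character(v)]])
      stack[[length(stack) + 1L]] <- list(node = ch,
                                          seq = apply_branch(top$seq, ch))
  }
  seqs
}

.simAlignment <- function(seqs, popLabels, prefix = "sim") {
  n <- nrow(seqs)
  hapAlignment(seqs, samples = sprintf("%s%04d", prefix, seq_len(n)),
               populations = popLabels, coordStart = 1L)
}

#' Simulate a constant-size population sample
#'
#' @param cfg a \code{\link{simConfig}} with \code{model = "constant"}
#' @return list with \code{alignment} (\linkS4class{HapAlignment}) and
#'   \code{metadata} (data.frame)
#' @export
simulateConstant <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"), cfg$model == "constant")
  set.seed(cfg$seed)
  gen <- .simGenealogy(cfg$nPerPop)
  seqs <- .mutateGenealogy(gen, cfg$theta, cfg$L, cfg$tstv, cfg$gammaShape)
  aln <- .simAlignment(seqs, "pop1")
  list(alignment = aln,
       metadata = data.frame(population_id = "pop1", group = "g1"))
}

#' Simulate a sample from a suddenly expanded population
#'
#' Instantaneous size change from theta0 to theta1 at mutational time tau
#' before the present (scaled time tau/theta1).
#'
#' @param cfg a \code{\link{simConfig}} with \code{model = "expansion"}
#' @return list with \code{alignment} and \code{metadata}
#' @export
simulateExpansion <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"), cfg$model == "expansion")
  set.seed(cfg$seed)
  boundary <- if (cfg$theta1 > 0) cfg$tau / cfg$theta1 else Inf
  shrink <- if (cfg$theta1 > 0) cfg$theta0 / cfg$theta1 else 1
  shrink <- max(shrink, 1e-8)            # guard a hard-zero ancestral size
  gen <- .simGenealogy(cfg$nPerPop, boundary = boundary, shrink = shrink)
  seqs <- .mutateGenealogy(gen, cfg$theta1, cfg$L, cfg$tstv, cfg$gammaShape)
  aln <- .simAlignment(seqs, "pop1")
  list(alignment = aln,
       metadata = data.frame(population_id = "pop1", group = "g1"))
}

#' Simulate a symmetric island-model metapopulation
#'
#' \code{nPops} demes exchanging migrants at total per-lineage rate Nm;
#' optional hierarchical group labels scale cross-group migration by
#' \code{crossGroupFactor}, injecting among-group structure for AMOVA
#' validation.  Nm >= 1e4 is simulated in its exact strong-migration
#' (panmictic) limit rather than event by event.
#'
#' @param cfg a \code{\link{simConfig}} with \code{model = "island"}
#' @return list with \code{alignment} and \code{metadata} (columns
#'   population_id, group)
#' @export
simulateIsland <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"), cfg$model == "island")
  set.seed(cfg$seed)
  groupOf <- cfg$groupOf
  if (is.null(groupOf)) groupOf <- rep("g1", cfg$nPops)
  groupIdx <- as.integer(factor(groupOf, levels = unique(groupOf)))
  gen <- .simGenealogyIsland(cfg$nPerPop, cfg$nPops, cfg$Nm, groupIdx,
                             cfg$crossGroupFactor)
  seqs <- .mutateGenealogy(gen, cfg$theta, cfg$L, cfg$tstv, cfg$gammaShape)
  pops <- sprintf("pop%02d", rep(seq_len(cfg$nPops), each = cfg$nPerPop))
  aln <- .simAlignment(seqs, pops)
  list(alignment = aln,
       metadata = data.frame(population_id = sprintf("pop%02d", seq_len(cfg$nPops)),
                             group = groupOf))
}

#' Simulate the study's hierarchical sampling design
#'
#' An island-model metapopulation whose demes are laid out on the study's
#' grouping grid: four region cells (eNA, wNA, eSS, wSS) each holding
#' \code{popsPerCell} populations, lifestyle (FM/PS) alternating within a
#' cell and language families assigned by region.  Migration within a
#' region cell runs at the full rate; migration between cells is scaled by
#' \code{crossGroupFactor}, so Region2 is the "true" grouping of the data.
#'
#' @param nPerPop samples per population
#' @param popsPerCell populations per region cell
#' @param theta per-deme scaled mutation rate
#' @param Nm within-cell scaled migration rate
#' @param crossGroupFactor cross-cell migration multiplier (default 0.1)
#' @param L sites
#' @param seed integer seed
#' @param tstv,gammaShape finite-sites mutation parameters
#' @return list with \code{alignment} and full study-style \code{metadata}
#'   (validated by \code{\link{validateSampleMetadata}})
#' @export
simulateHierarchical <- function(nPerPop = 20L, popsPerCell = 3L, theta = 3,
                                 Nm = 5, crossGroupFactor = 0.1, L = 328L,
                                 seed = 1L, tstv = 10, gammaShape = 0.4) {
  cells <- c("eNA", "wNA", "eSS", "wSS")
  nPops <- 4L * popsPerCell
  region2 <- rep(cells, each = popsPerCell)
  cfg <- simConfig(nPerPop = nPerPop, nPops = nPops, L = L, model = "island",
                   theta = theta, Nm = Nm, tstv = tstv,
                   gammaShape = gammaShape, seed = seed, groupOf = region2,
                   crossGroupFactor = crossGroupFactor)
  sim <- simulateIsland(cfg)
  region1 <- ifelse(region2 %in% c("eNA", "wNA"), "NA", "SS")
  lifestyle1 <- rep(c("FM", "PS"), length.out = popsPerCell)
  lifestyle1 <- rep(lifestyle1, 4L)[seq_len(nPops)]
  lifestyle2 <- paste0(substr(lifestyle1, 1L, 1L),
                       ifelse(region1 == "NA", "NA", "SS"))
  language <- c(eNA = "AA", wNA = "AA", eSS = "NS", wSS = "NC")[region2]
  md <- data.frame(population_id = sim$metadata$population_id,
                   country = "simland", region1 = region1, region2 = region2,
                   lifestyle1 = lifestyle1, lifestyle2 = lifestyle2,
                   language = unname(language))
  list(alignment = sim$alignment, metadata = validateSampleMetadata(md))
}

#' Write a simulated dataset in the package's input dialect
#'
#' Emits \code{<prefix>.fasta} (headers \code{sample population}) and
#' \code{<prefix>_meta.tsv}.
#'
#' @param sim a list with \code{alignment} and \code{metadata}
#' @param prefix output path prefix
#' @return the two file paths, invisibly
#' @export
writeSimulation <- function(sim, prefix) {
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, "_meta.tsv")
  writeHapAlignment(sim$alignment, fa)
  utils::write.table(sim$metadata, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa, tsv))
}
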
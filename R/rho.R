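#' Construct a mutation-annotated clade tree
#'
#' @param tree a rooted \code{ape} \code{phylo} object
#' @param mutations per-edge mutation counts in \code{tree$edge} row order;
#'   defaults to \code{tree$edge.length}
#' @param tipMult per-tip sample multiplicities (named or in tip order);
#'   default 1 for every tip
#' @return a \linkS4class{CladeTree}
#' @export
cladeTree <- function(tree, mutations = tree$edge.length, tipMult = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (is.null(mutations))
    stop("per-branch mutation counts are required (edge lengths absent)")
  nt <- length(tree$tip.label)
  if (is.null(tipMult)) tipMult <- stats::setNames(rep(1, nt), tree$tip.label)
  if (is.null(names(tipMult))) names(tipMult) <- tree$tip.label
  tipMult <- tipMult[tree$tip.label]
  methods::new("CladeTree", tree = tree, mutations = as.numeric(mutations),
               tipMult = tipMult)
}

#' Read a clade tree from a Newick file
#'
#' Branch lengths are interpreted as per-branch mutation counts.  Tip
#' multiplicities may be encoded as a \code{*k} suffix on the tip label
#' (\code{"H1*3"} = haplotype H1 sampled three times).
#'
#' @param path Newick file
#' @return a \linkS4class{CladeTree}
#' @export
readCladeTree <- function(path) {
  tr <- ape::read.tree(path)
  lab <- tr$tip.label
  mult <- rep(1, length(lab))
  has <- grepl("\\*[0-9]+$", lab)
  mult[has] <- as.numeric(sub(".*\\*", "", lab[has]))
  tr$tip.label <- sub("\\*[0-9]+$", "", lab)
  cladeTree(tr, tipMult = stats::setNames(mult, tr$tip.label))
}

#' Build a star clade tree
#'
#' n tips radiating from the root, each tip branch carrying k mutations:
#' the closed-form case rho = k, sigma_rho = sqrt(k/n).
#'
#' @param n number of tips
#' @param k mutations per tip branch
#' @return a \linkS4class{CladeTree}
#' @export
starCladeTree <- function(n, k = 1) {
  tr <- ape::read.tree(text = paste0("(", paste0("t", seq_len(n), ":", k,
                                                 collapse = ","), ");"))
  cladeTree(tr)
}

#' The rho statistic of a clade
#'
#' rho is the mean number of mutations separating the sampled lineages from
#' the clade's root (ancestral haplotype): rho = (1/n) sum_b m_b n_b over
#' branches b, with n_b the number of sampled lineages (tip multiplicities
#' included) descending from b.  The standard error follows the classical
#' genealogy-conditional form sigma_rho^2 = (1/n^2) sum_b m_b n_b^2.
#'
#' @param ct a \linkS4class{CladeTree}
#' @return list with \code{rho}, \code{sigmaRho}, \code{n}
#' @export
rhoFromTree <- function(ct) {
  tr <- ct@tree
  nt <- length(tr$tip.label)
  if (nt < 1L) stop("empty clade")
  n <- sum(ct@tipMult)
  # lineages under each node (tips weighted by multiplicity)
  nnode <- nt + tr$Nnode
  under <- numeric(nnode)
  under[seq_len(nt)] <- ct@tipMult
  # accumulate child weights up the tree: edges sorted child-desc works for
  # any valid phylo since parents always have larger indices than... not
  # guaranteed; iterate in reverse depth order instead
  ord <- order(.nodeDepths(tr), decreasing = TRUE)
  for (v in ord) {
    if (v <= nt) next
    kids <- tr$edge[tr$edge[, 1L] == v, 2L]
    under[v] <- sum(under[kids])
  }
  nb <- under[tr$edge[, 2L]]
  rho <- sum(ct@mutations * nb) / n
  sigma <- sqrt(sum(ct@mutations * nb^2)) / n
  list(rho = rho, sigmaRho = sigma, n = n)
}

.nodeDepths <- function(tr) {
  nt <- length(tr$tip.label)
  nnode <- nt + tr$Nnode
  depth <- rep(NA_real_, nnode)
  root <- setdiff(tr$edge[, 1L], tr$edge[, 2L])[1L]
  depth[root] <- 0
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      if (!is.na(depth[p]) && is.na(depth[ch])) {
        depth[ch] <- depth[p] + 1
        done <- FALSE
      }
    }
    if (done) break
  }
  depth
}

#' Mutation-rate clocks for rho dating
#'
#' The calibrated mitochondrial substitution intervals: one substitution
#' per 3624 years over the whole mitogenome (corrected for purifying
#' selection) and one synonymous substitution per 7884 years.
#'
#' @param totalYears years per substitution, whole-mitogenome clock
#' @param synonymousYears years per synonymous substitution
#' @return a named list of class \code{clockConfig}
#' @export
clockConfig <- function(totalYears = 3624, synonymousYears = 7884) {
  if (totalYears <= 0 || synonymousYears <= 0) stop("rates must be > 0")
  structure(list(total = totalYears, synonymous = synonymousYears),
            class = "clockConfig")
}

#' Convert a rho estimate to an age in years
#'
#' age = rho x years-per-substitution; 95% CI = age +/- 1.96 sigma_rho x
#' years-per-substitution, reported untruncated (a lower bound below zero
#' is kept as computed and flagged by a warning).
#'
#' @param rho rho statistic, or the list returned by
#'   \code{\link{rhoFromTree}}
#' @param sigmaRho standard error of rho (ignored when \code{rho} is a list)
#' @param clock "total" or "synonymous"
#' @param clocks a \code{\link{clockConfig}}
#' @param n number of sampled lineages (for the record)
#' @return a \linkS4class{RhoEstimate}
#' @export
ageFromRho <- function(rho, sigmaRho = 0, clock = c("total", "synonymous"),
                       clocks = clockConfig(), n = NA_real_) {
  if (is.list(rho)) {
    sigmaRho <- rho$sigmaRho; n <- rho$n; rho <- rho$rho
  }
  clock <- match.arg(clock)
  rate <- clocks[[clock]]
  if (is.null(rate)) stop("unknown clock: ", clock)
  age <- rho * rate
  ci <- age + c(-1.96, 1.96) * sigmaRho * rate
  if (ci[1L] < 0 && rho > 0)
    warning("lower CI bound is negative (reported untruncated)")
  methods::new("RhoEstimate", rho = rho, sigmaRho = sigmaRho, n = n,
               clock = clock, yearsPerSub = rate, ageYears = age,
               ci95Years = ci)
}

#' Partition mutations into synonymous and other
#'
#' @param mutations data.frame (or vector of positions) with a
#'   \code{position} column of rCRS positions
#' @param annotation data.frame with columns \code{position} and
#'   \code{class} ("synonymous" or anything else); must cover every queried
#'   position
#' @return list with \code{synonymous} and \code{other} counts
#' @export
classifyMutations <- function(mutations, annotation) {
  pos <- if (is.data.frame(mutations)) mutations$position else mutations
  if (!length(pos)) return(list(synonymous = 0L, other = 0L))
  m <- match(pos, annotation$position)
  if (anyNA(m))
    stop("no annotation for position(s): ",
         paste(sort(unique(pos[is.na(m)])), collapse = ", "))
  cls <- annotation$class[m]
  list(synonymous = sum(cls == "synonymous"),
       other = sum(cls != "synonymous"))
}

#' Clade-age report across clades and clocks
#'
#' @param clades named list of \linkS4class{CladeTree}
#' @param clocks a \code{\link{clockConfig}}
#' @param which clocks to report
#' @return data.frame with clade, n, rho, sigmaRho, clock, ageYears, ciLow,
#'   ciHigh
#' @export
cladeAgeTable <- function(clades, clocks = clockConfig(),
                          which = c("total", "synonymous")) {
  rows <- list()
  for (nm in names(clades)) {
    est <- rhoFromTree(clades[[nm]])
    for (cl in which) {
      re <- suppressWarnings(ageFromRho(est, clock = cl, clocks = clocks))
      rows[[length(rows) + 1L]] <-
        data.frame(clade = nm, n = est$n, rho = est$rho,
                   sigmaRho = est$sigmaRho, clock = cl,
                   ageYears = re@ageYears, ciLow = re@ci95Years[1L],
                   ciHigh = re@ci95Years[2L])
    }
  }
  do.call(rbind, rows)
}
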
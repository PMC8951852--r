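#' @useDynLib mtPopGen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' HapAlignment: an rCRS-anchored haplotype alignment with population labels
#'
#' The central data container of the package: an equal-length alignment of
#' mtDNA (typically HVS-1) sequences, stored as a character matrix with one
#' row per sampled individual, together with the rCRS coordinate of every
#' retained column and a population label per sample.  Columns need not be
#' contiguous: windowing and ambiguity masking drop columns while keeping
#' their original rCRS coordinates, so downstream position reports stay
#' anchored to the reference numbering.
#'
#' @slot seqs character matrix (samples x sites), alphabet A,C,G,T,N,-
#' @slot positions integer vector of rCRS positions, one per column,
#'   strictly increasing, all within 1..16569
#' @slot samples character vector of unique sample identifiers (row order)
#' @slot populations character vector of population labels, parallel to
#'   \code{samples}
#' @export
setClass("HapAlignment",
  slots = c(
    seqs = "matrix",
    positions = "integer",
    samples = "character",
    populations = "character"
  )
)

setValidity("HapAlignment", function(object) {
  msg <- character()
  n <- nrow(object@seqs)
  L <- ncol(object@seqs)
  if (length(object@samples) != n)
    msg <- c(msg, "length(samples) must equal nrow(seqs)")
  if (length(object@populations) != n)
    msg <- c(msg, "length(populations) must equal nrow(seqs)")
  if (length(object@positions) != L)
    msg <- c(msg, "length(positions) must equal ncol(seqs)")
  if (anyDuplicated(object@samples))
    msg <- c(msg, "sample identifiers must be unique")
  if (L > 0) {
    if (is.unsorted(object@positions, strictly = TRUE))
      msg <- c(msg, "positions must be strictly increasing")
    if (min(object@positions) < 1L || max(object@positions) > 16569L)
      msg <- c(msg, "positions must lie within the rCRS range 1..16569")
  }
  if (n > 0 && L > 0) {
    bad <- setdiff(unique(as.vector(object@seqs)), .DNA_ALPHABET)
    if (length(bad))
      msg <- c(msg, paste0("disallowed characters in alignment: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' AnalysisWindow: an rCRS coordinate window with exclusion intervals
#'
#' Coordinates are 1-based rCRS positions and all intervals are closed on
#' both ends, so the default HVS-1 window 16032..16370 spans
#' 16370 - 16032 + 1 = 339 positions, and removing the default exclusion
#' interval 16184..16194 (11 positions) leaves 328.
#'
#' @slot start,end integer rCRS bounds of the window (closed interval)
#' @slot exclusions integer matrix with columns \code{start}, \code{end};
#'   each row a closed interval inside \code{[start, end]}
#' @export
setClass("AnalysisWindow",
  slots = c(start = "integer", end = "integer", exclusions = "matrix")
)

setValidity("AnalysisWindow", function(object) {
  msg <- character()
  if (object@start > object@end) msg <- c(msg, "start must be <= end")
  ex <- object@exclusions
  if (nrow(ex)) {
    if (ncol(ex) != 2L) msg <- c(msg, "exclusions must have two columns")
    else {
      if (any(ex[, 1L] > ex[, 2L]))
        msg <- c(msg, "each exclusion must have start <= end")
      if (any(ex[, 1L] < object@start) || any(ex[, 2L] > object@end))
        msg <- c(msg, "exclusions must lie within the window")
    }
  }
  if (length(msg)) msg else TRUE
})

#' HaplotypeTable: haplotype counts for one population
#'
#' @slot population population identifier
#' @slot counts named integer vector; names are haplotype strings (all the
#'   same length), values their sample counts
#' @export
setClass("HaplotypeTable",
  slots = c(population = "character", counts = "integer")
)

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  if (length(object@counts)) {
    if (is.null(names(object@counts)))
      msg <- c(msg, "counts must be named by haplotype string")
    if (length(unique(nchar(names(object@counts)))) > 1L)
      msg <- c(msg, "all haplotype strings must have identical length")
    if (any(object@counts < 1L))
      msg <- c(msg, "all counts must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' MismatchFit: sudden-expansion fit to a mismatch distribution
#'
#' @slot observed relative frequencies of pairwise-difference classes 0..d
#' @slot expected model expectation over the same classes (remainder mass
#'   folded into the last class)
#' @slot tau,theta0,theta1 fitted sudden-expansion parameters
#' @slot ssd minimised sum of squared deviations
#' @slot hri Harpending's raggedness index of the observed spectrum
#' @slot pSSD,pHri parametric-bootstrap p-values (NA when not computed)
#' @slot reps,seed bootstrap replicate count and seed
#' @export
setClass("MismatchFit",
  slots = c(observed = "numeric", expected = "numeric",
            tau = "numeric", theta0 = "numeric", theta1 = "numeric",
            ssd = "numeric", hri = "numeric",
            pSSD = "numeric", pHri = "numeric",
            reps = "integer", seed = "integer")
)

setValidity("MismatchFit", function(object) {
  msg <- character()
  if (length(object@observed) != length(object@expected))
    msg <- c(msg, "observed and expected must have equal length")
  if (abs(sum(object@observed) - 1) > 1e-9)
    msg <- c(msg, "observed must sum to 1")
  if (abs(sum(object@expected) - 1) > 1e-6)
    msg <- c(msg, "expected must sum to 1")
  if (object@tau < 0 || object@theta0 < 0 || object@theta1 < 0)
    msg <- c(msg, "tau, theta0, theta1 must be nonnegative")
  if (object@ssd < 0 || object@hri < 0)
    msg <- c(msg, "ssd and hri must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' PhistMatrix: pairwise Phi-ST matrices between populations
#'
#' @slot populations ordered population identifiers
#' @slot phist symmetric matrix of pairwise Phi-ST (zero diagonal)
#' @slot pvals permutation p-values (NA when perms = 0)
#' @slot linearized -ln(1 - Phi-ST) after clipping negatives to zero
#' @slot perms,seed permutation count and seed
#' @slot method distance model used between haplotypes
#' @export
setClass("PhistMatrix",
  slots = c(populations = "character", phist = "matrix", pvals = "matrix",
            linearized = "matrix", perms = "integer", seed = "integer",
            method = "character")
)

setValidity("PhistMatrix", function(object) {
  msg <- character()
  k <- length(object@populations)
  for (nm in c("phist", "pvals", "linearized")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(k, k)))
      msg <- c(msg, paste0(nm, " must be ", k, " x ", k))
  }
  if (k && any(abs(diag(object@phist)) > 1e-12))
    msg <- c(msg, "phist diagonal must be zero")
  if (k && !isTRUE(all.equal(object@phist, t(object@phist), tolerance = 1e-12)))
    msg <- c(msg, "phist must be symmetric")
  if (length(msg)) msg else TRUE
})

#' AmovaResult: two-level hierarchical AMOVA decomposition
#'
#' Variance of squared inter-haplotype distances decomposed into among-group
#' (a), among-populations-within-group (b) and within-population (c)
#' components, with fixation indices Phi-CT = a/T, Phi-SC = b/(b+c) and
#' Phi-ST = (a+b)/T, and permutation p-values under the standard three
#' permutation schemes.
#'
#' @slot scheme grouping-scheme name
#' @slot df,ss degrees of freedom and sums of squares (among groups,
#'   among populations within groups, within populations)
#' @slot sigma2 variance components (a, b, c), reported as computed
#'   (negative estimates are not truncated)
#' @slot pct components as percentages of their total
#' @slot phi fixation indices (ct, sc, st)
#' @slot pvals permutation p-values for (ct, sc, st)
#' @slot perms,seed permutation count and seed
#' @slot flags character vector of degeneracy warnings (e.g. single
#'   population in a group)
#' @export
setClass("AmovaResult",
  slots = c(scheme = "character", df = "numeric", ss = "numeric",
            sigma2 = "numeric", pct = "numeric", phi = "numeric",
            pvals = "numeric", perms = "integer", seed = "integer",
            flags = "character")
)

setValidity("AmovaResult", function(object) {
  msg <- character()
  if (length(object@sigma2) != 3L) msg <- c(msg, "sigma2 must have length 3")
  if (length(object@phi) != 3L) msg <- c(msg, "phi must have length 3")
  tot <- sum(object@sigma2)
  if (is.finite(tot) && abs(sum(object@pct) - 100) > 1e-6)
    msg <- c(msg, "percentages must sum to 100")
  if (length(msg)) msg else TRUE
})

#' CladeTree: a rooted clade tree annotated with per-branch mutation counts
#'
#' @slot tree an \code{ape} \code{phylo} object (rooted)
#' @slot mutations numeric per-edge mutation counts, in \code{tree$edge}
#'   row order
#' @slot tipMult per-tip sample multiplicities (named by tip label);
#'   identical sampled haplotypes can be carried as one tip with
#'   multiplicity > 1
#' @export
setClass("CladeTree",
  slots = c(tree = "ANY", mutations = "numeric", tipMult = "numeric")
)

setValidity("CladeTree", function(object) {
  msg <- character()
  tr <- object@tree
  if (!inherits(tr, "phylo")) msg <- c(msg, "tree must be an ape phylo object")
  else {
    if (length(object@mutations) != nrow(tr$edge))
      msg <- c(msg, "mutations must have one entry per edge")
    if (length(object@tipMult) != length(tr$tip.label))
      msg <- c(msg, "tipMult must have one entry per tip")
    if (any(object@mutations < 0)) msg <- c(msg, "mutation counts must be >= 0")
    if (any(object@tipMult < 1)) msg <- c(msg, "tip multiplicities must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' RhoEstimate: rho statistic and clock-converted clade age
#'
#' @slot rho mean mutational divergence of sampled lineages from the clade
#'   root
#' @slot sigmaRho standard error of rho
#' @slot n number of sampled lineages
#' @slot clock clock name ("total" or "synonymous")
#' @slot yearsPerSub calibrated years per substitution
#' @slot ageYears rho * yearsPerSub
#' @slot ci95Years age +/- 1.96 * sigmaRho * yearsPerSub (untruncated;
#'   a negative lower bound is reported as computed)
#' @export
setClass("RhoEstimate",
  slots = c(rho = "numeric", sigmaRho = "numeric", n = "numeric",
            clock = "character", yearsPerSub = "numeric",
            ageYears = "numeric", ci95Years = "numeric")
)

setValidity("RhoEstimate", function(object) {
  msg <- character()
  if (object@rho < 0) msg <- c(msg, "rho must be >= 0")
  if (object@sigmaRho < 0) msg <- c(msg, "sigmaRho must be >= 0")
  if (object@yearsPerSub <= 0) msg <- c(msg, "yearsPerSub must be > 0")
  if (length(object@ci95Years) != 2L) msg <- c(msg, "ci95Years must have length 2")
  if (length(msg)) msg else TRUE
})
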
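#' @describeIn HapAlignment number of sampled sequences
#' @param x,object an object
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @describeIn HapAlignment number of retained alignment columns
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @describeIn HapAlignment population label per sample
#' @export
setGeneric("samplePopulations", function(x) standardGeneric("samplePopulations"))

#' @describeIn HapAlignment sample identifiers
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @describeIn HapAlignment rCRS coordinate of each retained column
#' @export
setGeneric("rcrsPositions", function(x) standardGeneric("rcrsPositions"))

#' @describeIn HapAlignment underlying character matrix (samples x sites)
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' @describeIn HaplotypeTable haplotype counts (named integer vector)
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))

#' @describeIn HaplotypeTable haplotype relative frequencies
#' @export
setGeneric("haplotypeFreqs", function(x) standardGeneric("haplotypeFreqs"))

setMethod("nSamples", "HapAlignment", function(x) nrow(x@seqs))
setMethod("nSites", "HapAlignment", function(x) ncol(x@seqs))
setMethod("samplePopulations", "HapAlignment", function(x) x@populations)
setMethod("sampleIDs", "HapAlignment", function(x) x@samples)
setMethod("rcrsPositions", "HapAlignment", function(x) x@positions)
setMethod("alignmentMatrix", "HapAlignment", function(x) x@seqs)
setMethod("nSamples", "HaplotypeTable", function(x) sum(x@counts))
setMethod("haplotypeCounts", "HaplotypeTable", function(x) x@counts)
setMethod("haplotypeFreqs", "HaplotypeTable", function(x) x@counts / sum(x@counts))

setMethod("show", "HapAlignment", function(object) {
  pops <- unique(object@populations)
  cat("HapAlignment:", nSamples(object), "sequences,", nSites(object),
      "sites,", length(pops), "population(s)\n")
  if (nSites(object) > 0)
    cat("  rCRS positions", min(object@positions), "..",
        max(object@positions), "\n")
  if (length(pops))
    cat("  populations:", paste(utils::head(pops, 6), collapse = ", "),
        if (length(pops) > 6) "..." else "", "\n")
})

setMethod("show", "AnalysisWindow", function(object) {
  cat("AnalysisWindow: rCRS", object@start, "..", object@end)
  if (nrow(object@exclusions)) {
    ex <- apply(object@exclusions, 1L,
                function(r) paste0(r[1L], "-", r[2L]))
    cat(" excluding", paste(ex, collapse = ", "))
  }
  cat("\n")
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable: population", object@population, "-",
      length(object@counts), "haplotype(s),", sum(object@counts),
      "sample(s)\n")
})

setMethod("show", "MismatchFit", function(object) {
  cat("MismatchFit (sudden-expansion model)\n")
  cat(sprintf("  tau = %.4g  theta0 = %.4g  theta1 = %.4g\n",
              object@tau, object@theta0, object@theta1))
  cat(sprintf("  SSD = %.6g (p = %s)   Hri = %.6g (p = %s)\n",
              object@ssd, format(object@pSSD), object@hri,
              format(object@pHri)))
})

setMethod("show", "PhistMatrix", function(object) {
  cat("PhistMatrix:", length(object@populations), "populations,",
      object@perms, "permutations, distance method:", object@method, "\n")
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (two-level), scheme:", object@scheme, "\n")
  lab <- c("Among groups", "Among populations within groups",
           "Within populations")
  for (i in 1:3)
    cat(sprintf("  %-34s sigma2 = %9.5f  (%6.2f%%)\n", lab[i],
                object@sigma2[i], object@pct[i]))
  cat(sprintf("  Phi_CT = %.5f (p = %s)  Phi_SC = %.5f (p = %s)  Phi_ST = %.5f (p = %s)\n",
              object@phi[1], format(object@pvals[1]),
              object@phi[2], format(object@pvals[2]),
              object@phi[3], format(object@pvals[3])))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "CladeTree", function(object) {
  cat("CladeTree:", length(object@tree$tip.label), "tips,",
      sum(object@tipMult), "sampled lineages,",
      sum(object@mutations), "mutations on", nrow(object@tree$edge),
      "branches\n")
})

setMethod("show", "RhoEstimate", function(object) {
  cat(sprintf("RhoEstimate: rho = %.4f +/- %.4f (n = %g lineages)\n",
              object@rho, object@sigmaRho, object@n))
  cat(sprintf("  %s clock (%g y/sub): age = %.0f y, 95%% CI [%.0f, %.0f]\n",
              object@clock, object@yearsPerSub, object@ageYears,
              object@ci95Years[1], object@ci95Years[2]))
})
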
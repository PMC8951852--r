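#' Build the study's grouping schemes from metadata
#'
#' Returns named population -> group mappings for the five grouping
#' variables: Language, Region1, Region2, Lifestyle1, Lifestyle2.
#'
#' @param meta metadata data.frame (see \code{\link{readSampleMetadata}})
#' @param which scheme names to build
#' @return named list of named character vectors (population_id -> group)
#' @export
groupingSchemes <- function(meta, which = c("Language", "Region1", "Region2",
                                            "Lifestyle1", "Lifestyle2")) {
  colmap <- c(Language = "language", Region1 = "region1", Region2 = "region2",
              Lifestyle1 = "lifestyle1", Lifestyle2 = "lifestyle2")
  which <- match.arg(which, names(colmap), several.ok = TRUE)
  out <- lapply(which, function(w)
    stats::setNames(meta[[colmap[[w]]]], meta$population_id))
  stats::setNames(out, which)
}

.checkScheme <- function(a, scheme) {
  pops <- unique(a@populations)
  missing <- setdiff(pops, names(scheme))
  if (length(missing))
    stop("grouping scheme does not cover population(s): ",
         paste(missing, collapse = ", "))
  scheme[pops]
}

#' Two-level hierarchical AMOVA
#'
#' Decomposes the variance of squared inter-haplotype distances into
#' among-group, among-populations-within-group and within-population
#' components (sums of squares computed from pairwise squared distances:
#' the SS of a set of N sequences is (1/N) sum_\{i<j\} delta_ij^2), yielding
#' Phi_CT = sigma2_a / sigma2_T, Phi_SC = sigma2_b / (sigma2_b + sigma2_c)
#' and Phi_ST = (sigma2_a + sigma2_b) / sigma2_T, so that
#' (1 - Phi_ST) = (1 - Phi_CT)(1 - Phi_SC) by construction.  Negative
#' variance components are reported as computed (not truncated).
#' Permutation p-values use the standard three schemes: individuals among
#' all populations (Phi_ST), whole populations among groups (Phi_CT), and
#' individuals among populations within their group (Phi_SC), each with
#' p = (#\{perm >= obs\} + 1)/(perms + 1).
#'
#' @param a a multi-population \linkS4class{HapAlignment} (every population
#'   >= 2 samples)
#' @param scheme named character vector population_id -> group label
#'   (>= 2 groups), or a single group for a one-level analysis
#' @param cfg a \code{\link{distanceConfig}}
#' @param perms permutations (default 10000; 0 skips p-values)
#' @param seed integer seed
#' @param schemeName label stored in the result
#' @return an \linkS4class{AmovaResult}
#' @export
amovaTwoLevel <- function(a, scheme, cfg = distanceConfig(), perms = 10000L,
                          seed = 1L, schemeName = "scheme") {
  scheme <- .checkScheme(a, scheme)
  pops <- unique(a@populations)
  if (any(table(a@populations) < 2L))
    stop("every population needs >= 2 samples")
  groupOfPop <- scheme[pops]
  glev <- unique(groupOfPop)
  flags <- character()
  singles <- names(table(groupOfPop))[table(groupOfPop) == 1L]
  if (length(singles))
    flags <- c(flags, paste0("group(s) with a single population (Phi_SC ",
                             "contribution degenerate): ",
                             paste(singles, collapse = ", ")))
  d2 <- pairwiseDistances(a, cfg)^2
  popIdx <- as.integer(factor(a@populations, levels = pops)) - 1L
  grpIdx <- as.integer(factor(groupOfPop, levels = glev)) - 1L
  set.seed(seed)
  res <- .cpp_amova2(d2, popIdx, grpIdx, as.integer(perms))
  sigma2 <- res$sigma2
  tot <- sum(sigma2)
  methods::new("AmovaResult", scheme = schemeName,
               df = res$df, ss = res$ss, sigma2 = sigma2,
               pct = 100 * sigma2 / tot,
               phi = stats::setNames(res$phi, c("ct", "sc", "st")),
               pvals = stats::setNames(res$pvals, c("ct", "sc", "st")),
               perms = as.integer(perms), seed = as.integer(seed),
               flags = flags)
}

#' Run AMOVA under several grouping schemes
#'
#' @param a a multi-population \linkS4class{HapAlignment}
#' @param schemes named list of grouping schemes (see
#'   \code{\link{groupingSchemes}})
#' @param cfg a \code{\link{distanceConfig}}
#' @param perms permutations per scheme
#' @param seed master seed; per-scheme seeds derived from it
#' @return named list of \linkS4class{AmovaResult}
#' @export
runAllSchemes <- function(a, schemes, cfg = distanceConfig(), perms = 10000L,
                          seed = 1L) {
  out <- lapply(seq_along(schemes), function(i)
    amovaTwoLevel(a, schemes[[i]], cfg, perms,
                  seed = (seed + i) %% .Machine$integer.max,
                  schemeName = names(schemes)[i]))
  stats::setNames(out, names(schemes))
}

#' Tabulate one or more AMOVA results
#'
#' @param results an \linkS4class{AmovaResult} or list of them
#' @return data.frame with one row per scheme
#' @export
amovaTable <- function(results) {
  if (methods::is(results, "AmovaResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(scheme = r@scheme,
               sigma2_a = r@sigma2[1L], sigma2_b = r@sigma2[2L],
               sigma2_c = r@sigma2[3L],
               pct_a = r@pct[1L], pct_b = r@pct[2L], pct_c = r@pct[3L],
               phi_ct = r@phi[["ct"]], p_ct = r@pvals[["ct"]],
               phi_sc = r@phi[["sc"]], p_sc = r@pvals[["sc"]],
               phi_st = r@phi[["st"]], p_st = r@pvals[["st"]],
               perms = r@perms, seed = r@seed, row.names = NULL)))
}
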
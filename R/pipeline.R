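# deterministic per-stage child seed from a master seed and stage name
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 1000 * h) %% (2^31 - 1))
}

#' Run the full population analysis
#'
#' Config-driven end-to-end runner producing the study-style result bundle
#' on any dataset (real or simulated): (i) a per-population table of
#' diversity, neutrality and mismatch statistics, (ii) the pairwise Phi-ST
#' and linearized matrices with NMDS coordinates and stress, (iii) AMOVA
#' under the requested grouping schemes, (iv) Kruskal-Wallis tables of the
#' indices across groupings, and (v) an optional clade-age table.  A run
#' manifest (JSON) records the seed and every parameter.  Per-population
#' failures are isolated: the run continues and the failure is recorded.
#'
#' @param config a named list, or path to a YAML file, with entries:
#'   \code{fasta}, \code{meta} (file paths) or \code{alignment},
#'   \code{metadata} (in-memory objects); \code{coordStart};
#'   \code{window} (list \code{start}, \code{end}) and \code{exclude}
#'   (list of \code{start}/\code{end} pairs) or omitted for the HVS-1
#'   defaults; \code{maskAmbiguous} (default TRUE); \code{gammaShape}
#'   (0.4), \code{tstv} (10); \code{perms} (10000), \code{bootReps}
#'   (1000), \code{neutralityReps} (10000); \code{schemes} (character
#'   vector); \code{mdsRestarts} (50); \code{seed}; \code{outDir}
#'   (NULL for no files); \code{clades} (named list of Newick paths,
#'   optional)
#' @return list with \code{perPopulation}, \code{phist}, \code{ordination},
#'   \code{amova}, \code{kruskalWallis}, \code{cladeAges}, \code{failures},
#'   \code{manifest}
#' @export
runFullAnalysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(coordStart = 16024L, maskAmbiguous = TRUE, gammaShape = 0.4,
         tstv = 10, perms = 10000L, bootReps = 1000L,
         neutralityReps = 10000L,
         schemes = c("Language", "Region1", "Region2", "Lifestyle1",
                     "Lifestyle2"),
         mdsRestarts = 50L, seed = 1L, outDir = NULL, window = NULL,
         exclude = NULL, clades = NULL),
    config)
  seed <- as.integer(cfg$seed)
  # --- load ---------------------------------------------------------------
  a <- if (!is.null(cfg$alignment)) cfg$alignment
       else readHapAlignment(cfg$fasta, coordStart = cfg$coordStart)
  meta <- if (!is.null(cfg$metadata)) validateSampleMetadata(cfg$metadata)
          else readSampleMetadata(cfg$meta)
  unknown <- setdiff(unique(samplePopulations(a)), meta$population_id)
  if (length(unknown))
    stop("population(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  # --- window + mask ------------------------------------------------------
  if (!is.null(cfg$window)) {
    ex <- if (is.null(cfg$exclude)) NULL
          else do.call(rbind, lapply(cfg$exclude, function(e)
            c(e$start, e$end)))
    w <- hvs1Window(cfg$window$start, cfg$window$end, ex)
    a <- applyWindow(a, w)
  } else if (min(rcrsPositions(a)) <= 16032L && max(rcrsPositions(a)) >= 16370L) {
    a <- applyWindow(a, hvs1Window())
  }
  if (isTRUE(cfg$maskAmbiguous)) a <- maskAmbiguous(a)
  dcfg <- distanceConfig(gammaShape = cfg$gammaShape, tstv = cfg$tstv)
  failures <- list()
  # --- per-population table ----------------------------------------------
  div <- diversityTable(a)
  neut <- tryCatch(
    neutralityTable(a, reps = cfg$neutralityReps,
                    seed = .stageSeed(seed, "neutrality")),
    error = function(e) { failures$neutrality <<- conditionMessage(e); NULL })
  mism <- tryCatch(
    mismatchTable(a, reps = cfg$bootReps, seed = .stageSeed(seed, "mismatch")),
    error = function(e) { failures$mismatch <<- conditionMessage(e); NULL })
  perPop <- div
  if (!is.null(neut))
    perPop <- merge(perPop,
                    neut[, setdiff(names(neut), c("n", "S", "reps", "seed"))],
                    by = "population_id", sort = FALSE)
  if (!is.null(mism)) perPop <- merge(perPop, mism, by = "population_id",
                                      sort = FALSE)
  # --- distances + ordination ---------------------------------------------
  phist <- tryCatch(
    phistMatrix(a, dcfg, perms = cfg$perms, seed = .stageSeed(seed, "phist")),
    error = function(e) { failures$phist <<- conditionMessage(e); NULL })
  ord <- if (!is.null(phist) && length(phist@populations) >= 3L)
    tryCatch(nmdsOrdination(phist, restarts = cfg$mdsRestarts,
                            seed = .stageSeed(seed, "mds")),
             error = function(e) { failures$mds <<- conditionMessage(e); NULL })
  else NULL
  # --- AMOVA ---------------------------------------------------------------
  schemes <- groupingSchemes(meta, cfg$schemes)
  amv <- tryCatch(
    runAllSchemes(a, schemes, dcfg, perms = cfg$perms,
                  seed = .stageSeed(seed, "amova")),
    error = function(e) { failures$amova <<- conditionMessage(e); NULL })
  # --- Kruskal-Wallis ------------------------------------------------------
  kw <- tryCatch(kruskalWallisTable(perPop, meta),
                 error = function(e) { failures$kruskalWallis <<- conditionMessage(e); NULL })
  # --- clade ages ----------------------------------------------------------
  ages <- NULL
  if (!is.null(cfg$clades)) {
    clades <- lapply(cfg$clades, readCladeTree)
    ages <- cladeAgeTable(clades)
  }
  manifest <- list(seed = seed, package = "mtPopGen",
                   version = as.character(utils::packageVersion("mtPopGen")),
                   nSamples = nSamples(a), nSites = nSites(a),
                   nPopulations = length(unique(samplePopulations(a))),
                   parameters = cfg[setdiff(names(cfg),
                                            c("alignment", "metadata"))])
  out <- list(perPopulation = perPop, phist = phist, ordination = ord,
              amova = amv, kruskalWallis = kw, cladeAges = ages,
              failures = failures, manifest = manifest)
  if (!is.null(cfg$outDir)) .writeBundle(out, cfg$outDir)
  out
}

.writeBundle <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(out$perPopulation, "per_population.tsv")
  if (!is.null(out$phist)) {
    utils::write.table(out$phist@phist, file.path(dir, "phist_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(out$phist@linearized,
                       file.path(dir, "phist_linearized.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(out$ordination)) {
    co <- as.data.frame(out$ordination$coordinates)
    co <- cbind(population_id = out$phist@populations, co)
    wt(co, "mds_coordinates.tsv")
    writeLines(paste("stress", format(out$ordination$stress, digits = 10)),
               file.path(dir, "mds_stress.txt"))
  }
  if (!is.null(out$amova)) wt(amovaTable(out$amova), "amova.tsv")
  if (!is.null(out$kruskalWallis))
    utils::write.table(out$kruskalWallis,
                       file.path(dir, "kruskal_wallis.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(out$cladeAges)) wt(out$cladeAges, "clade_ages.tsv")
  jsonlite::write_json(out$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}
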
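#' Construct a HapAlignment from a character matrix
#'
#' @param seqs character matrix (samples x sites) over A,C,G,T,N,-; lower
#'   case is normalised to upper case
#' @param positions integer rCRS positions, one per column; default
#'   \code{coordStart .. coordStart+ncol-1}
#' @param samples sample identifiers
#' @param populations population labels, recycled if length 1
#' @param coordStart rCRS position of the first column (used when
#'   \code{positions} is NULL)
#' @return a \linkS4class{HapAlignment}
#' @export
hapAlignment <- function(seqs, positions = NULL, samples = NULL,
                         populations = "pop1", coordStart = 1L) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("sequences have unequal lengths")
    seqs <- do.call(rbind, strsplit(seqs, ""))
  }
  seqs <- toupper(seqs)
  n <- nrow(seqs)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  if (length(populations) == 1L) populations <- rep(populations, n)
  if (is.null(positions))
    positions <- seq.int(coordStart, length.out = ncol(seqs))
  dimnames(seqs) <- NULL
  methods::new("HapAlignment", seqs = seqs, positions = as.integer(positions),
               samples = as.character(samples),
               populations = as.character(populations))
}

#' Read an aligned FASTA of HVS-1 sequences
#'
#' Sequence headers carry the sample identifier and the population label as
#' the first two whitespace- or pipe-separated fields
#' (\code{">GUE01 Guerrara"}).  All sequences must have the same aligned
#' length; lower case is normalised to upper case and any character outside
#' A, C, G, T, N, - is an error.
#'
#' @param path FASTA file
#' @param coordStart rCRS position (1-based) of the first alignment column
#' @return a \linkS4class{HapAlignment}
#' @export
readHapAlignment <- function(path, coordStart = 16024L) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1L) {
    expect <- as.integer(names(sort(table(w), decreasing = TRUE))[1L])
    bad <- which(w != expect)[1L]
    stop("ragged alignment: record '", names(ss)[bad], "' has length ",
         w[bad], ", expected ", expect)
  }
  hdr <- strsplit(names(ss), "[ \t|]+")
  sample_id <- vapply(hdr, `[`, "", 1L)
  population <- vapply(hdr, function(h) if (length(h) >= 2L) h[2L] else NA_character_, "")
  if (anyNA(population))
    stop("FASTA headers must carry '<sample_id> <population_id>'; offending record: ",
         sample_id[which(is.na(population))[1L]])
  seqs <- toupper(as.character(ss))
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), .DNA_ALPHABET)
  if (length(bad))
    stop("disallowed characters in FASTA: ", paste(bad, collapse = ", "))
  hapAlignment(unname(seqs), samples = sample_id, populations = population,
               coordStart = coordStart)
}

#' Write a HapAlignment as FASTA
#'
#' Headers use the package's input dialect \code{<sample_id> <population_id>}
#' so that written files round-trip through \code{\link{readHapAlignment}}.
#'
#' @param a a \linkS4class{HapAlignment}
#' @param path output file
#' @export
writeHapAlignment <- function(a, path) {
  seqs <- apply(a@seqs, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- paste(a@samples, a@populations)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' The default HVS-1 analysis window
#'
#' The 339-bp hypervariable window nps 16,032..16,370 with the
#' alignment-uncertain interval 16,184..16,194 excluded (the exclusion
#' removes 11 positions, leaving 328).
#'
#' @param start,end rCRS bounds (closed interval)
#' @param exclusions two-column matrix of closed exclusion intervals, or
#'   NULL for none
#' @return an \linkS4class{AnalysisWindow}
#' @export
hvs1Window <- function(start = 16032L, end = 16370L,
                       exclusions = cbind(16184L, 16194L)) {
  if (is.null(exclusions))
    exclusions <- matrix(integer(), ncol = 2L)
  exclusions <- matrix(as.integer(exclusions), ncol = 2L)
  methods::new("AnalysisWindow", start = as.integer(start),
               end = as.integer(end), exclusions = exclusions)
}

.windowPositions <- function(w, applyExclusions = TRUE) {
  pos <- seq.int(w@start, w@end)
  if (applyExclusions && nrow(w@exclusions))
    for (i in seq_len(nrow(w@exclusions)))
      pos <- pos[pos < w@exclusions[i, 1L] | pos > w@exclusions[i, 2L]]
  pos
}

#' Restrict an alignment to an analysis window
#'
#' Keeps exactly the columns whose rCRS position lies inside the window and
#' outside every exclusion interval, preserving column order.  Every
#' position of the (exclusion-reduced) window must be present in the
#' alignment; a missing stretch is an error.
#'
#' @param a a \linkS4class{HapAlignment}
#' @param w an \linkS4class{AnalysisWindow}; default \code{hvs1Window()}
#' @param applyExclusions drop the exclusion intervals as well (default TRUE)
#' @return the windowed \linkS4class{HapAlignment}
#' @export
applyWindow <- function(a, w = hvs1Window(), applyExclusions = TRUE) {
  want <- .windowPositions(w, applyExclusions)
  missing <- setdiff(want, a@positions)
  if (length(missing))
    stop("alignment does not cover window positions ", min(missing), "..",
         max(missing))
  keep <- a@positions %in% want
  methods::initialize(a, seqs = a@seqs[, keep, drop = FALSE],
                      positions = a@positions[keep])
}

#' Drop alignment columns containing ambiguous characters
#'
#' Removes every column in which any sequence carries N or a gap.  This is
#' the package's default policy for haplotype definition and all downstream
#' per-site statistics: a single global column mask keeps every pairwise
#' comparison on the same set of sites (complete-case columns), mirroring
#' the global exclusion of an alignment-uncertain region.
#'
#' @param a a \linkS4class{HapAlignment}
#' @return the masked \linkS4class{HapAlignment}
#' @export
maskAmbiguous <- function(a) {
  if (nSites(a) == 0L) return(a)
  bad <- apply(a@seqs == "N" | a@seqs == "-", 2L, any)
  methods::initialize(a, seqs = a@seqs[, !bad, drop = FALSE],
                      positions = a@positions[!bad])
}

#' Read per-population sample metadata
#'
#' Tab-separated with a header row; required columns \code{population_id},
#' \code{country}, \code{region1}, \code{region2}, \code{lifestyle1},
#' \code{lifestyle2}, \code{language}.  Factor levels follow the study
#' design: region1 in \{NA, SS\} (North Africa / Sahel-Savannah belt),
#' region2 in \{eNA, wNA, eSS, wSS\}, lifestyle1 in \{FM, PS\}
#' (farmers / pastoralists), lifestyle2 in \{FNA, PNA, FSS, PSS\}, language
#' in \{AA, NC, NS\}.  Consistency between the coarse and fine groupings is
#' validated.
#'
#' @param path TSV file
#' @return data.frame of validated metadata
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = NULL,
                          colClasses = "character")
  validateSampleMetadata(md)
}

#' Validate a sample-metadata data.frame
#'
#' @param md data.frame with the columns described in
#'   \code{\link{readSampleMetadata}}
#' @return the validated data.frame (invisibly unchanged)
#' @export
validateSampleMetadata <- function(md) {
  need <- c("population_id", "country", "region1", "region2",
            "lifestyle1", "lifestyle2", "language")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  lv <- list(region1 = c("NA", "SS"),
             region2 = c("eNA", "wNA", "eSS", "wSS"),
             lifestyle1 = c("FM", "PS"),
             lifestyle2 = c("FNA", "PNA", "FSS", "PSS"),
             language = c("AA", "NC", "NS"))
  for (col in names(lv)) {
    bad <- setdiff(unique(md[[col]]), lv[[col]])
    if (length(bad))
      stop("metadata column '", col, "' has invalid levels: ",
           paste(bad, collapse = ", "))
  }
  if (anyDuplicated(md$population_id))
    stop("duplicated population_id in metadata")
  r1 <- ifelse(md$region2 %in% c("eNA", "wNA"), "NA", "SS")
  if (any(r1 != md$region1))
    stop("region2 inconsistent with region1 for population(s): ",
         paste(md$population_id[r1 != md$region1], collapse = ", "))
  l2 <- paste0(substr(md$lifestyle1, 1L, 1L),
               ifelse(md$region1 == "NA", "NA", "SS"))
  if (any(l2 != md$lifestyle2))
    stop("lifestyle2 inconsistent with (lifestyle1, region1) for population(s): ",
         paste(md$population_id[l2 != md$lifestyle2], collapse = ", "))
  md
}

#' Collapse an alignment into per-population haplotype tables
#'
#' Two samples share a haplotype iff their (windowed, masked) sequences are
#' identical strings.
#'
#' @param a a \linkS4class{HapAlignment}
#' @param meta optional metadata data.frame; when given, every population in
#'   the alignment must appear in \code{meta$population_id}
#' @return named list of \linkS4class{HaplotypeTable}, one per population
#'   (alignment order of first appearance)
#' @export
collapseHaplotypes <- function(a, meta = NULL) {
  if (!is.null(meta)) {
    unknown <- setdiff(unique(a@populations), meta$population_id)
    if (length(unknown))
      stop("populations absent from metadata: ",
           paste(unknown, collapse = ", "))
  }
  hapstr <- apply(a@seqs, 1L, paste, collapse = "")
  pops <- unique(a@populations)
  out <- lapply(pops, function(p) {
    tab <- table(hapstr[a@populations == p])
    methods::new("HaplotypeTable", population = p,
                 counts = stats::setNames(as.integer(tab), names(tab)))
  })
  stats::setNames(out, pops)
}

#' Subset an alignment to one or more populations
#'
#' @param a a \linkS4class{HapAlignment}
#' @param pops population labels to keep
#' @return the subset \linkS4class{HapAlignment}
#' @export
subsetPopulations <- function(a, pops) {
  unknown <- setdiff(pops, a@populations)
  if (length(unknown))
    stop("unknown population(s): ", paste(unknown, collapse = ", "))
  keep <- a@populations %in% pops
  methods::initialize(a, seqs = a@seqs[keep, , drop = FALSE],
                      samples = a@samples[keep],
                      populations = a@populations[keep])
}
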
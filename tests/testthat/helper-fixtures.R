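# Programmatic fixtures: low-divergence alignments derived from a random
# ancestral sequence, the regime HVS-1 data live in.

randAlignment <- function(n, L, pops = "pop1", mutRate = 0.08, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(anc, each = n), n, L)
  nmut <- stats::rbinom(1, n * L, mutRate)
  if (nmut > 0) {
    idx <- sample(n * L, nmut)
    m[idx] <- vapply(m[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  hapAlignment(m, populations = pops)
}

writeTempFasta <- function(headers, seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), f)
  f
}

# a tiny valid study-style metadata frame for a set of populations
makeMeta <- function(pops) {
  k <- length(pops)
  region2 <- rep(c("eNA", "wNA", "eSS", "wSS"), length.out = k)
  region1 <- ifelse(region2 %in% c("eNA", "wNA"), "NA", "SS")
  lifestyle1 <- rep(c("FM", "PS"), length.out = k)
  data.frame(population_id = pops, country = "testland",
             region1 = region1, region2 = region2,
             lifestyle1 = lifestyle1,
             lifestyle2 = paste0(substr(lifestyle1, 1, 1),
                                 ifelse(region1 == "NA", "NA", "SS")),
             language = rep(c("AA", "NC", "NS"), length.out = k))
}
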
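#' Nei's unbiased haplotype (gene) diversity
#'
#' H = n(1 - sum p_i^2)/(n - 1): the probability that two sequences drawn
#' without replacement carry different haplotypes.
#'
#' @param t a \linkS4class{HaplotypeTable}
#' @return H in [0, 1]
#' @export
haplotypeDiversity <- function(t) {
  n <- sum(t@counts)
  if (n < 2L) stop("haplotype diversity undefined for n < 2")
  p <- t@counts / n
  h <- n * (1 - sum(p^2)) / (n - 1)
  min(max(h, 0), 1)
}

.seqIndicator <- function(seqs) {
  lapply(c("A", "C", "G", "T"), function(b) (seqs == b) * 1)
}

# n x n matrix of raw pairwise differences (Hamming) on all columns
.pairwiseDiffMatrix <- function(a) {
  seqs <- a@seqs
  L <- ncol(seqs)
  ind <- .seqIndicator(seqs)
  matches <- Reduce(`+`, lapply(ind, function(I) tcrossprod(I)))
  d <- L - matches
  diag(d) <- 0
  d
}

#' Mean number of pairwise differences
#'
#' Average Hamming distance over all n(n-1)/2 unordered sequence pairs,
#' computed on the retained (unmasked) columns.
#'
#' @param a a \linkS4class{HapAlignment} restricted to one population
#' @return k >= 0
#' @export
meanPairwiseDifferences <- function(a) {
  n <- nSamples(a)
  if (n < 2L) stop("mean pairwise differences undefined for n < 2")
  # site-wise identity: sum over columns of the discordant pair count
  npairs <- n * (n - 1) / 2
  cnt <- .alleleCountMatrix(a@seqs)         # alphabet x sites
  concord <- colSums(cnt * (cnt - 1) / 2)
  sum(npairs - concord) / npairs
}

# per-column allele counts, one row per alphabet character (vectorised)
.alleleCountMatrix <- function(seqs) {
  out <- vapply(.DNA_ALPHABET, function(b) colSums(seqs == b),
                numeric(ncol(seqs)))
  if (ncol(seqs) == 1L) out <- matrix(out, nrow = 1L,
                                      dimnames = list(NULL, .DNA_ALPHABET))
  t(out)
}

#' Nucleotide diversity per site
#'
#' pi = k / L with k the mean number of pairwise differences and L the
#' number of analysed sites.
#'
#' @param a a \linkS4class{HapAlignment} restricted to one population
#' @return pi >= 0
#' @export
nucleotideDiversity <- function(a) {
  L <- nSites(a)
  if (L == 0L) stop("no sites left after masking")
  meanPairwiseDifferences(a) / L
}

#' Number of segregating sites
#'
#' @param a a \linkS4class{HapAlignment}
#' @return count of polymorphic columns
#' @export
segregatingSites <- function(a) {
  if (nSites(a) == 0L) return(0L)
  cnt <- .alleleCountMatrix(a@seqs)
  sum(colSums(cnt > 0) > 1L)
}

#' Per-population diversity table
#'
#' @param a a multi-population \linkS4class{HapAlignment}
#' @return data.frame with population_id, n, nHap, H, k, pi, S, L
#' @export
diversityTable <- function(a) {
  pops <- unique(a@populations)
  rows <- lapply(pops, function(p) {
    ap <- subsetPopulations(a, p)
    ht <- collapseHaplotypes(ap)[[1L]]
    n <- nSamples(ap)
    if (n >= 2L) {
      k <- meanPairwiseDifferences(ap)
      data.frame(population_id = p, n = n, nHap = length(ht@counts),
                 H = haplotypeDiversity(ht), k = k, pi = k / nSites(ap),
                 S = segregatingSites(ap), L = nSites(ap))
    } else {
      data.frame(population_id = p, n = n, nHap = length(ht@counts),
                 H = NA_real_, k = NA_real_, pi = NA_real_,
                 S = segregatingSites(ap), L = nSites(ap))
    }
  })
  do.call(rbind, rows)
}
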
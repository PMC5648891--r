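#' Consensus barcode of each cluster
#'
#' The per-position majority base over a cluster's member reads (reads, not
#' distinct barcodes, so the tally reflects sequencing multiplicity); ties
#' are broken toward the lexicographically smallest base.  The consensus
#' estimates the original, pre-error barcode of the molecule the cluster
#' represents, and is the per-molecule unit for the error-rate and
#' base-composition estimators.
#'
#' @param clusters A `barcode_clusters` object from [cluster_barcodes()].
#' @return Character vector of consensus strings (over the compared
#'   positions), one per cluster, in cluster-id order.
#' @export
cluster_consensus <- function(clusters) {
  stopifnot(inherits(clusters, "barcode_clusters"))
  ok <- !is.na(clusters$membership)
  nC <- clusters$n_clusters
  if (nC == 0L) return(character(0))
  masked <- clusters$masked[ok]
  mem <- factor(clusters$membership[ok], levels = seq_len(nC))
  k <- nchar(masked[1])
  M <- .char_matrix(masked, k)
  cons <- matrix("", nC, k)
  for (c in seq_len(k)) {
    col <- factor(M[, c], levels = sort(unique(M[, c])))
    tab <- table(mem, col)
    cons[, c] <- colnames(tab)[max.col(tab, ties.method = "first")]
  }
  do.call(paste0, as.data.frame(cons, stringsAsFactors = FALSE))
}

#' Estimate the per-base substitution error rate
#'
#' Compares every read's barcode (over the compared positions) with its
#' cluster's consensus; the substitution rate is the fraction of mismatching
#' bases.  Singleton clusters carry no evidence about errors (the single
#' read defines its own consensus) and are excluded from both numerator and
#' denominator.  Requires clustering at `distance >= 1`, otherwise no read
#' can differ from its consensus.
#'
#' @param clusters A `barcode_clusters` object built with `distance >= 1`.
#' @return List with `rate` (per base), `mismatches`, `bases_compared` and
#'   `n_clusters_used`.
#' @export
estimate_substitution_rate <- function(clusters) {
  stopifnot(inherits(clusters, "barcode_clusters"))
  if (clusters$distance < 1L)
    warning("distance 0 clustering cannot observe substitutions")
  cons <- cluster_consensus(clusters)
  ok <- !is.na(clusters$membership)
  mem <- clusters$membership[ok]
  big <- which(clusters$sizes >= 2L)
  use <- mem %in% big
  if (!any(use))
    return(list(rate = NA_real_, mismatches = 0L, bases_compared = 0L,
                n_clusters_used = 0L))
  reads <- clusters$masked[ok][use]
  ref <- cons[mem[use]]
  k <- nchar(reads[1])
  mism <- sum(.hamming_at(reads, ref, seq_len(k)))
  bases <- length(reads) * k
  list(rate = mism / bases, mismatches = as.integer(mism),
       bases_compared = as.integer(bases),
       n_clusters_used = length(big))
}

#' Per-position fixed-base mismatch rates
#'
#' The fraction of reads mismatching the expected base at each designed
#' fixed position, measured on observations *before* the fixed-base filter
#' (after length filtering and mapping).  Pure substitution noise at rate e
#' gives a flat profile near e; insertions/deletions upstream of a position
#' inflate its rate, so rates growing with distance from the sequencing
#' primer site are the signature of indel errors.
#'
#' @param observations Observation data.frame with a `barcode` column,
#'   taken upstream of [fixed_base_filter()].
#' @param design A [barcode_design()].
#' @return Data.frame with columns `position`, `expected_base`,
#'   `mismatch_rate`, `n_reads`.
#' @export
estimate_fixed_base_mismatch_rates <- function(observations, design) {
  stopifnot(inherits(design, "barcode_design"))
  n <- nrow(observations)
  rate <- vapply(seq_along(design$fixed_positions), function(i) {
    p <- design$fixed_positions[i]
    mean(substr(observations$barcode, p, p) != design$fixed_bases[i])
  }, numeric(1))
  data.frame(position = design$fixed_positions,
             expected_base = design$fixed_bases,
             mismatch_rate = rate,
             n_reads = n,
             stringsAsFactors = FALSE)
}

#' Per-position base composition of the random-base region
#'
#' The fraction of A/C/G/T at each compared position among cluster
#' *consensuses* — each molecule is counted once regardless of its read
#' multiplicity, so the estimate reflects the composition of the original
#' barcode pool, not amplification bias.  Departures from 25% per base
#' reduce the effective randomness of the barcode and raise the number of
#' random bases needed for a given molecule count.
#'
#' @param clusters A `barcode_clusters` object.
#' @return Matrix of fractions with one row per compared position (labeled
#'   with the barcode position when the clustering recorded positions) and
#'   columns A, C, G, T; rows sum to 1.  Zero-row matrix for an empty
#'   cluster set.
#' @export
estimate_base_composition <- function(clusters) {
  stopifnot(inherits(clusters, "barcode_clusters"))
  cons <- cluster_consensus(clusters)
  bases <- c("A", "C", "G", "T")
  if (length(cons) == 0L) {
    out <- matrix(numeric(0), 0, 4, dimnames = list(NULL, bases))
    return(out)
  }
  k <- nchar(cons[1])
  M <- .char_matrix(cons, k)
  out <- t(vapply(seq_len(k), function(c) {
    tab <- table(factor(M[, c], levels = bases))
    as.numeric(tab) / sum(tab)
  }, numeric(4)))
  colnames(out) <- bases
  rownames(out) <- if (!is.null(clusters$positions))
    as.character(clusters$positions) else as.character(seq_len(k))
  out
}
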
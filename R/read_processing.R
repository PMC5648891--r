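#' Read and write FASTQ read sets
#'
#' Reads are carried through the pipeline as a plain data.frame of
#' observations with columns `read_id`, `sample_index` and `seq` (columns
#' `barcode`, `templates`, `n_templates` are added by later stages).
#' Quality strings are parsed and ignored: filtering in this scheme is
#' purely sequence-based.
#'
#' @param path FASTQ file (optionally gzipped).
#' @param sample_index Index label to attach to every read (e.g. `"A"`);
#'   use one call per pre-demultiplexed file.
#' @return A data.frame of observations.
#' @export
read_fastq <- function(path, sample_index = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sample_index = sample_index,
             seq = as.character(x),
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param observations Data.frame with `read_id` and `seq`.
#' @export
write_fastq <- function(observations, path) {
  x <- Biostrings::DNAStringSet(observations$seq)
  names(x) <- observations$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(observations$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

.filter_stats <- function(stage, n_in, n_kept) {
  data.frame(stage = stage, n_in = as.integer(n_in),
             n_kept = as.integer(n_kept),
             n_removed = as.integer(n_in - n_kept),
             stringsAsFactors = FALSE)
}

#' Demultiplex reads by sample index sequence
#'
#' Assigns each read to the index whose sequence is closest in Hamming
#' distance to the observed index read, provided the distance does not
#' exceed `max_index_mismatch` and the minimum is unique.  Ties and
#' too-distant reads go to the `undetermined` stream.  The default
#' `max_index_mismatch = 0` reproduces exact demultiplexing.
#'
#' @param index_reads Character vector of observed index sequences, one per
#'   read.
#' @param index_map Named character vector mapping index label to index
#'   sequence, e.g. `c(A = "CGCTCATT", B = "GAGATTCC")`.
#' @param max_index_mismatch Maximum tolerated mismatches (default 0).
#' @return Character vector of assigned labels (`NA` = undetermined),
#'   parallel to `index_reads`.
#' @export
demultiplex <- function(index_reads, index_map, max_index_mismatch = 0L) {
  if (anyDuplicated(index_map))
    stop("duplicate index sequences in index_map")
  if (length(unique(nchar(index_map))) != 1L)
    stop("index sequences must all have the same length")
  if (max_index_mismatch < 0L) stop("max_index_mismatch must be >= 0")
  index_reads <- as.character(index_reads)
  D <- vapply(unname(index_map),
              function(s) .hamming_at(index_reads,
                                      rep_len(s, length(index_reads)),
                                      seq_len(nchar(s))),
              integer(length(index_reads)))
  D <- matrix(D, nrow = length(index_reads))
  best <- do.call(pmin, as.data.frame(D))
  nbest <- rowSums(D == best)
  lab <- names(index_map)[max.col(-D, ties.method = "first")]
  lab[best > max_index_mismatch | nbest > 1L] <- NA_character_
  lab
}

#' Filter reads by length
#'
#' Keeps reads whose length falls inside the design's accepted window
#' (inclusive on both ends).  Out-of-window reads are dropped, not trimmed.
#'
#' @param observations Observation data.frame (see [read_fastq()]).
#' @param design A [barcode_design()].
#' @return List with `observations` (kept reads) and `stats` (one-row
#'   filter-stage summary).
#' @export
length_filter <- function(observations, design) {
  L <- nchar(observations$seq)
  keep <- L >= design$length_window[1] & L <= design$length_window[2]
  list(observations = observations[keep, , drop = FALSE],
       stats = .filter_stats("length", length(keep), sum(keep)))
}

#' Extract the barcode region from each read
#'
#' The barcode is the first `barcode_length` bases of the read (the barcode
#' region sits at the 5' end).  Reads too short to cover the region are
#' flagged and dropped.
#'
#' @inheritParams length_filter
#' @return List with `observations` (kept reads, now with a `barcode`
#'   column) and `stats`.
#' @export
extract_barcode <- function(observations, design) {
  L <- design$barcode_length
  ok <- nchar(observations$seq) >= L
  out <- observations[ok, , drop = FALSE]
  out$barcode <- substr(out$seq, 1L, L)
  list(observations = out,
       stats = .filter_stats("barcode_extraction", length(ok), sum(ok)))
}

#' Remove reads with N in the barcode
#'
#' @inheritParams length_filter
#' @return List with `observations` and `stats`.
#' @export
n_filter <- function(observations) {
  keep <- !grepl("N", observations$barcode, fixed = TRUE)
  list(observations = observations[keep, , drop = FALSE],
       stats = .filter_stats("N_in_barcode", length(keep), sum(keep)))
}

#' Remove reads with mismatched fixed bases
#'
#' A mismatch at a designed fixed position reveals that an insertion or
#' deletion upstream has shifted the barcode out of its reading frame (or
#' that the fixed base itself was mis-sequenced); such reads are removed.
#' A read survives only if it matches the expected base at *every* selected
#' fixed position.
#'
#' @inheritParams length_filter
#' @param selected_fixed Which fixed positions to use: explicit positions,
#'   `"furthest:k"`, or `NULL` for all — see [select_fixed_positions()].
#' @return List with `observations`, `stats`, and `selected` (the positions
#'   used).
#' @export
fixed_base_filter <- function(observations, design, selected_fixed = NULL) {
  sel <- select_fixed_positions(design, selected_fixed)
  expected <- design$fixed_bases[match(sel, design$fixed_positions)]
  keep <- rep(TRUE, nrow(observations))
  for (i in seq_along(sel)) {
    keep <- keep &
      substr(observations$barcode, sel[i], sel[i]) == expected[i]
  }
  list(observations = observations[keep, , drop = FALSE],
       stats = .filter_stats("fixed_base", length(keep), sum(keep)),
       selected = sel)
}
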
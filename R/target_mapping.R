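#' Assign reads to reference templates by their target region
#'
#' The native mapper compares the designed target region of each read
#' (fixed read coordinates, ungapped) against every reference target and
#' assigns all templates within `max_mismatch` substitutions.  This is
#' appropriate for the small designed reference panels this scheme targets
#' (a handful of short target sequences at known read coordinates); for
#' gapped or genome-scale alignment, import the output of an external
#' aligner with [import_sam()].
#'
#' Reads shorter than the target-region end are compared over the covered
#' positions only; at least half the target must be covered.  Indels inside
#' the target region are not chased — such reads typically carry a shifted
#' barcode frame and fall to the fixed-base filter anyway.
#'
#' @param observations Observation data.frame with a `seq` column.
#' @param templates A [template_set()].
#' @param max_mismatch Maximum substitutions allowed; default
#'   `ceiling(width/10)` (1 for 8-base targets, 5 for 50-base targets).
#' @param multi Keep reads assigned to more than one template (`TRUE`, used
#'   in misidentification mode) or drop them (`FALSE`, uniquely mapped reads
#'   only — the default).
#' @return List with `observations` (mapped reads with `templates` — a
#'   comma-separated set of template ids — and `n_templates` columns) and
#'   `stats`.
#' @export
map_targets <- function(observations, templates, max_mismatch = NULL,
                        multi = FALSE) {
  stopifnot(inherits(templates, "template_set"))
  design <- attr(templates, "design")
  a <- design$target_region[1]; b <- design$target_region[2]
  w <- b - a + 1L
  if (is.null(max_mismatch)) max_mismatch <- ceiling(w / 10)
  n <- nrow(observations)
  targ <- substr(observations$seq, a, b)
  targ <- formatC(targ, width = -w)                     # right-pad to w
  M <- .char_matrix(targ, w)
  covered <- rowSums(M != " ")
  hits <- matrix(FALSE, n, nrow(templates))
  for (r in seq_len(nrow(templates))) {
    ref <- strsplit(templates$target_sequence[r], "", fixed = TRUE)[[1]]
    mism <- integer(n)
    for (c in seq_len(w))
      mism <- mism + (M[, c] != ref[c] & M[, c] != " ")
    hits[, r] <- mism <= max_mismatch & covered >= ceiling(w / 2)
  }
  nt <- rowSums(hits)
  tmpl <- rep(NA_character_, n)
  ids <- templates$template_id
  one <- nt == 1L
  if (any(one))
    tmpl[one] <- ids[max.col(hits[one, , drop = FALSE],
                             ties.method = "first")]
  mi <- which(nt > 1L)
  if (length(mi))
    tmpl[mi] <- vapply(mi, function(i)
      paste(ids[hits[i, ]], collapse = ","), character(1))
  keep <- if (multi) nt >= 1L else nt == 1L
  out <- observations[keep, , drop = FALSE]
  out$templates <- tmpl[keep]
  out$n_templates <- as.integer(nt[keep])
  list(observations = out,
       stats = .filter_stats(if (multi) "mapped_multi" else "mapped_unique",
                             n, sum(keep)))
}

#' Import template assignments from a SAM file
#'
#' Interoperability with external aligners: alignments (including secondary
#' alignments, which mark multi-mapped reads) are taken at face value and
#' converted into the same observation columns that [map_targets()]
#' produces.  Unmapped records are dropped.  Reference names must match the
#' template ids of the reference set.
#'
#' @param sam_path Path to a headered single-end SAM file.
#' @param observations Observation data.frame holding the reads that were
#'   aligned (matched by `read_id`); reads without any alignment are
#'   dropped.
#' @param templates A [template_set()].
#' @param multi Keep multi-mapped reads (see [map_targets()]).
#' @return List with `observations` and `stats`.
#' @export
import_sam <- function(sam_path, observations, templates, multi = FALSE) {
  stopifnot(inherits(templates, "template_set"))
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "flag"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(x$flag, 4L)
  qname <- as.character(x$qname)[mapped]
  rname <- as.character(x$rname)[mapped]
  unknown <- setdiff(unique(rname), templates$template_id)
  if (length(unknown))
    stop("SAM reference name(s) not in the template set: ",
         paste(unknown, collapse = ", "))
  # distinct templates per read (primary + secondary alignments)
  key <- !duplicated(paste0(qname, "\r", rname))
  per_read <- split(rname[key], qname[key])
  ids <- names(per_read)
  tmpl <- vapply(per_read, function(v) paste(sort(v), collapse = ","),
                 character(1))
  nt <- lengths(per_read)
  m <- match(observations$read_id, ids)
  found <- !is.na(m)
  keep <- found & (if (multi) nt[m] >= 1L else nt[m] == 1L)
  keep[is.na(keep)] <- FALSE
  out <- observations[keep, , drop = FALSE]
  out$templates <- unname(tmpl[m[keep]])
  out$n_templates <- as.integer(nt[m[keep]])
  list(observations = out,
       stats = .filter_stats("mapped_sam", nrow(observations), sum(keep)))
}
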
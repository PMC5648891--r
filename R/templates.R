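#' Reference set of barcoded templates
#'
#' A template set binds a [barcode_design()] to the target sequences it
#' carries.  Each template has a unique id, a target sequence whose length
#' equals the width of the design's target region, and optionally a known
#' ground-truth input copy number (used by the simulator and by
#' input-vs-output comparisons).
#'
#' @param design A [barcode_design()].
#' @param template_id Character vector of unique template labels.
#' @param target_sequence Character vector of DNA target sequences, parallel
#'   to `template_id`.
#' @param input_copies Optional numeric vector of known input molecule
#'   counts (per sample), parallel to `template_id`; `NA` when unknown.
#' @return An object of class `template_set`: a data.frame with columns
#'   `template_id`, `target_sequence`, `input_copies` and the design stored
#'   in `attr(, "design")`.
#' @export
template_set <- function(design, template_id, target_sequence,
                         input_copies = NA_real_) {
  stopifnot(inherits(design, "barcode_design"))
  template_id <- as.character(template_id)
  target_sequence <- toupper(as.character(target_sequence))
  if (length(template_id) != length(target_sequence))
    stop("template_id and target_sequence must have equal length")
  if (anyDuplicated(template_id))
    stop("template_id values must be unique")
  w <- design$target_region[2] - design$target_region[1] + 1L
  bad <- nchar(target_sequence) != w
  if (any(bad))
    stop("target sequence length must equal the target-region width (", w,
         "): ", paste(template_id[bad], collapse = ", "))
  if (anyDuplicated(target_sequence))
    warning("duplicate target sequences in reference; assignments will be ",
            "inherently ambiguous")
  input_copies <- rep_len(as.numeric(input_copies), length(template_id))
  out <- data.frame(template_id = template_id,
                    target_sequence = target_sequence,
                    input_copies = input_copies,
                    stringsAsFactors = FALSE)
  attr(out, "design") <- design
  class(out) <- c("template_set", "data.frame")
  out
}

#' @export
`[.template_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("template_id", "target_sequence") %in% names(out))) {
    attr(out, "design") <- attr(x, "design")
    class(out) <- class(x)
  }
  out
}

#' @export
print.template_set <- function(x, ...) {
  d <- attr(x, "design")
  cat("Template set (design '", d$name, "'), ", nrow(x), " templates\n",
      sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

# Synthetic stand-in target sequences for the bundled template panel.  The
# published oligo sequences live in a vendor order sheet; these were drawn
# once at random with large pairwise Hamming separation and frozen.
.st_targets <- c(ST1 = "AAAACTCC", ST2 = "ATGTGTAA", ST3 = "GTAGAATC",
                 ST4 = "GGCCTTTC", ST5 = "CATATCTC")
.lt_targets <- c(
  LT1 = "GTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACAC",
  LT2 = "TGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAA",
  LT3 = "AGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGA",
  LT4 = "CCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCT",
  LT5 = "GAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAATATCTAA",
  LT6 = "CGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCA")

# Per-sample input copy numbers of the study panel.
.panel_copies <- c(LT1 = 40000, LT2 = 40000, LT3 = 4000, LT4 = 300,
                   LT5 = 100, LT6 = 20,
                   ST1 = 20000, ST2 = 20000, ST3 = 4000, ST4 = 4000,
                   ST5 = 4000)

#' Bundled default template panels
#'
#' The bundled panel mirrors the study composition: five short templates
#' ST1-ST5 (8-base targets, short design) with per-sample input copies
#' 20,000 / 20,000 / 4,000 / 4,000 / 4,000, and six long templates LT1-LT6
#' (50-base targets, long design) with 40,000 / 40,000 / 4,000 / 300 / 100 /
#' 20 copies.  Target sequences are synthetic stand-ins (see source) with
#' wide pairwise separation; replace them via [template_set()] or
#' [read_reference_fasta()] to analyze real data.
#'
#' @param which `"short"`, `"long"`, or `"both"`.
#' @return A `template_set` (or, for `"both"`, a named list of two).
#' @export
default_templates <- function(which = c("both", "short", "long")) {
  which <- match.arg(which)
  short <- template_set(default_design("short_template"),
                        names(.st_targets), unname(.st_targets),
                        unname(.panel_copies[names(.st_targets)]))
  long <- template_set(default_design("long_template"),
                       names(.lt_targets), unname(.lt_targets),
                       unname(.panel_copies[names(.lt_targets)]))
  switch(which,
         short = short,
         long = long,
         both = list(short = short, long = long))
}

#' Read reference target sequences from FASTA
#'
#' Sequence names become template ids; sequences must all match the
#' design's target-region width.
#'
#' @param path FASTA file of target sequences.
#' @param design The [barcode_design()] the targets belong to.
#' @param input_copies Optional named numeric vector of known copies.
#' @return A [template_set()].
#' @export
read_reference_fasta <- function(path, design, input_copies = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  copies <- if (is.null(input_copies)) NA_real_
            else unname(input_copies[ids])
  template_set(design, ids, as.character(seqs), copies)
}

#' Write a template set's target sequences to FASTA
#'
#' @param templates A [template_set()].
#' @param path Output FASTA path.
#' @export
write_reference_fasta <- function(templates, path) {
  x <- Biostrings::DNAStringSet(templates$target_sequence)
  names(x) <- templates$template_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
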
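# run fun() under a temporary RNG state seeded with `seed`
.seeded <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fun()
}

#' Randomly subsample reads
#'
#' Draws exactly `round(fraction * N)` reads uniformly without replacement
#' (exact-count subsampling, so a nominal 10% draw always uses the same
#' number of reads), reproducibly under `seed`.
#'
#' @param observations Observation data.frame.
#' @param fraction Fraction of reads to keep, in (0, 1].
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return The subsampled observation data.frame.
#' @export
subsample_reads <- function(observations, fraction, seed = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n <- nrow(observations)
  m <- round(fraction * n)
  if (m >= n) return(observations)
  idx <- .seeded(seed, function() sample.int(n, m))
  observations[sort(idx), , drop = FALSE]
}

#' Truncate the barcode to its first k random bases
#'
#' Computational truncation for the random-base sweep: returns the `k`
#' random positions closest to the 5' end (read order), to be passed as the
#' `positions` of the clustering.
#'
#' @param design A [barcode_design()].
#' @param k Number of random bases to keep, `1 <= k <=` number of random
#'   positions.
#' @return Integer vector of k barcode positions.
#' @export
truncate_random_bases <- function(design, k) {
  k <- as.integer(k)
  nr <- length(design$random_positions)
  if (is.na(k) || k < 1L || k > nr)
    stop("k must be between 1 and ", nr)
  design$random_positions[seq_len(k)]
}

.count_fun <- function(mode) {
  switch(mode,
         per_category = count_per_category,
         index_resolved = resolve_index_contamination,
         full_resolved = resolve_misidentification,
         stop("unknown mode: ", mode))
}

.curve_aggregate <- function(rows, swept_name) {
  # rows: data.frame(value, template_id, sample_index, molecules, reads,
  # repeat_i); aggregate to mean/sd per (value, template, index)
  key <- paste0(rows$value, "\v", rows$template_id, "\r",
                rows$sample_index)
  mean_m <- tapply(rows$molecules, key, mean)
  sd_m <- tapply(rows$molecules, key, stats::sd)
  n_rep <- tapply(rows$molecules, key, length)
  mean_r <- tapply(rows$reads, key, mean)
  kk <- names(mean_m)
  sep1 <- regexpr("\v", kk, fixed = TRUE)
  val <- as.numeric(substr(kk, 1L, sep1 - 1L))
  rest <- substr(kk, sep1 + 1L, nchar(kk))
  sep2 <- regexpr("\r", rest, fixed = TRUE)
  out <- data.frame(
    swept = swept_name,
    value = val,
    template_id = substr(rest, 1L, sep2 - 1L),
    sample_index = substr(rest, sep2 + 1L, nchar(rest)),
    mean_molecules = as.numeric(mean_m),
    sd_molecules = ifelse(is.na(sd_m), 0, as.numeric(sd_m)),
    n_repeats = as.integer(n_rep),
    mean_reads = as.numeric(mean_r),
    stringsAsFactors = FALSE)
  out$coverage <- ifelse(out$mean_molecules > 0,
                         out$mean_reads / out$mean_molecules, NA)
  # relative to the count at the maximal swept value, per (template, index)
  ref_val <- max(out$value)
  grp <- paste0(out$template_id, "\r", out$sample_index)
  ref <- out$mean_molecules[out$value == ref_val]
  names(ref) <- grp[out$value == ref_val]
  out$relative <- out$mean_molecules / ref[grp]
  out <- out[order(out$template_id, out$sample_index, out$value), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' Saturation of the cluster count with sequencing coverage
#'
#' The second requirement for accurate digital counting: every molecule's
#' barcode must be read at least once.  The curve is measured by randomly
#' removing reads — for each subsampling fraction, `n_repeats` independent
#' subsamples are drawn, the chosen counting mode is run on each, and the
#' mean and standard deviation of the per-(template, index) molecule count
#' are reported.  A plateau (count invariant to further depth) certifies
#' that the coverage requirement is met.
#'
#' @param observations Filtered, mapped observation data.frame.
#' @param design The [barcode_design()].
#' @param fractions Subsampling fractions; default the percent ladder
#'   100, 32, 10, 3.2, 1, 0.32, 0.1.
#' @param n_repeats Independent subsamples per fraction (default 8); the
#'   100% point is deterministic and is computed once.
#' @param seed Base seed; repeat r draws with seed `seed + r`.
#' @param distance,positions,method Passed to the clustering.
#' @param mode Counting mode: `"per_category"`, `"index_resolved"` or
#'   `"full_resolved"`.
#' @return A `saturation_curve` data.frame with, per swept value and
#'   (template, index): `mean_molecules`, `sd_molecules`, `n_repeats`,
#'   `mean_reads`, `coverage` (reads per molecule) and `relative` (count
#'   normalized to the maximal swept value).
#' @export
coverage_curve <- function(observations, design = NULL,
                           fractions = c(0.001, 0.0032, 0.01, 0.032, 0.1,
                                         0.32, 1),
                           n_repeats = 8L, seed = 1L, distance = 2L,
                           positions = NULL,
                           mode = c("per_category", "index_resolved",
                                    "full_resolved"),
                           method = "pigeonhole") {
  mode <- match.arg(mode)
  fractions <- sort(as.numeric(fractions))
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must be in (0, 1]")
  count <- .count_fun(mode)
  rows <- list()
  for (f in fractions) {
    reps <- if (f >= 1) 1L else n_repeats
    for (r in seq_len(reps)) {
      sub <- subsample_reads(observations, f, seed = seed + r)
      rep_ <- count(sub, design = design, distance = distance,
                    positions = positions, method = method)
      if (nrow(rep_) == 0L) next
      rows[[length(rows) + 1L]] <-
        data.frame(value = f, template_id = rep_$template_id,
                   sample_index = rep_$sample_index,
                   molecules = rep_$molecules, reads = rep_$reads,
                   stringsAsFactors = FALSE)
    }
  }
  .curve_aggregate(do.call(rbind, rows), "coverage_fraction")
}

#' Saturation of the cluster count with the number of random bases
#'
#' The first requirement for accurate digital counting: the barcode variety
#' must exceed the number of molecules.  The curve is measured by
#' computationally truncating the barcode to its first k random bases for a
#' grid of k, at a fixed subsampling fraction (default 10% of reads, drawn
#' `n_repeats` times).  Counts are normalized to the count at the largest
#' k; a plateau near 1 certifies that the variety requirement is met.
#'
#' @inheritParams coverage_curve
#' @param ks Grid of random-base counts to sweep (default 4 up to the
#'   design's full complement, step 4).
#' @param fraction Subsampling fraction applied before the sweep.
#' @return A `saturation_curve` data.frame (swept variable `random_bases`).
#' @export
random_base_curve <- function(observations, design, ks = NULL,
                              fraction = 0.1, n_repeats = 8L, seed = 1L,
                              distance = 2L,
                              mode = c("per_category", "index_resolved",
                                       "full_resolved"),
                              method = "pigeonhole") {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "barcode_design"))
  nr <- length(design$random_positions)
  if (is.null(ks)) ks <- unique(c(seq(4L, nr, by = 4L), nr))
  ks <- sort(as.integer(ks))
  count <- .count_fun(mode)
  reps <- if (fraction >= 1) 1L else n_repeats
  rows <- list()
  for (r in seq_len(reps)) {
    sub <- subsample_reads(observations, fraction, seed = seed + r)
    for (k in ks) {
      pos <- truncate_random_bases(design, k)
      rep_ <- count(sub, design = design, distance = distance,
                    positions = pos, method = method)
      if (nrow(rep_) == 0L) next
      rows[[length(rows) + 1L]] <-
        data.frame(value = k, template_id = rep_$template_id,
                   sample_index = rep_$sample_index,
                   molecules = rep_$molecules, reads = rep_$reads,
                   stringsAsFactors = FALSE)
    }
  }
  .curve_aggregate(do.call(rbind, rows), "random_bases")
}

#' Required number of random bases
#'
#' Scans a random-base saturation curve for the smallest number of random
#' bases at which the relative cluster count reaches the threshold
#' (default 0.95, i.e. 95% counting accuracy relative to the full
#' barcode).
#'
#' @param curve A `saturation_curve` from [random_base_curve()], or any
#'   data.frame with columns `value`, `template_id`, `sample_index`,
#'   `relative`.
#' @param threshold Relative-count threshold (default 0.95).
#' @return Data.frame with one row per (template, index): columns
#'   `required_bases` (`NA` when the threshold is never reached) and
#'   `reached`.
#' @export
required_random_bases <- function(curve, threshold = 0.95) {
  grp <- paste0(curve$template_id, "\r", curve$sample_index)
  res <- lapply(split(seq_len(nrow(curve)), grp), function(rows) {
    v <- curve$value[rows]; rel <- curve$relative[rows]
    o <- order(v)
    hit <- which(rel[o] >= threshold)
    if (length(hit))
      list(required = v[o][hit[1]], reached = TRUE)
    else list(required = NA_real_, reached = FALSE)
  })
  kk <- names(res)
  sep <- regexpr("\r", kk, fixed = TRUE)
  out <- data.frame(
    template_id = substr(kk, 1L, sep - 1L),
    sample_index = substr(kk, sep + 1L, nchar(kk)),
    required_bases = vapply(res, function(x) x$required, numeric(1)),
    reached = vapply(res, function(x) x$reached, logical(1)),
    threshold = threshold,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
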
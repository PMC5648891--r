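.count_report <- function(template_id, sample_index, molecules, reads,
                          mode, clusters_total, distance, positions) {
  out <- data.frame(template_id = template_id,
                    sample_index = sample_index,
                    molecules = as.numeric(molecules),
                    reads = as.numeric(reads),
                    coverage = ifelse(molecules > 0, reads / molecules, NA),
                    mode = rep_len(mode, length(template_id)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$template_id, out$sample_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clusters_total") <- clusters_total
  attr(out, "distance") <- distance
  attr(out, "positions") <- positions
  class(out) <- c("count_report", "data.frame")
  out
}

# Majority-rule assignment of clusters to (template, index) categories with
# fractional coefficients: each cluster contributes 1, split as 1/m over the
# m categories tied for the largest (weighted) read tally.
.majority_counts <- function(cluster, template, index, w) {
  cat_key <- paste0(template, "\r", index)
  key <- paste0(cluster, "\v", cat_key)
  agg <- rowsum(w, key, reorder = TRUE)
  rn <- rownames(agg)
  sep1 <- regexpr("\v", rn, fixed = TRUE)
  cl <- substr(rn, 1L, sep1 - 1L)
  cat_of_row <- substr(rn, sep1 + 1L, nchar(rn))
  tall <- agg[, 1L]
  mx <- stats::ave(tall, cl, FUN = max)
  is_max <- tall >= mx - 1e-9
  m <- stats::ave(as.numeric(is_max), cl, FUN = sum)
  contrib <- ifelse(is_max, 1 / m, 0)
  molecules <- rowsum(contrib, cat_of_row)
  reads <- rowsum(tall, cat_of_row)
  parts <- strsplit(rownames(molecules), "\r", fixed = TRUE)
  list(template = vapply(parts, `[`, "", 1L),
       index = vapply(parts, `[`, "", 2L),
       molecules = molecules[, 1L],
       reads = reads[, 1L],
       n_clusters = length(unique(cl)))
}

.default_positions <- function(design, positions) {
  if (!is.null(positions)) return(as.integer(positions))
  if (!is.null(design)) return(design$random_positions)
  NULL
}

#' Per-category molecule counts
#'
#' The baseline digital count: reads are grouped by (template, sample
#' index), barcodes are clustered independently within each group, and the
#' number of clusters is reported as the number of molecules present before
#' amplification.  No cross-category information is used, so index
#' contamination and mapping misidentification are *not* detected.
#'
#' @param observations Filtered, uniquely mapped observation data.frame
#'   (columns `barcode`, `sample_index`, `templates`, `n_templates`).
#' @param design The [barcode_design()]; its random positions are the
#'   default compared positions.
#' @param distance Clustering bound (*Distance*), default 2.
#' @param positions Barcode positions compared during clustering; `NULL`
#'   uses the design's random positions.
#' @param method Clustering method, see [cluster_barcodes()].
#' @return A `count_report` data.frame with one row per (template, index):
#'   columns `template_id`, `sample_index`, `molecules`, `reads`,
#'   `coverage` (reads per molecule) and `mode`.  The total molecule count
#'   always equals the total number of clusters.
#' @export
count_per_category <- function(observations, design = NULL, distance = 2L,
                               positions = NULL,
                               method = "pigeonhole") {
  positions <- .default_positions(design, positions)
  obs <- observations[observations$n_templates == 1L, , drop = FALSE]
  if (nrow(obs) == 0L)
    return(.count_report(character(0), character(0), numeric(0),
                         numeric(0), "per_category", 0L, distance,
                         positions))
  key <- paste0(obs$templates, "\r", obs$sample_index)
  groups <- split(seq_len(nrow(obs)), key)
  tmpl <- character(0); idx <- character(0)
  mols <- numeric(0); rds <- numeric(0); tot <- 0L
  for (g in names(groups)) {
    rows <- groups[[g]]
    cl <- cluster_barcodes(obs$barcode[rows], distance = distance,
                           positions = positions, method = method)
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    tmpl <- c(tmpl, parts[1]); idx <- c(idx, parts[2])
    mols <- c(mols, cl$n_clusters)
    rds <- c(rds, sum(!is.na(cl$membership)))
    tot <- tot + cl$n_clusters
  }
  .count_report(tmpl, idx, mols, rds, "per_category", tot, distance,
                positions)
}

#' Resolve cross-index contamination
#'
#' For each template, reads from *all* sample indices are pooled and
#' clustered together.  A cluster containing reads from more than one index
#' betrays contamination (primer carry-over, index sequencing errors or
#' index switching), because two independent samples essentially never draw
#' the same random barcode.  Each cluster contributes 1 molecule to the
#' index holding the majority of its reads; when the tally is exactly tied
#' between indices the cluster is split fractionally (coefficient 1/m to
#' each of the m tied indices, 0.5 each for a two-way tie).
#'
#' @inheritParams count_per_category
#' @return A `count_report` with `mode = "index_resolved"`.
#' @export
resolve_index_contamination <- function(observations, design = NULL,
                                        distance = 2L, positions = NULL,
                                        method = "pigeonhole") {
  positions <- .default_positions(design, positions)
  obs <- observations[observations$n_templates == 1L, , drop = FALSE]
  if (nrow(obs) == 0L)
    return(.count_report(character(0), character(0), numeric(0),
                         numeric(0), "index_resolved", 0L, distance,
                         positions))
  groups <- split(seq_len(nrow(obs)), obs$templates)
  tmpl <- character(0); idx <- character(0)
  mols <- numeric(0); rds <- numeric(0); tot <- 0L
  for (g in names(groups)) {
    rows <- groups[[g]]
    cl <- cluster_barcodes(obs$barcode[rows], distance = distance,
                           positions = positions, method = method)
    ok <- !is.na(cl$membership)
    if (!any(ok)) next
    res <- .majority_counts(cl$membership[ok],
                            rep(g, sum(ok)),
                            obs$sample_index[rows][ok],
                            rep(1, sum(ok)))
    tmpl <- c(tmpl, res$template); idx <- c(idx, res$index)
    mols <- c(mols, res$molecules); rds <- c(rds, res$reads)
    tot <- tot + cl$n_clusters
  }
  .count_report(tmpl, idx, mols, rds, "index_resolved", tot, distance,
                positions)
}

#' Resolve contamination and target misidentification
#'
#' The full resolution mode: reads mapped to *any* template, from all
#' indices, multi-mapped reads included, are pooled and clustered together.
#' A multi-mapped read contributes weight `1/(number of assigned
#' templates)` to each of its templates' tallies.  Each cluster contributes
#' 1 molecule to the (template, index) category with the largest weighted
#' read tally; exact ties are split 1/m over the m tied categories.
#' A cluster spanning several templates exposes a mapping
#' misidentification; one spanning several indices exposes contamination.
#'
#' @inheritParams count_per_category
#' @return A `count_report` with `mode = "full_resolved"`.
#' @export
resolve_misidentification <- function(observations, design = NULL,
                                      distance = 2L, positions = NULL,
                                      method = "pigeonhole") {
  positions <- .default_positions(design, positions)
  obs <- observations[observations$n_templates >= 1L, , drop = FALSE]
  if (nrow(obs) == 0L)
    return(.count_report(character(0), character(0), numeric(0),
                         numeric(0), "full_resolved", 0L, distance,
                         positions))
  cl <- cluster_barcodes(obs$barcode, distance = distance,
                         positions = positions, method = method)
  ok <- !is.na(cl$membership)
  # expand multi-mapped reads: one row per (read, template), weight 1/k
  tl <- strsplit(obs$templates[ok], ",", fixed = TRUE)
  k <- lengths(tl)
  rows <- rep(seq_len(sum(ok)), k)
  res <- .majority_counts(cl$membership[ok][rows],
                          unlist(tl, use.names = FALSE),
                          obs$sample_index[ok][rows],
                          rep(1 / k, k))
  .count_report(res$template, res$index, res$molecules, res$reads,
                "full_resolved", cl$n_clusters, distance, positions)
}

#' @export
print.count_report <- function(x, ...) {
  cat("Count report (mode = ", x$mode[1], ", Distance = ",
      attr(x, "distance"), "): ", attr(x, "clusters_total"),
      " clusters total\n", sep = "")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
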
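#' Hamming distance over selected barcode positions
#'
#' The clustering bound ("Distance") counts the number of positions at which
#' two barcodes differ, over a chosen subset of positions.  Two barcodes
#' that turn into each other through base changes at exactly two positions
#' are at distance 2.
#'
#' @param b1,b2 Character vectors of barcodes (recycled to common length).
#' @param positions 1-based positions to compare; `NULL` compares every
#'   position (barcodes must then have equal length).
#' @return Integer vector of pairwise distances.
#' @examples
#' masked_hamming("ACGT", "TGCA")           # 4
#' masked_hamming("AAAA", "AATA")           # 1
#' @export
masked_hamming <- function(b1, b2, positions = NULL) {
  b1 <- as.character(b1); b2 <- as.character(b2)
  n <- max(length(b1), length(b2))
  b1 <- rep_len(b1, n); b2 <- rep_len(b2, n)
  if (is.null(positions)) {
    if (any(nchar(b1) != nchar(b2)))
      stop("barcodes of unequal length; give explicit positions")
    out <- integer(n)
    for (L in unique(nchar(b1))) {
      idx <- which(nchar(b1) == L)
      out[idx] <- .hamming_at(b1[idx], b2[idx], seq_len(L))
    }
    return(out)
  }
  positions <- as.integer(positions)
  if (any(nchar(b1) < max(positions)) || any(nchar(b2) < max(positions)))
    stop("barcode(s) do not cover all requested positions")
  .hamming_at(b1, b2, positions)
}

.hamming_at <- function(b1, b2, positions) {
  d <- integer(length(b1))
  for (p in positions)
    d <- d + (substr(b1, p, p) != substr(b2, p, p))
  d
}

# n x k character matrix from equal-length strings
.char_matrix <- function(strings, width = NULL) {
  if (is.null(width)) width <- nchar(strings[1])
  matrix(unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE),
         ncol = width, byrow = TRUE)
}

# concatenate the selected positions of each barcode into one string
.mask_positions <- function(barcodes, positions) {
  if (is.null(positions)) return(barcodes)
  cols <- lapply(as.integer(positions),
                 function(p) substr(barcodes, p, p))
  do.call(paste0, cols)
}

#' Bounded single-linkage clustering of barcode sequences
#'
#' Implements the clustering at the heart of digital counting.  Initially
#' every (distinct) barcode is its own cluster; whenever two barcodes differ
#' at no more than `distance` of the compared positions, their clusters are
#' merged; merging continues until no two clusters can be merged.  The
#' result is the partition of barcodes into connected components of the
#' "differs by at most `distance` bases" relation (single linkage: members
#' of a cluster need only be chained, not mutually close).  `distance = 0`
#' reduces to counting distinct barcode strings.
#'
#' Reads whose compared positions contain `N` are removed before clustering
#' (their membership is `NA`).
#'
#' The default method deduplicates barcodes over the compared positions,
#' generates candidate pairs by pigeonhole partitioning — the compared
#' positions are split into `distance + 1` contiguous segments, and any two
#' barcodes within the bound must agree exactly on at least one segment —
#' verifies candidates with [masked_hamming()], and takes connected
#' components.  This is exact, not heuristic; `method = "naive"` is the
#' quadratic all-pairs reference used for cross-checking.
#'
#' @param barcodes Character vector of barcodes, one element per read
#'   (multiplicities matter for downstream tallies).
#' @param distance Non-negative integer bound on the number of mismatches
#'   for merging (the *Distance* parameter).
#' @param positions Barcode positions to compare (normally the design's
#'   random positions, possibly truncated); `NULL` uses every position.
#' @param method `"pigeonhole"` (default) or `"naive"`.
#' @return An object of class `barcode_clusters` with elements
#'   `membership` (integer cluster id per input read, `NA` for N-removed
#'   reads), `n_clusters`, `cluster_id` (per cluster: its lexicographically
#'   smallest member barcode over the compared positions), `sizes` (reads
#'   per cluster), `masked` (compared-position string per read),
#'   `distance`, `positions`, `n_removed_N`.
#' @examples
#' cl <- cluster_barcodes(c("AAAA", "AAAA", "AAAT", "GGGG"), distance = 1)
#' cl$n_clusters   # 2: {AAAA, AAAA, AAAT} and {GGGG}
#' @export
cluster_barcodes <- function(barcodes, distance = 2L, positions = NULL,
                             method = c("pigeonhole", "naive")) {
  method <- match.arg(method)
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 0L)
    stop("distance must be a non-negative integer")
  barcodes <- as.character(barcodes)
  n <- length(barcodes)
  if (n == 0L)
    return(structure(list(membership = integer(0), n_clusters = 0L,
                          cluster_id = character(0), sizes = integer(0),
                          masked = character(0), distance = distance,
                          positions = positions, n_removed_N = 0L),
                     class = "barcode_clusters"))
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) == 0L) stop("positions must be non-empty")
    if (any(nchar(barcodes) < max(positions)))
      stop("barcode(s) shorter than the largest compared position")
  } else if (length(unique(nchar(barcodes))) > 1L) {
    stop("barcodes of unequal length; give explicit positions")
  }
  masked <- .mask_positions(barcodes, positions)
  k <- nchar(masked[1])

  ok <- !grepl("N", masked, fixed = TRUE)
  membership <- rep(NA_integer_, n)
  u <- unique(masked[ok])
  nu <- length(u)
  if (nu == 0L) {
    comp <- integer(0)
  } else if (distance == 0L || nu == 1L) {
    comp <- seq_len(nu)
  } else if (k <= distance) {
    comp <- rep(1L, nu)          # every pair is within the bound
  } else {
    edges <- if (method == "naive") .all_pairs_edges(u, k, distance)
             else .pigeonhole_edges(u, k, distance)
    if (nrow(edges) == 0L) {
      comp <- seq_len(nu)
    } else {
      g <- igraph::make_undirected_graph(edges = as.vector(t(edges)),
                                         n = nu)
      comp <- igraph::components(g)$membership
    }
  }
  # canonical ids: clusters ordered by their lexicographically smallest member
  if (nu > 0L) {
    reps <- unname(vapply(split(u, comp), min, character(1)))
    o <- order(reps)
    remap <- integer(length(reps)); remap[o] <- seq_along(reps)
    comp <- remap[comp]
    reps <- reps[o]
    membership[ok] <- comp[match(masked[ok], u)]
  } else reps <- character(0)
  sizes <- if (nu > 0L) tabulate(membership[ok], nbins = length(reps))
           else integer(0)
  structure(list(membership = membership,
                 n_clusters = length(reps),
                 cluster_id = reps,
                 sizes = sizes,
                 masked = masked,
                 distance = distance,
                 positions = positions,
                 n_removed_N = sum(!ok)),
            class = "barcode_clusters")
}

#' @export
print.barcode_clusters <- function(x, ...) {
  cat("Barcode clustering: ", length(x$membership), " reads -> ",
      x$n_clusters, " clusters (Distance = ", x$distance, ")\n", sep = "")
  if (x$n_removed_N > 0L)
    cat("  ", x$n_removed_N, " read(s) removed for N in compared bases\n",
        sep = "")
  invisible(x)
}

# all-pairs candidate edges (quadratic reference path)
.all_pairs_edges <- function(u, k, d) {
  nu <- length(u)
  M <- .char_matrix(u, k)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(nu - 1L)) {
    rest <- (i + 1L):nu
    mism <- integer(length(rest))
    for (c in seq_len(k))
      mism <- mism + (M[rest, c] != M[i, c])
    hit <- rest[mism <= d]
    ii <- c(ii, rep.int(i, length(hit))); jj <- c(jj, hit)
  }
  cbind(ii, jj)
}

# pigeonhole candidate generation + exact verification
.pigeonhole_edges <- function(u, k, d) {
  nu <- length(u)
  M <- .char_matrix(u, k)
  nseg <- d + 1L
  bounds <- floor(seq(0L, k, length.out = nseg + 1L))
  keys <- numeric(0)
  for (s in seq_len(nseg)) {
    a <- bounds[s] + 1L; b <- bounds[s + 1L]
    seg <- substr(u, a, b)
    grp <- split(seq_len(nu), seg)
    grp <- grp[lengths(grp) >= 2L]
    if (!length(grp)) next
    pair_keys <- lapply(grp, function(g) {
      s_ <- length(g)
      i <- rep(g[-s_], times = (s_ - 1L):1L)
      j <- g[sequence((s_ - 1L):1L, from = 2:s_)]
      (i - 1) * nu + j                     # i < j encoded as one double
    })
    keys <- c(keys, unlist(pair_keys, use.names = FALSE))
  }
  if (!length(keys)) return(cbind(integer(0), integer(0)))
  keys <- unique(keys)
  i <- as.integer((keys - 1) %/% nu) + 1L
  j <- as.integer((keys - 1) %% nu) + 1L
  # verify candidates in chunks to bound memory
  keep <- logical(length(i))
  chunk <- 2000000L
  for (st in seq(1L, length(i), by = chunk)) {
    en <- min(st + chunk - 1L, length(i))
    ic <- i[st:en]; jc <- j[st:en]
    mism <- integer(en - st + 1L)
    for (c in seq_len(k)) {
      mism <- mism + (M[ic, c] != M[jc, c])
    }
    keep[st:en] <- mism <= d
  }
  cbind(i[keep], j[keep])
}

#' Count unique barcodes
#'
#' The number of distinct barcode strings over the compared positions —
#' clustering with `distance = 0`.  This is the raw digital count before
#' any error correction.
#'
#' @inheritParams cluster_barcodes
#' @return Integer count.
#' @export
count_unique <- function(barcodes, positions = NULL) {
  cluster_barcodes(barcodes, distance = 0L, positions = positions)$n_clusters
}
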
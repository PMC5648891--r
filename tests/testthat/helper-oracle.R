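# Independent brute-force clustering oracle: all-pairs Hamming comparison
# and a plain union-find, sharing no code with the package's pigeonhole
# candidate search.

oracle_cluster <- function(barcodes, distance, positions = NULL) {
  chars <- strsplit(barcodes, "", fixed = TRUE)
  if (!is.null(positions))
    chars <- lapply(chars, function(x) x[positions])
  keep <- !vapply(chars, function(x) any(x == "N"), logical(1))
  chars <- chars[keep]
  masked <- vapply(chars, paste, character(1), collapse = "")
  n <- length(chars)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (sum(chars[[i]] != chars[[j]]) <= distance) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(masked, roots))
}

# canonical signature of a partition: sorted multiset of sorted member lists
partition_signature <- function(groups) {
  sig <- vapply(groups, function(g) paste(sort(g), collapse = "|"),
                character(1))
  sort(unname(sig))
}

# partition signature from a barcode_clusters object (masked strings)
clusters_signature <- function(cl) {
  ok <- !is.na(cl$membership)
  partition_signature(split(cl$masked[ok], cl$membership[ok]))
}

random_barcodes <- function(n, k, n_distinct = NULL) {
  if (is.null(n_distinct)) n_distinct <- n
  base <- replicate(n_distinct,
                    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                          collapse = ""))
  if (n == n_distinct) return(sample(base))
  sample(base, n, replace = TRUE)
}

# parent barcodes plus mutated children within max_subs substitutions,
# so near-neighbor structure actually exercises the merging logic
noisy_barcodes <- function(n_parents, k, n_children, max_subs = 3) {
  parents <- random_barcodes(n_parents, k)
  children <- vapply(sample(parents, n_children, replace = TRUE),
                     function(p) {
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    pos <- sample.int(k, sample.int(max_subs, 1))
    ch[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  sample(c(parents, children))
}

# single-template, single-index config for quick simulations
one_template_config <- function(which = "short", copies = 200, ...) {
  ts <- default_templates(which)
  ts1 <- ts[1, ]
  ts1$input_copies <- copies
  simulation_config(ts1, indices = c(A = "CGCTCATT"), ...)
}
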
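short <- default_design("short_template")

obs_df <- function(seqs, index = "A") {
  data.frame(read_id = paste0("r", seq_along(seqs)),
             sample_index = index, seq = seqs,
             stringsAsFactors = FALSE)
}

test_that("demultiplexing assigns exact indices and routes ties away", {
  idx <- c(A = "CGCTCATT", B = "GAGATTCC")
  expect_equal(demultiplex(c("CGCTCATT", "GAGATTCC"), idx), c("A", "B"))
  # one mismatch is unassignable at the exact default
  expect_true(is.na(demultiplex("CGCTCATA", idx)))
  expect_equal(demultiplex("CGCTCATA", idx, max_index_mismatch = 1), "A")
  # equidistant read at the tolerance: tie, undetermined
  idx2 <- c(A = "AAAA", B = "AATT")
  expect_true(is.na(demultiplex("AATA", idx2, max_index_mismatch = 1)))
  expect_error(demultiplex("AAAA", c(A = "AAAA", B = "AAAA")), "duplicate")
})

test_that("length filter keeps the inclusive window and drops the rest", {
  r <- obs_df(c(strrep("A", 33), strrep("A", 34), strrep("A", 39),
                strrep("A", 40)))
  out <- length_filter(r, short)
  expect_equal(nchar(out$observations$seq), c(34L, 39L))
  expect_equal(out$stats$n_in, 4L)
  expect_equal(out$stats$n_kept + out$stats$n_removed, out$stats$n_in)

  long <- default_design("long_template")
  r <- obs_df(c(strrep("C", 89), strrep("C", 90), strrep("C", 120)))
  out <- length_filter(r, long)
  expect_equal(nchar(out$observations$seq), c(90L, 120L))
})

test_that("barcode extraction takes the first barcode_length bases", {
  r <- obs_df(paste0(strrep("G", 30), "ACGTA"))          # 35-base read
  out <- extract_barcode(r, short)
  expect_equal(out$observations$barcode, strrep("G", 30))
  # too-short read is flagged out
  out <- extract_barcode(obs_df(strrep("G", 29)), short)
  expect_equal(nrow(out$observations), 0L)
  expect_equal(out$stats$n_removed, 1L)
})

test_that("N filter removes any barcode containing N", {
  r <- obs_df(rep("x", 3))
  r$barcode <- c(paste0("ACGN", strrep("A", 26)), strrep("A", 30),
                 strrep("N", 30))
  out <- n_filter(r)
  expect_equal(out$observations$barcode, strrep("A", 30))
  expect_equal(out$stats$n_removed, 2L)
})

# barcode matching the short design at every fixed position, random
# elsewhere
conforming_barcode <- function(design, n = 1) {
  vapply(seq_len(n), function(i) {
    ch <- sample(c("A", "C", "G", "T"), design$barcode_length,
                 replace = TRUE)
    ch[design$fixed_positions] <- design$fixed_bases
    paste(ch, collapse = "")
  }, character(1))
}

test_that("fixed-base filter removes any selected-position mismatch", {
  set.seed(1)
  r <- obs_df(rep("x", 2))
  good <- conforming_barcode(short)
  bad <- good
  substr(bad, 21, 21) <- if (substr(good, 21, 21) == "A") "C" else "A"
  r$barcode <- c(good, bad)
  out <- fixed_base_filter(r, short, "furthest:4")
  expect_equal(out$observations$barcode, good)
  expect_equal(out$selected, c(16L, 21L, 24L, 28L))
  # a mismatch at an unselected fixed position survives a furthest:4 filter
  bad5 <- good
  substr(bad5, 5, 5) <- if (substr(good, 5, 5) == "A") "C" else "A"
  r$barcode <- c(good, bad5)
  expect_equal(nrow(fixed_base_filter(r, short, "furthest:4")$observations),
               2L)
  expect_equal(nrow(fixed_base_filter(r, short, NULL)$observations), 1L)
  expect_error(fixed_base_filter(r, short, c(3L)), "3")
})

test_that("with zero simulated errors the fixed-base filter removes nothing", {
  cfg <- one_template_config(copies = 100, sub_rate = 0, ins_rate = 0,
                             del_rate = 0, n_rate = 0, min_reads = 1)
  sim <- simulate_reads(cfg, seed = 5)
  obs <- extract_barcode(sim$reads, short)$observations
  out <- fixed_base_filter(obs, short, NULL)
  expect_equal(out$stats$n_removed, 0L)
})

test_that("a deletion upstream of the selected fixed bases is caught at the
           expected rate", {
  # A 1-base deletion shifts every downstream base one step left; each
  # selected fixed position then shows the next base of the barcode, which
  # matches the expected fixed base with probability ~1/4 per position.
  # With k selected positions downstream of the deletion, escape
  # probability is ~(1/4)^k; removal should approach 1 - (1/4)^k.
  set.seed(42)
  n <- 2000
  bcs <- conforming_barcode(short, n)
  # delete barcode position 1, sequence slides left (next base enters at 30)
  shifted <- paste0(substr(bcs, 2, 30),
                    sample(c("A", "C", "G", "T"), n, replace = TRUE))
  r <- obs_df(rep("x", n)); r$barcode <- shifted
  kept <- nrow(fixed_base_filter(r, short, "furthest:4")$observations)
  removal <- 1 - kept / n
  expect_gte(removal, 1 - (1 / 4)^4 - 0.02)
})

test_that("filtering is invariant to input read order", {
  set.seed(7)
  cfg <- one_template_config(copies = 50, min_reads = 1, sub_rate = 0.01,
                             del_rate = 0.002, ins_rate = 0.002)
  sim <- simulate_reads(cfg, seed = 2)
  run <- function(reads) {
    x <- length_filter(reads, short)$observations
    x <- extract_barcode(x, short)$observations
    x <- n_filter(x)$observations
    x <- fixed_base_filter(x, short, "furthest:4")$observations
    sort(x$read_id)
  }
  shuffled <- sim$reads[sample.int(nrow(sim$reads)), ]
  expect_equal(run(shuffled), run(sim$reads))
})

test_that("FASTQ round-trips through write and read", {
  r <- obs_df(c("ACGTACGTAANCGT", "GGGTTTCCCAAATT"))
  f <- tempfile(fileext = ".fastq")
  write_fastq(r, f)
  back <- read_fastq(f, sample_index = "A")
  expect_equal(back$seq, r$seq)
  expect_equal(back$read_id, r$read_id)
  expect_equal(back$sample_index, rep("A", 2))
})
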
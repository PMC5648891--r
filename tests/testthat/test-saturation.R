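short <- default_design("short_template")

test_that("subsampling draws the exact count, reproducibly", {
  set.seed(2)
  obs <- data.frame(read_id = paste0("r", 1:1000), sample_index = "A",
                    seq = "ACGT", stringsAsFactors = FALSE)
  sub <- subsample_reads(obs, 0.1, seed = 99)
  expect_equal(nrow(sub), 100L)
  expect_true(all(sub$read_id %in% obs$read_id))
  expect_identical(subsample_reads(obs, 0.1, seed = 99), sub)
  expect_false(identical(subsample_reads(obs, 0.1, seed = 100), sub))
  expect_identical(subsample_reads(obs, 1.0, seed = 1), obs)
  expect_error(subsample_reads(obs, 0), "fraction")
  expect_error(subsample_reads(obs, 1.5), "fraction")
})

test_that("random-base truncation keeps the first k random positions", {
  expect_equal(truncate_random_bases(short, 24),
               short$random_positions)
  expect_equal(truncate_random_bases(short, 4), c(1L, 2L, 3L, 4L))
  expect_error(truncate_random_bases(short, 0), "between")
  expect_error(truncate_random_bases(short, 25), "between")
})

test_that("required random bases is the smallest k reaching the threshold", {
  curve <- data.frame(value = c(4, 8, 12, 16, 20, 24),
                      template_id = "ST1", sample_index = "A",
                      relative = c(0.01, 0.60, 0.93, 0.96, 0.99, 1.0))
  out <- required_random_bases(curve, threshold = 0.95)
  expect_equal(out$required_bases, 16)
  expect_true(out$reached)
  # flat curve at 1: smallest k on the grid
  curve$relative <- 1
  expect_equal(required_random_bases(curve)$required_bases, 4)
  # never reaching the threshold
  curve$relative <- seq(0.1, 0.6, length.out = 6)
  out <- required_random_bases(curve)
  expect_true(is.na(out$required_bases))
  expect_false(out$reached)
})

# near-Poisson coverage (high NB size) so that subsampling to coverage
# ~7 leaves essentially no molecule unread, isolating the saturation
# property itself from coverage overdispersion
zero_error_obs <- function(copies = 200, seed = 13) {
  cfg <- one_template_config(copies = copies, sub_rate = 0, ins_rate = 0,
                             del_rate = 0, n_rate = 0, min_reads = 1,
                             dispersion = 50)
  sim <- simulate_reads(cfg, seed = seed)
  obs <- extract_barcode(sim$reads, short)$observations
  obs$templates <- "ST1"; obs$n_templates <- 1L
  obs
}

test_that("zero-error coverage curve plateaus at the molecule count", {
  obs <- zero_error_obs(200)
  cv <- coverage_curve(obs, design = short, fractions = c(0.5, 1),
                       n_repeats = 3, seed = 7)
  expect_equal(cv$mean_molecules, rep(200, 2), tolerance = 0.005)
  # the 100% point is deterministic: SD 0, computed once
  expect_equal(cv$sd_molecules[cv$value == 1], 0)
  expect_equal(cv$n_repeats[cv$value == 1], 1L)
  expect_equal(cv$relative[cv$value == 1], 1)
  # coverage is reads per molecule
  expect_equal(cv$coverage, cv$mean_reads / cv$mean_molecules)
})

test_that("random-base curve saturates like the birthday bound and is
           monotone", {
  obs <- zero_error_obs(200)
  # distance 0: the raw unique count is what the birthday bound predicts
  rb <- random_base_curve(obs, short, ks = c(4, 8, 16, 24), fraction = 1,
                          seed = 7, distance = 0)
  # k = 4: only 256 barcode patterns exist; expected distinct count is
  # K (1 - (1 - 1/K)^N)
  K <- 4^4; N <- 200
  exp4 <- K * (1 - (1 - 1 / K)^N)
  got4 <- rb$mean_molecules[rb$value == 4]
  expect_lt(abs(got4 - exp4) / exp4, 0.1)
  # monotone non-decreasing in k, relative 1 at max
  expect_true(all(diff(rb$mean_molecules[order(rb$value)]) >= 0))
  expect_equal(rb$relative[rb$value == 24], 1)
  expect_equal(rb$mean_molecules[rb$value == 24], 200)
})

test_that("substitution rate is recovered from cluster consensuses", {
  cfg <- one_template_config(copies = 150, min_reads = 1, sub_rate = 0.01,
                             ins_rate = 0, del_rate = 0, n_rate = 0)
  sim <- simulate_reads(cfg, seed = 21)
  bc <- substr(sim$reads$seq, 1, 30)
  cl <- cluster_barcodes(bc, distance = 3,
                         positions = short$random_positions)
  est <- estimate_substitution_rate(cl)
  expect_lt(abs(est$rate - 0.01), 0.0015)
  expect_gt(est$n_clusters_used, 100)
  # zero-error data: rate exactly 0
  obs0 <- zero_error_obs(100)
  cl0 <- cluster_barcodes(obs0$barcode, distance = 2,
                          positions = short$random_positions)
  expect_equal(estimate_substitution_rate(cl0)$rate, 0)
})

test_that("fixed-base mismatch rates are flat under substitutions and grow
           with position under deletions", {
  e <- 0.02
  cfg <- one_template_config(copies = 150, min_reads = 1, sub_rate = e,
                             ins_rate = 0, del_rate = 0, n_rate = 0)
  sim <- simulate_reads(cfg, seed = 22)
  obs <- extract_barcode(sim$reads, short)$observations
  rates <- estimate_fixed_base_mismatch_rates(obs, short)
  expect_true(all(abs(rates$mismatch_rate - e) < 0.01))
  # deletions: mismatch probability grows with distance from the primer
  cfg <- one_template_config(copies = 150, min_reads = 1, sub_rate = 0,
                             ins_rate = 0, del_rate = 0.01, n_rate = 0)
  sim <- simulate_reads(cfg, seed = 23)
  obs <- extract_barcode(length_filter(sim$reads, short)$observations,
                         short)$observations
  rates <- estimate_fixed_base_mismatch_rates(obs, short)
  expect_gt(rates$mismatch_rate[rates$position == 28],
            rates$mismatch_rate[rates$position == 5])
  expect_gt(stats::cor(rates$position, rates$mismatch_rate), 0.8)
  # zero-error data: all rates 0
  obs0 <- zero_error_obs(100)
  expect_equal(estimate_fixed_base_mismatch_rates(obs0, short)$mismatch_rate,
               rep(0, 6))
})

test_that("base composition of the barcode pool is recovered per molecule", {
  comp <- c(A = 0.17, C = 0.29, G = 0.29, T = 0.25)
  cfg <- one_template_config(copies = 400, min_reads = 1, sub_rate = 0.003,
                             ins_rate = 0, del_rate = 0, n_rate = 0,
                             composition = comp)
  sim <- simulate_reads(cfg, seed = 24)
  obs <- extract_barcode(sim$reads, short)$observations
  obs <- fixed_base_filter(obs, short, NULL)$observations
  cl <- cluster_barcodes(obs$barcode, distance = 2,
                         positions = short$random_positions)
  f <- estimate_base_composition(cl)
  expect_equal(dim(f), c(24L, 4L))
  expect_equal(rowSums(f), rep(1, 24), ignore_attr = TRUE)
  # per-position binomial error over ~400 molecules
  expect_true(all(abs(sweep(f, 2, comp[colnames(f)])) < 0.1))
  expect_true(all(abs(colMeans(f) - comp[colnames(f)]) < 0.03))
  # empty cluster set
  f0 <- estimate_base_composition(cluster_barcodes(character(0)))
  expect_equal(nrow(f0), 0L)
})
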
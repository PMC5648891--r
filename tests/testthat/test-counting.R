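# minimal observation frames built directly at the barcode level
bc_obs <- function(barcode, index = "A", template = "T1") {
  n <- length(barcode)
  data.frame(read_id = sprintf("r%d", seq_len(n)),
             sample_index = rep_len(index, n),
             barcode = rep_len(barcode, n),
             templates = rep_len(template, n),
             n_templates = lengths(strsplit(rep_len(template, n), ",")),
             stringsAsFactors = FALSE)
}

test_that("per-category counts equal cluster counts and report coverage", {
  set.seed(1)
  b <- rep(random_barcodes(10, 12), each = 10)      # 100 reads, 10 barcodes
  rep_ <- count_per_category(bc_obs(b), distance = 0)
  expect_equal(rep_$molecules, 10)
  expect_equal(rep_$reads, 100)
  expect_equal(rep_$coverage, 10)
  expect_equal(attr(rep_, "clusters_total"), 10)
  # empty category
  empty <- count_per_category(bc_obs(character(0)), distance = 0)
  expect_equal(nrow(empty), 0L)
})

test_that("index contamination resolves by read majority with 0.5 ties", {
  # one barcode cluster: 3 A reads, 1 B read -> majority A
  obs <- bc_obs(rep("ACGTACGT", 4), index = c("A", "A", "A", "B"))
  rep_ <- resolve_index_contamination(obs, distance = 0)
  expect_equal(rep_$molecules[rep_$sample_index == "A"], 1)
  expect_equal(rep_$molecules[rep_$sample_index == "B"], 0)
  # exact tie: 2 vs 2 -> 0.5 each
  obs <- bc_obs(rep("ACGTACGT", 4), index = c("A", "A", "B", "B"))
  rep_ <- resolve_index_contamination(obs, distance = 0)
  expect_equal(rep_$molecules[rep_$sample_index == "A"], 0.5)
  expect_equal(rep_$molecules[rep_$sample_index == "B"], 0.5)
  # single-index cluster contributes 1 to its index
  obs <- bc_obs(rep("ACGTACGT", 3), index = "A")
  rep_ <- resolve_index_contamination(obs, distance = 0)
  expect_equal(rep_$molecules, 1)
  # total is conserved
  expect_equal(sum(rep_$molecules), attr(rep_, "clusters_total"))
})

test_that("misidentification resolves by weighted majority with 1/m ties", {
  # 5 reads uniquely ST1/A + 1 read uniquely ST2/A in one cluster
  obs <- bc_obs(rep("ACGTACGT", 6), template = c(rep("ST1", 5), "ST2"))
  rep_ <- resolve_misidentification(obs, distance = 0)
  expect_equal(rep_$molecules[rep_$template_id == "ST1"], 1)
  expect_equal(rep_$molecules[rep_$template_id == "ST2"], 0)
  # a read mapped to two templates contributes 0.5 to each tally:
  # 1 read ST1,ST2 + 1 read ST2 -> tallies ST1 = 0.5, ST2 = 1.5
  obs <- bc_obs(rep("ACGTACGT", 2), template = c("ST1,ST2", "ST2"))
  rep_ <- resolve_misidentification(obs, distance = 0)
  expect_equal(rep_$molecules[rep_$template_id == "ST2"], 1)
  expect_equal(rep_$molecules[rep_$template_id == "ST1"], 0)
  # equal weighted tallies in (ST1, A) and (ST2, B): 0.5 each
  obs <- bc_obs(rep("ACGTACGT", 2), index = c("A", "B"),
                template = c("ST1", "ST2"))
  rep_ <- resolve_misidentification(obs, distance = 0)
  expect_equal(sort(rep_$molecules[rep_$molecules > 0]), c(0.5, 0.5))
  expect_equal(sum(rep_$molecules), 1)
  # three-way tie generalizes to 1/3
  obs <- bc_obs(rep("ACGTACGT", 3), template = c("T1", "T2", "T3"))
  rep_ <- resolve_misidentification(obs, distance = 0)
  expect_equal(rep_$molecules, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("counts are conserved and modes agree on clean data", {
  set.seed(5)
  cfg <- one_template_config(copies = 120, min_reads = 1, sub_rate = 0.01)
  sim <- simulate_reads(cfg, seed = 4)
  design <- default_design("short_template")
  obs <- extract_barcode(length_filter(sim$reads, design)$observations,
                         design)$observations
  obs <- n_filter(obs)$observations
  obs$templates <- "ST1"; obs$n_templates <- 1L
  for (f in list(count_per_category, resolve_index_contamination,
                 resolve_misidentification)) {
    rep_ <- f(obs, design = design, distance = 2)
    expect_equal(sum(rep_$molecules), attr(rep_, "clusters_total"))
  }
  # single-index, single-template: all three modes give the same counts
  r1 <- count_per_category(obs, design = design, distance = 2)
  r2 <- resolve_index_contamination(obs, design = design, distance = 2)
  r3 <- resolve_misidentification(obs, design = design, distance = 2)
  expect_equal(r1$molecules, r2$molecules)
  expect_equal(r2$molecules, r3$molecules)
})

test_that("resolving contamination never raises the minority-index count", {
  set.seed(6)
  ts <- default_templates("short")[1, ]
  ts$input_copies <- 150
  cfg <- simulation_config(ts, indices = c(A = "CGCTCATT",
                                           B = "GAGATTCC"),
                           min_reads = 1, swap_prob = 0.02)
  sim <- simulate_reads(cfg, seed = 12)
  design <- default_design("short_template")
  obs <- extract_barcode(length_filter(sim$reads, design)$observations,
                         design)$observations
  obs <- n_filter(obs)$observations
  obs$templates <- "ST1"; obs$n_templates <- 1L
  unresolved <- count_per_category(obs, design = design, distance = 2)
  resolved <- resolve_index_contamination(obs, design = design,
                                          distance = 2)
  for (ix in c("A", "B")) {
    u <- unresolved$molecules[unresolved$sample_index == ix]
    r <- resolved$molecules[resolved$sample_index == ix]
    expect_lte(r, u)
  }
})
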
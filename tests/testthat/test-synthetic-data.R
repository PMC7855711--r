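small_cfg <- function(seed = 7, ...) {
  cohort_config(
    n_datasets = 3, samples_per_group = 30, n_decoy_mrna = 10,
    n_decoy_lncrna = 4, n_decoy_mirna = 3, seed = seed, ...
  )
}

test_that("identical seeds reproduce the cohort exactly", {
  a <- generate_cohort(small_cfg())
  b <- generate_cohort(small_cfg())
  expect_identical(
    lapply(a$datasets, `[[`, "values"),
    lapply(b$datasets, `[[`, "values")
  )
  d <- generate_cohort(small_cfg(seed = 8))
  expect_false(identical(a$datasets$DS01$values, d$datasets$DS01$values))
})

test_that("config invariants are enforced before generation", {
  expect_error(cohort_config(noise_sd = 0), class = "cernascreen_error_validation")
  expect_error(cohort_config(sponge_coupling = 1.2), class = "cernascreen_error_validation")
  expect_error(cohort_config(missing_feature_fraction = 1), class = "cernascreen_error_validation")
  expect_error(cohort_config(n_bait_up = -1), class = "cernascreen_error_validation")
})

test_that("values are complete outside the declared missing-feature pattern", {
  ch <- generate_cohort(small_cfg(missing_feature_fraction = 0.3))
  for (ds in ch$datasets) {
    expect_false(anyNA(ds$values))
    present <- ch$truth$feature_presence
    expect_setequal(
      rownames(ds$values),
      present$feature_id[present$dataset_id == ds$dataset_id]
    )
  }
  # the reference dataset carries every feature, including miRNAs
  expect_true(all(ch$truth$axis_mirna_ids %in% rownames(ch$datasets$DS01$values)))
})

test_that("empirical sponge correlations match the closed-form loading formula", {
  cfg <- cohort_config(
    n_datasets = 1, samples_per_group = 60, sponge_coupling = 0.8,
    noise_sd = 1, n_decoy_mrna = 5, n_decoy_lncrna = 2, n_decoy_mirna = 2,
    missing_feature_fraction = 0, seed = 42
  )
  ch <- generate_cohort(cfg)
  v <- ch$datasets$DS01$values
  lam2 <- 0.8^2
  expected <- lam2 / (lam2 + 1) # 0.3902
  rs <- vapply(
    ch$truth$axis_mrna_ids,
    function(g) cor(v[ch$truth$sponge_lncrna_id, ], v[g, ]), 1
  )
  # mean over 5 planted mRNAs: SE ~ (1 - r^2)/sqrt(5 * n) ~ 0.031
  expect_lt(abs(mean(rs) - expected), 3 * (1 - expected^2) / sqrt(5 * 120))
  rneg <- vapply(
    ch$truth$axis_mirna_ids,
    function(g) cor(v[ch$truth$sponge_lncrna_id, ], v[g, ]), 1
  )
  expect_true(all(rneg < 0))
})

test_that("zero effect size makes baits behave like decoys", {
  cfg <- small_cfg(bait_effect_size = 0)
  ch <- generate_cohort(cfg)
  calls <- differential_by_contrast(
    ch$datasets$DS01, severity_contrast(),
    alpha = 0.01
  )
  expect_lte(sum(calls$feature_id %in% c(ch$truth$bait_up_ids, ch$truth$bait_down_ids)), 1)
})

test_that("interaction tables mirror the planted truth and exclusion config", {
  cfg <- cohort_config(
    n_datasets = 1, samples_per_group = 10, n_axis_mirnas = 3, n_axis_mrnas = 1,
    n_decoy_mrna = 2, n_decoy_lncrna = 1, n_decoy_mirna = 2,
    n_mirnas_without_targets = 2, interaction_false_positive_rows = 0, seed = 3
  )
  ch <- generate_cohort(cfg)
  tabs <- generate_interaction_tables(ch$truth, cfg)
  expect_equal(nrow(tabs$targets), 3) # 3 planted pairs, no decoys
  mirnas <- tibble::tibble(mirna_id = c(ch$truth$axis_mirna_ids, ch$truth$no_target_mirna_ids))
  expect_message(kept <- expand_validated_targets(mirnas, tabs$targets))
  expect_setequal(attr(kept, "excluded"), ch$truth$no_target_mirna_ids)
  expect_setequal(
    tabs$cancer$mirna_id[tabs$cancer$disease == "CRC"],
    ch$truth$oncomir_ids
  )
})

test_that("noise-free qPCR plates invert exactly and noisy ones are unbiased", {
  exact <- generate_qpcr_plate(c(A = 1, B = 2), n_per_group = 4, ct_noise_sd = 0, seed = 1)
  rp <- qpcr_report(exact, reference_id = "PPIA", case = "case", control = "control")
  expect_equal(rp$fold_change[rp$target_id == "A"], 1)
  expect_equal(rp$fold_change[rp$target_id == "B"], 2)
  expect_error(generate_qpcr_plate(c(A = -1), seed = 1), class = "cernascreen_error_domain")

  est <- vapply(1:200, function(s) {
    plate <- generate_qpcr_plate(c(T1 = 0.5), n_per_group = 6, ct_noise_sd = 0.2, seed = s)
    qpcr_report(plate, reference_id = "PPIA", case = "case", control = "control")$fold_change
  }, 1)
  expect_lt(abs(mean(est) - 0.5) / 0.5, 0.1)
})

test_that("sub-seed derivation separates stages and stays in integer range", {
  expect_identical(sub_seed(7, "cohort", 1), sub_seed(7, "cohort", 1))
  expect_false(sub_seed(7, "cohort", 1) == sub_seed(7, "qpcr", 1))
  expect_false(sub_seed(7, "cohort", 1) == sub_seed(7, "cohort", 2))
  big <- sub_seed(2^30, "interactions", 10^6)
  expect_true(is.integer(big) && big > 0)
})
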
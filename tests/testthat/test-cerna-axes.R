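mir_dataset <- function(n = 100, seed = 70) {
  set.seed(seed)
  lnc <- rnorm(n)
  m <- rbind(
    LNC1 = lnc,
    MIR_ANTI = -lnc + rnorm(n, sd = 0.3),
    MIR_SAME = lnc,
    MIR_IND = rnorm(n)
  )
  colnames(m) <- sprintf("S%03d", seq_len(n))
  make_dataset(m, biotypes = tibble::tibble(
    feature_id = rownames(m),
    biotype = c("lncRNA", "miRNA", "miRNA", "miRNA")
  ))
}

test_that("negative-miRNA selection keeps anti-correlated, never positive, miRNAs", {
  rec <- select_negative_mirnas("LNC1", mir_dataset())
  expect_true("MIR_ANTI" %in% rec$mirna_id)
  expect_false("MIR_SAME" %in% rec$mirna_id)
  expect_true(all(rec$r < 0))
  expect_error(
    select_negative_mirnas("NOT_THERE", mir_dataset()),
    class = "cernascreen_error_lookup"
  )
})

test_that("independent miRNAs pass the negative screen at about alpha/2", {
  set.seed(71)
  n_sel <- 0L
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    x <- rnorm(100)
    y <- rnorm(100)
    ct <- cor.test(x, y)
    if (ct$estimate < 0 && ct$p.value <= 0.05) n_sel <- n_sel + 1L
  }
  # one-sided half of alpha = 0.05: expect ~10/400
  expect_gt(n_sel / n_rep, 0.005)
  expect_lt(n_sel / n_rep, 0.06)
  # and the package selector on a null dataset agrees with the sign rule
  rec <- select_negative_mirnas("LNC1", mir_dataset(seed = 72), alpha = 0.5)
  expect_true(all(rec$r < 0))
})

test_that("evidence merge is a union with per-channel flags", {
  corr <- select_negative_mirnas("LNC1", mir_dataset())
  binding <- interaction_table(
    tibble::tibble(
      lncrna_id = "LNC1", mirna_id = c("MIR_ANTI", "MIR_BIND_ONLY"),
      source_db = "DB"
    ),
    "lncrna_mirna_binding"
  )
  merged <- merge_mirna_evidence(corr, binding, "LNC1")
  both <- merged[merged$mirna_id == "MIR_ANTI", ]
  expect_true(both$correlation_selected && both$binding_predicted)
  only_bind <- merged[merged$mirna_id == "MIR_BIND_ONLY", ]
  expect_true(only_bind$binding_predicted)
  expect_false(only_bind$correlation_selected)
  expect_true(is.na(only_bind$r_lnc_mirna))

  empty_bind <- interaction_table(
    tibble::tibble(lncrna_id = character(), mirna_id = character(), source_db = character()),
    "lncrna_mirna_binding"
  )
  expect_setequal(merge_mirna_evidence(corr, empty_bind, "LNC1")$mirna_id, corr$mirna_id)
})

test_that("target expansion deduplicates and drops target-less miRNAs", {
  mirnas <- tibble::tibble(mirna_id = c("miR-1", "miR-2"))
  targets <- interaction_table(tibble::tibble(
    mirna_id = c("miR-1", "miR-1", "miR-1"),
    mrna_id = c("GA", "GA", "GB"),
    source_db = c("DB1", "DB2", "DB1")
  ), "mirna_mrna_validated")
  expect_message(res <- expand_validated_targets(mirnas, targets), regexp = "miR-2")
  expect_setequal(res$mrna_id[res$mirna_id == "miR-1"], c("GA", "GB"))
  expect_identical(attr(res, "excluded"), "miR-2")
  empty <- expand_validated_targets(tibble::tibble(mirna_id = character()), targets)
  expect_equal(nrow(empty), 0)
})

test_that("the oncomiR filter matches disease rows and reports all directions", {
  cancer <- interaction_table(tibble::tibble(
    mirna_id = c("miR-30a-5p", "miR-x", "miR-dual", "miR-dual"),
    disease = c("CRC", "Glioma", "CRC", "crc"),
    direction = c("Downregulated", "Upregulated", "Upregulated", "Downregulated"),
    source_db = c("mirCancer", "mirCancer", "mirCancer", "mir2Disease")
  ), "mirna_cancer")
  mirnas <- tibble::tibble(mirna_id = c("miR-30a-5p", "miR-x", "miR-dual"))
  res <- filter_oncomirs(mirnas, cancer, "CRC")
  expect_setequal(res$mirna_id, c("miR-30a-5p", "miR-dual"))
  expect_equal(res$mirna_cancer_direction[res$mirna_id == "miR-30a-5p"], "Downregulated")
  expect_equal(
    res$mirna_cancer_direction[res$mirna_id == "miR-dual"],
    "Downregulated/Upregulated"
  )
})

published_axis_inputs <- function() {
  t4 <- table4_axes()
  targets <- t4 |> dplyr::distinct(mirna_id, mrna_id)
  mirnas <- targets |>
    dplyr::mutate(r_lnc_mirna = -0.2, p_lnc_mirna = 1e-4)
  lnc_mrna <- t4 |>
    dplyr::distinct(mrna_id, .keep_all = TRUE) |>
    dplyr::transmute(mrna_id, r = r_lnc_mrna, p = dplyr::coalesce(p_lnc_mrna, 1e-6))
  mir_mrna <- t4 |> dplyr::select("mirna_id", "mrna_id", r = "r_mirna_mrna", p = "p_mirna_mrna")
  list(mirnas = mirnas, lnc_mrna = lnc_mrna, mir_mrna = mir_mrna)
}

test_that("published axis rows assemble with the expected strict_pass flags", {
  inp <- published_axis_inputs()
  ax <- assemble_axes("LINC00483", inp$mirnas, inp$lnc_mrna, inp$mir_mrna)
  dsp <- ax[ax$mirna_id == "miR-30a-5p" & ax$mrna_id == "DSP", ]
  expect_equal(nrow(dsp), 1)
  expect_true(dsp$strict_pass)
  expect_equal(dsp$r_mirna_mrna, -0.11)
  expect_equal(dsp$r_lnc_mrna, 0.406)

  cd9 <- ax[ax$mirna_id == "miR-544a" & ax$mrna_id == "CD9", ]
  expect_equal(nrow(cd9), 1)
  expect_false(cd9$strict_pass)
  strict <- assemble_axes("LINC00483", inp$mirnas, inp$lnc_mrna, inp$mir_mrna, strict = TRUE)
  expect_false(any(strict$mirna_id == "miR-544a" & strict$mrna_id == "CD9"))
  # ranked by descending lncRNA-mRNA coefficient
  expect_false(is.unsorted(rev(ax$r_lnc_mrna)))
})

test_that("axes obey the sign constraints and strict output nests in lenient", {
  inp <- published_axis_inputs()
  lenient <- assemble_axes("LINC00483", inp$mirnas, inp$lnc_mrna, inp$mir_mrna)
  strict <- assemble_axes("LINC00483", inp$mirnas, inp$lnc_mrna, inp$mir_mrna, strict = TRUE)
  expect_true(all(lenient$r_lnc_mrna > 0))
  expect_false(any(lenient$strict_pass & lenient$r_mirna_mrna >= 0))
  key <- function(d) paste(d$mirna_id, d$mrna_id)
  expect_true(all(key(strict) %in% key(lenient)))
})

test_that("mRNAs outside the target sets and pairs without correlations yield no axis", {
  inp <- published_axis_inputs()
  extra_lm <- dplyr::bind_rows(
    inp$lnc_mrna,
    tibble::tibble(mrna_id = "NOT_A_TARGET", r = 0.9, p = 1e-20)
  )
  ax <- assemble_axes("LINC00483", inp$mirnas, extra_lm, inp$mir_mrna)
  expect_false("NOT_A_TARGET" %in% ax$mrna_id)

  mm_missing <- inp$mir_mrna[-1, ] # drop the miR-30a-5p/DSP record
  expect_message(
    ax2 <- assemble_axes("LINC00483", inp$mirnas, inp$lnc_mrna, mm_missing),
    regexp = "skipped"
  )
  expect_false(any(ax2$mirna_id == "miR-30a-5p" & ax2$mrna_id == "DSP"))
})
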
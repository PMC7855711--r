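test_that("a feature identical in both groups is never called", {
  m <- rand_matrix(5, 20, seed = 10)
  m[1, ] <- 3 # constant: excluded as degenerate
  m[2, ] <- rep(c(1, 2), 10) # same values in both groups
  expect_message(
    res <- differential_by_contrast(make_dataset(m), severity_contrast(), alpha = 0.05),
    regexp = "constant"
  )
  expect_false(any(c("G01", "G02") %in% res$feature_id))
})

test_that("a planted 3-SD shift is recovered with F equal to t-squared", {
  set.seed(20)
  n <- 20
  m <- rand_matrix(10, 2 * n)
  sev <- rep(c("severe", "mild"), each = n)
  m[4, sev == "severe"] <- m[4, sev == "severe"] + 3
  m[7, sev == "mild"] <- m[7, sev == "mild"] + 3
  ds <- make_dataset(m, severity = sev)
  res <- differential_by_contrast(ds, severity_contrast(), alpha = 0.01)
  expect_true(all(c("G04", "G07") %in% res$feature_id))
  expect_equal(res$direction[res$feature_id == "G04"], "up_in_severe")
  expect_equal(res$direction[res$feature_id == "G07"], "down_in_severe")

  tt <- t.test(m[4, sev == "severe"], m[4, sev == "mild"], var.equal = TRUE)
  expect_equal(res$statistic[res$feature_id == "G04"], unname(tt$statistic)^2,
    tolerance = 1e-9
  )
  expect_equal(res$p[res$feature_id == "G04"], tt$p.value, tolerance = 1e-9)
  orc <- oracle_anova_f(m[4, sev == "severe"], m[4, sev == "mild"])
  expect_equal(res$statistic[res$feature_id == "G04"], orc$f, tolerance = 1e-9)
})

test_that("null features are called at about the nominal rate, near zero after FDR", {
  set.seed(30)
  m <- rand_matrix(1000, 40, prefix = "N")
  ds <- make_dataset(m, severity = sample(rep(c("severe", "mild"), 20)))
  raw <- differential_by_contrast(ds, severity_contrast(), alpha = 0.01, use_fdr = FALSE)
  expect_lte(nrow(raw) / 1000, 0.025)
  adj <- differential_by_contrast(ds, severity_contrast(), alpha = 0.01, use_fdr = TRUE)
  expect_lte(nrow(adj), 2)
})

test_that("a group with fewer than 2 samples skips the contrast with a warning", {
  m <- rand_matrix(4, 5, seed = 40)
  ds <- make_dataset(m, severity = c("severe", rep("mild", 4)))
  expect_warning(
    res <- differential_by_contrast(ds, severity_contrast()),
    regexp = "fewer than 2"
  )
  expect_equal(nrow(res), 0)
})

test_that("consensus voting applies the support-fraction rule and conflict exclusion", {
  call_row <- function(ds, gene, dir) {
    tibble::tibble(
      dataset_id = ds, feature_id = gene, contrast_label = "c",
      statistic = 10, p = 1e-4, q = 1e-3, direction = dir
    )
  }
  calls <- dplyr::bind_rows(
    call_row(c("D1", "D2", "D3"), "GDOWN", "down_in_severe"),
    call_row(c("D1", "D2"), "GBOTH", "up_in_severe"),
    call_row(c("D3", "D4"), "GBOTH", "down_in_severe"),
    call_row("D1", "GWEAK", "up_in_severe")
  )
  expect_warning(res <- consensus_genes(calls, 4), regexp = "GBOTH")
  expect_equal(res$feature_id, "GDOWN")
  expect_equal(res$support_fraction, 0.75)
  expect_equal(res$supporting_datasets, "D1,D2,D3")
  expect_identical(attr(res, "conflicts"), "GBOTH")
  expect_false("GWEAK" %in% res$feature_id)
})

test_that("consensus is order-invariant and monotone in min_fraction", {
  set.seed(50)
  calls <- tibble::tibble(
    dataset_id = sample(sprintf("D%d", 1:6), 40, replace = TRUE),
    feature_id = sample(sprintf("G%d", 1:8), 40, replace = TRUE),
    contrast_label = "c", statistic = 5, p = 1e-3, q = 1e-2,
    direction = sample(c("up_in_severe", "down_in_severe"), 40, replace = TRUE)
  )
  a <- suppressWarnings(consensus_genes(calls, 6))
  b <- suppressWarnings(consensus_genes(calls[sample(nrow(calls)), ], 6))
  expect_equal(as.data.frame(a), as.data.frame(b))
  for (f in c(0.5, 0.7, 0.9)) {
    lo <- suppressWarnings(consensus_genes(calls, 6, min_fraction = f))
    hi <- suppressWarnings(consensus_genes(calls, 6, min_fraction = f + 0.1))
    expect_true(all(paste(hi$feature_id, hi$direction) %in% paste(lo$feature_id, lo$direction)))
  }
})

test_that("empty call sets give empty lists, not errors", {
  res <- consensus_genes(NULL, 4)
  expect_equal(nrow(res), 0)
})
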
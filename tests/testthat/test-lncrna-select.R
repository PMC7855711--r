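lnc_bait_dataset <- function(seed = 60, n = 50) {
  set.seed(seed)
  m <- rbind(
    BAIT1 = rnorm(n), BAIT2 = rnorm(n),
    LNC_COPY = 0, LNC_NOISE = rnorm(n)
  )
  m["LNC_COPY", ] <- m["BAIT1", ]
  colnames(m) <- sprintf("S%02d", seq_len(n))
  make_dataset(m, biotypes = tibble::tibble(
    feature_id = rownames(m),
    biotype = c("mRNA", "mRNA", "lncRNA", "lncRNA")
  ))
}

baits_tbl <- function() {
  suppressWarnings(consensus_genes(tibble::tibble(
    dataset_id = "D1", feature_id = c("BAIT1", "BAIT2"), contrast_label = "c",
    statistic = 9, p = 1e-4, q = 1e-3,
    direction = c("down_in_severe", "up_in_severe")
  ), 1))
}

test_that("an lncRNA identical to a bait is retained with r = 1", {
  rec <- correlate_lncrnas(lnc_bait_dataset(), baits_tbl())
  hit <- rec[rec$lncrna_id == "LNC_COPY" & rec$bait_id == "BAIT1", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$r, 1)
  expect_equal(hit$sign, "positive")
})

test_that("independent lncRNAs are rarely retained at alpha 0.01", {
  set.seed(61)
  hits <- 0L
  for (i in 1:40) {
    ds <- lnc_bait_dataset(seed = 1000 + i)
    rec <- correlate_lncrnas(ds, baits_tbl())
    hits <- hits + sum(rec$lncrna_id == "LNC_NOISE")
  }
  # 40 replicates x 2 baits at alpha = 0.01 -> expect ~0.8 false hits
  expect_lte(hits, 5)
})

test_that("correlation records equal the brute-force pairwise oracle", {
  set.seed(62)
  ds <- lnc_bait_dataset(seed = 62, n = 10)
  rec <- correlate_lncrnas(ds, baits_tbl(), alpha = 1)
  for (i in seq_len(nrow(rec))) {
    orc <- oracle_pearson(ds$values[rec$lncrna_id[i], ], ds$values[rec$bait_id[i], ])
    expect_equal(rec$r[i], orc$r, tolerance = 1e-10)
    expect_equal(rec$p[i], orc$p, tolerance = 1e-10)
  }
})

test_that("per-sign voting assigns retained triples to the right lists", {
  mk <- function(ds, lnc, bait, sign) {
    tibble::tibble(
      dataset_id = ds, lncrna_id = lnc, bait_id = bait,
      r = ifelse(sign == "positive", 0.6, -0.6), p = 1e-4, n = 50, sign = sign
    )
  }
  records <- dplyr::bind_rows(
    mk(sprintf("D%d", 1:6), "LNC_A", "BAIT1", "positive"), # 6/10 with down-bait -> A
    mk(sprintf("D%d", 1:4), "LNC_MIX", "BAIT1", "positive"), # 4/10 -> dropped
    mk(sprintf("D%d", 5:10), "LNC_MIX", "BAIT1", "negative"), # 6/10 -> C
    mk(sprintf("D%d", 1:5), "LNC_D", "BAIT2", "negative") # 5/10 with up-bait -> D
  )
  lists <- vote_and_build_lists(records, baits_tbl(), 10)
  expect_equal(cernascreen:::list_members(lists, "A"), "LNC_A")
  expect_equal(cernascreen:::list_members(lists, "C"), "LNC_MIX")
  expect_equal(cernascreen:::list_members(lists, "D"), "LNC_D")
  expect_length(cernascreen:::list_members(lists, "B"), 0)
  detail <- attr(lists, "detail")
  expect_false(any(detail$lncrna_id == "LNC_MIX" & detail$sign == "positive"))
})

test_that("candidate classification applies the intersection algebra", {
  lists <- four_lists(
    A = c("TS1", "TS2", "X1"), D = c("TS1", "TS2", "X2"),
    B = c("ONC1", "TS1"), C = c("ONC1", "TS1")
  )
  res <- classify_candidates(lists)
  expect_equal(res$role[res$lncrna_id == "TS2"], "tumor_suppressor")
  expect_equal(res$role[res$lncrna_id == "ONC1"], "oncogene")
  expect_equal(res$role[res$lncrna_id == "TS1"], "conflict")
  expect_false(any(c("X1", "X2") %in% res$lncrna_id))
  # disjoint roles, idempotent under input ordering
  expect_equal(
    classify_candidates(four_lists(
      A = rev(c("TS1", "TS2", "X1")), D = c("TS2", "X2", "TS1"),
      B = c("TS1", "ONC1"), C = c("TS1", "ONC1")
    )),
    res
  )
  expect_equal(nrow(classify_candidates(four_lists())), 0)
})
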
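cs_extdata <- function(file) {
  path <- system.file("extdata", file, package = "cernascreen")
  if (!nzchar(path)) stop_cs(paste0("packaged fixture not found: ", file), "io")
  path
}

#' Packaged published-table fixtures
#'
#' The package ships, as plain TSV fixtures, the published colorectal-cancer
#' screening tables it can be checked against: the four signed lncRNA lists
#' (`table2_lists()`), the candidate lncRNAs the source study reported from
#' them (`table2_reported()`), the consensus bait-gene lists
#' (`bait_genes_reported()`), the published lncRNA-miRNA-mRNA axis rows
#' with their correlations (`table4_axes()`; one truncated p-value cell is
#' carried as `NA` with a note, never repaired), and the miRNA screen
#' result (`mirna_screen_fixture()`): the merged miRNA set together with a
#' validated-target table derived from the published axis rows, in which
#' four miRNAs deliberately have no target rows.
#'
#' @return `table2_lists()`: a [four_lists()] object. `table2_reported()`,
#'   `bait_genes_reported()`, `table4_axes()`: tibbles.
#'   `mirna_screen_fixture()`: list with `mirnas` (tibble) and `targets`
#'   (an [interaction_table()]).
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
table2_lists <- function() {
  tab <- readr::read_tsv(cs_extdata("table2_lncrna_lists.tsv"),
    col_types = "cc", progress = FALSE
  )
  four_lists(
    A = tab$lncrna_id[tab$list == "A"], B = tab$lncrna_id[tab$list == "B"],
    C = tab$lncrna_id[tab$list == "C"], D = tab$lncrna_id[tab$list == "D"]
  )
}

#' @rdname fixtures
#' @export
table2_reported <- function() {
  readr::read_tsv(cs_extdata("table2_reported_candidates.tsv"),
    col_types = "cc", progress = FALSE
  )
}

#' @rdname fixtures
#' @export
bait_genes_reported <- function() {
  readr::read_tsv(cs_extdata("bait_genes_reported.tsv"),
    col_types = "cc", progress = FALSE
  )
}

#' @rdname fixtures
#' @export
table4_axes <- function() {
  readr::read_tsv(cs_extdata("table4_axes.tsv"),
    col_types = readr::cols(
      mirna_id = "c", mirna_cancer_direction = "c", mrna_id = "c",
      r_mirna_mrna = "d", p_mirna_mrna = "d",
      r_lnc_mrna = "d", p_lnc_mrna = "d", note = "c"
    ), progress = FALSE
  )
}

#' @rdname fixtures
#' @export
mirna_screen_fixture <- function() {
  mirnas <- readr::read_tsv(cs_extdata("mirna_screen_set.tsv"),
    col_types = "c", progress = FALSE
  )
  targets <- read_interaction_table(
    cs_extdata("mirna_targets_table4.tsv"), "mirna_mrna_validated"
  )
  list(mirnas = mirnas, targets = targets)
}

#' Synthetic per-dataset bait-call fixture
#'
#' A synthetic table of per-dataset differential calls over 12 datasets,
#' constructed so that consensus voting at the default 50% threshold
#' returns exactly the published up- and down-regulated bait-gene lists:
#' the published genes are supported by 8 of 12 datasets, four decoy genes
#' by only 5, and one gene splits 6/6 between directions to exercise the
#' conflict rule.
#'
#' @return A tibble of differential calls (see
#'   [differential_by_contrast()]).
#' @export
bait_calls_fixture <- function() {
  readr::read_tsv(cs_extdata("bait_calls_fixture.tsv"),
    col_types = readr::cols(
      dataset_id = "c", feature_id = "c", contrast_label = "c",
      statistic = "d", p = "d", q = "d", direction = "c"
    ), progress = FALSE
  )
}

#' Classify the packaged published four-list fixture
#'
#' Loads the packaged four signed lncRNA lists, applies
#' [classify_candidates()] and annotates each call with whether the source
#' study also reported it (`reported`). The full B-and-C intersection is
#' returned even where the study's stated candidate set was smaller, so
#' such editorial exclusions are visible rather than silently mirrored.
#'
#' @return Tibble with columns `lncrna_id`, `role`, `source_lists`,
#'   `reported`.
#' @examples
#' \dontrun{
#' run_table2_fixture()
#' }
#' @export
run_table2_fixture <- function() {
  calls <- classify_candidates(table2_lists())
  reported <- table2_reported()
  calls |>
    mutate(reported = paste(.data$lncrna_id, .data$role) %in%
      paste(reported$lncrna_id, reported$role))
}
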
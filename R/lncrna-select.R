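#' Correlate every lncRNA with every bait gene in one dataset
#'
#' Computes the Pearson coefficient (pairwise-complete, p from the
#' t-transform) for every (lncRNA, bait) pair measured in the dataset and
#' keeps the pairs with `p < alpha`.
#'
#' @param dataset An [expression_dataset()].
#' @param baits A [consensus_genes()] tibble (or any tibble with
#'   `feature_id`).
#' @param alpha Significance cutoff, default `0.01` (strict `<`).
#' @return Tibble with columns `dataset_id`, `lncrna_id`, `bait_id`, `r`,
#'   `p`, `n`, `sign` (`"positive"` / `"negative"`).
#' @export
correlate_lncrnas <- function(dataset, baits, alpha = 0.01) {
  stopifnot(inherits(dataset, "expression_dataset"))
  lnc <- intersect(features_of_biotype(dataset, "lncRNA"), rownames(dataset$values))
  bait_ids <- intersect(unique(baits$feature_id), rownames(dataset$values))
  empty <- tibble(
    dataset_id = character(), lncrna_id = character(), bait_id = character(),
    r = double(), p = double(), n = double(), sign = character()
  )
  if (!length(lnc)) {
    warn(paste0(dataset$dataset_id, ": no lncRNA features; empty correlation screen"))
    return(empty)
  }
  if (!length(bait_ids)) {
    return(empty)
  }
  rec <- cor_screen(dataset$values, lnc, bait_ids)
  rec <- rec[rec$p < alpha & rec$r != 0, , drop = FALSE]
  tibble(
    dataset_id = dataset$dataset_id,
    lncrna_id = rec$feature_a,
    bait_id = rec$feature_b,
    r = rec$r, p = rec$p, n = as.double(rec$n),
    sign = if_else(rec$r > 0, "positive", "negative")
  )
}

#' Vote lncRNA-bait associations across datasets and build the four lists
#'
#' A (lncRNA, bait, sign) triple is retained when it is significant with
#' that sign in at least `min_fraction` of the consulted datasets. Retained
#' triples are assigned to the four signed lists by correlation sign x bait
#' direction: positive/down-bait -> A, positive/up-bait -> B,
#' negative/down-bait -> C, negative/up-bait -> D.
#'
#' @param records Bound rows from [correlate_lncrnas()] over all datasets.
#' @param baits The [consensus_genes()] result giving each bait's direction.
#' @param n_datasets_consulted Denominator of the support fraction.
#' @param min_fraction Support threshold, default `0.5`.
#' @return An object of class `four_lists`: a tibble with one row per
#'   retained (lncrna_id, list) membership (`list` in `A`-`D`), plus the
#'   supporting baits and fractions; the per-triple detail is attached as
#'   attribute `"detail"`.
#' @export
vote_and_build_lists <- function(records, baits, n_datasets_consulted, min_fraction = 0.5) {
  stopifnot(n_datasets_consulted >= 1)
  dirs <- tibble(bait_id = baits$feature_id, bait_direction = baits$direction)
  empty <- tibble(
    lncrna_id = character(), list = character(),
    bait_id = character(), sign = character(),
    support_fraction = double(), supporting_datasets = character()
  )
  if (is.null(records) || nrow(records) == 0) {
    detail <- empty
  } else {
    detail <- records |>
      distinct(.data$lncrna_id, .data$bait_id, .data$sign, .data$dataset_id) |>
      group_by(.data$lncrna_id, .data$bait_id, .data$sign) |>
      summarise(
        n_support = n_distinct(.data$dataset_id),
        supporting_datasets = paste(sort(unique(.data$dataset_id)), collapse = ","),
        .groups = "drop"
      ) |>
      filter(frac_ge(.data$n_support, n_datasets_consulted, min_fraction)) |>
      mutate(support_fraction = .data$n_support / n_datasets_consulted) |>
      inner_join(dirs, by = "bait_id") |>
      mutate(list = dplyr::case_when(
        .data$sign == "positive" & .data$bait_direction == "down" ~ "A",
        .data$sign == "positive" & .data$bait_direction == "up" ~ "B",
        .data$sign == "negative" & .data$bait_direction == "down" ~ "C",
        .data$sign == "negative" & .data$bait_direction == "up" ~ "D"
      )) |>
      select(
        "lncrna_id", "list", "bait_id", "sign",
        "support_fraction", "supporting_datasets"
      ) |>
      arrange(.data$list, .data$lncrna_id, .data$bait_id)
  }
  memb <- distinct(detail, .data$lncrna_id, .data$list)
  structure(
    memb,
    detail = detail,
    min_fraction = min_fraction,
    class = c("four_lists", class(memb))
  )
}

#' Build a `four_lists` object directly from membership sets
#'
#' Used for printed or externally supplied lists, e.g. published tables of
#' lncRNAs correlated with bait genes.
#'
#' @param A,B,C,D Character vectors: lncRNAs positively correlated with
#'   down-baits (A), positively with up-baits (B), negatively with
#'   down-baits (C), negatively with up-baits (D).
#' @return A `four_lists` object.
#' @examples
#' four_lists(A = c("L1", "L2"), B = "L3", C = "L3", D = "L1")
#' @export
four_lists <- function(A = character(), B = character(), C = character(), D = character()) {
  memb <- bind_rows(
    tibble(lncrna_id = unique(as.character(A)), list = "A"),
    tibble(lncrna_id = unique(as.character(B)), list = "B"),
    tibble(lncrna_id = unique(as.character(C)), list = "C"),
    tibble(lncrna_id = unique(as.character(D)), list = "D")
  )
  structure(memb, detail = memb, class = c("four_lists", class(memb)))
}

#' @export
print.four_lists <- function(x, ...) {
  sizes <- table(factor(x$list, levels = c("A", "B", "C", "D")))
  cat(
    "<four_lists> A:", sizes[["A"]], " B:", sizes[["B"]],
    " C:", sizes[["C"]], " D:", sizes[["D"]], "\n"
  )
  NextMethod()
}

list_members <- function(lists, which) {
  sort(unique(lists$lncrna_id[lists$list == which]))
}

#' Classify candidate lncRNAs from the four signed lists
#'
#' Set algebra over the four lists: lncRNAs in both A and D are
#' tumor-suppressor candidates; lncRNAs in both B and C are oncogene
#' candidates; an lncRNA qualifying for both intersections is reported as
#' `conflict` and removed from both candidate sets. Deterministic and
#' order-independent; output sorted lexicographically.
#'
#' @param lists A `four_lists` object (from [vote_and_build_lists()] or
#'   [four_lists()]).
#' @return Tibble with columns `lncrna_id`, `role`
#'   (`"tumor_suppressor"` / `"oncogene"` / `"conflict"`), `source_lists`.
#' @examples
#' classify_candidates(four_lists(A = "L1", D = "L1"))
#' @export
classify_candidates <- function(lists) {
  stopifnot(inherits(lists, "four_lists"))
  ts <- intersect(list_members(lists, "A"), list_members(lists, "D"))
  onc <- intersect(list_members(lists, "B"), list_members(lists, "C"))
  confl <- intersect(ts, onc)
  out <- bind_rows(
    tibble(lncrna_id = setdiff(ts, confl), role = "tumor_suppressor", source_lists = "A,D"),
    tibble(lncrna_id = setdiff(onc, confl), role = "oncogene", source_lists = "B,C"),
    tibble(lncrna_id = confl, role = "conflict", source_lists = "A,B,C,D")
  )
  arrange(out, .data$lncrna_id)
}
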
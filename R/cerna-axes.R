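#' Read an interaction evidence table
#'
#' Three kinds of TSV evidence tables are consumed: lncRNA-miRNA binding
#' predictions (`lncrna_id, mirna_id, source_db`), validated miRNA-mRNA
#' targets (`mirna_id, mrna_id, source_db`) and miRNA-cancer dysregulation
#' annotations (`mirna_id, disease, direction, source_db`). Duplicate rows
#' (same pair and source) are dropped.
#'
#' @param path TSV file path.
#' @param kind One of `"lncrna_mirna_binding"`, `"mirna_mrna_validated"`,
#'   `"mirna_cancer"`.
#' @return A tibble with attribute `"kind"`.
#' @export
read_interaction_table <- function(path, kind = c(
                                     "lncrna_mirna_binding",
                                     "mirna_mrna_validated", "mirna_cancer"
                                   )) {
  kind <- match.arg(kind)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE)
  interaction_table(tab, kind)
}

#' @rdname read_interaction_table
#' @param tab A data frame with the columns of the given kind.
#' @export
interaction_table <- function(tab, kind = c(
                                "lncrna_mirna_binding",
                                "mirna_mrna_validated", "mirna_cancer"
                              )) {
  kind <- match.arg(kind)
  need <- switch(kind,
    lncrna_mirna_binding = c("lncrna_id", "mirna_id", "source_db"),
    mirna_mrna_validated = c("mirna_id", "mrna_id", "source_db"),
    mirna_cancer = c("mirna_id", "disease", "direction", "source_db")
  )
  tab <- as_tibble(tab)
  if (!all(need %in% names(tab))) {
    stop_cs(
      paste0(kind, " table needs columns: ", paste(need, collapse = ", ")),
      "validation"
    )
  }
  if (any(!nzchar(unlist(tab[need[1:2]])) | is.na(unlist(tab[need[1:2]])))) {
    stop_cs("interaction identifiers must be non-empty", "validation")
  }
  out <- distinct(tab[need])
  attr(out, "kind") <- kind
  out
}

# case-insensitive, trimmed identifier key (no alias resolution)
id_key <- function(x) tolower(trimws(x))

#' Select miRNAs negatively correlated with a lncRNA
#'
#' Correlates the lncRNA with every miRNA-biotype feature of the dataset
#' and keeps miRNAs with negative coefficient and `p <= alpha`.
#'
#' @param lnc_id Feature id of the lncRNA (must be measured).
#' @param dataset An [expression_dataset()] containing miRNA features.
#' @param alpha Significance cutoff, default `0.001`.
#' @return Tibble with columns `dataset_id`, `lncrna_id`, `mirna_id`, `r`,
#'   `p`, `n`.
#' @export
select_negative_mirnas <- function(lnc_id, dataset, alpha = 0.001) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!lnc_id %in% rownames(dataset$values)) {
    stop_cs(paste0("`", lnc_id, "` is not measured in ", dataset$dataset_id), "lookup")
  }
  mir <- setdiff(intersect(features_of_biotype(dataset, "miRNA"), rownames(dataset$values)), lnc_id)
  if (!length(mir)) {
    return(tibble(
      dataset_id = character(), lncrna_id = character(), mirna_id = character(),
      r = double(), p = double(), n = double()
    ))
  }
  rec <- cor_screen(dataset$values, lnc_id, mir)
  rec <- rec[rec$r < 0 & rec$p <= alpha, , drop = FALSE]
  tibble(
    dataset_id = dataset$dataset_id, lncrna_id = lnc_id,
    mirna_id = rec$feature_b, r = rec$r, p = rec$p, n = as.double(rec$n)
  )
}

#' Merge correlation-selected and binding-predicted miRNAs
#'
#' Takes the union of miRNAs selected by negative correlation with the
#' lncRNA and miRNAs with predicted binding sites on it, flagging which
#' evidence channel(s) supplied each one. Correlation statistics are kept
#' where available.
#'
#' @param correlation_hits Output of [select_negative_mirnas()].
#' @param binding_table An [interaction_table()] of kind
#'   `"lncrna_mirna_binding"`.
#' @param lnc_id The lncRNA whose binding rows are relevant.
#' @return Tibble with columns `mirna_id`, `correlation_selected`,
#'   `binding_predicted`, `r_lnc_mirna`, `p_lnc_mirna`.
#' @export
merge_mirna_evidence <- function(correlation_hits, binding_table, lnc_id) {
  if (!identical(attr(binding_table, "kind"), "lncrna_mirna_binding")) {
    stop_cs("binding_table must have kind `lncrna_mirna_binding`", "validation")
  }
  bind_mirnas <- unique(binding_table$mirna_id[id_key(binding_table$lncrna_id) == id_key(lnc_id)])
  corr <- correlation_hits |>
    group_by(.data$mirna_id) |>
    summarise(r_lnc_mirna = .data$r[which.min(.data$p)], p_lnc_mirna = min(.data$p), .groups = "drop")
  all_ids <- union(corr$mirna_id, bind_mirnas)
  out <- tibble(mirna_id = sort(all_ids)) |>
    mutate(
      correlation_selected = id_key(.data$mirna_id) %in% id_key(corr$mirna_id),
      binding_predicted = id_key(.data$mirna_id) %in% id_key(bind_mirnas)
    ) |>
    left_join(corr, by = "mirna_id")
  out
}

#' Expand miRNAs to their validated mRNA targets
#'
#' Looks each miRNA up in a validated-target table and returns the distinct
#' (miRNA, mRNA) pairs. miRNAs with no target row are dropped and reported
#' (attribute `"excluded"` and a message), mirroring the rule that a
#' target-less miRNA cannot anchor an axis.
#'
#' @param mirnas Tibble with a `mirna_id` column (e.g. from
#'   [merge_mirna_evidence()]).
#' @param targets_table An [interaction_table()] of kind
#'   `"mirna_mrna_validated"`.
#' @return Tibble of distinct pairs `mirna_id`, `mrna_id`, carrying the
#'   evidence columns of `mirnas`; excluded miRNA ids in attribute
#'   `"excluded"`.
#' @export
expand_validated_targets <- function(mirnas, targets_table) {
  if (!identical(attr(targets_table, "kind"), "mirna_mrna_validated")) {
    stop_cs("targets_table must have kind `mirna_mrna_validated`", "validation")
  }
  tt <- distinct(tibble(
    mirna_key = id_key(targets_table$mirna_id),
    mrna_id = targets_table$mrna_id
  ))
  out <- mirnas |>
    mutate(mirna_key = id_key(.data$mirna_id)) |>
    inner_join(tt, by = "mirna_key", relationship = "many-to-many") |>
    select(-"mirna_key") |>
    distinct() |>
    relocate("mirna_id", "mrna_id")
  excluded <- sort(setdiff(mirnas$mirna_id, out$mirna_id))
  if (length(excluded)) {
    inform(paste0(
      "miRNA(s) without validated targets excluded: ",
      paste(excluded, collapse = ", ")
    ))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Keep only miRNAs with documented involvement in a disease
#'
#' Filters a miRNA set to those having at least one row for the given
#' disease in a miRNA-cancer annotation table, attaching the recorded
#' dysregulation direction(s). Conflicting directions from different
#' sources are all reported (slash-joined), never resolved by guessing.
#'
#' @param mirnas Tibble with a `mirna_id` column.
#' @param cancer_table An [interaction_table()] of kind `"mirna_cancer"`.
#' @param disease Disease label, matched case-insensitively.
#' @return The rows of `mirnas` for annotated miRNAs, with an added
#'   `mirna_cancer_direction` column.
#' @export
filter_oncomirs <- function(mirnas, cancer_table, disease) {
  if (!identical(attr(cancer_table, "kind"), "mirna_cancer")) {
    stop_cs("cancer_table must have kind `mirna_cancer`", "validation")
  }
  ann <- cancer_table |>
    filter(id_key(.data$disease) == id_key(.env$disease)) |>
    group_by(mirna_key = id_key(.data$mirna_id)) |>
    summarise(
      mirna_cancer_direction = paste(sort(unique(.data$direction)), collapse = "/"),
      .groups = "drop"
    )
  mirnas |>
    mutate(mirna_key = id_key(.data$mirna_id)) |>
    inner_join(ann, by = "mirna_key") |>
    select(-"mirna_key")
}

#' Assemble sign-constrained lncRNA-miRNA-mRNA axes
#'
#' Under the miRNA-sponge model the lncRNA and mRNA should be positively
#' correlated while the shared miRNA is negatively correlated with both.
#' One axis is emitted per (miRNA, mRNA) pair such that the mRNA is a
#' validated target of the miRNA and the lncRNA-mRNA correlation is
#' positive and significant. The negative miRNA-mRNA requirement is soft
#' by default: every axis carries a `strict_pass` flag (`TRUE` iff the
#' lncRNA-miRNA correlation is negative-significant and the miRNA-mRNA
#' correlation is negative); `strict = TRUE` keeps only passing axes.
#' Output is ranked by descending lncRNA-mRNA coefficient.
#'
#' @param lnc_id The candidate lncRNA.
#' @param mirna_targets Target pairs from [expand_validated_targets()]
#'   (optionally filtered by [filter_oncomirs()]); carries the per-miRNA
#'   evidence flags and lncRNA-miRNA correlation where available.
#' @param corr_lnc_mrna Correlation records for (lncRNA, mRNA) pairs:
#'   tibble with `mrna_id`, `r`, `p`.
#' @param corr_mirna_mrna Correlation records for (miRNA, mRNA) pairs:
#'   tibble with `mirna_id`, `mrna_id`, `r`, `p`.
#' @param alpha_lnc_mrna Significance cutoff for the positive lncRNA-mRNA
#'   correlation, default `0.01`.
#' @param min_r_lnc_mrna Minimum lncRNA-mRNA coefficient, default `0`
#'   (keep all positive); raise to mirror "highest R-values" filtering.
#' @param top_k_mrnas Optionally keep only the top-k mRNAs per miRNA by
#'   lncRNA-mRNA coefficient (default `Inf`).
#' @param strict If `TRUE`, drop axes failing the negative miRNA-mRNA
#'   check instead of flagging them.
#' @return A tibble of class `cerna_axes`: one row per axis with
#'   `lncrna_id`, `mirna_id`, `mrna_id`, the three correlation/p pairs,
#'   evidence flags, `mirna_cancer_direction` (if present) and
#'   `strict_pass`. Pairs lacking a required miRNA-mRNA correlation record
#'   are skipped with a message, never fabricated.
#' @export
assemble_axes <- function(lnc_id, mirna_targets, corr_lnc_mrna, corr_mirna_mrna,
                          alpha_lnc_mrna = 0.01, min_r_lnc_mrna = 0,
                          top_k_mrnas = Inf, strict = FALSE) {
  lm <- corr_lnc_mrna |>
    select("mrna_id", r_lnc_mrna = "r", p_lnc_mrna = "p") |>
    distinct(.data$mrna_id, .keep_all = TRUE)
  mm <- corr_mirna_mrna |>
    select("mirna_id", "mrna_id", r_mirna_mrna = "r", p_mirna_mrna = "p") |>
    distinct(.data$mirna_id, .data$mrna_id, .keep_all = TRUE)
  ax <- mirna_targets |>
    inner_join(lm, by = "mrna_id") |>
    filter(.data$r_lnc_mrna > 0, .data$r_lnc_mrna >= min_r_lnc_mrna, .data$p_lnc_mrna <= alpha_lnc_mrna)
  withmm <- ax |> left_join(mm, by = c("mirna_id", "mrna_id"))
  skipped <- withmm |> filter(is.na(.data$r_mirna_mrna))
  if (nrow(skipped)) {
    inform(paste0(
      nrow(skipped), " axis candidate(s) skipped for missing miRNA-mRNA correlation: ",
      paste(head(paste(skipped$mirna_id, skipped$mrna_id, sep = "/"), 5), collapse = ", "),
      if (nrow(skipped) > 5) ", ..." else ""
    ))
  }
  out <- withmm |>
    filter(!is.na(.data$r_mirna_mrna)) |>
    mutate(
      lncrna_id = lnc_id,
      target_validated = TRUE,
      strict_pass = !is.na(.data$r_lnc_mirna) & .data$r_lnc_mirna < 0 & .data$r_mirna_mrna < 0
    ) |>
    relocate("lncrna_id")
  if (is.finite(top_k_mrnas)) {
    out <- out |>
      group_by(.data$mirna_id) |>
      arrange(desc(.data$r_lnc_mrna), .by_group = TRUE) |>
      dplyr::slice_head(n = top_k_mrnas) |>
      ungroup()
  }
  if (strict) out <- filter(out, .data$strict_pass)
  out <- arrange(out, desc(.data$r_lnc_mrna), .data$mirna_id, .data$mrna_id)
  class(out) <- c("cerna_axes", class(out))
  out
}

#' Plot assembled ceRNA axes
#'
#' Scatter of each axis's miRNA-mRNA coefficient against its lncRNA-mRNA
#' coefficient, coloured by whether the axis passes the strict
#' negative-correlation check.
#'
#' @param object A `cerna_axes` tibble from [assemble_axes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cerna_axes <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$r_lnc_mrna, y = .data$r_mirna_mrna,
      colour = .data$strict_pass
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "r(lncRNA, mRNA)", y = "r(miRNA, mRNA)",
      title = paste0("ceRNA axes", if (nrow(object)) paste0(" for ", object$lncrna_id[1]) else "")
    )
}
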
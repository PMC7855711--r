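#' Per-dataset differential screen against a severity contrast
#'
#' For every protein-coding (mRNA biotype) feature measured in the dataset,
#' performs a one-way ANOVA between the samples at the contrast's severe
#' levels and those at its mild levels (for two groups the F statistic
#' equals the square of the pooled-variance t statistic). Raw p-values are
#' adjusted across all tested features of this dataset x contrast by
#' [fdr_adjust()], and only features passing the cutoff are returned, with
#' a direction given by the sign of `mean(severe) - mean(mild)`.
#'
#' @param dataset An [expression_dataset()].
#' @param contrast A [contrast_spec()].
#' @param alpha Significance cutoff, default `0.01`.
#' @param use_fdr If `TRUE` (default) the cutoff applies to the adjusted
#'   q-value; if `FALSE`, to the raw p-value.
#' @return A tibble of significant calls with columns `dataset_id`,
#'   `feature_id`, `contrast_label`, `statistic` (F), `p`, `q`,
#'   `direction` (`"up_in_severe"` / `"down_in_severe"`). Zero rows if the
#'   contrast is skipped (a group with fewer than 2 samples raises a
#'   warning) or nothing passes.
#' @export
differential_by_contrast <- function(dataset, contrast, alpha = 0.01, use_fdr = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"), inherits(contrast, "contrast_spec"))
  empty <- tibble(
    dataset_id = character(), feature_id = character(), contrast_label = character(),
    statistic = double(), p = double(), q = double(), direction = character()
  )
  ann <- dataset$sample_annotations
  if (!contrast$clinical_feature %in% names(ann)) {
    warn(paste0(
      dataset$dataset_id, ": clinical feature `", contrast$clinical_feature,
      "` not annotated; contrast skipped"
    ))
    return(empty)
  }
  lev <- ann[[contrast$clinical_feature]]
  severe <- ann$sample_id[lev %in% contrast$severe_levels]
  mild <- ann$sample_id[lev %in% contrast$mild_levels]
  if (length(severe) < 2 || length(mild) < 2) {
    warn(paste0(
      dataset$dataset_id, ": fewer than 2 samples in a group of `",
      contrast$label, "`; contrast skipped"
    ))
    return(empty)
  }
  feats <- intersect(rownames(dataset$values), features_of_biotype(dataset, "mRNA"))
  if (!length(feats)) {
    return(empty)
  }
  xs <- dataset$values[feats, severe, drop = FALSE]
  xm <- dataset$values[feats, mild, drop = FALSE]
  n1 <- rowSums(!is.na(xs))
  n2 <- rowSums(!is.na(xm))
  m1 <- rowMeans(xs, na.rm = TRUE)
  m2 <- rowMeans(xm, na.rm = TRUE)
  ss1 <- rowSums((xs - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((xm - m2)^2, na.rm = TRUE)
  testable <- n1 >= 2 & n2 >= 2
  pooled <- (ss1 + ss2) / (n1 + n2 - 2)
  constant <- testable & pooled == 0
  if (any(constant)) {
    inform(paste0(
      dataset$dataset_id, ": ", sum(constant),
      " constant feature(s) excluded from `", contrast$label, "`"
    ))
  }
  keep <- testable & !constant
  if (!any(keep)) {
    return(empty)
  }
  # one-way two-group ANOVA: F = between-group MS / pooled within MS = t^2
  f <- (n1 * n2 / (n1 + n2)) * (m1 - m2)^2 / pooled
  df2 <- n1 + n2 - 2
  p <- pt(sqrt(f), df = df2, lower.tail = FALSE) * 2
  res <- tibble(
    dataset_id = dataset$dataset_id,
    feature_id = feats[keep],
    contrast_label = contrast$label,
    statistic = unname(f[keep]),
    p = unname(p[keep])
  )
  res$q <- fdr_adjust(res$p)
  crit <- if (use_fdr) res$q else res$p
  res <- res[crit <= alpha, , drop = FALSE]
  res$direction <- if_else(m1[res$feature_id] - m2[res$feature_id] > 0,
    "up_in_severe", "down_in_severe"
  )
  res
}

#' Cross-dataset consensus vote for bait genes
#'
#' Pools per-dataset differential calls (from any number of severity
#' contrasts) and retains a gene in a direction when the fraction of
#' consulted datasets calling it in that direction is at least
#' `min_fraction`. A dataset supports a direction if any of its contrasts
#' calls it. Genes meeting the threshold in both directions are excluded
#' from both lists and reported as conflicts.
#'
#' @param calls Tibble of differential calls as returned by
#'   [differential_by_contrast()] (rows from several datasets bound
#'   together).
#' @param n_datasets_consulted Number of datasets consulted, the
#'   denominator of the support fraction (includes datasets in which a
#'   gene was unmeasured).
#' @param min_fraction Support threshold in `(0, 1]`, default `0.5`.
#' @return A tibble of class `consensus_genes` with columns `feature_id`,
#'   `direction` (`"up"` / `"down"`), `support_fraction`,
#'   `supporting_datasets` (comma-joined ids). Conflicting genes are
#'   attached as attribute `"conflicts"`.
#' @export
consensus_genes <- function(calls, n_datasets_consulted, min_fraction = 0.5) {
  stopifnot(n_datasets_consulted >= 1, min_fraction > 0, min_fraction <= 1)
  empty <- tibble(
    feature_id = character(), direction = character(),
    support_fraction = double(), supporting_datasets = character()
  )
  if (is.null(calls) || nrow(calls) == 0) {
    out <- empty
  } else {
    votes <- calls |>
      mutate(direction = if_else(.data$direction == "up_in_severe", "up",
        if_else(.data$direction == "down_in_severe", "down", .data$direction)
      )) |>
      distinct(.data$feature_id, .data$direction, .data$dataset_id) |>
      group_by(.data$feature_id, .data$direction) |>
      summarise(
        support_fraction = n_distinct(.data$dataset_id) / n_datasets_consulted,
        supporting_datasets = paste(sort(unique(.data$dataset_id)), collapse = ","),
        n_support = n_distinct(.data$dataset_id),
        .groups = "drop"
      ) |>
      filter(frac_ge(.data$n_support, n_datasets_consulted, min_fraction))
    both <- votes |>
      dplyr::count(.data$feature_id) |>
      filter(.data$n > 1) |>
      pull(.data$feature_id)
    if (length(both)) {
      warn(paste0(
        "conflicting consensus direction, excluded: ",
        paste(sort(both), collapse = ", ")
      ))
    }
    out <- votes |>
      filter(!.data$feature_id %in% both) |>
      select(-"n_support") |>
      arrange(.data$direction, .data$feature_id)
    attr(out, "conflicts") <- sort(both)
  }
  attr(out, "min_fraction") <- min_fraction
  attr(out, "n_datasets_consulted") <- n_datasets_consulted
  class(out) <- c("consensus_genes", class(out))
  out
}

#' @export
print.consensus_genes <- function(x, ...) {
  cat(
    "<consensus_genes> ", sum(x$direction == "up"), " up / ",
    sum(x$direction == "down"), " down (min support ",
    attr(x, "min_fraction"), " of ", attr(x, "n_datasets_consulted"),
    " datasets)\n",
    sep = ""
  )
  if (length(attr(x, "conflicts"))) {
    cat("  conflicts excluded:", paste(attr(x, "conflicts"), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Plot consensus bait-gene support
#'
#' Dot plot of per-gene support fractions by direction, with the voting
#' threshold drawn as a dashed line.
#'
#' @param object A [consensus_genes()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.consensus_genes <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$support_fraction,
      y = stats::reorder(.data$feature_id, .data$support_fraction),
      colour = .data$direction
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = attr(object, "min_fraction") %||% 0.5,
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "support fraction (datasets)", y = NULL,
      title = "Consensus bait genes"
    )
}
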
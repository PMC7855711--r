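#' Read a Ct table from CSV
#'
#' Columns: `sample_id`, `group`, `target_id`, `ct`, `replicate`, and
#' optionally `pair_id` linking matched samples (e.g. tumor and adjacent
#' mucosa of one patient).
#'
#' @param path CSV file path.
#' @return A tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    target_id = readr::col_character(),
    ct = readr::col_double(),
    replicate = readr::col_integer(),
    .default = readr::col_character()
  ), progress = FALSE)
  validate_ct(tab)
}

validate_ct <- function(tab) {
  tab <- as_tibble(tab)
  need <- c("sample_id", "group", "target_id", "ct", "replicate")
  if (!all(need %in% names(tab))) {
    stop_cs(paste0("Ct table needs columns: ", paste(need, collapse = ", ")), "validation")
  }
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0)) {
    stop_cs("Ct values must be finite and positive", "validation")
  }
  if (anyDuplicated(tab[c("sample_id", "target_id", "replicate")])) {
    stop_cs("(sample_id, target_id, replicate) must be unique", "validation")
  }
  tab
}

#' Per-sample delta-Ct against a reference gene
#'
#' For each sample, technical replicates are averaged (arithmetic mean of
#' Ct) and `dCt = mean(Ct_target) - mean(Ct_reference)` is computed. Lower
#' dCt means higher expression relative to the reference.
#'
#' @param records Ct records (see [read_ct_table()]).
#' @param target_id,reference_id Feature ids present in `records`.
#' @return Tibble with one row per sample: `sample_id`, `group`,
#'   `pair_id` (if present), `delta_ct`.
#' @examples
#' rec <- tibble::tibble(
#'   sample_id = "s1", group = "tumor",
#'   target_id = rep(c("LNC", "PPIA"), each = 2),
#'   ct = c(25, 25, 20, 20), replicate = c(1, 2, 1, 2)
#' )
#' delta_ct(rec, "LNC", "PPIA")
#' @export
delta_ct <- function(records, target_id, reference_id) {
  records <- validate_ct(records)
  keep <- records[records$target_id %in% c(target_id, reference_id), , drop = FALSE]
  means <- keep |>
    group_by(.data$sample_id, .data$target_id) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "target_id", values_from = "mean_ct")
  if (!reference_id %in% names(means) || anyNA(means[[reference_id]])) {
    missing <- if (!reference_id %in% names(means)) {
      unique(keep$sample_id)
    } else {
      means$sample_id[is.na(means[[reference_id]])]
    }
    stop_cs(
      paste0(
        "missing reference `", reference_id, "` for sample(s): ",
        paste(missing, collapse = ", ")
      ),
      "missing_reference"
    )
  }
  if (!target_id %in% names(means)) {
    stop_cs(paste0("target `", target_id, "` not measured"), "lookup")
  }
  meta <- distinct(records[intersect(c("sample_id", "group", "pair_id"), names(records))])
  means |>
    mutate(delta_ct = .data[[target_id]] - .data[[reference_id]]) |>
    select("sample_id", "delta_ct") |>
    left_join(meta, by = "sample_id") |>
    relocate("sample_id", dplyr::any_of(c("group", "pair_id")), "delta_ct") |>
    filter(!is.na(.data$delta_ct))
}

#' 2^-ddCt fold change between two groups
#'
#' `ddCt = mean(dCt_case) - mean(dCt_control)`; the relative quantity of
#' the case group versus the control group is `2^(-ddCt)`.
#'
#' @param group_case,group_control Numeric vectors of per-sample dCt
#'   values; both non-empty.
#' @return A single fold-change value.
#' @examples
#' fold_change(c(4, 4), c(5, 5)) # one cycle lower dCt -> 2-fold up
#' @export
fold_change <- function(group_case, group_control) {
  if (!length(group_case) || !length(group_control)) {
    stop_cs("both groups must be non-empty", "validation")
  }
  ddct <- mean(group_case) - mean(group_control)
  2^(-ddct)
}

#' Paired or unpaired t-test on delta-Ct values
#'
#' Student's two-sample t-test (pooled variance) when unpaired; a paired
#' t-test on within-pair differences when `paired = TRUE`, matched via
#' `pair_a` / `pair_b`. Significance is flagged at `p <= 0.05`.
#'
#' @param group_a,group_b Numeric dCt vectors.
#' @param paired Use a paired test (default `FALSE`).
#' @param pair_a,pair_b Pair identifiers aligned with `group_a` /
#'   `group_b`; required when `paired = TRUE`. Every pair id must occur
#'   exactly once on each side.
#' @param welch Use Welch's unequal-variance test instead of pooled
#'   Student (unpaired only; default `FALSE`).
#' @return One-row tibble: `t`, `df`, `p`, `significant` (at `p <= 0.05`).
#' @export
compare_groups <- function(group_a, group_b, paired = FALSE,
                           pair_a = NULL, pair_b = NULL, welch = FALSE) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (paired) {
    if (is.null(pair_a) || is.null(pair_b)) {
      stop_cs("paired test needs pair_a and pair_b identifiers", "validation")
    }
    unmatched <- c(setdiff(pair_a, pair_b), setdiff(pair_b, pair_a))
    if (length(unmatched) || anyDuplicated(pair_a) || anyDuplicated(pair_b)) {
      stop_cs(
        paste0(
          "incomplete pairing; unmatched pair_id(s): ",
          paste(sort(unique(unmatched)), collapse = ", ")
        ),
        "incomplete_pairing"
      )
    }
    if (length(pair_a) < 2) {
      stop_cs("paired test needs at least 2 pairs", "insufficient_data")
    }
    d <- group_a[order(pair_a)] - group_b[order(pair_b)]
    if (sd(d) == 0) {
      stop_cs("zero variance of paired differences", "degenerate_input")
    }
    tt <- t.test(group_a[order(pair_a)], group_b[order(pair_b)], paired = TRUE)
  } else {
    if (length(group_a) < 2 || length(group_b) < 2) {
      stop_cs("unpaired test needs at least 2 values per group", "insufficient_data")
    }
    if (sd(group_a) == 0 && sd(group_b) == 0) {
      if (mean(group_a) == mean(group_b)) {
        return(tibble(t = 0, df = length(group_a) + length(group_b) - 2, p = 1, significant = FALSE))
      }
      stop_cs("zero variance in both groups", "degenerate_input")
    }
    tt <- t.test(group_a, group_b, var.equal = !welch)
  }
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, significant = tt$p.value <= 0.05
  )
}

#' Relative-quantification report for a Ct table
#'
#' For each target, computes per-sample dCt against the reference gene,
#' the case-vs-control `2^-ddCt` fold change and the group comparison
#' ([compare_groups()]). When `paired = TRUE`, samples are matched by
#' `pair_id` and per-pair fold changes are also attached (attribute
#' `"pair_fold_changes"`).
#'
#' @param records Ct records (see [read_ct_table()]).
#' @param targets Target feature ids to report (default: all non-reference
#'   targets in the table).
#' @param reference_id Reference (housekeeping) gene id.
#' @param case,control Group labels.
#' @param paired Use a paired t-test matched on `pair_id`.
#' @param welch Passed to [compare_groups()].
#' @return A tibble of class `qpcr_report`: one row per target with `n_case`,
#'   `n_control`, `delta_delta_ct`, `fold_change`, `t`, `df`, `p`,
#'   `significant`.
#' @export
qpcr_report <- function(records, targets = NULL, reference_id, case, control,
                        paired = FALSE, welch = FALSE) {
  records <- validate_ct(records)
  targets <- targets %||% setdiff(unique(records$target_id), reference_id)
  rows <- purrr::map(targets, function(tg) {
    dct <- delta_ct(records, tg, reference_id)
    a <- dct[dct$group == case, , drop = FALSE]
    b <- dct[dct$group == control, , drop = FALSE]
    # a degenerate comparison (e.g. a noise-free synthetic plate) still
    # yields a fold change; the test statistics are reported as NA
    cmp <- tryCatch(
      if (paired) {
        compare_groups(a$delta_ct, b$delta_ct,
          paired = TRUE,
          pair_a = a$pair_id, pair_b = b$pair_id, welch = welch
        )
      } else {
        compare_groups(a$delta_ct, b$delta_ct, welch = welch)
      },
      cernascreen_error_degenerate_input = function(e) {
        tibble(t = NA_real_, df = NA_real_, p = NA_real_, significant = NA)
      }
    )
    tibble(
      target_id = tg, n_case = nrow(a), n_control = nrow(b),
      delta_delta_ct = mean(a$delta_ct) - mean(b$delta_ct),
      fold_change = fold_change(a$delta_ct, b$delta_ct)
    ) |>
      dplyr::bind_cols(cmp)
  })
  out <- bind_rows(rows)
  if (paired) {
    pf <- purrr::map(targets, function(tg) {
      dct <- delta_ct(records, tg, reference_id)
      wide <- dct |>
        select("pair_id", "group", "delta_ct") |>
        tidyr::pivot_wider(names_from = "group", values_from = "delta_ct")
      tibble(
        target_id = tg, pair_id = wide$pair_id,
        fold_change = 2^(-(wide[[case]] - wide[[control]]))
      )
    })
    attr(out, "pair_fold_changes") <- bind_rows(pf)
  }
  class(out) <- c("qpcr_report", class(out))
  out
}

#' Plot a qPCR report
#'
#' Bar plot of per-target fold changes on a log2 axis, significant targets
#' (p <= 0.05) highlighted.
#'
#' @param object A [qpcr_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qpcr_report <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = stats::reorder(.data$target_id, .data$fold_change),
      y = .data$fold_change, fill = .data$significant
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "fold change (2^-ddCt)", title = "Relative quantification") +
    ggplot2::coord_flip()
}
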
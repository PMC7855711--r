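#' Run the full screening pipeline on a dataset collection
#'
#' Executes the three in-silico stages end-to-end: (1) per-dataset
#' differential screening of mRNAs against the severity contrasts and
#' consensus voting into up/down bait-gene lists; (2) lncRNA-bait
#' correlation screens per dataset, cross-dataset voting into the four
#' signed lists and candidate classification (A&D -> tumor suppressor,
#' B&C -> oncogene); (3) for each tumor-suppressor candidate (or a named
#' lncRNA), reconstruction of its lncRNA-miRNA-mRNA axes: negatively
#' correlated miRNAs from the designated miRNA-bearing dataset, union with
#' binding-site evidence, validated-target expansion, oncomiR filtering
#' and sign-constrained axis assembly against the mRNAs whose positive
#' correlation with the lncRNA is supported by at least `min_fraction` of
#' datasets. Deterministic: identical inputs give identical output.
#'
#' @param datasets Named list of [expression_dataset()] objects.
#' @param contrasts List of [contrast_spec()] objects.
#' @param binding_table,targets_table,cancer_table
#'   [interaction_table()]s of the three kinds (any may be `NULL` to skip
#'   axis reconstruction).
#' @param disease Disease label for the oncomiR filter.
#' @param lnc_ids lncRNAs to reconstruct axes for; default: all
#'   tumor-suppressor candidates.
#' @param axis_dataset Id of the complete, miRNA-bearing dataset used for
#'   miRNA correlations and reported axis statistics (default: the first
#'   dataset containing miRNA features).
#' @param alpha_de,alpha_corr,alpha_mirna Significance cutoffs for the DE
#'   screen, the lncRNA/mRNA correlation screens and the miRNA screen
#'   (defaults 0.01, 0.01, 0.001).
#' @param min_fraction Cross-dataset support threshold (default 0.5).
#' @param strict Enforce the negative miRNA-mRNA constraint when
#'   assembling axes (default `FALSE`: recorded and flagged).
#' @param use_fdr Apply the DE cutoff to FDR-adjusted q-values (default
#'   `TRUE`).
#' @return An object of class `cerna_run`: a list with `de_calls`,
#'   `baits`, `lnc_records`, `lists`, `candidates`, `mirna_stages`,
#'   `axes` (tibble over all screened lncRNAs) and `report` (the funnel
#'   counts and configuration echo).
#' @export
run_screen <- function(datasets, contrasts,
                       binding_table = NULL, targets_table = NULL, cancer_table = NULL,
                       disease = "CRC", lnc_ids = NULL, axis_dataset = NULL,
                       alpha_de = 0.01, alpha_corr = 0.01, alpha_mirna = 0.001,
                       min_fraction = 0.5, strict = FALSE, use_fdr = TRUE) {
  stopifnot(length(datasets) >= 1, all(vapply(datasets, inherits, TRUE, "expression_dataset")))
  if (inherits(contrasts, "contrast_spec")) contrasts <- list(contrasts)
  n_ds <- length(datasets)
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  # stage 1: differential screen + consensus baits
  de_calls <- bind_rows(lapply(datasets, function(ds) {
    bind_rows(lapply(contrasts, function(ct) {
      withCallingHandlers(
        differential_by_contrast(ds, ct, alpha = alpha_de, use_fdr = use_fdr),
        warning = function(w) {
          note(conditionMessage(w))
          invokeRestart("muffleWarning")
        },
        message = function(m) {
          note(conditionMessage(m))
          invokeRestart("muffleMessage")
        }
      )
    }))
  }))
  baits <- withCallingHandlers(
    consensus_genes(de_calls, n_datasets_consulted = n_ds, min_fraction = min_fraction),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  # stage 2: lncRNA-bait correlation + four lists + candidates
  lnc_records <- bind_rows(lapply(datasets, function(ds) {
    withCallingHandlers(
      correlate_lncrnas(ds, baits, alpha = alpha_corr),
      warning = function(w) {
        note(conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }))
  lists <- vote_and_build_lists(lnc_records, baits, n_ds, min_fraction = min_fraction)
  candidates <- classify_candidates(lists)

  # stage 3: ceRNA axes per candidate lncRNA
  axis_dataset <- axis_dataset %||% {
    has_mir <- vapply(datasets, function(d) length(features_of_biotype(d, "miRNA")) > 0, TRUE)
    if (any(has_mir)) names(datasets)[which(has_mir)[1]] else NA_character_
  }
  lnc_ids <- lnc_ids %||% candidates$lncrna_id[candidates$role == "tumor_suppressor"]
  have_tables <- !is.null(binding_table) && !is.null(targets_table)
  axes <- list()
  mirna_stages <- tibble(
    lncrna_id = character(), n_corr_selected = integer(), n_union = integer(),
    n_after_targets = integer(), n_after_oncomir = integer()
  )
  if (have_tables && !is.na(axis_dataset) && length(lnc_ids)) {
    ds_ax <- datasets[[axis_dataset]]
    for (lnc in lnc_ids) {
      if (!lnc %in% rownames(ds_ax$values)) {
        note(paste0(lnc, " unmeasured in axis dataset ", axis_dataset, "; skipped"))
        next
      }
      neg <- select_negative_mirnas(lnc, ds_ax, alpha = alpha_mirna)
      mir <- merge_mirna_evidence(neg, binding_table, lnc)
      expanded <- withCallingHandlers(
        expand_validated_targets(mir, targets_table),
        message = function(m) {
          note(conditionMessage(m))
          invokeRestart("muffleMessage")
        }
      )
      after_onc <- if (!is.null(cancer_table)) {
        filter_oncomirs(expanded, cancer_table, disease)
      } else {
        expanded
      }
      lm <- consensus_lnc_mrna(datasets, lnc, alpha_corr, min_fraction, axis_dataset)
      mm_targets <- unique(after_onc$mrna_id)
      mm_mirnas <- unique(after_onc$mirna_id)
      mm <- if (length(mm_targets) && length(mm_mirnas)) {
        present_m <- intersect(mm_mirnas, rownames(ds_ax$values))
        present_t <- intersect(mm_targets, rownames(ds_ax$values))
        if (length(present_m) && length(present_t)) {
          cor_screen(ds_ax$values, present_m, present_t) |>
            rename(mirna_id = "feature_a", mrna_id = "feature_b")
        } else {
          tibble(mirna_id = character(), mrna_id = character(), r = double(), p = double())
        }
      } else {
        tibble(mirna_id = character(), mrna_id = character(), r = double(), p = double())
      }
      ax <- withCallingHandlers(
        assemble_axes(lnc, after_onc, lm, mm,
          alpha_lnc_mrna = alpha_corr, strict = strict
        ),
        message = function(m) {
          note(conditionMessage(m))
          invokeRestart("muffleMessage")
        }
      )
      axes[[lnc]] <- ax
      mirna_stages <- bind_rows(mirna_stages, tibble(
        lncrna_id = lnc,
        n_corr_selected = dplyr::n_distinct(neg$mirna_id),
        n_union = nrow(mir),
        n_after_targets = dplyr::n_distinct(expanded$mirna_id),
        n_after_oncomir = dplyr::n_distinct(after_onc$mirna_id)
      ))
    }
  }
  axes_tbl <- if (length(axes)) bind_rows(axes) else NULL

  list_sizes <- vapply(c("A", "B", "C", "D"), function(l) length(list_members(lists, l)), 1L)
  report <- list(
    config = list(
      alpha_de = alpha_de, alpha_corr = alpha_corr, alpha_mirna = alpha_mirna,
      min_fraction = min_fraction, strict = strict, use_fdr = use_fdr,
      disease = disease, axis_dataset = axis_dataset
    ),
    counts = list(
      datasets_read = n_ds,
      de_calls = nrow(de_calls),
      baits_up = sum(baits$direction == "up"),
      baits_down = sum(baits$direction == "down"),
      list_A = unname(list_sizes["A"]), list_B = unname(list_sizes["B"]),
      list_C = unname(list_sizes["C"]), list_D = unname(list_sizes["D"]),
      candidates_tumor_suppressor = sum(candidates$role == "tumor_suppressor"),
      candidates_oncogene = sum(candidates$role == "oncogene"),
      candidates_conflict = sum(candidates$role == "conflict"),
      axes_emitted = if (is.null(axes_tbl)) 0L else nrow(axes_tbl)
    ),
    mirna_funnel = mirna_stages,
    warnings = warnings_log
  )
  structure(
    list(
      de_calls = de_calls, baits = baits, lnc_records = lnc_records,
      lists = lists, candidates = candidates, mirna_stages = mirna_stages,
      axes = axes_tbl, report = report
    ),
    class = "cerna_run"
  )
}

# mRNAs positively and significantly correlated with the lncRNA in at least
# min_fraction of datasets; the reported record comes from the axis dataset
# when it supports the pair, else the supporting record with median r.
consensus_lnc_mrna <- function(datasets, lnc_id, alpha, min_fraction, axis_dataset) {
  n_ds <- length(datasets)
  recs <- bind_rows(lapply(datasets, function(ds) {
    mr <- setdiff(
      intersect(features_of_biotype(ds, "mRNA"), rownames(ds$values)),
      lnc_id
    )
    if (!lnc_id %in% rownames(ds$values) || !length(mr)) {
      return(NULL)
    }
    out <- cor_screen(ds$values, lnc_id, mr)
    out$dataset_id <- ds$dataset_id
    out
  }))
  if (is.null(recs) || nrow(recs) == 0) {
    return(tibble(mrna_id = character(), r = double(), p = double()))
  }
  sig <- recs[recs$r > 0 & recs$p <= alpha, , drop = FALSE]
  if (!nrow(sig)) {
    return(tibble(mrna_id = character(), r = double(), p = double()))
  }
  pick_record <- function(df) {
    i <- if (!is.na(axis_dataset) && axis_dataset %in% df$dataset_id) {
      match(axis_dataset, df$dataset_id)
    } else {
      order(df$r)[ceiling(nrow(df) / 2)]
    }
    tibble(n_support = n_distinct(df$dataset_id), r = df$r[i], p = df$p[i])
  }
  sig |>
    group_by(mrna_id = .data$feature_b) |>
    dplyr::group_modify(~ pick_record(.x)) |>
    ungroup() |>
    filter(frac_ge(.data$n_support, n_ds, min_fraction)) |>
    select("mrna_id", "r", "p")
}

#' @export
print.cerna_run <- function(x, ...) {
  cnt <- x$report$counts
  cat("<cerna_run>\n")
  cat(
    "  datasets:", cnt$datasets_read, " DE calls:", cnt$de_calls,
    " baits:", cnt$baits_up, "up /", cnt$baits_down, "down\n"
  )
  cat(
    "  lists A-D:", cnt$list_A, cnt$list_B, cnt$list_C, cnt$list_D,
    " candidates:", cnt$candidates_tumor_suppressor, "TS /",
    cnt$candidates_oncogene, "ONC /", cnt$candidates_conflict, "conflict\n"
  )
  cat("  axes emitted:", cnt$axes_emitted, "\n")
  invisible(x)
}

#' @describeIn run_screen Candidate calls of a run as a tibble.
#' @param x A `cerna_run`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cerna_run <- function(x, ...) {
  as_tibble(x$candidates)
}

#' @describeIn run_screen One-row tibble of the run's funnel counts.
#' @exportS3Method generics::glance
glance.cerna_run <- function(x, ...) {
  as_tibble(x$report$counts)
}

#' Serialize a run report to JSON
#'
#' Writes the configuration echo, funnel counts, miRNA funnel and warnings
#' of a [run_screen()] result as JSON; the file round-trips through
#' [jsonlite::read_json()].
#'
#' @param run A `cerna_run`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_run_report <- function(run, path) {
  stopifnot(inherits(run, "cerna_run"))
  rep <- run$report
  rep$mirna_funnel <- as.data.frame(rep$mirna_funnel)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
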
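#' Configuration for the synthetic multi-dataset cohort generator
#'
#' The generator emulates the statistical structure the screening pipeline
#' assumes: a collection of heterogeneous log-scale expression datasets in
#' which planted "bait" mRNAs shift with a clinical severity contrast, a
#' sponge lncRNA loads positively on a shared latent factor together with
#' its axis mRNAs and the down-regulated baits (and negatively with its
#' axis miRNAs and the up-regulated baits), and decoy features are
#' independent noise. The first dataset plays the role of the complete,
#' miRNA-bearing reference collection (a TCGA-like compendium): it carries
#' all biotypes and no missing features, while the remaining datasets are
#' mRNA/lncRNA-only and drop each feature independently with probability
#' `missing_feature_fraction`.
#'
#' @param n_datasets Number of datasets in the collection (default 8).
#' @param samples_per_group Samples per severe and per mild group in each
#'   dataset (default 60).
#' @param n_bait_up,n_bait_down Planted severity-associated mRNAs up/down
#'   in the severe group (defaults 5 and 19).
#' @param bait_effect_size Group mean shift in within-group SD units
#'   (default 1.5).
#' @param n_decoy_mrna,n_decoy_lncrna,n_decoy_mirna Independent-noise
#'   features per biotype (defaults 60, 20, 12).
#' @param sponge_coupling Latent-factor loading in `[0, 1]` shared by the
#'   sponge lncRNA, axis mRNAs and baits (+) and axis miRNAs (-)
#'   (default 0.8).
#' @param n_axis_mirnas,n_axis_mrnas Planted axis members (defaults 3, 5);
#'   every (axis miRNA, axis mRNA) pair is a planted triplet.
#' @param n_mirnas_without_targets Extra negatively-coupled miRNAs given
#'   no validated-target rows, to exercise the exclusion rule (default 0).
#' @param noise_sd Residual SD on the log scale (default 1).
#' @param missing_feature_fraction Probability that a feature is
#'   unmeasured in a given non-reference dataset (default 0.1).
#' @param interaction_false_positive_rows Decoy rows per interaction
#'   table (default 10).
#' @param seed Master seed; all randomness is derived from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_datasets = 8, samples_per_group = 60,
                          n_bait_up = 5, n_bait_down = 19,
                          bait_effect_size = 1.5,
                          n_decoy_mrna = 60, n_decoy_lncrna = 20, n_decoy_mirna = 12,
                          sponge_coupling = 0.8,
                          n_axis_mirnas = 3, n_axis_mrnas = 5,
                          n_mirnas_without_targets = 0,
                          noise_sd = 1, missing_feature_fraction = 0.1,
                          interaction_false_positive_rows = 10,
                          seed = 1) {
  cfg <- list(
    n_datasets = n_datasets, samples_per_group = samples_per_group,
    n_bait_up = n_bait_up, n_bait_down = n_bait_down,
    bait_effect_size = bait_effect_size,
    n_decoy_mrna = n_decoy_mrna, n_decoy_lncrna = n_decoy_lncrna,
    n_decoy_mirna = n_decoy_mirna,
    sponge_coupling = sponge_coupling,
    n_axis_mirnas = n_axis_mirnas, n_axis_mrnas = n_axis_mrnas,
    n_mirnas_without_targets = n_mirnas_without_targets,
    noise_sd = noise_sd, missing_feature_fraction = missing_feature_fraction,
    interaction_false_positive_rows = interaction_false_positive_rows,
    seed = seed
  )
  counts <- cfg[grep("^n_", names(cfg))]
  if (any(unlist(counts) < 0)) stop_cs("counts must be >= 0", "validation")
  if (cfg$n_datasets < 1 || cfg$samples_per_group < 2) {
    stop_cs("need >= 1 dataset and >= 2 samples per group", "validation")
  }
  if (cfg$sponge_coupling < 0 || cfg$sponge_coupling > 1) {
    stop_cs("sponge_coupling must lie in [0, 1]", "validation")
  }
  if (cfg$noise_sd <= 0) stop_cs("noise_sd must be > 0", "validation")
  if (cfg$missing_feature_fraction < 0 || cfg$missing_feature_fraction >= 1) {
    stop_cs("missing_feature_fraction must lie in [0, 1)", "validation")
  }
  if (cfg$bait_effect_size < 0) stop_cs("bait_effect_size must be >= 0", "validation")
  structure(cfg, class = "cohort_config")
}

pad_ids <- function(prefix, n) {
  if (n == 0) {
    return(character(0))
  }
  sprintf("%s%02d", prefix, seq_len(n))
}

#' Generate a synthetic multi-dataset cohort with planted truth
#'
#' Draws the collection described by [cohort_config()]. The expression
#' model for feature `g` in sample `s` of dataset `d` is
#' `x = mu_gd + delta_gd * severe_s + lambda_g * f_s + e`, with per-dataset
#' baselines `mu_gd ~ N(8, 1)` (platform heterogeneity), group shifts
#' `delta_gd = effect * jitter_d * sd_within` for baits (jitter uniform in
#' 0.8-1.2), shared latent factor `f_s ~ N(0, 1)` and residual
#' `e ~ N(0, noise_sd^2)`. The implied correlation between two features
#' with loadings `l1`, `l2` is `l1 * l2 / sqrt((l1^2 + s^2)(l2^2 + s^2))`.
#' Identical seeds give identical output.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `datasets` (named list of
#'   [expression_dataset()]) and `truth` (a `planted_truth` list: bait ids,
#'   sponge id, axis triplets, oncomiR ids, no-target miRNA ids, decoy
#'   ids, per-dataset feature presence, the seed and the config).
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_datasets = 2, samples_per_group = 10,
#'   n_decoy_mrna = 5, n_decoy_lncrna = 2, n_decoy_mirna = 2, seed = 7
#' ))
#' names(cohort$datasets)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  bait_up <- pad_ids("BG_UP_", cfg$n_bait_up)
  bait_down <- pad_ids("BG_DN_", cfg$n_bait_down)
  axis_mrna <- pad_ids("AXM_", cfg$n_axis_mrnas)
  axis_mirna <- pad_ids("MIR_AX_", cfg$n_axis_mirnas)
  nt_mirna <- pad_ids("MIR_NT_", cfg$n_mirnas_without_targets)
  dec_mrna <- pad_ids("DEC_MRNA_", cfg$n_decoy_mrna)
  dec_lnc <- pad_ids("DEC_LNC_", cfg$n_decoy_lncrna)
  dec_mir <- pad_ids("DEC_MIR_", cfg$n_decoy_mirna)
  sponge <- "LNC_SPONGE"

  lam <- c(
    setNames(rep(-cfg$sponge_coupling, length(bait_up)), bait_up),
    setNames(rep(cfg$sponge_coupling, length(bait_down)), bait_down),
    setNames(rep(cfg$sponge_coupling, length(axis_mrna)), axis_mrna),
    setNames(cfg$sponge_coupling, sponge),
    setNames(rep(-cfg$sponge_coupling, length(axis_mirna)), axis_mirna),
    setNames(rep(-cfg$sponge_coupling, length(nt_mirna)), nt_mirna),
    setNames(rep(0, length(dec_mrna)), dec_mrna),
    setNames(rep(0, length(dec_lnc)), dec_lnc),
    setNames(rep(0, length(dec_mir)), dec_mir)
  )
  # severe-group shift direction: +1 up-baits, -1 down-baits, 0 otherwise
  shift_dir <- setNames(rep(0, length(lam)), names(lam))
  shift_dir[bait_up] <- 1
  shift_dir[bait_down] <- -1

  mrna_feats <- c(bait_up, bait_down, axis_mrna, dec_mrna)
  lnc_feats <- c(sponge, dec_lnc)
  mir_feats <- c(axis_mirna, nt_mirna, dec_mir)
  biotypes <- tibble(
    feature_id = c(mrna_feats, lnc_feats, mir_feats),
    biotype = c(
      rep("mRNA", length(mrna_feats)),
      rep("lncRNA", length(lnc_feats)),
      rep("miRNA", length(mir_feats))
    )
  )

  ds_ids <- sprintf("DS%02d", seq_len(cfg$n_datasets))
  presence <- list()
  datasets <- lapply(seq_len(cfg$n_datasets), function(d) {
    with_seed_cs(sub_seed(cfg$seed, "cohort", d), {
      is_ref <- d == 1L
      feats <- if (is_ref) names(lam) else setdiff(names(lam), mir_feats)
      if (!is_ref && cfg$missing_feature_fraction > 0) {
        drop <- stats::runif(length(feats)) < cfg$missing_feature_fraction
        feats <- feats[!drop]
      }
      n <- cfg$samples_per_group
      samples <- c(
        sprintf("%s_sev_%02d", ds_ids[d], seq_len(n)),
        sprintf("%s_mil_%02d", ds_ids[d], seq_len(n))
      )
      severe <- rep(c(1, 0), each = n)
      f <- rnorm(2 * n)
      jitter <- stats::runif(1, 0.8, 1.2)
      mu <- rnorm(length(feats), mean = 8, sd = 1)
      sd_within <- sqrt(lam[feats]^2 + cfg$noise_sd^2)
      delta <- cfg$bait_effect_size * jitter * sd_within * shift_dir[feats]
      vals <- matrix(
        mu + outer(delta, severe) + outer(lam[feats], f) +
          rnorm(length(feats) * 2 * n, sd = cfg$noise_sd),
        nrow = length(feats), dimnames = list(feats, samples)
      )
      ann <- tibble(
        sample_id = samples,
        severity = if_else(severe == 1, "severe", "mild")
      )
      presence[[d]] <<- tibble(dataset_id = ds_ids[d], feature_id = feats)
      expression_dataset(ds_ids[d], vals, ann, biotypes[biotypes$feature_id %in% feats, ])
    })
  })
  names(datasets) <- ds_ids

  truth <- structure(
    list(
      bait_up_ids = bait_up, bait_down_ids = bait_down,
      sponge_lncrna_id = sponge,
      axis_mirna_ids = axis_mirna, axis_mrna_ids = axis_mrna,
      axis_triplets = tidyr::expand_grid(mirna_id = axis_mirna, mrna_id = axis_mrna),
      no_target_mirna_ids = nt_mirna,
      oncomir_ids = c(axis_mirna, nt_mirna),
      decoy_mrna_ids = dec_mrna, decoy_lncrna_ids = dec_lnc, decoy_mirna_ids = dec_mir,
      feature_presence = bind_rows(presence),
      seed = cfg$seed, config = unclass(cfg)
    ),
    class = "planted_truth"
  )
  list(datasets = datasets, truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(
    "<planted_truth> baits:", length(x$bait_up_ids), "up /",
    length(x$bait_down_ids), "down; sponge:", x$sponge_lncrna_id,
    "; triplets:", nrow(x$axis_triplets), "\n"
  )
  invisible(x)
}

#' Generate interaction evidence tables matching a planted truth
#'
#' The binding table contains every (sponge lncRNA, axis miRNA) pair (and
#' the no-target miRNAs), the validated-target table every planted
#' (axis miRNA, axis mRNA) pair while deliberately omitting rows for the
#' no-target miRNAs, and the cancer table annotates the planted oncomiRs
#' for the study disease. Each table additionally carries
#' `interaction_false_positive_rows` decoy rows referencing decoy
#' features, plus off-disease decoy annotations.
#'
#' @param truth `planted_truth` from [generate_cohort()].
#' @param config The matching [cohort_config()].
#' @param disease Disease label for the oncomiR annotations
#'   (default `"CRC"`).
#' @return Named list of three [interaction_table()]s: `binding`,
#'   `targets`, `cancer`.
#' @export
generate_interaction_tables <- function(truth, config, disease = "CRC") {
  stopifnot(inherits(truth, "planted_truth"), inherits(config, "cohort_config"))
  k <- config$interaction_false_positive_rows
  with_seed_cs(sub_seed(config$seed, "interactions", 0L), {
    decoy_pair <- function(a, b, n) {
      if (n == 0 || !length(a) || !length(b)) {
        return(tibble(id_a = character(), id_b = character()))
      }
      tibble(
        id_a = sample(a, n, replace = TRUE),
        id_b = sample(b, n, replace = TRUE)
      )
    }
    bind_dec <- decoy_pair(truth$decoy_lncrna_ids, truth$decoy_mirna_ids, k)
    binding <- interaction_table(bind_rows(
      tibble(
        lncrna_id = truth$sponge_lncrna_id,
        mirna_id = c(truth$axis_mirna_ids, truth$no_target_mirna_ids),
        source_db = "SYN_BIND"
      ),
      tibble(lncrna_id = bind_dec$id_a, mirna_id = bind_dec$id_b, source_db = "SYN_BIND_DECOY")
    ), "lncrna_mirna_binding")
    targ_dec <- decoy_pair(truth$decoy_mirna_ids, truth$decoy_mrna_ids, k)
    targets <- interaction_table(bind_rows(
      tibble(
        mirna_id = truth$axis_triplets$mirna_id,
        mrna_id = truth$axis_triplets$mrna_id,
        source_db = "SYN_TARGET"
      ),
      tibble(mirna_id = targ_dec$id_a, mrna_id = targ_dec$id_b, source_db = "SYN_TARGET_DECOY")
    ), "mirna_mrna_validated")
    cancer <- interaction_table(bind_rows(
      tibble(
        mirna_id = truth$oncomir_ids, disease = disease,
        direction = "Upregulated", source_db = "SYN_CANCER"
      ),
      if (length(truth$decoy_mirna_ids)) {
        tibble(
          mirna_id = truth$decoy_mirna_ids, disease = "OtherDisease",
          direction = "Upregulated", source_db = "SYN_CANCER"
        )
      }
    ), "mirna_cancer")
    list(binding = binding, targets = targets, cancer = cancer)
  })
}

#' Generate a synthetic qPCR plate with known fold changes
#'
#' Reference-gene Cts are drawn around a fixed baseline of 20 cycles and
#' target Cts around 25 in the control group; in the case group each
#' target's Ct is offset by `-log2(fold_change)` so that the true
#' `2^-ddCt` equals the requested fold change. Gaussian noise of SD
#' `ct_noise_sd` is added to every replicate measurement. With zero noise
#' the plate inverts exactly.
#'
#' @param fold_changes Named numeric vector: target id -> true fold change
#'   (case vs control); all values must be positive.
#' @param n_per_group Samples per group (default 6).
#' @param ct_noise_sd Replicate-level Ct noise SD (default 0.2).
#' @param seed Seed for the plate.
#' @param n_replicates Technical replicates per (sample, target)
#'   (default 2).
#' @param reference_id Reference gene id (default `"PPIA"`).
#' @return A tibble of Ct records (see [read_ct_table()]) with groups
#'   `"case"` / `"control"` and pair ids `P01..`.
#' @export
generate_qpcr_plate <- function(fold_changes, n_per_group = 6, ct_noise_sd = 0.2,
                                seed = 1, n_replicates = 2, reference_id = "PPIA") {
  if (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes)))) {
    stop_cs("fold_changes must be a named vector", "validation")
  }
  if (any(fold_changes <= 0)) stop_cs("fold changes must be > 0", "domain")
  with_seed_cs(sub_seed(seed, "qpcr", 0L), {
    grid <- tidyr::expand_grid(
      group = c("case", "control"),
      idx = seq_len(n_per_group),
      target_id = c(reference_id, names(fold_changes)),
      replicate = seq_len(n_replicates)
    ) |>
      mutate(
        sample_id = sprintf("%s_%02d", .data$group, .data$idx),
        pair_id = sprintf("P%02d", .data$idx),
        base = if_else(.data$target_id == reference_id, 20, 25),
        offset = if_else(
          .data$group == "case" & .data$target_id != reference_id,
          -log2(fold_changes)[.data$target_id], 0
        ),
        offset = if_else(is.na(.data$offset), 0, .data$offset),
        ct = .data$base + .data$offset +
          if (ct_noise_sd > 0) rnorm(dplyr::n(), sd = ct_noise_sd) else 0
      ) |>
      select("sample_id", "group", "pair_id", "target_id", "ct", "replicate")
    validate_ct(grid)
  })
}

#' Write a synthetic cohort to disk in the package's input layout
#'
#' Writes one TSV triple per dataset, a YAML manifest, the three
#' interaction tables and `truth.json`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param tables Output of [generate_interaction_tables()] (optional).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, tables = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$datasets, function(ds) {
    stem <- ds$dataset_id
    write_expression_dataset(
      ds,
      file.path(dir, paste0(stem, "_matrix.tsv")),
      file.path(dir, paste0(stem, "_annotations.tsv")),
      file.path(dir, paste0(stem, "_biotypes.tsv"))
    )
    list(
      dataset_id = stem,
      matrix = paste0(stem, "_matrix.tsv"),
      annotations = paste0(stem, "_annotations.tsv"),
      biotypes = paste0(stem, "_biotypes.tsv")
    )
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(datasets = unname(entries)), manifest)
  if (!is.null(tables)) {
    readr::write_tsv(tables$binding, file.path(dir, "lncrna_mirna_binding.tsv"), progress = FALSE)
    readr::write_tsv(tables$targets, file.path(dir, "mirna_mrna_targets.tsv"), progress = FALSE)
    readr::write_tsv(tables$cancer, file.path(dir, "mirna_cancer.tsv"), progress = FALSE)
  }
  truth <- cohort$truth
  jsonlite::write_json(
    lapply(unclass(truth), function(x) if (inherits(x, "data.frame")) as.data.frame(x) else x),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
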
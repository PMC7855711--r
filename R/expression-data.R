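#' Expression dataset container
#'
#' One study's expression data: a numeric feature x sample matrix (assumed
#' log-scale unless `log2_transform = TRUE` at read time), a per-sample
#' clinical annotation table and a per-feature biotype table. Missing
#' expression values are allowed and represented as `NA`.
#'
#' @param dataset_id Short identifier for the study.
#' @param values Numeric matrix, rows named by feature_id, columns by
#'   sample_id. All non-missing entries must be finite.
#' @param sample_annotations Data frame with a `sample_id` column plus one
#'   column per clinical feature (categorical levels; `NA` allowed).
#' @param feature_biotypes Data frame with columns `feature_id` and
#'   `biotype` (one of `"mRNA"`, `"lncRNA"`, `"miRNA"`). Features of the
#'   matrix absent from this table default to `"mRNA"` (with a message).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `dataset_id`, `values`, `sample_annotations` (tibble) and
#'   `feature_biotypes` (tibble).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' ann <- data.frame(sample_id = paste0("S", 1:4),
#'                   metastasis = c("M0", "M0", "M1", "M1"))
#' bio <- data.frame(feature_id = paste0("G", 1:3),
#'                   biotype = c("mRNA", "mRNA", "lncRNA"))
#' ds <- expression_dataset("demo", m, ann, bio)
#' ds
#' @export
expression_dataset <- function(dataset_id, values, sample_annotations, feature_biotypes) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1, nzchar(dataset_id))
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_cs("`values` must be a numeric matrix", "validation")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_cs("`values` must have feature_id rownames and sample_id colnames", "validation")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop_cs(paste0("duplicate feature_id: ", paste(dup, collapse = ", ")), "duplicate_feature")
  }
  bad <- values[!is.na(values)]
  if (any(!is.finite(bad))) {
    stop_cs("non-missing expression values must be finite", "validation")
  }
  ann <- as_tibble(sample_annotations)
  if (!"sample_id" %in% names(ann)) {
    stop_cs("sample annotations need a `sample_id` column", "validation")
  }
  missing_ann <- setdiff(colnames(values), ann$sample_id)
  if (length(missing_ann)) {
    stop_cs(
      paste0("samples without an annotation record: ", paste(missing_ann, collapse = ", ")),
      "validation"
    )
  }
  ann <- ann[match(colnames(values), ann$sample_id), , drop = FALSE]
  clin <- setdiff(names(ann), "sample_id")
  for (cf in clin) {
    if (all(is.na(ann[[cf]]))) {
      stop_cs(paste0("clinical feature `", cf, "` has no non-missing level"), "validation")
    }
  }
  bio <- as_tibble(feature_biotypes)
  if (!all(c("feature_id", "biotype") %in% names(bio))) {
    stop_cs("feature biotypes need `feature_id` and `biotype` columns", "validation")
  }
  ok_bio <- c("mRNA", "lncRNA", "miRNA")
  if (!all(bio$biotype %in% ok_bio)) {
    stop_cs("biotype must be one of mRNA, lncRNA, miRNA", "validation")
  }
  unlabelled <- setdiff(rownames(values), bio$feature_id)
  if (length(unlabelled)) {
    inform(paste0(
      dataset_id, ": ", length(unlabelled),
      " feature(s) without a biotype row default to mRNA"
    ))
    bio <- bind_rows(bio, tibble(feature_id = unlabelled, biotype = "mRNA"))
  }
  bio <- distinct(bio[bio$feature_id %in% rownames(values), c("feature_id", "biotype")])
  if (anyDuplicated(bio$feature_id)) {
    stop_cs("conflicting biotype rows for the same feature_id", "validation")
  }
  structure(
    list(
      dataset_id = dataset_id,
      values = values,
      sample_annotations = ann,
      feature_biotypes = bio
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(
    "<expression_dataset> ", x$dataset_id, ": ",
    nrow(x$values), " features x ", ncol(x$values), " samples\n",
    sep = ""
  )
  cat("  biotypes:", paste(
    names(table(x$feature_biotypes$biotype)),
    table(x$feature_biotypes$biotype),
    collapse = ", "
  ), "\n")
  cat("  clinical features:", paste(
    setdiff(names(x$sample_annotations), "sample_id"),
    collapse = ", "
  ), "\n")
  invisible(x)
}

#' Feature ids of a given biotype
#' @param dataset An [expression_dataset()].
#' @param biotype One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @return Character vector of feature ids.
#' @export
features_of_biotype <- function(dataset, biotype) {
  stopifnot(inherits(dataset, "expression_dataset"))
  dataset$feature_biotypes$feature_id[dataset$feature_biotypes$biotype == biotype]
}

#' Read an expression dataset from its TSV file triple
#'
#' The matrix file is tab-separated with a header row
#' `feature_id<TAB>sample1<TAB>...` and one feature per row; the annotation
#' file is keyed by `sample_id`; the biotype file has columns `feature_id`
#' and `biotype`. The missing-value token is `"NA"`. Values are assumed
#' log-scale; set `log2_transform = TRUE` for linear-scale inputs, which
#' applies `log2(x + 1)`.
#'
#' @param matrix_path,annotations_path,biotypes_path File paths.
#' @param dataset_id Identifier; defaults to the matrix file name stem.
#' @param log2_transform Apply `log2(x + 1)` to the matrix (default `FALSE`).
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(matrix_path, annotations_path, biotypes_path,
                                    dataset_id = NULL, log2_transform = FALSE) {
  dataset_id <- dataset_id %||% sub("\\.[^.]*$", "", basename(matrix_path))
  header <- strsplit(readLines(matrix_path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "feature_id") {
    stop_cs(
      paste0(matrix_path, " line 1: malformed header (expected `feature_id<TAB>sample...`)"),
      "parse"
    )
  }
  raw <- readr::read_tsv(
    matrix_path,
    col_types = readr::cols(
      feature_id = readr::col_character(),
      .default = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(
    as.numeric(ifelse(vals == "NA", NA, vals)),
    nrow = nrow(vals), dimnames = list(raw$feature_id, colnames(vals))
  ))
  bad <- which(is.na(num) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop_cs(
      paste0(
        matrix_path, " line ", bad[1, 1] + 1L, ": non-numeric cell `",
        vals[bad[1, , drop = FALSE]], "` (only `NA` marks missing values)"
      ),
      "parse"
    )
  }
  if (log2_transform) num <- log2(num + 1)
  ann <- readr::read_tsv(annotations_path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE)
  bio <- readr::read_tsv(biotypes_path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE)
  expression_dataset(dataset_id, num, ann, bio)
}

#' Write an expression dataset to a TSV file triple
#'
#' Inverse of [read_expression_dataset()]. Expression values are written
#' with up to 6 significant digits (the package's text formatting
#' contract); re-reading reproduces the written values bit-identically.
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,annotations_path,biotypes_path Output file paths.
#' @return Invisibly, the dataset.
#' @export
write_expression_dataset <- function(dataset, matrix_path, annotations_path, biotypes_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  txt <- matrix(
    ifelse(is.na(v), "NA", formatC(signif(v, 6), format = "g", digits = 6)),
    nrow = nrow(v), dimnames = dimnames(v)
  )
  df <- tibble(feature_id = rownames(v))
  df <- dplyr::bind_cols(df, as_tibble(txt))
  readr::write_tsv(df, matrix_path, progress = FALSE)
  readr::write_tsv(dataset$sample_annotations, annotations_path, progress = FALSE)
  readr::write_tsv(dataset$feature_biotypes, biotypes_path, progress = FALSE)
  invisible(dataset)
}

#' Define a severity contrast over a clinical feature
#'
#' A contrast splits samples into a "severe" group (e.g. `M1`, `MSI`,
#' mutated, advanced stage) and a "mild" reference group by listing the
#' categorical levels belonging to each side.
#'
#' @param clinical_feature Name of the annotation column.
#' @param severe_levels,mild_levels Non-overlapping, non-empty character
#'   vectors of levels.
#' @param label Free-text label (defaults to
#'   `"<feature>:<severe> vs <mild>"`).
#' @return A `contrast_spec` object.
#' @examples
#' contrast_spec("metastasis", "M1", "M0")
#' @export
contrast_spec <- function(clinical_feature, severe_levels, mild_levels, label = NULL) {
  stopifnot(is.character(clinical_feature), length(clinical_feature) == 1)
  severe_levels <- as.character(severe_levels)
  mild_levels <- as.character(mild_levels)
  if (!length(severe_levels) || !length(mild_levels)) {
    stop_cs("both severe_levels and mild_levels must be non-empty", "validation")
  }
  if (length(intersect(severe_levels, mild_levels))) {
    stop_cs("severe_levels and mild_levels must not overlap", "validation")
  }
  label <- label %||% paste0(
    clinical_feature, ":", paste(severe_levels, collapse = "/"),
    " vs ", paste(mild_levels, collapse = "/")
  )
  structure(
    list(
      clinical_feature = clinical_feature,
      severe_levels = severe_levels,
      mild_levels = mild_levels,
      label = label
    ),
    class = "contrast_spec"
  )
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat("<contrast_spec>", x$label, "\n")
  invisible(x)
}

#' Read a dataset collection from a manifest
#'
#' The manifest is a YAML (or JSON) list under key `datasets`, each entry
#' with `dataset_id`, `matrix`, `annotations`, `biotypes` (paths relative
#' to the manifest's directory).
#'
#' @param manifest_path Path to the manifest file.
#' @param log2_transform Passed to [read_expression_dataset()].
#' @return A named list of [expression_dataset()] objects.
#' @export
read_cohort <- function(manifest_path, log2_transform = FALSE) {
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$datasets) || !length(man$datasets)) {
    stop_cs("manifest has no `datasets` entries", "validation")
  }
  base <- dirname(manifest_path)
  out <- lapply(man$datasets, function(d) {
    paths <- file.path(base, c(d$matrix, d$annotations, d$biotypes))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop_cs(paste0("manifest references missing file(s): ", paste(missing, collapse = ", ")), "io")
    }
    read_expression_dataset(paths[1], paths[2], paths[3],
      dataset_id = d$dataset_id, log2_transform = log2_transform
    )
  })
  setNames(out, vapply(out, `[[`, "", "dataset_id"))
}
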
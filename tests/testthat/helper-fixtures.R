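# small in-code dataset builders used across test files

make_dataset <- function(values, severity = NULL, biotypes = NULL, id = "DS_T") {
  severity <- severity %||% rep(c("severe", "mild"), length.out = ncol(values))
  ann <- tibble::tibble(sample_id = colnames(values), severity = severity)
  biotypes <- biotypes %||% tibble::tibble(
    feature_id = rownames(values), biotype = "mRNA"
  )
  expression_dataset(id, values, ann, biotypes)
}

rand_matrix <- function(nf, ns, prefix = "G", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(nf * ns),
    nrow = nf,
    dimnames = list(sprintf("%s%02d", prefix, seq_len(nf)), sprintf("S%02d", seq_len(ns)))
  )
}

severity_contrast <- function() contrast_spec("severity", "severe", "mild")

`%||%` <- rlang::`%||%`
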
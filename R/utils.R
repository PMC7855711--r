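#' @noRd
stop_cs <- function(message, class, ...) {
  abort(message, class = c(paste0("cernascreen_error_", class), "cernascreen_error"), ...)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Each stage
#' (and, within a stage, each dataset) draws from its own sub-seed so that
#' adding a stage or a feature never perturbs draws made elsewhere. The
#' derivation is a small deterministic integer hash of the master seed, a
#' stage name and an index, kept below 2^31 - 1.
#'
#' @param seed Master seed (integer).
#' @param stage Character stage label, e.g. `"cohort"`.
#' @param index Non-negative integer index within the stage.
#' @return A single integer usable with [set.seed()].
#' @examples
#' sub_seed(7, "cohort", 1)
#' @export
sub_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (abs(as.double(seed)) * 48271 + h * 1299721 + as.double(index) * 69427) %% 2147483629
  as.integer(val) + 1L
}

# evaluate expr with a local RNG state seeded from `seed`
with_seed_cs <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# >= with tolerance so support fractions like 6/12 compare exactly against 0.5
frac_ge <- function(count, total, min_fraction) {
  count >= min_fraction * total - sqrt(.Machine$double.eps)
}
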
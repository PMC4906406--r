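#' Derive a reproducible sub-stream seed
#'
#' All stochastic stages draw their randomness from a stage-local seed
#' derived deterministically from one global seed and a stage label, so
#' adding or reordering stages never reshuffles unrelated randomness.
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1L, "controls")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(label)) {
    h <- (h * 31 + k) %% m
  }
  as.integer(h)
}

# stop with a classed validation error
abort_validation <- function(msg, class = "ctdnaprof_validation_error") {
  abort(msg, class = class)
}

# stop with a classed format error
abort_format <- function(msg) {
  abort(msg, class = "ctdnaprof_format_error")
}

# check required columns, error naming file context
check_columns <- function(df, required, context) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_format(sprintf(
      "%s: missing required column(s): %s",
      context, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
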
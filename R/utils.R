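#' Derive a stage-specific random seed from a global seed
#'
#' Stages of the pipeline each draw their own seed deterministically from the
#' single global seed and the stage name, so that any stage can be re-run in
#' isolation and reproduce the result of the full run.
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  # small multiplicative hash of the label folded into the global seed;
  # kept below 2^31 so it is a valid R integer seed
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(seed) * 7919 + h) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive scalar", name), call. = FALSE)
  }
}

assert_range <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2] ||
      x[1] < lower || x[2] > upper) {
    stop(sprintf("'%s' must be an ordered interval within [%s, %s]",
                 name, lower, upper), call. = FALSE)
  }
}

#' Geometric mean of strictly positive values
#'
#' @param values Numeric vector of strictly positive values.
#' @return `exp(mean(log(values)))`.
#' @examples
#' geometric_mean(c(10, 1000))  # 100
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0L) stop("geometric mean of an empty vector", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("geometric mean requires strictly positive finite values", call. = FALSE)
  }
  exp(mean(log(values)))
}
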
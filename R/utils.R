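#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows across all_of n
#' @importFrom stats fft rnorm runif median quantile sd var
NULL

# smallest power of two >= n
next_pow2 <- function(n) {
  2L^ceiling(log2(max(n, 1L)))
}

# validation helper: error message names the offending field
assert_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "cmcwave_validation_error")
  }
  invisible(TRUE)
}

assert_finite_signal <- function(x, arg = "x") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector", arg),
          class = "cmcwave_validation_error")
  }
  invisible(TRUE)
}

# evaluate `code` under a temporary RNG state seeded with `seed`;
# seed = NULL leaves the RNG stream alone
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# deterministically derive k child seeds (< 2^31) from one master seed
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, k))
}

# trapezoidal integral on a (possibly non-uniform) grid
trapz_integral <- function(x, y) {
  if (length(x) < 2L) return(0)
  pracma::trapz(x, y)
}
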
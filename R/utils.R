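deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Round half away from zero
#'
#' Commercial rounding, as used when printing percentage tables: exact halves
#' move away from zero (`round_half_away(87.5) == 88`), unlike base R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5))   # 1  2 -1
#' round_half_away(87.356)              # 87
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "photocolony_input_error")
}

stop_parse <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("photocolony_parse_error", "photocolony_input_error"))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number", name)
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    stop_input("`%s` = %g is outside its valid range", name, x)
  }
  invisible(x)
}

# run expr under a private, restored RNG stream; NULL seed = use current stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
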
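#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (half-up), the
#' convention used when displaying percentages in clinical summary tables.
#' Base R's `round()` rounds half to even, which gives e.g. `round(0.5) == 0`.
#'
#' @param x numeric vector (non-negative values expected for percentages).
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(83.72) # 84
#' round_half_up(11.5)  # 12
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("bilinorm_domain_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("bilinorm_validation_error", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("bilinorm_parse_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
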
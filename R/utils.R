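#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used for all
#' reported percentages and case counts (base [round()] rounds half to even).
#' Applied at report time only; internal arithmetic is never rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_away(0.25, 1)   # 0.3
#' round_half_away(-0.25, 1)  # -0.3
#' round_half_away(32.15160, 1)
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# shared sex literals
.sexes <- c("male", "female")

# reserved level id marking the reference exposure level
.ref_level <- "ref"

# reserved factor ids in attribution tables
.combined_id <- "__combined__"

is_count <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

is_year <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 1900 & x <= 2100 & abs(x - round(x)) < 1e-8
}

`%||%` <- function(a, b) if (is.null(a)) b else a
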
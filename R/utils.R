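# Shared constants and small numeric helpers.

POPULATIONS <- c("animal", "human")
DESIGNS <- c("baseline", "treatment")
STRATA <- c("animal_baseline", "human_baseline", "animal_treatment", "human_treatment")
RESPONSE_DOMAINS <- list(
  YN = c("Y", "N"),
  YNI = c("Y", "N", "I"),
  LUH = c("L", "U", "H"),
  LUHI = c("L", "U", "H", "I")
)

stratum_label <- function(population, design) paste(population, design, sep = "_")

#' Round half away from zero
#'
#' Fixed-point rounding where .5 always rounds up, the convention used for
#' displayed percentages (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(26.55, 1) # 26.6
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Display percentage from a count and a denominator
#'
#' Computes `100 * num / den` rounded half-up to one decimal, the display
#' convention used throughout the package's summary tables.
#'
#' @param num Numerator count.
#' @param den Denominator count.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @export
#' @examples
#' percent(954, 7872) # 12.1
percent <- function(num, den, digits = 1) {
  round_half_up(100 * num / den, digits)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
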
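#' Standardize an air-dry grain weight to 14% moisture content
#'
#' Grain weights measured after air drying are conventionally reported
#' at a common 14% moisture content. The dry matter is preserved and
#' re-expressed: `weight * (1 - moisture) / (1 - 0.14)`.
#'
#' @param weight Air-dry 100-grain weight (g).
#' @param moisture Moisture fraction of the weighed sample, in [0, 1).
#' @return Weight at 14% moisture (g).
#' @export
#' @examples
#' moisture_standardize(32, 0.14) # already at target: unchanged
#' moisture_standardize(28, 0)    # bone dry: 28 / 0.86
moisture_standardize <- function(weight, moisture) {
  if (any(moisture < 0) || any(moisture >= 1)) {
    rlang::abort("`moisture` must be a fraction in [0, 1)")
  }
  weight * (1 - moisture) / 0.86
}

#' Crude protein from total nitrogen
#'
#' The standard nitrogen-to-protein conversion: crude protein (%) is
#' total nitrogen (%) times 6.25.
#'
#' @param total_n_pct Total nitrogen content, percent, non-negative.
#' @return Crude protein content, percent.
#' @export
#' @examples
#' crude_protein_from_n(1.44) # 9%
crude_protein_from_n <- function(total_n_pct) {
  if (any(total_n_pct < 0)) rlang::abort("total nitrogen must be >= 0")
  6.25 * total_n_pct
}

#' Total nutrient delivered by a fertilizer programme
#'
#' Sums `rate * fraction` over all applications of nutrient-bearing
#' fertilizers, e.g. pure N from diammonium phosphate (18% N) plus
#' split urea dressings (46% N). Reported to one decimal, the
#' convention for kg/ha nutrient accounting.
#'
#' @param applications Data frame with columns `rate` (product kg/ha,
#'   >= 0) and `fraction` (nutrient mass fraction of product, in
#'   [0, 1]). Zero rows give 0.
#' @return Total nutrient, kg/ha, rounded to 1 decimal.
#' @export
#' @examples
#' nutrient_total(data.frame(rate = c(375, 345), fraction = c(0.18, 0.46)))
nutrient_total <- function(applications) {
  stopifnot(is.data.frame(applications))
  if (!nrow(applications)) return(0)
  if (!all(c("rate", "fraction") %in% names(applications))) {
    rlang::abort("`applications` must have columns `rate` and `fraction`")
  }
  if (any(applications$rate < 0)) rlang::abort("rates must be >= 0")
  if (any(applications$fraction < 0) || any(applications$fraction > 1)) {
    rlang::abort("nutrient fractions must lie in [0, 1]")
  }
  round(sum(applications$rate * applications$fraction), 1)
}
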
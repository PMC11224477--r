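unit_cols <- function(data) {
  intersect(c("year", "tillage", "variety", "replicate"), names(data))
}

#' Empirical filling rates from successive dry-weight samples
#'
#' For each consecutive pair of samples within a series, computes the
#' mean filling rate over the interval,
#' \eqn{G = (W_{current} - W_{previous}) / D}, where `D` is the number
#' of days between the samples. The rate is placed at the interval
#' midpoint `t_mid`, which centres the secant estimate of the
#' derivative. If any of the grouping columns `year`, `tillage`,
#' `variety`, `replicate` are present, rates are computed within each
#' unit.
#'
#' @param data A data frame with numeric columns `dap` (days after
#'   pollination) and `weight` (100-grain dry weight, g), optionally
#'   plus unit columns.
#' @return A tibble with the unit columns plus `t_mid`, `rate`
#'   (g/d) and `decreasing` (`TRUE` where the weight dropped between
#'   samples; such points are flagged, never dropped).
#' @export
#' @examples
#' filling_rates(data.frame(dap = c(15, 20, 25), weight = c(7, 12, 16)))
filling_rates <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("dap", "weight") %in% names(data))) {
    rlang::abort("`data` must have columns `dap` and `weight`")
  }
  by <- unit_cols(data)
  rate_one <- function(d) {
    d <- dplyr::arrange(d, .data$dap)
    if (anyDuplicated(d$dap)) {
      rlang::abort("duplicate `dap` values within a series",
                   class = "grainfill_duplicate_dap")
    }
    if (nrow(d) < 2) {
      rlang::abort("need at least 2 observations per series to compute rates")
    }
    dt <- diff(d$dap)
    dw <- diff(d$weight)
    tibble::tibble(
      t_mid = (d$dap[-1] + d$dap[-nrow(d)]) / 2,
      rate = dw / dt,
      decreasing = dw < 0
    )
  }
  out <- if (length(by)) {
    dplyr::reframe(dplyr::group_by(data, dplyr::across(dplyr::all_of(by))),
                   rate_one(dplyr::pick(dplyr::everything())))
  } else {
    rate_one(data)
  }
  if (any(out$decreasing)) {
    rlang::warn(paste0(sum(out$decreasing),
                       " interval(s) with decreasing weight flagged"))
  }
  tibble::as_tibble(out)
}

#' Peak filling rate from a quadratic fit to empirical rates
#'
#' Empirical filling-rate series typically rise then fall over the
#' sampling window; a concave quadratic
#' \eqn{rate = a + b t + c t^2} fitted by ordinary least squares
#' summarises that trend, and its vertex estimates the peak rate and
#' its timing: `peak_time = -b/(2c)`, `peak_rate = a - b^2/(4c)`.
#'
#' @param rates A data frame with columns `t_mid` and `rate`, e.g. from
#'   [filling_rates()]; at least 3 points. If unit columns are present
#'   the fit is done per unit.
#' @return A tibble with the unit columns plus `peak_time` (d) and
#'   `peak_rate` (g/d).
#' @export
#' @examples
#' r <- data.frame(t_mid = seq(15, 50, 5),
#'                 rate = 2 - 0.01 * (seq(15, 50, 5) - 30)^2)
#' quadratic_peak(r)
quadratic_peak <- function(rates) {
  stopifnot(is.data.frame(rates))
  if (!all(c("t_mid", "rate") %in% names(rates))) {
    rlang::abort("`rates` must have columns `t_mid` and `rate`")
  }
  by <- unit_cols(rates)
  peak_one <- function(d) {
    if (nrow(d) < 3) {
      rlang::abort("need at least 3 rate points for a quadratic fit")
    }
    co <- stats::coef(stats::lm(rate ~ t_mid + I(t_mid^2), data = d))
    a <- co[[1]]; b <- co[[2]]; cc <- co[[3]]
    if (!is.finite(cc) || cc >= 0) {
      rlang::abort(
        "quadratic fit is not concave: no interior rate peak identified",
        class = "grainfill_no_peak"
      )
    }
    tibble::tibble(peak_time = -b / (2 * cc), peak_rate = a - b^2 / (4 * cc))
  }
  out <- if (length(by)) {
    dplyr::reframe(dplyr::group_by(rates, dplyr::across(dplyr::all_of(by))),
                   peak_one(dplyr::pick(dplyr::everything())))
  } else {
    peak_one(rates)
  }
  tibble::as_tibble(out)
}
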
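#' Deterministic starting values for the logistic fit
#'
#' Seeds the nonlinear fit by linearizing the model: with a provisional
#' asymptote \eqn{A_0 = 1.05 \times \max(W)}, the logistic satisfies
#' \eqn{\ln(A_0/W - 1) = \ln B - C t}, so an ordinary least-squares
#' line through the transformed points (restricted to
#' \eqn{0 < W < A_0}) yields \eqn{C_0} from the slope and \eqn{B_0}
#' from the intercept. Purely deterministic, so repeated fits of the
#' same series always start (and end) at the same place.
#'
#' @param dap Sampling times, days after pollination.
#' @param weight 100-grain dry weights (g), all positive.
#' @return Named numeric vector `c(A, B, C)`.
#' @export
#' @examples
#' t <- seq(15, 55, 5)
#' init_logistic(t, logistic_weight(t, 30, 40, 0.15))
init_logistic <- function(dap, weight) {
  if (length(dap) != length(weight)) {
    rlang::abort("`dap` and `weight` must have equal length")
  }
  if (length(dap) < 3) {
    rlang::abort("need at least 3 points to initialize the logistic fit")
  }
  if (any(weight <= 0)) rlang::abort("weights must be positive")
  A0 <- 1.05 * max(weight)
  keep <- weight > 0 & weight < A0
  if (sum(keep) < 3) {
    rlang::abort("too few points below the provisional asymptote to linearize")
  }
  z <- log(A0 / weight[keep] - 1)
  co <- stats::coef(stats::lm(z ~ dap[keep]))
  C0 <- -co[[2]]
  if (!is.finite(C0) || C0 <= 0) {
    rlang::abort(
      "degenerate series: linearized slope implies non-positive rate parameter",
      class = "grainfill_degenerate_series"
    )
  }
  c(A = A0, B = unname(exp(co[[1]])), C = unname(C0))
}

#' Goodness of fit of predictions against observations
#'
#' `r_squared = 1 - SS_res/SS_tot` with `SS_tot` taken about the mean
#' of the observations (the mean-only model on the same points), and
#' `rmse = sqrt(SS_res/n)`.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A list with elements `r_squared` and `rmse`.
#' @export
goodness_of_fit <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    rlang::abort("zero total variance: r-squared is undefined",
                 class = "grainfill_zero_variance")
  }
  ss_res <- sum((observed - predicted)^2)
  list(r_squared = 1 - ss_res / ss_tot,
       rmse = sqrt(ss_res / length(observed)))
}

#' Fit the logistic filling model to one observed series
#'
#' Bounded Levenberg--Marquardt least squares (via
#' [minpack.lm::nlsLM()]) of \eqn{W = A/(1 + B e^{-Ct})} to an observed
#' filling series, started from the deterministic [init_logistic()]
#' values; no random restarts, so the fit is reproducible from the data
#' alone. All three parameters are constrained positive. A series the
#' optimizer cannot fit (flat weights, non-convergence within
#' `max_iter`) is returned with `converged = FALSE`, never silently
#' dropped or errored mid-pipeline.
#'
#' @param data Data frame with numeric columns `dap` and `weight`
#'   (one series); at least 4 points.
#' @param tol Relative tolerance on cost decrease.
#' @param max_iter Iteration cap.
#' @return An object of class `grainfill_fit`: a list with elements
#'   `params` (named vector A, B, C), `r_squared`, `rmse`, `n_obs`,
#'   `converged`, `n_iter`, `data`, and the underlying `nls` object
#'   (`fit`, `NULL` when the optimizer failed). Use [tidy()] /
#'   [glance()] for tibble summaries.
#' @export
#' @examples
#' t <- seq(15, 55, 5)
#' d <- data.frame(dap = t, weight = logistic_weight(t, 30, 40, 0.15))
#' fit <- fit_logistic(d)
#' glance(fit)
fit_logistic <- function(data, tol = 1e-10, max_iter = 200) {
  stopifnot(is.data.frame(data))
  if (!all(c("dap", "weight") %in% names(data))) {
    rlang::abort("`data` must have columns `dap` and `weight`")
  }
  if (nrow(data) < 4) {
    rlang::abort("need at least 4 points to fit 3 logistic parameters",
                 class = "grainfill_too_few_points")
  }
  data <- dplyr::arrange(tibble::as_tibble(data[c("dap", "weight")]),
                         .data$dap)
  failed <- function(start) {
    structure(
      list(params = c(A = NA_real_, B = NA_real_, C = NA_real_),
           r_squared = NA_real_, rmse = NA_real_, n_obs = nrow(data),
           converged = FALSE, n_iter = 0L, data = data, fit = NULL),
      class = "grainfill_fit"
    )
  }
  start <- tryCatch(init_logistic(data$dap, data$weight),
                    error = function(e) NULL)
  if (is.null(start)) return(failed())
  fit <- tryCatch(
    minpack.lm::nlsLM(
      weight ~ A / (1 + B * exp(-C * dap)),
      data = data,
      start = as.list(start),
      lower = c(1e-10, 1e-10, 1e-10),
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed())
  params <- stats::coef(fit)
  gof <- goodness_of_fit(data$weight, stats::fitted(fit))
  structure(
    list(params = params,
         r_squared = gof$r_squared,
         rmse = gof$rmse,
         n_obs = nrow(data),
         converged = isTRUE(fit$convInfo$isConv),
         n_iter = fit$convInfo$finIter,
         data = data,
         fit = fit),
    class = "grainfill_fit"
  )
}

#' @export
print.grainfill_fit <- function(x, ...) {
  cat("Logistic grain-filling fit (", x$n_obs, " points)\n", sep = "")
  if (all(is.finite(x$params))) {
    cat(sprintf("  A = %.4g g, B = %.4g, C = %.4g /d\n",
                x$params[["A"]], x$params[["B"]], x$params[["C"]]))
    cat(sprintf("  r^2 = %.6f, rmse = %.4g g, converged: %s\n",
                x$r_squared, x$rmse, x$converged))
  } else {
    cat("  fit failed (converged = FALSE)\n")
  }
  invisible(x)
}

#' @export
predict.grainfill_fit <- function(object, t = NULL, ...) {
  if (is.null(object$fit)) rlang::abort("cannot predict from a failed fit")
  if (is.null(t)) t <- object$data$dap
  p <- object$params
  logistic_weight(t, p[["A"]], p[["B"]], p[["C"]])
}

#' Tidiers for logistic filling fits
#'
#' `tidy()` returns one row per parameter (with asymptotic standard
#' errors when available); `glance()` a one-row fit summary.
#'
#' @param x A `grainfill_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy grainfill_fit
#' @export
tidy.grainfill_fit <- function(x, ...) {
  se <- rep(NA_real_, 3)
  if (!is.null(x$fit)) {
    se <- tryCatch(sqrt(diag(stats::vcov(x$fit))), error = function(e) se)
  }
  tibble::tibble(term = c("A", "B", "C"),
                 estimate = unname(x$params),
                 std.error = unname(se))
}

#' @rdname tidy.grainfill_fit
#' @method glance grainfill_fit
#' @export
glance.grainfill_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, rmse = x$rmse,
                 n.obs = x$n_obs, converged = x$converged,
                 n.iter = x$n_iter)
}

#' Fit logistic curves across all units of a trial
#'
#' Fits each experimental unit's series independently (the default), or
#' fits treatment-mean trajectories (weights averaged over replicates
#' at each sampling date) when `mode = "treatment_mean"` -- both
#' conventions are in use for filling-curve analysis and published
#' tables rarely say which was applied.
#'
#' @param data Long filling data with columns `dap`, `weight` and any
#'   of `year`, `tillage`, `variety`, `replicate`.
#' @param mode `"replicate"` or `"treatment_mean"`.
#' @inheritParams fit_logistic
#' @return A tibble with one row per fitted series: the unit columns
#'   plus `A`, `B`, `C`, `r_squared`, `rmse`, `n_obs`, `converged`.
#' @export
fit_filling <- function(data, mode = c("replicate", "treatment_mean"),
                        tol = 1e-10, max_iter = 200) {
  mode <- match.arg(mode)
  by <- unit_cols(data)
  if (mode == "treatment_mean") {
    by <- setdiff(by, "replicate")
    data <- dplyr::summarise(
      dplyr::group_by(data, dplyr::across(dplyr::all_of(c(by, "dap")))),
      weight = mean(.data$weight), .groups = "drop"
    )
  }
  fit_one <- function(d) {
    f <- fit_logistic(d, tol = tol, max_iter = max_iter)
    tibble::tibble(A = f$params[["A"]], B = f$params[["B"]],
                   C = f$params[["C"]], r_squared = f$r_squared,
                   rmse = f$rmse, n_obs = f$n_obs, converged = f$converged)
  }
  out <- if (length(by)) {
    dplyr::reframe(dplyr::group_by(data, dplyr::across(dplyr::all_of(by))),
                   fit_one(dplyr::pick(dplyr::everything())))
  } else {
    fit_one(data)
  }
  tibble::as_tibble(out)
}
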
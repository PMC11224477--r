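#' Phase-boundary offset constants for the logistic filling model
#'
#' The three-phase partition of a logistic filling trajectory
#' \eqn{W = A / (1 + B e^{-Ct})} hinges on two dimensionless offsets:
#' the peak-filling period starts and ends where the filling-rate curve
#' changes concavity (the roots of \eqn{d^3W/dt^3 = 0}), at
#' \eqn{t = (\ln B \mp k_1)/C} with \eqn{k_1 = \ln(2+\sqrt{3})}; and the
#' effective filling period ends where the weight reaches 99\% of the
#' asymptote, at \eqn{t = (\ln B + k_3)/C} with \eqn{k_3 = \ln 99}.
#'
#' Agronomic practice usually carries these as the rounded decimals
#' 1.317 and 4.59512, and printed phase tables are computed with them.
#' `"printed"` (the default) uses the rounded values so results
#' reproduce conventional tables digit for digit; `"exact"` uses
#' full-precision \eqn{\ln(2+\sqrt 3)} and \eqn{\ln 99}.
#'
#' @param constants `"printed"` or `"exact"`.
#' @return Named numeric vector with elements `k1` and `k3`.
#' @seealso [derive_phase_offsets()] for recovering both constants
#'   numerically from the model itself.
#' @export
#' @examples
#' phase_offsets()
#' phase_offsets("exact")
phase_offsets <- function(constants = c("printed", "exact")) {
  constants <- match.arg(constants)
  switch(constants,
    printed = c(k1 = 1.317, k3 = 4.59512),
    exact   = c(k1 = log(2 + sqrt(3)), k3 = log(99))
  )
}

check_logistic_params <- function(A, B, C, call = rlang::caller_env()) {
  if (any(!is.finite(A)) || any(!is.finite(B)) || any(!is.finite(C))) {
    rlang::abort("logistic parameters A, B, C must be finite", call = call)
  }
  if (any(A <= 0) || any(B <= 0) || any(C <= 0)) {
    rlang::abort(
      "invalid logistic parameters: A, B and C must all be positive",
      class = "grainfill_invalid_params", call = call
    )
  }
  invisible(TRUE)
}

#' Logistic grain-filling model and its derivatives
#'
#' The 100-grain dry weight after flowering is modelled as
#' \eqn{W(t) = A / (1 + B e^{-Ct})}, with `t` in days after flowering
#' (flowering day is t = 0), `A` the asymptotic 100-grain weight (g),
#' and `B`, `C` shape parameters (`C` in 1/d). `logistic_weight()`
#' evaluates the weight, `logistic_rate()` the instantaneous filling
#' rate \eqn{dW/dt = ABC e^{-Ct} / (1 + B e^{-Ct})^2} (g/d), and
#' `logistic_accel()` the second derivative (g/d^2). The rate is
#' maximal at \eqn{t = \ln B / C} where it equals \eqn{AC/4}.
#'
#' @param t Days after flowering; any finite numeric, vectorized.
#' @param A,B,C Logistic parameters, all strictly positive.
#' @return Numeric vector of weights (g), rates (g/d) or accelerations.
#' @export
#' @examples
#' logistic_weight(25, A = 30, B = 40, C = 0.15)
#' logistic_rate(log(40) / 0.15, A = 30, B = 40, C = 0.15) # = 30*0.15/4
logistic_weight <- function(t, A, B, C) {
  check_logistic_params(A, B, C)
  A / (1 + B * exp(-C * t))
}

#' @rdname logistic_weight
#' @export
logistic_rate <- function(t, A, B, C) {
  check_logistic_params(A, B, C)
  e <- B * exp(-C * t)
  A * C * e / (1 + e)^2
}

#' @rdname logistic_weight
#' @export
logistic_accel <- function(t, A, B, C) {
  check_logistic_params(A, B, C)
  p <- 1 / (1 + B * exp(-C * t))
  A * C^2 * p * (1 - p) * (1 - 2 * p)
}

# third derivative of W; its roots delimit the peak filling period
logistic_jerk <- function(t, A, B, C) {
  p <- 1 / (1 + B * exp(-C * t))
  A * C^3 * p * (1 - p) * (1 - 6 * p + 6 * p^2)
}

#' Recover the phase-offset constants from the model numerically
#'
#' Locates, by root bracketing on the model derivatives (not from any
#' stored constant), the two dimensionless offsets that define the
#' filling phases: `k1` from the earlier root of \eqn{d^3W/dt^3 = 0}
#' expressed as \eqn{t_1 = (\ln B - k_1)/C}, and `k3` from the solution
#' of \eqn{W(t) = 0.99 A} expressed as \eqn{t_3 = (\ln B + k_3)/C}.
#' Both are parameter-free; `A`, `B`, `C` only set the scale of the
#' search interval and default to a typical maize fit.
#'
#' @param A,B,C Logistic parameters used for the numeric search.
#' @param tol Root-finding tolerance on t (d).
#' @return A tibble with columns `constant` (`"k1"`, `"k3"`) and
#'   `value`; `k1` converges to \eqn{\ln(2+\sqrt 3) \approx 1.317} and
#'   `k3` to \eqn{\ln 99 \approx 4.59512}.
#' @export
#' @examples
#' derive_phase_offsets()
derive_phase_offsets <- function(A = 30, B = 40, C = 0.15, tol = 1e-12) {
  check_logistic_params(A, B, C)
  t_mid <- log(B) / C
  # earlier concavity change of the rate curve lies in (0, t_mid)
  r1 <- stats::uniroot(
    function(t) logistic_jerk(t, A, B, C),
    lower = t_mid - 10 / C, upper = t_mid - 1e-9 / C, tol = tol
  )$root
  r3 <- stats::uniroot(
    function(t) logistic_weight(t, A, B, C) - 0.99 * A,
    lower = t_mid, upper = t_mid + 20 / C, tol = tol
  )$root
  tibble::tibble(
    constant = c("k1", "k3"),
    value = c(log(B) - C * r1, C * r3 - log(B))
  )
}

#' Partition a logistic filling trajectory into three phases
#'
#' Splits the filling process described by fitted logistic parameters
#' into the gradual, fast and slow increase periods. The peak period
#' runs from \eqn{t_1 = (\ln B - k_1)/C} to \eqn{t_2 = (\ln B + k_1)/C}
#' (the concavity changes of the rate curve), and the effective filling
#' period ends at \eqn{t_3 = (\ln B + k_3)/C}, where the weight reaches
#' 99\% of `A`. Phase durations are `T1 = t1`, `T2 = t2 - t1`,
#' `T3 = t3 - t2`; phase gains `w1 = W1 - W0`, `w2 = W2 - W1`,
#' `w3 = W3 - W2` (with `W0 = A/(1+B)`, the model weight on flowering
#' day, and `Wi = W(ti)`); and mean phase rates `Vi = wi / Ti`. The
#' maximum instantaneous rate `G_max = A*C/4` occurs at
#' `t_max = ln(B)/C`.
#'
#' Two structural identities follow from the closed forms and hold for
#' every parameter triple: `T3/T2` and `V2/V3` are parameter-free
#' constants (about 1.2446 and 3.570), so any treatment shifts `V2`
#' and `V3` (and `T2`, `T3`) by identical percentages under this model.
#'
#' @param params A data frame with numeric columns `A`, `B`, `C`
#'   (one row per fitted unit; other columns are carried through).
#' @param constants Passed to [phase_offsets()].
#' @return The input tibble with columns `t1,t2,t3,T1,T2,T3,
#'   W0,W1,W2,W3,w1,w2,w3,V1,V2,V3,t_max,G_max` appended.
#' @export
#' @examples
#' partition_phases(data.frame(A = 30, B = 40, C = 0.15))
partition_phases <- function(params, constants = c("printed", "exact")) {
  stopifnot(is.data.frame(params))
  missing_cols <- setdiff(c("A", "B", "C"), names(params))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "`params` must have columns A, B, C; missing: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  k <- phase_offsets(constants)
  A <- params$A; B <- params$B; C <- params$C
  check_logistic_params(A, B, C)
  if (any(log(B) <= k[["k1"]])) {
    rlang::abort(
      paste0(
        "degenerate partition: ln(B) <= ", format(k[["k1"]]),
        " makes the gradual phase start at or before flowering (t1 <= 0)"
      ),
      class = "grainfill_degenerate_partition"
    )
  }
  t1 <- (log(B) - k[["k1"]]) / C
  t2 <- (log(B) + k[["k1"]]) / C
  t3 <- (log(B) + k[["k3"]]) / C
  W0 <- A / (1 + B)
  W1 <- logistic_weight(t1, A, B, C)
  W2 <- logistic_weight(t2, A, B, C)
  W3 <- logistic_weight(t3, A, B, C)
  out <- tibble::as_tibble(params)
  out$t1 <- t1; out$t2 <- t2; out$t3 <- t3
  out$T1 <- t1; out$T2 <- t2 - t1; out$T3 <- t3 - t2
  out$W0 <- W0; out$W1 <- W1; out$W2 <- W2; out$W3 <- W3
  out$w1 <- W1 - W0; out$w2 <- W2 - W1; out$w3 <- W3 - W2
  out$V1 <- out$w1 / out$T1
  out$V2 <- out$w2 / out$T2
  out$V3 <- out$w3 / out$T3
  out$t_max <- log(B) / C
  out$G_max <- A * C / 4
  out
}
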
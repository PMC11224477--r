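numeric_matrix <- function(data, min_rows = 3) {
  stopifnot(is.data.frame(data))
  x <- as.matrix(dplyr::select(data, dplyr::where(is.numeric)))
  if (nrow(x) < min_rows) {
    rlang::abort(paste0("need at least ", min_rows, " rows"))
  }
  if (anyNA(x)) rlang::abort("missing cells are not allowed")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(paste0("zero-variance column(s): ",
                        paste(colnames(x)[sds == 0], collapse = ", ")),
                 class = "grainfill_zero_variance")
  }
  x
}

#' Pearson correlation matrix with two-sided p-values
#'
#' Pairwise Pearson correlations over the numeric columns of a feature
#' table (e.g. 100-grain dry weight, per-phase filling rates and
#' durations, quality traits). p-values come from the exact null
#' distribution via \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n-2 degrees of
#' freedom, two-sided, unadjusted for multiplicity.
#'
#' @param data Data frame; non-numeric columns are ignored.
#' @return An object of class `grainfill_cor`: list with symmetric
#'   matrices `r` and `p` (unit diagonal, `p` diagonal `NA`) and the
#'   row count `n`. `tidy()` gives the lower triangle in long form.
#' @export
#' @examples
#' pearson_matrix(data.frame(x = 1:4, y = c(1, 2, 3, 5)))
pearson_matrix <- function(data) {
  x <- numeric_matrix(data, min_rows = 3)
  n <- nrow(x)
  r <- stats::cor(x)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "grainfill_cor")
}

#' @export
print.grainfill_cor <- function(x, digits = 3, ...) {
  cat("Pearson correlations (n =", x$n, ")\n")
  print(round(x$r, digits))
  invisible(x)
}

#' @rdname pearson_matrix
#' @param x A `grainfill_cor`.
#' @param ... Unused.
#' @method tidy grainfill_cor
#' @export
tidy.grainfill_cor <- function(x, ...) {
  nm <- colnames(x$r)
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = nm[idx[, 2]], var2 = nm[idx[, 1]],
    estimate = x$r[idx], p.value = x$p[idx]
  )
}

#' Principal component analysis on the correlation matrix
#'
#' Columns are standardized internally (correlation PCA), so each
#' variable contributes unit variance and the eigenvalues sum to the
#' number of variables; the explained-variance fraction of component i
#' is \eqn{\lambda_i / \sum \lambda}. For a reproducible orientation,
#' each component is sign-fixed so that its largest-magnitude loading
#' is positive.
#'
#' @param data Data frame of numeric feature columns, >= 3 rows.
#' @return Class `grainfill_pca`: list with `loadings` (variables x
#'   components), `explained` (fractions), `sdev`, and `scores`
#'   (standardized data projected on the loadings). `tidy()` returns
#'   loadings in long form; `glance()` the explained fractions.
#' @export
#' @examples
#' pca_correlation(data.frame(a = rnorm(10), b = rnorm(10)))
pca_correlation <- function(data) {
  x <- numeric_matrix(data, min_rows = 3)
  z <- scale(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  load <- eg$vectors
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  structure(
    list(loadings = load,
         explained = lam / sum(lam),
         sdev = sqrt(lam),
         scores = z %*% load),
    class = "grainfill_pca"
  )
}

#' @export
print.grainfill_pca <- function(x, ...) {
  cat("Correlation-matrix PCA\n")
  ev <- round(100 * x$explained, 1)
  cat("Explained variance (%):", paste(ev, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca_correlation
#' @param x A `grainfill_pca`.
#' @param ... Unused.
#' @method tidy grainfill_pca
#' @export
tidy.grainfill_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @rdname pca_correlation
#' @method glance grainfill_pca
#' @export
glance.grainfill_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$explained)),
                 explained = x$explained,
                 cumulative = cumsum(x$explained))
}

partial_f_p <- function(fit_small, fit_big) {
  rss0 <- sum(stats::resid(fit_small)^2)
  rss1 <- sum(stats::resid(fit_big)^2)
  df1 <- stats::df.residual(fit_big)
  if (df1 < 1 || rss1 <= 0) return(c(f = Inf, p = 0))
  f <- (rss0 - rss1) / (rss1 / df1)
  c(f = f, p = stats::pf(f, 1, df1, lower.tail = FALSE))
}

#' Stepwise multiple regression on partial-F thresholds
#'
#' Classical forward-with-backward-elimination stepwise selection as
#' used in agronomic quality analyses: at each step the candidate with
#' the smallest partial-F p-value enters if that p-value is at most
#' `sle`; then any included variable whose partial-F p-value exceeds
#' `sls` is removed (worst first); this repeats until the model is
#' stable. The defaults `sle = sls = 0.15` follow the long-standing
#' stepwise convention, under which terms with p around 0.08 are
#' retained in the final model. Exactly collinear candidates are
#' skipped with a warning; if a previously visited model recurs, the
#' procedure stops with a diagnostic rather than cycling.
#'
#' @param data Data frame holding response and candidate predictors.
#' @param response Name of the response column.
#' @param predictors Candidate predictor names (default: all other
#'   numeric columns).
#' @param sle Entry threshold on the partial-F p-value.
#' @param sls Stay threshold.
#' @param forward_only If `TRUE`, skip the elimination sweep.
#' @return Class `grainfill_stepwise`: list with the final `lm` fit
#'   (`model`, `NULL` if no variable entered), `selected`, a `steps`
#'   log, and the thresholds. `tidy()` mirrors the conventional report:
#'   term, coefficient, standard error, F-value (the squared t) and
#'   Pr>F; `glance()` gives R-squared and sizes.
#' @export
#' @examples
#' d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
#' d$y <- 2 * d$x1 + rnorm(30, sd = 0.1)
#' stepwise_regression(d, "y")
stepwise_regression <- function(data, response,
                                predictors = NULL,
                                sle = 0.15, sls = 0.15,
                                forward_only = FALSE) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(dplyr::select(data, dplyr::where(is.numeric))), response
    )
  }
  if (nrow(data) < length(predictors) + 2) {
    rlang::abort("need at least p + 2 rows for p candidate predictors")
  }
  fit_on <- function(vars) {
    fml <- if (length(vars)) {
      stats::reformulate(vars, response = response)
    } else {
      stats::as.formula(paste(response, "~ 1"))
    }
    stats::lm(fml, data = data)
  }
  selected <- character()
  steps <- list()
  seen <- character()
  repeat {
    key <- paste(sort(selected), collapse = "+")
    if (key %in% seen) {
      rlang::warn("stepwise selection revisited a model; stopping")
      break
    }
    seen <- c(seen, key)
    changed <- FALSE
    # forward step
    candidates <- setdiff(predictors, selected)
    if (length(candidates)) {
      base_fit <- fit_on(selected)
      entry <- purrr::map(candidates, function(v) {
        big <- fit_on(c(selected, v))
        if (anyNA(stats::coef(big))) return(NULL) # aliased: collinear
        partial_f_p(base_fit, big)
      })
      drop_collinear <- candidates[purrr::map_lgl(entry, is.null)]
      if (length(drop_collinear)) {
        rlang::warn(paste0("skipping exactly collinear candidate(s): ",
                           paste(drop_collinear, collapse = ", ")))
        predictors <- setdiff(predictors, drop_collinear)
      }
      keep <- !purrr::map_lgl(entry, is.null)
      candidates <- candidates[keep]
      entry <- entry[keep]
      if (length(candidates)) {
        ps <- purrr::map_dbl(entry, "p")
        best <- which.min(ps)
        if (ps[best] <= sle) {
          selected <- c(selected, candidates[best])
          steps[[length(steps) + 1]] <- tibble::tibble(
            action = "add", term = candidates[best], p.value = ps[best]
          )
          changed <- TRUE
        }
      }
    }
    # backward sweep
    if (!forward_only) {
      repeat {
        if (!length(selected)) break
        full <- fit_on(selected)
        ps <- purrr::map_dbl(selected, function(v) {
          partial_f_p(fit_on(setdiff(selected, v)), full)[["p"]]
        })
        worst <- which.max(ps)
        if (ps[worst] > sls) {
          steps[[length(steps) + 1]] <- tibble::tibble(
            action = "drop", term = selected[worst], p.value = ps[worst]
          )
          selected <- selected[-worst]
          changed <- TRUE
        } else break
      }
    }
    if (!changed) break
  }
  model <- if (length(selected)) fit_on(selected) else NULL
  structure(
    list(model = model, selected = selected,
         steps = dplyr::bind_rows(steps), sle = sle, sls = sls,
         response = response, null_model = fit_on(character())),
    class = "grainfill_stepwise"
  )
}

#' @export
print.grainfill_stepwise <- function(x, ...) {
  cat("Stepwise regression of", x$response,
      sprintf("(sle = %g, sls = %g)\n", x$sle, x$sls))
  if (!length(x$selected)) {
    cat("  no variable entered the model\n")
  } else {
    print(tidy(x))
  }
  invisible(x)
}

#' @rdname stepwise_regression
#' @param x A `grainfill_stepwise`.
#' @param ... Unused.
#' @method tidy grainfill_stepwise
#' @export
tidy.grainfill_stepwise <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric()))
  }
  sm <- stats::summary.lm(x$model)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]^2), # partial F on 1 df per term
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @rdname stepwise_regression
#' @method glance grainfill_stepwise
#' @export
glance.grainfill_stepwise <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(r.squared = 0, n.selected = 0L,
                          n.obs = stats::nobs(x$null_model)))
  }
  sm <- stats::summary.lm(x$model)
  tibble::tibble(r.squared = sm$r.squared,
                 n.selected = length(x$selected),
                 n.obs = stats::nobs(x$model))
}
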
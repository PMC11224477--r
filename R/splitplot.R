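signif_mark <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Split-plot analysis of variance with two error strata
#'
#' The classical analysis for a split-plot field trial: tillage (the
#' hard-to-randomize factor) occupies main plots within replicate
#' blocks, variety occupies subplots. Replicates are random blocks; the
#' main-plot error (Error I) is the Block x Tillage interaction, and
#' the subplot error (Error II) is the remaining residual. Tillage is
#' tested against Error I; variety and the interaction against
#' Error II. Sums of squares are the standard closed forms for a
#' balanced design, so `SS(Block) + SS(M) + SS(Error I) + SS(V) +
#' SS(M x V) + SS(Error II) = SS(Total)` exactly.
#'
#' The input must be balanced (every tillage x variety cell observed in
#' every block); unbalanced data raise an error rather than silently
#' switching to an approximate decomposition. Analyse one trait and one
#' year at a time, as multi-environment tables are conventionally
#' reported per year.
#'
#' @param data Data frame with columns `tillage`, `variety`,
#'   `replicate` and the response; if `trait`/`year` columns are
#'   present they must each hold a single value.
#' @param response Name of the response column (default `"value"`).
#' @return An object of class `grainfill_anova`: a tibble with columns
#'   `term`, `df`, `sumsq`, `meansq`, `statistic` (F where defined),
#'   `p.value` and `signif` (`**` p<0.01, `*` p<0.05, `ns`), with rows
#'   Block, Tillage (M), Error I, Variety (V), M x V, Error II, Total.
#'   Design sizes are attached as attributes `m`, `v`, `r`.
#' @export
#' @examples
#' d <- expand.grid(tillage = c("CK", "DPR"), variety = c("XY696", "XM6"),
#'                  replicate = 1:3)
#' d$value <- rnorm(nrow(d)) + (d$tillage == "DPR")
#' anova_splitplot(d)
anova_splitplot <- function(data, response = "value") {
  stopifnot(is.data.frame(data))
  need <- c("tillage", "variety", "replicate", response)
  if (!all(need %in% names(data))) {
    rlang::abort(paste0("`data` must have columns ",
                        paste(need, collapse = ", ")))
  }
  for (col in c("trait", "year")) {
    if (col %in% names(data) && dplyr::n_distinct(data[[col]]) > 1) {
      rlang::abort(paste0("`data` contains more than one ", col,
                          "; analyse each separately"))
    }
  }
  y <- data[[response]]
  M <- factor(data$tillage)
  V <- factor(data$variety)
  R <- factor(data$replicate)
  m <- nlevels(M); v <- nlevels(V); r <- nlevels(R)
  counts <- table(M, V, R)
  if (any(counts != 1) || r < 2) {
    rlang::abort(
      "unbalanced design: every tillage x variety cell must appear exactly once in each of >= 2 replicate blocks",
      class = "grainfill_unbalanced"
    )
  }
  n <- m * v * r
  cf <- sum(y)^2 / n
  ss_total <- sum(y^2) - cf
  ss_block <- sum(tapply(y, R, sum)^2) / (m * v) - cf
  ss_m <- sum(tapply(y, M, sum)^2) / (v * r) - cf
  ss_e1 <- sum(tapply(y, list(M, R), sum)^2) / v - cf - ss_m - ss_block
  ss_v <- sum(tapply(y, V, sum)^2) / (m * r) - cf
  ss_mv <- sum(tapply(y, list(M, V), sum)^2) / r - cf - ss_m - ss_v
  ss_e2 <- ss_total - ss_block - ss_m - ss_e1 - ss_v - ss_mv
  df <- c(r - 1, m - 1, (m - 1) * (r - 1), v - 1, (m - 1) * (v - 1),
          m * (v - 1) * (r - 1), n - 1)
  ss <- c(ss_block, ss_m, ss_e1, ss_v, ss_mv, ss_e2, ss_total)
  ms <- c(ss[1:6] / df[1:6], NA)
  f <- rep(NA_real_, 7)
  p <- rep(NA_real_, 7)
  note <- character()
  if (ms[3] > 0) {
    f[2] <- ms[2] / ms[3]
    p[2] <- stats::pf(f[2], df[2], df[3], lower.tail = FALSE)
  } else {
    note <- c(note, "Error I mean square is zero: F(M) undefined")
  }
  if (ms[6] > 0) {
    f[4] <- ms[4] / ms[6]
    f[5] <- ms[5] / ms[6]
    p[4] <- stats::pf(f[4], df[4], df[6], lower.tail = FALSE)
    p[5] <- stats::pf(f[5], df[5], df[6], lower.tail = FALSE)
  } else {
    note <- c(note, "Error II mean square is zero: F(V), F(M x V) undefined")
  }
  out <- tibble::tibble(
    term = c("Block", "Tillage (M)", "Error I", "Variety (V)", "M x V",
             "Error II", "Total"),
    df = df, sumsq = ss, meansq = ms,
    statistic = f, p.value = p, signif = signif_mark(p)
  )
  structure(out, class = c("grainfill_anova", class(out)),
            m = m, v = v, r = r, note = note)
}

#' @export
print.grainfill_anova <- function(x, ...) {
  cat("Split-plot ANOVA (tillage on main plots, variety on subplots)\n")
  NextMethod()
  note <- attr(x, "note")
  if (length(note)) cat("Note:", paste(note, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname anova_splitplot
#' @param x A `grainfill_anova`.
#' @param ... Unused.
#' @method tidy grainfill_anova
#' @export
tidy.grainfill_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

lsd_letters <- function(means, lsd) {
  ord <- order(means, decreasing = TRUE)
  ms <- means[ord]
  k <- length(ms)
  # maximal runs (in descending order) whose spread is within the LSD:
  # two levels share a letter iff their means differ by <= LSD
  ends <- vapply(seq_len(k),
                 function(i) max(which(ms[i] - ms <= lsd)), integer(1))
  keep <- !duplicated(ends)
  starts <- seq_len(k)[keep]
  ends <- ends[keep]
  maximal <- !c(FALSE, ends[-1] <= ends[-length(ends)])
  starts <- starts[maximal]; ends <- ends[maximal]
  groups <- character(k)
  for (g in seq_along(starts)) {
    idx <- starts[g]:ends[g]
    groups[idx] <- paste0(groups[idx], letters[g])
  }
  out <- character(k)
  out[ord] <- groups
  out
}

#' Least significant difference comparison with letter groups
#'
#' Computes the LSD at level `alpha`,
#' \eqn{LSD = t_{1-\alpha/2, df} \sqrt{2 \, MS_e / n}}, and assigns
#' compact letter codes by a descending-mean sweep: two levels share a
#' letter exactly when their means differ by at most the LSD.
#'
#' @param means Data frame with columns `level` and `mean`, or a named
#'   numeric vector of level means.
#' @param error_ms Error mean square from the appropriate stratum.
#' @param error_df Its degrees of freedom (>= 1).
#' @param n_per_mean Number of observations behind each mean.
#' @param alpha Significance level (default 0.05).
#' @return A tibble `level`, `mean`, `group`, sorted by descending
#'   mean, with attributes `lsd`, `alpha`, `error_df`.
#' @export
#' @examples
#' lsd_compare(c(CK = 10, DPR = 12), error_ms = 0.5, error_df = 12,
#'             n_per_mean = 4)
lsd_compare <- function(means, error_ms, error_df, n_per_mean,
                        alpha = 0.05) {
  if (is.numeric(means) && !is.null(names(means))) {
    means <- tibble::tibble(level = names(means), mean = unname(means))
  }
  stopifnot(is.data.frame(means),
            all(c("level", "mean") %in% names(means)))
  if (error_ms <= 0) rlang::abort("`error_ms` must be positive")
  if (error_df < 1) rlang::abort("`error_df` must be >= 1")
  if (n_per_mean <= 0) rlang::abort("`n_per_mean` must be positive")
  if (alpha <= 0 || alpha >= 1) rlang::abort("`alpha` must be in (0, 1)")
  lsd <- stats::qt(1 - alpha / 2, error_df) * sqrt(2 * error_ms / n_per_mean)
  out <- tibble::tibble(level = as.character(means$level),
                        mean = as.numeric(means$mean),
                        group = lsd_letters(as.numeric(means$mean), lsd))
  out <- dplyr::arrange(out, dplyr::desc(.data$mean))
  structure(out, class = c("grainfill_lsd", class(out)),
            lsd = lsd, alpha = alpha, error_df = error_df)
}

#' @export
print.grainfill_lsd <- function(x, ...) {
  cat(sprintf("LSD = %.4g at alpha = %g (error df = %.4g)\n",
              attr(x, "lsd"), attr(x, "alpha"), attr(x, "error_df")))
  NextMethod()
  invisible(x)
}

#' LSD comparison of tillage levels within each variety
#'
#' Comparing main-plot (tillage) means at a fixed subplot level mixes
#' the two error strata of a split-plot design. The default uses the
#' combined error \eqn{[(v-1) MS_{II} + MS_I]/v} with Satterthwaite
#' degrees of freedom; `method = "error2"` uses the subplot error alone
#' (a simpler convention, anticonservative when Error I dominates).
#'
#' @param data The trait data passed to [anova_splitplot()].
#' @param anova The corresponding `grainfill_anova` (computed from
#'   `data` if omitted).
#' @param response Response column name.
#' @param method `"combined"` or `"error2"`.
#' @param alpha Significance level.
#' @return A tibble of letter groupings, one block per variety.
#' @export
lsd_tillage_within_variety <- function(data, anova = NULL,
                                       response = "value",
                                       method = c("combined", "error2"),
                                       alpha = 0.05) {
  method <- match.arg(method)
  if (is.null(anova)) anova <- anova_splitplot(data, response = response)
  v <- attr(anova, "v"); r <- attr(anova, "r")
  ms1 <- anova$meansq[anova$term == "Error I"]
  ms2 <- anova$meansq[anova$term == "Error II"]
  df1 <- anova$df[anova$term == "Error I"]
  df2 <- anova$df[anova$term == "Error II"]
  if (method == "combined") {
    ms_eff <- ((v - 1) * ms2 + ms1) / v
    df_eff <- ((v - 1) * ms2 + ms1)^2 /
      (((v - 1) * ms2)^2 / df2 + ms1^2 / df1)
  } else {
    ms_eff <- ms2
    df_eff <- df2
  }
  purrr::map_dfr(unique(data$variety), function(vr) {
    d <- data[data$variety == vr, ]
    mns <- tapply(d[[response]], d$tillage, mean)
    cmp <- lsd_compare(mns, error_ms = ms_eff, error_df = df_eff,
                       n_per_mean = r, alpha = alpha)
    dplyr::bind_cols(tibble::tibble(variety = vr), cmp)
  })
}
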
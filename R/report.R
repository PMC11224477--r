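trait_wide <- function(traits) {
  tidyr::pivot_wider(traits, names_from = "trait", values_from = "value")
}

#' Run the full grain-filling analysis pipeline
#'
#' Chains every stage on a trial's tables: fits the logistic model per
#' unit, partitions each fit into the three filling phases, runs the
#' split-plot ANOVA (per year and trait) with LSD letter groupings for
#' tillage within each variety, assembles the unit-level feature table
#' (Y = fitted 100-grain dry weight at maturity, `0.99 * A`, plus
#' per-phase rates/durations and quality traits), and computes the
#' Pearson correlation matrix, correlation PCA, and stepwise
#' regressions of starch and fat content on the phase rates.
#'
#' @param filling Long filling observations (see [read_filling_csv()]).
#' @param traits Long maturity-trait records (see [read_trait_csv()]);
#'   optional -- without it the multivariate stages that need quality
#'   traits are skipped.
#' @param mode Curve-fitting mode, see [fit_filling()].
#' @param constants Phase-offset constants, see [phase_offsets()].
#' @param alpha Significance level for ANOVA stars and LSD.
#' @param sle,sls Stepwise entry/stay thresholds.
#' @return A `grainfill_report` list: `fits`, `phases`, `anova` (named
#'   list of `grainfill_anova`), `lsd` (named list of letter tables),
#'   `features`, `correlation`, `pca`, `stepwise` (named list).
#' @export
#' @examples
#' trial <- generate_trial(trial_config(years = 2020, replicates = 2))
#' rep <- analyze_trial(trial$filling, trial$traits)
#' names(rep$anova)
analyze_trial <- function(filling, traits = NULL,
                          mode = c("replicate", "treatment_mean"),
                          constants = c("printed", "exact"),
                          alpha = 0.05, sle = 0.15, sls = 0.15) {
  mode <- match.arg(mode)
  fits <- fit_filling(filling, mode = mode)
  ok <- fits[fits$converged & !is.na(fits$A), ]
  phases <- partition_phases(
    ok[c(unit_cols(ok), "A", "B", "C")], constants = constants
  )
  out <- list(fits = fits, phases = phases)

  anovas <- list()
  lsds <- list()
  if (!is.null(traits)) {
    combos <- dplyr::distinct(traits, .data$year, .data$trait)
    for (i in seq_len(nrow(combos))) {
      d <- traits[traits$year == combos$year[i] &
                    traits$trait == combos$trait[i], ]
      key <- paste(combos$year[i], combos$trait[i], sep = "_")
      anovas[[key]] <- anova_splitplot(d)
      lsds[[key]] <- lsd_tillage_within_variety(d, anovas[[key]],
                                                alpha = alpha)
    }
  }
  out$anova <- anovas
  out$lsd <- lsds

  features <- phases[c(unit_cols(phases), "V1", "V2", "V3",
                       "T1", "T2", "T3")]
  features$Y <- 0.99 * phases$A
  if (!is.null(traits)) {
    features <- dplyr::inner_join(features, trait_wide(traits),
                                  by = unit_cols(features))
  }
  out$features <- features

  num <- dplyr::select(features, -dplyr::any_of(c("year", "replicate"))) |>
    dplyr::select(dplyr::where(is.numeric))
  out$correlation <- pearson_matrix(num)
  out$pca <- pca_correlation(num)

  steps <- list()
  if (!is.null(traits)) {
    for (resp in intersect(c("total_starch_pct", "crude_fat_pct"),
                           names(features))) {
      steps[[resp]] <- stepwise_regression(
        features, response = resp, predictors = c("V1", "V2", "V3"),
        sle = sle, sls = sls
      )
    }
  }
  out$stepwise <- steps
  structure(out, class = "grainfill_report")
}

#' @export
print.grainfill_report <- function(x, ...) {
  cat("Grain-filling analysis report\n")
  cat("  fitted units:", nrow(x$fits),
      sprintf("(%d converged)\n", sum(x$fits$converged)))
  cat("  ANOVA tables:", length(x$anova), "\n")
  if (length(x$pca$explained)) {
    cat(sprintf("  PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
                100 * x$pca$explained[1], 100 * x$pca$explained[2]))
  }
  for (nm in names(x$stepwise)) {
    cat("  stepwise [", nm, "]: ",
        paste(x$stepwise[[nm]]$selected, collapse = " + "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a report's tables as CSV files
#'
#' Serializes every tabular component of an [analyze_trial()] report
#' into `dir`: fitted parameters, phase parameters, one ANOVA table
#' per year x trait (source, df, SS, MS, F, p, stars -- the layout of
#' conventional variance-analysis tables), LSD letter tables,
#' correlation matrix, PCA loadings and explained variance, and one
#' stepwise report per response (Variate, Index, Standard error,
#' F-value, Pr>F).
#'
#' @param report A `grainfill_report`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "grainfill_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(df, path)
    files <<- c(files, path)
  }
  emit(report$fits, "fits.csv")
  emit(report$phases, "phases.csv")
  for (nm in names(report$anova)) {
    emit(tidy(report$anova[[nm]]), paste0("anova_", nm, ".csv"))
  }
  for (nm in names(report$lsd)) {
    emit(report$lsd[[nm]], paste0("lsd_", nm, ".csv"))
  }
  emit(tidy(report$correlation), "correlation.csv")
  emit(tidy(report$pca), "pca_loadings.csv")
  emit(glance(report$pca), "pca_explained.csv")
  for (nm in names(report$stepwise)) {
    st <- tidy(report$stepwise[[nm]])
    names(st) <- c("Variate", "Index", "Standard error", "F-value", "Pr > F")
    emit(st, paste0("stepwise_", nm, ".csv"))
  }
  invisible(files)
}
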
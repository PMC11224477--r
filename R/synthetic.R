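default_quality_model <- function() {
  # linear maps from true per-phase filling parameters to quality traits;
  # signs chosen so grain weight associates positively with starch and
  # fat and negatively with protein and soluble sugar
  list(
    total_starch_pct = list(intercept = 65.62, coef = c(V1 = 10.86),
                            sd = 0.6),
    crude_fat_pct = list(intercept = 2.99,
                         coef = c(V1 = 2.34, V2 = -4.21, V3 = 18.43),
                         sd = 0.15),
    crude_protein_pct = list(intercept = 12.8, coef = c(V1 = -8),
                             sd = 0.25),
    soluble_sugar_pct = list(intercept = 8.5, coef = c(V2 = -4.5),
                             sd = 0.2)
  )
}

expand_effect <- function(x, levels, what) {
  out <- stats::setNames(rep(0, length(levels)), levels)
  if (length(x) == 1 && is.null(names(x))) {
    out[] <- x
  } else if (!is.null(names(x))) {
    unknown <- setdiff(names(x), levels)
    if (length(unknown)) {
      rlang::abort(paste0("unknown level(s) in `", what, "`: ",
                          paste(unknown, collapse = ", ")))
    }
    out[names(x)] <- x
  } else if (length(x) == length(levels)) {
    out[] <- x
  } else {
    rlang::abort(paste0("`", what, "` must be a scalar or named by level"))
  }
  out
}

#' Configuration of a synthetic split-plot grain-filling trial
#'
#' Describes a two-variety, nine-tillage, replicated split-plot trial
#' whose every unit follows a logistic filling trajectory with known
#' parameters, so pipeline output can be checked against ground truth.
#' Tillage acts multiplicatively on the asymptotic weight `A` and rate
#' parameter `C` (relative shifts; straw-incorporation treatments with
#' deep soil work carry the largest defaults, about +5% on `A` and a
#' low-teens shift of the peak rate `A*C/4`, matching the effect sizes
#' such trials report), and additively on `ln B` (filling lag).
#' Replicate-level biology is a lognormal jitter on `A` and `C`;
#' observation error is iid Gaussian on each weighing. Quality traits
#' are linear functions of the unit's true per-phase filling parameters
#' plus Gaussian noise (see `default_quality_model()` inside the
#' package source); the starch and fat maps use published-scale
#' coefficients so trait values land at realistic percentages.
#'
#' @param years Trial years.
#' @param tillage_levels Tillage treatment codes (default the nine
#'   codes CK, SC, SS, DP, NT, SCR, SSR, DPR, NTR).
#' @param varieties Variety codes.
#' @param replicates Number of replicate blocks.
#' @param base_params Named list (by variety) of `c(A, B, C)`.
#' @param a_effect,c_effect Relative tillage shifts on `A` / `C`:
#'   scalar, or named vector (missing levels get 0).
#' @param lnb_shift Additive tillage shift on `ln B`, same conventions.
#' @param year_a_effect Relative year shift on `A`, named by year.
#' @param rep_jitter_sd Lognormal sdlog of the replicate jitter applied
#'   to `A` and `C`.
#' @param noise_sd_weight SD (g) of the Gaussian weighing error.
#' @param sampling_start,sampling_step,n_points Sampling schedule in
#'   days after pollination (default 15 d, every 5 d, 9 samples).
#' @param quality_model Named list of trait models, each
#'   `list(intercept, coef, sd)` with `coef` named among
#'   V1, V2, V3, T1, T2, T3.
#' @param weight_trait_sd SD (g) of the maturity-weight trait noise.
#' @param seed Integer seed; generation is deterministic given it.
#' @return A `trial_config` list.
#' @export
#' @examples
#' cfg <- trial_config(years = 2020, replicates = 2, seed = 7)
#' trial <- generate_trial(cfg)
#' head(trial$filling)
trial_config <- function(years = c(2020, 2021),
                         tillage_levels = c("CK", "SC", "SS", "DP", "NT",
                                            "SCR", "SSR", "DPR", "NTR"),
                         varieties = c("XY696", "XM6"),
                         replicates = 3,
                         base_params = list(
                           XY696 = c(A = 33, B = 40, C = 0.150),
                           XM6 = c(A = 34.2, B = 48, C = 0.148)
                         ),
                         a_effect = c(SC = 0.010, SS = 0.015, DP = 0.020,
                                      NT = 0.005, SCR = 0.020, SSR = 0.047,
                                      DPR = 0.055, NTR = 0.010),
                         c_effect = c(SC = 0.005, SS = 0.010, DP = 0.015,
                                      NT = -0.005, SCR = 0.010, SSR = 0.050,
                                      DPR = 0.070),
                         lnb_shift = 0,
                         year_a_effect = NULL,
                         rep_jitter_sd = 0.01,
                         noise_sd_weight = 0.3,
                         sampling_start = 15, sampling_step = 5,
                         n_points = 9,
                         quality_model = default_quality_model(),
                         weight_trait_sd = 0.25,
                         seed = 1) {
  stopifnot(replicates >= 1, n_points >= 4, noise_sd_weight >= 0,
            rep_jitter_sd >= 0)
  if (!all(varieties %in% names(base_params))) {
    rlang::abort("`base_params` must name every variety")
  }
  if (is.null(year_a_effect)) {
    year_a_effect <- stats::setNames(
      c(0, rep(0.01, length(years) - 1)), as.character(years)
    )
  }
  cfg <- list(
    years = years,
    tillage_levels = tillage_levels,
    varieties = varieties,
    replicates = replicates,
    base_params = base_params,
    a_effect = expand_effect(a_effect, tillage_levels, "a_effect"),
    c_effect = expand_effect(c_effect, tillage_levels, "c_effect"),
    lnb_shift = expand_effect(lnb_shift, tillage_levels, "lnb_shift"),
    year_a_effect = expand_effect(year_a_effect, as.character(years),
                                  "year_a_effect"),
    rep_jitter_sd = rep_jitter_sd,
    noise_sd_weight = noise_sd_weight,
    sampling = sampling_start + sampling_step * (seq_len(n_points) - 1),
    quality_model = quality_model,
    weight_trait_sd = weight_trait_sd,
    seed = seed
  )
  class(cfg) <- "trial_config"
  cfg
}

# draws the per-unit true logistic parameters; caller controls the RNG
draw_unit_params <- function(config) {
  units <- tidyr::expand_grid(
    year = config$years,
    tillage = config$tillage_levels,
    variety = config$varieties,
    replicate = seq_len(config$replicates)
  )
  base <- do.call(rbind, config$base_params[units$variety])
  jitter_a <- exp(stats::rnorm(nrow(units), 0, config$rep_jitter_sd))
  jitter_c <- exp(stats::rnorm(nrow(units), 0, config$rep_jitter_sd))
  units$A <- unname(base[, "A"] *
    (1 + config$a_effect[units$tillage]) *
    (1 + config$year_a_effect[as.character(units$year)]) * jitter_a)
  units$C <- unname(base[, "C"] * (1 + config$c_effect[units$tillage]) *
                      jitter_c)
  units$B <- unname(exp(log(base[, "B"]) + config$lnb_shift[units$tillage]))
  k1 <- max(phase_offsets("printed")[["k1"]], phase_offsets("exact")[["k1"]])
  if (any(log(units$B) <= k1)) {
    rlang::abort(
      "configuration yields ln(B) <= 1.317 for some unit: the phase partition would be degenerate",
      class = "grainfill_degenerate_partition"
    )
  }
  units
}

#' Ground-truth phase parameters implied by a trial configuration
#'
#' Reproduces exactly the per-unit true logistic parameters that
#' [generate_trial()] uses for the same configuration (identical seed,
#' identical draws) and returns their closed-form phase partition, for
#' use as the recovery target in pipeline tests.
#'
#' @param config A [trial_config()].
#' @param constants Passed to [partition_phases()].
#' @return A tibble: unit columns, true `A`, `B`, `C`, and all phase
#'   parameters.
#' @export
true_parameter_table <- function(config,
                                 constants = c("printed", "exact")) {
  stopifnot(inherits(config, "trial_config"))
  units <- withr::with_seed(config$seed, draw_unit_params(config))
  partition_phases(units, constants = constants)
}

#' Generate a synthetic grain-filling trial
#'
#' Simulates the full trial described by `config`: for every
#' year x tillage x variety x replicate unit, true logistic parameters
#' are drawn (treatment effects times replicate jitter), dry weights
#' are emitted at the sampling schedule with Gaussian weighing error,
#' and maturity traits (100-grain weight at 14% moisture plus four
#' quality traits) are generated from the unit's true phase parameters.
#' Byte-identical output for identical config and seed.
#'
#' @param config A [trial_config()].
#' @return A list of three tibbles: `filling` (long weight series),
#'   `traits` (long trait records), `truth` (true unit parameters and
#'   phase partition).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  withr::with_seed(config$seed, {
    units <- draw_unit_params(config)
    filling <- tidyr::expand_grid(units, dap = config$sampling)
    filling$weight <- logistic_weight(filling$dap, filling$A, filling$B,
                                      filling$C) +
      stats::rnorm(nrow(filling), 0, config$noise_sd_weight)
    filling <- dplyr::select(filling, "year", "tillage", "variety",
                             "replicate", "dap", "weight")
    truth <- partition_phases(units)
    maturity_dry <- 0.99 * truth$A +
      stats::rnorm(nrow(truth), 0, config$weight_trait_sd)
    traits <- list(
      tibble::tibble(
        truth[c("year", "tillage", "variety", "replicate")],
        trait = "hundred_grain_weight_14pct",
        value = moisture_standardize(maturity_dry, 0)
      )
    )
    for (trait in names(config$quality_model)) {
      qm <- config$quality_model[[trait]]
      val <- qm$intercept
      for (v in names(qm$coef)) val <- val + qm$coef[[v]] * truth[[v]]
      val <- val + stats::rnorm(nrow(truth), 0, qm$sd)
      traits[[length(traits) + 1]] <- tibble::tibble(
        truth[c("year", "tillage", "variety", "replicate")],
        trait = trait, value = val
      )
    }
    list(filling = filling,
         traits = dplyr::bind_rows(traits),
         truth = truth)
  })
}
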
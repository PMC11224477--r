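test_that("split-plot SS match a brute-force marginal-means oracle", {
  d <- withr::with_seed(21, splitplot_data(
    m = 2, v = 2, r = 2,
    tillage_eff = c(0, 1.5), variety_eff = c(0, -0.8),
    interaction_eff = matrix(c(0, 0, 0, 0.6), 2, 2),
    block_eff = c(0, 0.3), noise_sd = 0.2
  ))
  a <- anova_splitplot(d)
  ss <- splitplot_ss_oracle(d)
  expect_equal(a$sumsq, unname(ss), tolerance = 1e-9)
})

test_that("F ratios agree with aov's two-stratum decomposition", {
  d <- withr::with_seed(33, splitplot_data(
    m = 4, v = 2, r = 3, tillage_eff = c(0, 1, 2, 0.5),
    variety_eff = c(0, 1), noise_sd = 0.5
  ))
  a <- anova_splitplot(d)
  # aov warns that the Error() model is singular for this layout; the
  # stratum decomposition it returns is still the classical one
  fit <- suppressWarnings(
    stats::aov(value ~ replicate_f + tillage * variety +
                 Error(replicate_f:tillage),
               data = transform(d, replicate_f = factor(replicate)))
  )
  s <- summary(fit)
  e1 <- s[[grep("replicate_f:tillage", names(s))]][[1]]
  e2 <- s[["Error: Within"]][[1]]
  rownames(e1) <- trimws(rownames(e1))
  rownames(e2) <- trimws(rownames(e2))
  expect_equal(a$statistic[a$term == "Tillage (M)"],
               e1["tillage", "F value"], tolerance = 1e-8)
  expect_equal(a$p.value[a$term == "Variety (V)"],
               e2["variety", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(a$meansq[a$term == "Error II"],
               e2["Residuals", "Mean Sq"], tolerance = 1e-8)
})

test_that("SS are additive and invariant to replicate relabelling", {
  for (seed in 1:5) {
    d <- withr::with_seed(seed, splitplot_data(m = 9, v = 2, r = 3,
                                               noise_sd = 1))
    a <- anova_splitplot(d)
    parts <- a$sumsq[a$term != "Total"]
    expect_equal(sum(parts), a$sumsq[a$term == "Total"], tolerance = 1e-9)
    # permuting block labels leaves every SS unchanged
    perm <- c(2, 3, 1)
    dp <- transform(d, replicate = perm[replicate])
    expect_equal(anova_splitplot(dp)$sumsq, a$sumsq, tolerance = 1e-9)
  }
})

test_that("constructed contrasts land in the right stratum", {
  # pure variety effect: all tillage SS vanish
  d <- splitplot_data(m = 3, v = 2, r = 3, variety_eff = c(0, 1))
  a <- anova_splitplot(d)
  expect_equal(a$sumsq[a$term == "Tillage (M)"], 0, tolerance = 1e-12)
  expect_equal(a$sumsq[a$term == "M x V"], 0, tolerance = 1e-12)
  n <- nrow(d)
  expect_equal(a$sumsq[a$term == "Variety (V)"], n / 4 * 1^2)
})

test_that("degenerate and unbalanced inputs are refused or flagged", {
  d <- splitplot_data(m = 2, v = 2, r = 2)
  a <- anova_splitplot(d) # all values equal
  expect_true(all(a$sumsq < 1e-20))
  expect_true(all(is.na(a$statistic)))
  expect_gt(length(attr(a, "note")), 0)
  expect_error(anova_splitplot(splitplot_data(m = 2, v = 2, r = 3)[-1, ]),
               class = "grainfill_unbalanced")
})

test_that("stars follow the 0.05 / 0.01 convention", {
  d <- withr::with_seed(5, splitplot_data(m = 3, v = 2, r = 3,
                                          variety_eff = c(0, 10),
                                          noise_sd = 0.5))
  a <- anova_splitplot(d)
  expect_equal(a$signif[a$term == "Variety (V)"], "**")
  expect_true(a$p.value[a$term == "Variety (V)"] < 0.01)
})

test_that("LSD value and letters match the textbook formula", {
  cmp <- lsd_compare(c(A = 10, B = 12), error_ms = 0.5, error_df = 12,
                     n_per_mean = 4)
  expect_equal(attr(cmp, "lsd"), 1.08940641483, tolerance = 1e-9)
  # difference of 2 exceeds the LSD: distinct letters
  expect_equal(cmp$group, c("a", "b"))
  expect_equal(cmp$level, c("B", "A")) # sorted descending
  # equal means always share a letter
  cmp0 <- lsd_compare(c(A = 10, B = 10), 0.5, 12, 4)
  expect_equal(cmp0$group, c("a", "a"))
})

test_that("letter groups share a letter exactly when |diff| <= LSD", {
  means <- c(a = 10, b = 9.5, c = 9.1, d = 8.0, e = 7.9)
  cmp <- lsd_compare(means, error_ms = 0.5, error_df = 12, n_per_mean = 4)
  lsd <- attr(cmp, "lsd")
  for (i in seq_len(nrow(cmp))) {
    for (j in seq_len(nrow(cmp))) {
      shares <- any(strsplit(cmp$group[i], "")[[1]] %in%
                      strsplit(cmp$group[j], "")[[1]])
      expect_equal(shares, abs(cmp$mean[i] - cmp$mean[j]) <= lsd,
                   info = paste(cmp$level[i], cmp$level[j]))
    }
  }
})

test_that("within-variety tillage LSD uses the combined stratum", {
  d <- withr::with_seed(8, splitplot_data(m = 4, v = 2, r = 3,
                                          tillage_eff = c(0, 0.5, 2, 2.1),
                                          noise_sd = 0.4))
  a <- anova_splitplot(d)
  out <- lsd_tillage_within_variety(d, a)
  expect_equal(nrow(out), 8)
  ms1 <- a$meansq[a$term == "Error I"]
  ms2 <- a$meansq[a$term == "Error II"]
  ms_eff <- ((2 - 1) * ms2 + ms1) / 2
  # combined error lies between the strata
  expect_true(ms_eff >= min(ms1, ms2) && ms_eff <= max(ms1, ms2))
  out2 <- lsd_tillage_within_variety(d, a, method = "error2")
  expect_equal(names(out2), names(out))
})
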
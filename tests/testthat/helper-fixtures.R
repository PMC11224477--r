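# shared fixtures, all generated in code

logistic_series <- function(A = 30, B = 40, C = 0.15, t = seq(15, 55, 5),
                            noise_sd = 0, ...) {
  data.frame(dap = t,
             weight = A / (1 + B * exp(-C * t)) +
               stats::rnorm(length(t), 0, noise_sd))
}

random_params <- function(n, seed = 101) {
  withr::with_seed(seed, data.frame(
    A = runif(n, 25, 40),
    B = exp(runif(n, 2.5, 4.5)),
    C = runif(n, 0.10, 0.20)
  ))
}

# small balanced split-plot layout with configurable effects
splitplot_data <- function(m = 3, v = 2, r = 3,
                           tillage_eff = rep(0, m),
                           variety_eff = rep(0, v),
                           interaction_eff = matrix(0, m, v),
                           block_eff = rep(0, r),
                           noise_sd = 0, seed = NULL) {
  d <- expand.grid(tillage = paste0("M", seq_len(m)),
                   variety = paste0("V", seq_len(v)),
                   replicate = seq_len(r))
  i <- as.integer(d$tillage); j <- as.integer(d$variety)
  k <- as.integer(d$replicate)
  mu <- 10 + tillage_eff[i] + variety_eff[j] +
    interaction_eff[cbind(i, j)] + block_eff[k]
  noise <- if (noise_sd > 0) {
    if (!is.null(seed)) withr::with_seed(seed, rnorm(nrow(d), 0, noise_sd))
    else rnorm(nrow(d), 0, noise_sd)
  } else 0
  d$value <- mu + noise
  d
}

# brute-force split-plot sums of squares from marginal means
splitplot_ss_oracle <- function(d) {
  y <- d$value
  gm <- mean(y)
  mean_of <- function(...) tapply(y, list(...), mean)
  m <- nlevels(factor(d$tillage)); v <- nlevels(factor(d$variety))
  r <- nlevels(factor(d$replicate))
  mb <- mean_of(d$tillage, d$replicate)
  mv <- mean_of(d$tillage, d$variety)
  mm <- mean_of(d$tillage); vv <- mean_of(d$variety)
  bb <- mean_of(d$replicate)
  ss_block <- m * v * sum((bb - gm)^2)
  ss_m <- v * r * sum((mm - gm)^2)
  ss_e1 <- v * sum((mb - outer(mm, bb, "+") + gm)^2)
  ss_v <- m * r * sum((vv - gm)^2)
  ss_mv <- r * sum((mv - outer(mm, vv, "+") + gm)^2)
  ss_tot <- sum((y - gm)^2)
  c(block = ss_block, m = ss_m, e1 = ss_e1, v = ss_v, mv = ss_mv,
    e2 = ss_tot - ss_block - ss_m - ss_e1 - ss_v - ss_mv, total = ss_tot)
}
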
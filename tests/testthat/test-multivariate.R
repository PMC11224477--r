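test_that("pearson matrix matches a two-pass oracle and cor.test", {
  d <- withr::with_seed(2, data.frame(a = rnorm(15), b = rnorm(15),
                                      c = rnorm(15)))
  pm <- pearson_matrix(d)
  # two-pass covariance oracle
  two_pass <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(pm$r[i, j], two_pass(d[[i]], d[[j]]), tolerance = 1e-12)
  }
  ct <- stats::cor.test(d$a, d$b)
  expect_equal(pm$p["a", "b"], ct$p.value, tolerance = 1e-12)
  expect_equal(pm$r, t(pm$r))
  expect_equal(unname(diag(pm$r)), rep(1, 3))
})

test_that("pearson handles exact and degenerate relationships", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(1, 2, 3, 5))
  pm <- pearson_matrix(d)
  expect_equal(pm$r["x", "y"], 0.982707629824, tolerance = 1e-9)
  dup <- data.frame(x = c(1, 2, 3), x2 = c(1, 2, 3), z = c(2, 1, 3))
  expect_equal(pearson_matrix(dup)$r["x", "x2"], 1)
  neg <- data.frame(x = c(1, 2, 3), y = -c(1, 2, 3))
  expect_equal(pearson_matrix(neg)$r["x", "y"], -1)
  expect_error(pearson_matrix(data.frame(x = c(1, 1, 1), y = c(1, 2, 3))),
               "zero-variance")
})

test_that("correlation PCA matches eigen structure and prcomp", {
  d <- withr::with_seed(9, {
    f1 <- rnorm(40); f2 <- rnorm(40)
    data.frame(a = f1 + rnorm(40, 0, 0.01), b = -f1 + rnorm(40, 0, 0.01),
               c = f2 + rnorm(40, 0, 0.01), d = f2 + rnorm(40, 0, 0.01))
  })
  p <- pca_correlation(d)
  expect_equal(sum(p$explained), 1)
  # 2 latent factors: first two components carry essentially everything
  expect_gt(sum(p$explained[1:2]), 0.99)
  # agreement with prcomp on the standardized data (up to sign)
  pr <- stats::prcomp(d, scale. = TRUE)
  expect_equal(abs(unname(p$loadings)), abs(unname(pr$rotation)),
               tolerance = 1e-8)
  expect_equal(p$sdev^2 / sum(p$sdev^2), p$explained)
  # sign convention: largest-magnitude loading of each component positive
  for (j in 1:4) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  # reconstruction from all components reproduces the standardized table
  z <- scale(as.matrix(d))
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(z),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("two correlated columns give eigenvalues 1 + r and 1 - r", {
  d <- withr::with_seed(4, {
    x <- rnorm(60); data.frame(x = x, y = x + rnorm(60, 0, 1))
  })
  r <- stats::cor(d$x, d$y)
  p <- pca_correlation(d)
  expect_equal(p$sdev^2, c(1 + r, 1 - r), tolerance = 1e-10)
})

test_that("stepwise selects the true support in a clean signal", {
  d <- withr::with_seed(14, {
    x1 <- rnorm(40); x2 <- rnorm(40)
    data.frame(x1 = x1, x2 = x2, y = 2 * x1 + rnorm(40, 0, 1e-8))
  })
  st <- stepwise_regression(d, "y", sle = 0.05, sls = 0.05)
  expect_equal(st$selected, "x1")
  td <- tidy(st)
  expect_equal(td$estimate[td$term == "x1"], 2, tolerance = 1e-6)
  expect_lt(sum(stats::resid(st$model)^2), 1e-10)
})

test_that("single candidate with sle = 1 reduces to simple OLS", {
  d <- withr::with_seed(15, data.frame(x = rnorm(25)))
  d$y <- 1 + 0.7 * d$x + withr::with_seed(16, rnorm(25))
  st <- stepwise_regression(d, "y", predictors = "x", sle = 1, sls = 1)
  expect_equal(st$selected, "x")
  slope <- stats::cov(d$x, d$y) / stats::var(d$x)
  expect_equal(tidy(st)$estimate[2], slope, tolerance = 1e-12)
})

test_that("final coefficients equal a direct solve on the selected columns", {
  d <- withr::with_seed(17, {
    x1 <- rnorm(50); x2 <- rnorm(50); x3 <- rnorm(50)
    data.frame(x1 = x1, x2 = x2, x3 = x3,
               y = 1 + x1 - 2 * x3 + rnorm(50, 0, 0.5))
  })
  st <- stepwise_regression(d, "y")
  X <- cbind(1, as.matrix(d[st$selected]))
  beta <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(unname(tidy(st)$estimate), unname(drop(beta)),
               tolerance = 1e-10)
})

test_that("under the null the model stays empty at the expected rate", {
  # one candidate: P(enter) is exactly sle = 0.05
  empty1 <- withr::with_seed(18, replicate(400, {
    d <- data.frame(x = rnorm(30), y = rnorm(30))
    length(stepwise_regression(d, "y", predictors = "x",
                               sle = 0.05, sls = 0.05)$selected) == 0
  }))
  expect_gt(mean(empty1), 0.91)
  expect_lt(mean(empty1), 0.99)
  # three candidates: empty fraction near (1 - 0.05)^3
  empty3 <- withr::with_seed(19, replicate(300, {
    d <- data.frame(x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30),
                    y = rnorm(30))
    length(stepwise_regression(d, "y", sle = 0.05, sls = 0.05)$selected) == 0
  }))
  expect_gt(mean(empty3), 0.78)
})

test_that("p = 0.08 terms are retained under the 0.15 stay default", {
  # construct a predictor whose partial p sits between 0.05 and 0.15
  found <- withr::with_seed(20, {
    reps <- replicate(200, {
      d <- data.frame(x = rnorm(20))
      d$y <- 0.4 * d$x + rnorm(20)
      st <- stepwise_regression(d, "y", predictors = "x")
      if (!length(st$selected)) return(NA)
      p <- tidy(st)$p.value[2]
      if (p > 0.05 && p < 0.15) "kept_moderate" else "other"
    })
    any(reps == "kept_moderate", na.rm = TRUE)
  })
  expect_true(found)
})

test_that("exactly collinear candidates are skipped with a warning", {
  d <- withr::with_seed(22, data.frame(x1 = rnorm(20)))
  d$x2 <- 2 * d$x1
  d$y <- d$x1 + withr::with_seed(23, rnorm(20, 0, 0.1))
  expect_warning(st <- stepwise_regression(d, "y"), "collinear")
  expect_equal(st$selected, "x1")
})
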
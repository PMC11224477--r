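test_that("logistic weight evaluates the model and honours its bounds", {
  # half of A at t = lnB/C by symmetry
  expect_equal(logistic_weight(log(40) / 0.15, 30, 40, 0.15), 15)
  # direct substitution at t = 0
  expect_equal(logistic_weight(0, 30, 40, 0.15), 30 / 41)
  # asymptote
  expect_equal(logistic_weight(1e4, 30, 40, 0.15), 30, tolerance = 1e-10)
  # strictly increasing and bounded in (0, A)
  t <- seq(-20, 120, 0.5)
  w <- logistic_weight(t, 30, 40, 0.15)
  expect_true(all(diff(w) > 0))
  expect_true(all(w > 0 & w < 30))
  expect_error(logistic_weight(10, -1, 40, 0.15),
               class = "grainfill_invalid_params")
  expect_error(logistic_weight(10, 30, 0, 0.15),
               class = "grainfill_invalid_params")
})

test_that("logistic rate is the derivative, positive, peaking at AC/4", {
  expect_equal(logistic_rate(log(40) / 0.15, 30, 40, 0.15), 30 * 0.15 / 4)
  expect_equal(logistic_rate(0, 30, 40, 0.15), 30 * 40 * 0.15 / 41^2)
  # finite-difference check at assorted times and parameters
  h <- 1e-5
  for (t in c(0, 10, 24.6, 50)) {
    fd <- (logistic_weight(t + h, 28, 33, 0.13) -
             logistic_weight(t - h, 28, 33, 0.13)) / (2 * h)
    expect_equal(logistic_rate(t, 28, 33, 0.13), fd, tolerance = 1e-7)
  }
  t <- seq(-10, 100, 0.5)
  expect_true(all(logistic_rate(t, 30, 40, 0.15) > 0))
})

test_that("phase partition reproduces the closed forms", {
  ph <- partition_phases(data.frame(A = 30, B = 40, C = 0.15))
  # frozen from independent closed-form evaluation with offsets
  # 1.317 and 4.59512 (the printed-constants default)
  expect_equal(ph$t1, 15.8125296941, tolerance = 1e-9)
  expect_equal(ph$t2, 33.3725296941, tolerance = 1e-9)
  expect_equal(ph$t3, 55.2266630274, tolerance = 1e-9)
  expect_equal(ph$T2, 17.56, tolerance = 1e-9)
  expect_equal(ph$T3, 21.8541333333, tolerance = 1e-9)
  expect_equal(ph$W1, 6.33953544934, tolerance = 1e-9)
  expect_equal(ph$W2, 23.6604645507, tolerance = 1e-9)
  expect_equal(ph$V2, 0.98638548413, tolerance = 1e-9)
  expect_equal(ph$W0, 30 / 41)
  expect_equal(ph$t_max, log(40) / 0.15)
  expect_equal(ph$G_max, 30 * 0.15 / 4)
})

test_that("partition satisfies ordering, mass balance and scale equivariance", {
  pars <- random_params(200)
  ph <- partition_phases(pars, constants = "exact")
  expect_true(all(ph$t1 > 0 & ph$t1 < ph$t_max & ph$t_max < ph$t2 &
                    ph$t2 < ph$t3))
  expect_equal(ph$t_max, (ph$t1 + ph$t2) / 2)
  expect_true(all(ph$V2 > ph$V1 & ph$V2 > ph$V3))
  expect_true(all(ph$T3 > ph$T2))
  # mass balance: gains sum to 0.99A - W0
  expect_equal(ph$w1 + ph$w2 + ph$w3, 0.99 * ph$A - ph$W0,
               tolerance = 1e-9)
  # scaling A by k scales weights/rates, leaves times alone;
  # scaling C by k divides times, multiplies rates
  k <- 2.7
  phA <- partition_phases(transform(pars, A = A * k), constants = "exact")
  expect_equal(phA$t1, ph$t1)
  expect_equal(phA$W2, ph$W2 * k)
  expect_equal(phA$V1, ph$V1 * k)
  expect_equal(phA$G_max, ph$G_max * k)
  phC <- partition_phases(transform(pars, C = C * k), constants = "exact")
  expect_equal(phC$t3, ph$t3 / k)
  expect_equal(phC$V2, ph$V2 * k)
})

test_that("W1/A, W2/A, W3/A are the fixed logistic fractions", {
  ph <- partition_phases(random_params(50, seed = 7), constants = "exact")
  expect_equal(ph$W1 / ph$A, rep(0.211324865405, 50), tolerance = 1e-9)
  expect_equal(ph$W2 / ph$A, rep(1 - 0.211324865405, 50), tolerance = 1e-9)
  expect_equal(ph$W3 / ph$A, rep(0.99, 50), tolerance = 1e-9)
})

test_that("V2/V3 and T3/T2 are parameter-free constants", {
  for (mode in c("printed", "exact")) {
    ph <- partition_phases(random_params(100, seed = 3), constants = mode)
    expect_lt(diff(range(ph$V2 / ph$V3)), 1e-12)
    expect_lt(diff(range(ph$T3 / ph$T2)), 1e-12)
    expect_equal(mean(ph$V2 / ph$V3), 3.5698, tolerance = 1e-3)
    expect_equal(mean(ph$T3 / ph$T2), 1.2446, tolerance = 1e-3)
  }
})

test_that("degenerate partition is refused when lnB <= k1", {
  expect_error(partition_phases(data.frame(A = 1, B = exp(1.317), C = 1)),
               class = "grainfill_degenerate_partition")
  # just above the boundary: t1 small and positive, V1 finite
  eps <- 1e-6
  ph <- partition_phases(data.frame(A = 1, B = exp(1.317 + eps), C = 1))
  expect_gt(ph$t1, 0)
  expect_lt(ph$t1, 1e-5)
  expect_true(is.finite(ph$V1))
})

test_that("numeric root-finding recovers the printed offset constants", {
  k <- derive_phase_offsets(A = 28, B = 55, C = 0.12)
  expect_equal(k$value[k$constant == "k1"], log(2 + sqrt(3)),
               tolerance = 1e-8)
  expect_equal(k$value[k$constant == "k3"], log(99), tolerance = 1e-8)
})
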
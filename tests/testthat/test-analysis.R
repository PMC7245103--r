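# build a sweep_result by hand from known curves
fake_sweep <- function(values, ..., parameter = "D") {
  curves <- list(...)
  summaries <- data.frame(value = values, curves, check.names = FALSE)
  structure(list(parameter = parameter, grid = values, summaries = summaries,
                 tracked = names(curves), n_reps = 1L, seed = 1L,
                 window = c(0.5, 1)),
            class = "sweep_result")
}

test_that("parameter sweeps have the right shape and are reproducible", {
  p <- unit_dimer_params()
  net <- dimer_network(p)
  sw <- sweep_parameter(net, p, "D", c(0.5, 2), init_counts = c(M1 = 80),
                        horizon = 2, n_reps = 1, seed = 5, tracked = "M2c")
  expect_identical(nrow(sw$summaries), 2L)
  sw2 <- sweep_parameter(net, p, "D", c(0.5, 2), init_counts = c(M1 = 80),
                         horizon = 2, n_reps = 1, seed = 5, tracked = "M2c")
  expect_identical(sw$summaries, sw2$summaries)
  # corner-dimer yield increases with the dimerization ratio
  expect_gt(sw$summaries$M2c[2], sw$summaries$M2c[1])
  expect_error(sweep_parameter(net, p, "banana", 1, c(M1 = 1), 1, 1, 1),
               "parameter must be")
  expect_error(sweep_parameter(net, p, "D", numeric(0), c(M1 = 1), 1, 1, 1),
               "non-empty")
})

test_that("the critical-point detector finds steps and refuses flat curves", {
  v <- seq(0.125, 0.925, by = 0.05)  # the step at 0.5 falls between grid points
  step <- fake_sweep(v, M154c = ifelse(v < 0.5, 0, 10))
  cp <- detect_critical_point(step, "M154c")
  expect_false(cp$no_transition)
  expect_equal(cp$critical_value, 0.5, tolerance = 1e-12)

  set.seed(42)
  logi <- fake_sweep(v, M154c = 10 / (1 + exp(-(v - 0.3) / 0.02)) +
                       rnorm(length(v), sd = 0.1))
  cp2 <- detect_critical_point(logi, "M154c")
  expect_lt(abs(cp2$critical_value - 0.3), 0.05 + 1e-9)  # within grid spacing

  flat <- fake_sweep(v, M154c = rep(3, length(v)))
  expect_true(detect_critical_point(flat, "M154c")$no_transition)
  expect_error(detect_critical_point(step, "M9"), "not tracked")
})

test_that("scaling-exponent fits recover synthetic power laws on both sides", {
  dc <- 0.5
  v <- sort(c(dc - seq(0.005, 0.12, by = 0.005), dc + seq(0.005, 0.12, by = 0.005)))
  set.seed(7)
  jit <- exp(rnorm(length(v), sd = 0.005))  # avoid exact-fit degeneracy
  a <- abs(v - dc)^0.5 * jit
  fit <- fit_scaling_exponents(fake_sweep(v, M154c = a), dc, "M154c")
  expect_equal(fit$left$exponent, 0.5, tolerance = 0.05)
  expect_equal(fit$right$exponent, 0.5, tolerance = 0.05)

  two <- ifelse(v < dc, abs(v - dc)^0.3, abs(v - dc)^0.8) * jit
  fit2 <- fit_scaling_exponents(fake_sweep(v, M154c = two), dc, "M154c")
  expect_equal(fit2$left$exponent, 0.3, tolerance = 0.05)
  expect_equal(fit2$right$exponent, 0.8, tolerance = 0.05)
  expect_gt(fit2$right$exponent, fit2$left$exponent)

  onesided <- ifelse(v < dc, 0, abs(v - dc)^0.5 * jit)
  fit3 <- fit_scaling_exponents(fake_sweep(v, M154c = onesided), dc, "M154c")
  expect_true(fit3$left$undetermined)
  expect_false(fit3$right$undetermined)
})

test_that("the coexistence metric is a normalized minimum with interior peak", {
  expect_identical(coexistence_metric(c(0, 5), c(10, 10)), 0)
  expect_identical(coexistence_metric(c(10, 7), c(10, 7)), 1)
  v <- seq(0, 1, by = 0.1)
  ball <- pmax(0, 1 - abs(v - 0.3) / 0.3)
  wheel <- pmax(0, 1 - abs(v - 0.7) / 0.3)
  cx <- coexistence_curve(fake_sweep(v, M132e = ball, M154c = wheel))
  peak <- cx$value[which.max(cx$coexistence)]
  expect_gt(peak, 0.3)
  expect_lt(peak, 0.7)
})

test_that("the tangent lag time behaves on canonical growth shapes", {
  t <- seq(0, 10, by = 0.05)
  # saturating growth from t = 0: maximum slope at the start, no lag
  sat <- data.frame(t, 1 - exp(-t))
  expect_lt(abs(lag_time(sat)), 0.1)

  # logistic: lag equals the closed-form tangent intercept
  k <- 2; t0 <- 5
  y <- 1 / (1 + exp(-k * (t - t0)))
  y0 <- y[1]
  lag_exact <- t0 - (0.5 - y0) / (k / 4)
  expect_equal(lag_time(data.frame(t, y)), lag_exact, tolerance = 0.1)
  expect_gt(lag_time(data.frame(t, y)), 1)

  expect_error(lag_time(data.frame(t, exp(-t))), "non-increasing")
})

test_that("lag time is read consistently from traces, trajectories and ensembles", {
  t <- seq(0, 10, by = 0.1)
  y <- 1 / (1 + exp(-2 * (t - 4)))
  tr <- kinetic_trace(t, y)
  expect_equal(lag_time(tr), lag_time(data.frame(t, y)))
  fake_traj <- structure(list(grid = t,
                              counts = matrix(y, nrow = 1,
                                              dimnames = list("M154c", NULL)),
                              events = 0, init = NULL, seed = 1),
                         class = "trajectory")
  expect_equal(lag_time(fake_traj, "M154c"), lag_time(tr))
  expect_error(lag_time(fake_traj), "species")
})

test_that("strengthening the template effect does not reduce wheel yield", {
  p <- rate_params()
  net <- giant_network()
  yields <- vapply(c(10, 20), function(tf) {
    ptf <- update_params(p, template_factor = tf)
    ens <- run_ensemble(net, ptf, c(M1 = 3000), 40, n_reps = 12,
                        seed_base = 4000)
    unname(ens$time_averaged_abundance["M154c"])
  }, numeric(1))
  expect_gte(yields[2], 0.8 * yields[1])
})
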
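test_that("release fraction implements the gel-band formula", {
  expect_equal(as.numeric(release_fraction(0, 90)), 0)
  expect_equal(as.numeric(release_fraction(30, 30)), 1)   # empty pellet
  expect_equal(as.numeric(release_fraction(30, 90)), 0.5) # 60 / 120
  expect_error(release_fraction(0, 0), "undefined")
  expect_error(release_fraction(-1, 5), "non-negative")
  # values outside [0, 1] are clipped and flagged
  f <- release_fraction(80, 30)  # 160/110 > 1
  expect_equal(as.numeric(f), 1)
  expect_true(attr(f, "clipped"))
  # alternative denominator reading 2(S+P)
  expect_equal(as.numeric(release_fraction(30, 60,
                                           denominator = "twice_rest")),
               0.5)
})

test_that("exponential-rise fit recovers noiseless and noisy truth", {
  x <- seq(0, 10, length.out = 12)
  y <- 0.8 * (1 - exp(-0.5 * x))
  cf <- fit_exponential_rise(data.frame(time = x, value = y))$coef
  expect_equal(cf[["a"]], 0.8, tolerance = 1e-6)
  expect_equal(cf[["b"]], 0.5, tolerance = 1e-6)
  # with offset
  cf2 <- fit_exponential_rise(data.frame(time = x, value = 0.1 + y),
                              with_offset = TRUE)$coef
  expect_equal(cf2[["y0"]], 0.1, tolerance = 1e-5)
  # seeded noise: recovery within 10%
  set.seed(3)
  yn <- y + rnorm(12, 0, 0.02)
  cfn <- fit_exponential_rise(data.frame(time = x, value = yn))$coef
  expect_lt(abs(cfn[["a"]] - 0.8) / 0.8, 0.1)
  expect_lt(abs(cfn[["b"]] - 0.5) / 0.5, 0.1)
  expect_error(fit_exponential_rise(data.frame(time = 1:3,
                                               value = c(0, 1, 1))),
               "at least")
})

test_that("constant-zero series yields a degenerate amplitude or failure", {
  x <- seq(0, 10, length.out = 12)
  res <- tryCatch(fit_exponential_rise(data.frame(time = x,
                                                  value = rep(0, 12))),
                  error = function(e) e)
  if (inherits(res, "error")) succeed()
  else expect_lt(res$coef[["a"]], 1e-6)
})

test_that("sigmoid fit recovers its own parameterization, either sign of b", {
  x <- seq(0.5, 10, length.out = 12)
  y <- 0.05 + 0.6 / (1 + (x / 4)^(-4))  # rising: b < 0
  cf <- fit_sigmoid(data.frame(time = x, value = y))$coef
  expect_equal(unname(cf[c("y0", "a", "x0", "b")]),
               c(0.05, 0.6, 4, -4), tolerance = 1e-6)
  # decreasing curve: b > 0
  yd <- 0.05 + 0.6 / (1 + (x / 4)^(4))
  cfd <- fit_sigmoid(data.frame(time = x, value = yd))$coef
  expect_equal(cfd[["b"]], 4, tolerance = 1e-5)
  # noisy x0 recovery within 10%
  set.seed(9)
  cfn <- fit_sigmoid(data.frame(time = x,
                                value = y + rnorm(12, 0, 0.02)))$coef
  expect_lt(abs(cfn[["x0"]] - 4) / 4, 0.1)
  expect_error(fit_sigmoid(data.frame(time = c(0, 1:11),
                                      value = rep(0.5, 12))),
               "positive times")
})

test_that("tangent-intercept lag of a fitted sigmoid is sensible", {
  x <- seq(5, 300, length.out = 20)
  y <- 0 + 1 / (1 + (x / 60)^(-6))
  f <- fit_sigmoid(data.frame(time = x, value = y))
  expect_gt(f$lag, 0)
  expect_lt(f$lag, 60)  # intercept precedes the inflection point
  # a sharper sigmoid has a lag closer to its inflection point
  y2 <- 0 + 1 / (1 + (x / 60)^(-12))
  f2 <- fit_sigmoid(data.frame(time = x, value = y2))
  expect_gt(f2$lag, f$lag)
})

test_that("model selection prefers the generating family", {
  x <- seq(0, 10, length.out = 12)
  set.seed(17)
  y <- 0.8 * (1 - exp(-0.5 * x)) + rnorm(12, 0, 0.02)
  fit <- fit_kinetics(data.frame(time = x, value = y))
  expect_true(fit$form %in% c("exp_rise", "exp_rise_offset"))
  expect_identical(fit$lag, 0)
  expect_false(fit$lag_detected)
  # sharp sigmoid truth
  x2 <- seq(5, 300, length.out = 16)
  set.seed(18)
  y2 <- 1 / (1 + (x2 / 60)^(-6)) + rnorm(16, 0, 0.02)
  fit2 <- fit_kinetics(data.frame(time = x2, value = y2))
  expect_identical(fit2$form, "sigmoid")
  expect_true(fit2$lag_detected)
  expect_gt(fit2$lag, 0)
})

test_that("kinfit methods are coherent", {
  x <- seq(0.5, 10, length.out = 12)
  set.seed(4)
  y <- 0.05 + 0.6 / (1 + (x / 4)^(-4)) + rnorm(12, 0, 0.01)
  fit <- fit_kinetics(data.frame(time = x, value = y))
  expect_s3_class(fit, "kinfit")
  expect_named(coef(fit), c("y0", "a", "x0", "b"), ignore.order = TRUE)
  expect_equal(fitted(fit), predict(fit))
  expect_equal(residuals(fit), y - fitted(fit))
  expect_equal(predict(fit, newdata = c(2, 4)),
               fit$fit$fitted_fun(c(2, 4)))
  s <- summary(fit)
  expect_s3_class(s, "summary.kinfit")
  expect_true(all(c("form", "aicc") %in% names(s$table)))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(12L, 2L))
  expect_output(print(fit), "selected form")
})

test_that("end-to-end lag phenomenology distinguishes slow and fast isomerization", {
  ch <- chain_spec(200)
  times <- release_time_grid()
  seeds <- replicate_seeds(1000)
  slow <- fit_kinetics(averaged_release_tc(
    rate_parameters(k_iso = 0.05), ch, times, seeds))
  fast <- fit_kinetics(averaged_release_tc(
    rate_parameters(k_iso = 5), ch, times, seeds))
  nusg <- fit_kinetics(averaged_release_tc(
    rate_parameters(k_iso = 0.05, nusg_factor = 100), ch, times, seeds,
    nusg = TRUE))
  expect_identical(slow$form, "sigmoid")
  expect_gt(slow$lag, 0)
  expect_true(fast$form %in% c("exp_rise", "exp_rise_offset"))
  expect_identical(fast$lag, 0)
  expect_true(nusg$form %in% c("exp_rise", "exp_rise_offset"))
  expect_identical(nusg$lag, 0)
})

test_that("estimated lag tracks the mean commitment time across k_iso", {
  # The tangent-intercept lag of the model traces follows the mean
  # commitment time across the isomerization-rate sweep; for the ATP
  # trace the late-phase intercept converges to E[T] itself.
  k_sweep <- c(0.01, 0.02, 0.05, 0.1, 0.2)
  tt <- seq(10, 2000, by = 10)
  mct <- atp_lag <- rel_lag <- numeric(length(k_sweep))
  for (i in seq_along(k_sweep)) {
    p <- rate_parameters(k_iso = k_sweep[i])
    mct[i] <- mean_commitment_time(p)
    atp_lag[i] <- tangent_lag(simulate_atp_trace(p, tt))
    rel_lag[i] <- tangent_lag(simulate_release_analytic(p, chain_spec(200),
                                                        tt))
  }
  expect_gte(cor(atp_lag, mct, method = "spearman"), 0.9)
  expect_gte(cor(rel_lag, mct, method = "spearman"), 0.9)
  # the ATP lag estimates the commitment time quantitatively
  expect_true(all(abs(atp_lag - mct) / mct < 0.1))
})
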
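test_that("mean commitment time matches the closed form and its limits", {
  # two sequential unit-rate steps
  expect_equal(mean_commitment_time(
    rate_parameters(k_on = 1, k_off = 0, k_iso = 1)), 2.0)
  # reversible binding adds one expected futile cycle
  expect_equal(mean_commitment_time(
    rate_parameters(k_on = 1, k_off = 1, k_iso = 1)), 3.0)
  # NusG multiplier is exactly equivalent to scaling k_iso
  p_slow <- rate_parameters(k_on = 1, k_off = 1, k_iso = 0.05,
                            nusg_factor = 100)
  p_fast <- rate_parameters(k_on = 1, k_off = 1, k_iso = 5)
  expect_identical(mean_commitment_time(p_slow, nusg = TRUE),
                   mean_commitment_time(p_fast))
  expect_equal(mean_commitment_time(p_slow, nusg = TRUE), 1.4)
})

test_that("mean commitment time agrees with stochastic sampling", {
  p <- rate_parameters(k_on = 1, k_off = 1, k_iso = 1)
  set.seed(101)
  s <- rhoterm:::sample_commitment_times(p, 1e5)
  expect_lt(abs(mean(s) - 3) / 3, 0.02)
})

test_that("commitment time decreases in k_iso and nusg_factor", {
  set.seed(7)
  for (i in 1:5) {
    k_on <- runif(1, 0.05, 2); k_off <- runif(1, 0, 2)
    ks <- sort(runif(4, 0.01, 5))
    mct <- sapply(ks, function(k) mean_commitment_time(
      rate_parameters(k_on = k_on, k_off = k_off, k_iso = k)))
    expect_true(all(diff(mct) < 0))
    nf <- c(1, 2, 10, 100)
    mctn <- sapply(nf, function(f) mean_commitment_time(
      rate_parameters(k_on = k_on, k_off = k_off, k_iso = 0.05,
                      nusg_factor = f), nusg = TRUE))
    expect_true(all(diff(mctn) < 0))
  }
})

test_that("invalid rate parameters are rejected", {
  expect_error(rate_parameters(k_on = 0), "strictly positive")
  expect_error(rate_parameters(k_iso = -1), "strictly positive")
  expect_error(rate_parameters(k_off = -0.1), ">= 0")
  expect_error(rate_parameters(nusg_factor = 0), "strictly positive")
  expect_error(chain_spec(-1), "non-negative")
  expect_error(chain_spec(2.5), "integer")
})

test_that("analytic release curve is a CDF with the hypoexponential limit", {
  p <- rate_parameters(k_on = 1, k_off = 0, k_iso = 1, k_step = 1,
                       k_dislodge = 1)
  ch <- chain_spec(3)
  tt <- c(1e-9, seq(0.5, 40, by = 0.5))
  tc <- simulate_release_analytic(p, ch, tt)
  expect_lt(tc$value[1], 1e-6)                 # F(0) = 0
  expect_true(all(diff(tc$value) >= -1e-10))   # monotone
  expect_gt(tail(tc$value, 1), 0.999)          # F -> 1
  # hypoexponential mean = sum of reciprocal stage rates = 6 s
  sim <- simulate_release_stochastic(p, ch, n_traj = 1e4, seed = 11)
  expect_lt(abs(mean(sim$release_times) - 6) / 6, 0.05)
  # hypoexponential variance = sum of reciprocal squared rates = 6 s^2
  expect_lt(abs(var(sim$release_times) - 6) / 6, 0.10)
})

test_that("fast isomerization collapses to the two-stage closed form", {
  p <- rate_parameters(k_on = 1, k_off = 0, k_iso = 1000, k_step = 1,
                       k_dislodge = 1)
  tt <- seq(0.25, 20, by = 0.25)
  tc <- simulate_release_analytic(p, chain_spec(0), tt)
  two_step <- 1 - (1 + tt) * exp(-tt)  # Erlang(2, 1) CDF
  expect_lt(max(abs(tc$value - two_step)), 1e-3)
})

test_that("slow isomerization with a long chain produces a visible lag", {
  p <- rate_parameters(k_on = 1, k_off = 1, k_iso = 0.05, k_step = 1,
                       k_dislodge = 1)
  ch <- chain_spec(50)
  tc <- simulate_release_analytic(p, ch, c(5, 200))
  expect_lt(tc$value[1], 0.05)
  expect_gt(tc$value[2], 0.9)
  # stochastic cross-check at the same two times
  sim <- simulate_release_stochastic(p, ch, n_traj = 1e4, seed = 21)
  ec <- stats::ecdf(sim$release_times)
  expect_lt(abs(ec(5) - tc$value[1]), 0.02)
  expect_lt(abs(ec(200) - tc$value[2]), 0.02)
})

test_that("stochastic simulation is seed-deterministic and handles n_traj = 1", {
  p <- rate_parameters()
  ch <- chain_spec(10)
  s1 <- simulate_release_stochastic(p, ch, n_traj = 500, seed = 42)
  s2 <- simulate_release_stochastic(p, ch, n_traj = 500, seed = 42)
  expect_identical(s1$release_times, s2$release_times)
  one <- simulate_release_stochastic(p, ch, n_traj = 1, seed = 1)
  expect_length(one$release_times, 1L)
  expect_setequal(unique(one$timecourse$value), c(0, 1))  # single-jump ECDF
})

test_that("ATP trace follows the committed-state integral", {
  # instant commitment: f(t) ~ min(1, 0.01 t)
  p <- rate_parameters(k_on = 1e4, k_off = 0, k_iso = 1e4, k_cat = 0.01,
                       atp_pool = 1)
  a <- simulate_atp_trace(p, times = c(10, 50, 99.9))
  expect_lt(abs(a$value[2] - 0.5) / 0.5, 0.01)
  expect_true(all(diff(a$value) >= 0))
  expect_true(all(a$value <= 1))
  # slow isomerization lags behind fast; NusG equivalence is exact
  base <- rate_parameters(k_on = 0.05, k_off = 0.005, k_iso = 0.05,
                          nusg_factor = 100)
  tt <- seq(10, 900, by = 10)
  slow <- simulate_atp_trace(base, tt)
  fast <- simulate_atp_trace(modifyList(base, list(k_iso = 5)), tt)
  expect_gt(tangent_lag(slow), tangent_lag(fast))
  nusg <- simulate_atp_trace(base, tt, nusg = TRUE)
  expect_lt(max(abs(nusg$value - fast$value)), 0.01)
})

test_that("termination zone prediction matches the catch-up closed form", {
  p <- rate_parameters(k_on = 1, k_off = 0, k_iso = 1, k_dislodge = Inf)
  # deterministic commitment time of 10 s: distance 10*20*60/40 = 300 nt
  z <- predict_termination_zone(p, rnap_speed = 20, rho_speed = 60,
                                commitment_times = rep(10, 100))
  expect_equal(z$mean_distance, 300)
  expect_equal(z$mc_mean, 300)
  expect_true(all(z$distances > 0))
  expect_error(predict_termination_zone(p, rnap_speed = 20, rho_speed = 20),
               "catch-up")
})

test_that("termination distance shrinks as isomerization speeds up", {
  # fast binding so commitment is isomerization-limited: the slow
  # terminator's zone sits several-fold further out, mirroring the
  # distal t_rac-like versus proximal t_R1-like distance classes
  mk <- function(k_iso, nusg = FALSE) predict_termination_zone(
    rate_parameters(k_on = 1, k_off = 1, k_iso = k_iso),
    rnap_speed = 20, rho_speed = 60, n_traj = 2000, seed = 5,
    nusg = nusg)
  slow <- mk(0.05); fast <- mk(5)
  expect_gt(slow$mean_distance / fast$mean_distance, 3)
  expect_lt(abs(slow$mc_mean - slow$mean_distance) / slow$mean_distance,
            0.05)
  # NusG reproduces the early-termination shift
  nusg <- mk(0.05, nusg = TRUE)
  expect_lt(nusg$mean_distance, slow$mean_distance)
  expect_equal(nusg$mean_distance, fast$mean_distance)
})
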
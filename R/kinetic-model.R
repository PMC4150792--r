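#' Mean time to form a translocase-competent Rho
#'
#' Closed-form mean first-passage time from free Rho to the committed
#' (closed-hexamer) state for the reversible-binding-then-isomerization
#' chain Free <-> Bound(OH) -> Committed(CH):
#' \deqn{T = (k_{off} + k_{eff}) / (k_{on} k_{eff}) + 1/k_{eff}}
#' with \eqn{k_{eff} = k_{iso} \cdot nusg\_factor} when NusG is present and
#' \eqn{k_{iso}} otherwise. The mean decreases monotonically in both
#' `k_iso` and `nusg_factor`: a faster isomerization drives the reversible
#' binding equilibrium towards the irreversible committed form.
#'
#' @param params a [rate_parameters()] object.
#' @param nusg logical; apply the NusG multiplier to the isomerization
#'   rate?
#' @return Mean commitment time in seconds.
#' @examples
#' mean_commitment_time(rate_parameters(k_on = 1, k_off = 0, k_iso = 1)) # 2 s
#' @export
mean_commitment_time <- function(params, nusg = FALSE) {
  validate_rate_params(params)
  ke <- effective_k_iso(params, nusg)
  (params$k_off + ke) / (params$k_on * ke) + 1 / ke
}

# Mean time from free Rho to RNA release (commitment + translocation +
# dislodging); used for hypoexponential checks.
mean_release_time <- function(params, chain, nusg = FALSE) {
  mean_commitment_time(params, nusg) +
    chain$n_steps / params$k_step +
    (if (is.finite(params$k_dislodge)) 1 / params$k_dislodge else 0)
}

#' Analytic release kinetics of the recruitment chain
#'
#' Integrates the master equation of the linear recruitment CTMC and
#' returns the probability that the nascent RNA has been released by each
#' requested time, i.e. the model analogue of a fraction-released time
#' course from a road-blocked elongation complex. With `k_off = 0` the
#' release-time distribution is hypoexponential with mean equal to the sum
#' of the reciprocal stage rates.
#'
#' @inheritParams mean_commitment_time
#' @param chain a [chain_spec()] object.
#' @param times non-empty numeric vector of non-negative, strictly
#'   increasing sampling times (seconds).
#' @param nusg logical; apply the NusG multiplier to `k_iso`?
#' @return A [timecourse()] of kind `"release"`.
#' @examples
#' p <- rate_parameters(k_on = 1, k_off = 0, k_iso = 1, k_step = 1,
#'                      k_dislodge = 1)
#' simulate_release_analytic(p, chain_spec(3), times = c(1, 5, 10, 20))
#' @export
simulate_release_analytic <- function(params, chain, times, nusg = FALSE) {
  validate_rate_params(params)
  stopifnot(inherits(chain, "chain_spec"))
  if (length(times) == 0L) stop("time grid must be non-empty", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  p_abs <- master_absorption_prob(params, chain, times, nusg)
  timecourse(times, p_abs, kind = "release")
}

# P(released by t) for the recruitment chain started in the free state,
# via numerical integration of the master equation at rtol 1e-8. The
# banded chain structure gives an O(m) derivative: states are
# 1 Free, 2 Bound(OH), 2+i (i = 1..L) the committed state and the
# remaining irreversible stages (exit rates `irrev`), last = Released.
# An infinite k_dislodge drops that stage (instant-dislodging limit).
master_absorption_prob <- function(params, chain, times, nusg = FALSE) {
  ke <- effective_k_iso(params, nusg)
  k_on <- params$k_on; k_off <- params$k_off
  irrev <- rep(params$k_step, chain$n_steps)
  if (is.finite(params$k_dislodge)) irrev <- c(irrev, params$k_dislodge)
  L <- length(irrev)
  m <- 3L + L
  tt <- times
  add0 <- tt[1] > 0
  if (add0) tt <- c(0, tt)
  deriv <- function(t, y, parms) {
    dy <- numeric(m)
    dy[1] <- -k_on * y[1] + k_off * y[2]
    dy[2] <- k_on * y[1] - (k_off + ke) * y[2]
    if (L > 0L) {
      run <- y[3:(2L + L)]
      inflow <- c(ke * y[2], irrev[-L] * run[-L])
      dy[3:(2L + L)] <- inflow - irrev * run
      dy[m] <- irrev[L] * run[L]
    } else {
      dy[3] <- ke * y[2]
    }
    list(dy)
  }
  sol <- deSolve::ode(y = c(1, rep(0, m - 1L)), times = tt, func = deriv,
                      parms = NULL, rtol = 1e-8, atol = 1e-12,
                      method = "lsoda")
  p <- sol[, m + 1L]
  if (add0) p <- p[-1L]
  pmin(pmax(p, 0), 1)
}

# Exact stochastic sample of commitment times (first passage
# Free -> Committed). The number of binding attempts is geometric with
# success probability k_eff/(k_eff + k_off); each attempt spends
# Exp(k_on) free and Exp(k_off + k_eff) bound.
sample_commitment_times <- function(params, n, nusg = FALSE) {
  ke <- effective_k_iso(params, nusg)
  tot <- ke + params$k_off
  attempts <- rgeom(n, prob = ke / tot) + 1L
  rgamma(n, shape = attempts, rate = params$k_on) +
    rgamma(n, shape = attempts, rate = tot)
}

sample_release_times <- function(params, chain, n, nusg = FALSE) {
  tt <- sample_commitment_times(params, n, nusg)
  if (chain$n_steps > 0L)
    tt <- tt + rgamma(n, shape = chain$n_steps, rate = params$k_step)
  if (is.finite(params$k_dislodge))
    tt <- tt + rexp(n, rate = params$k_dislodge)
  tt
}

#' Stochastic release kinetics (exact chain sampling)
#'
#' Draws exact first-passage (release) times of the recruitment CTMC --
#' distributionally identical to a Gillespie simulation of the linear
#' scheme, with the holding times of each stage sampled directly -- and
#' returns both the sample and its empirical CDF on a time grid. Serves as
#' the stochastic cross-check for [simulate_release_analytic()].
#'
#' @inheritParams simulate_release_analytic
#' @param n_traj number of trajectories (>= 1).
#' @param seed integer seed; identical seeds give bit-identical samples.
#' @param times optional time grid for the empirical CDF; defaults to 50
#'   points spanning the sample.
#' @return A list of class `"release_sim"` with elements `release_times`
#'   (numeric sample) and `timecourse` (empirical CDF as a
#'   [timecourse()]).
#' @export
simulate_release_stochastic <- function(params, chain, n_traj = 10000L,
                                        seed = NULL, times = NULL,
                                        nusg = FALSE) {
  validate_rate_params(params)
  stopifnot(inherits(chain, "chain_spec"))
  if (n_traj < 1) stop("n_traj must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rt <- sample_release_times(params, chain, n_traj, nusg)
  if (is.null(times))
    times <- seq(min(rt) * 0.5, max(rt), length.out = 50L)
  ec <- stats::ecdf(rt)
  structure(list(release_times = rt,
                 timecourse = timecourse(times, ec(times), "release")),
            class = "release_sim")
}

#' @export
print.release_sim <- function(x, ...) {
  cat(sprintf("Stochastic release sample: %d trajectories, mean %.3g s, sd %.3g s\n",
              length(x$release_times), mean(x$release_times),
              stats::sd(x$release_times)))
  invisible(x)
}

#' ATP-hydrolysis kinetics of recruitment
#'
#' Models nascent-RNA-activated ATP hydrolysis as proceeding at `k_cat`
#' per Rho from the moment of commitment (the closed-hexamer state): the
#' fraction of the ATP pool hydrolyzed by time t is
#' \deqn{f(t) = \min\{1, (k_{cat}/pool) \int_0^t P(\mathrm{committed\ by\ } s) ds\}.}
#' A slow isomerization therefore shows up as a lag before hydrolysis
#' starts, as seen for weak terminators; NusG removes the lag by
#' accelerating the isomerization.
#'
#' @inheritParams simulate_release_analytic
#' @return A [timecourse()] of kind `"atp"`.
#' @export
simulate_atp_trace <- function(params, times, nusg = FALSE) {
  validate_rate_params(params)
  if (length(times) == 0L) stop("time grid must be non-empty", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  ke <- effective_k_iso(params, nusg)
  k_on <- params$k_on; k_off <- params$k_off
  tt <- times
  add0 <- tt[1] > 0
  if (add0) tt <- c(0, tt)
  # states: free, bound, cumulative time spent committed
  sol <- deSolve::ode(
    y = c(f = 1, b = 0, int_c = 0), times = tt,
    func = function(t, y, parms) {
      cc <- 1 - y[1] - y[2]
      list(c(-k_on * y[1] + k_off * y[2],
             k_on * y[1] - (k_off + ke) * y[2],
             cc))
    },
    parms = NULL, rtol = 1e-8, atol = 1e-12)
  int_c <- sol[, "int_c"]
  if (add0) int_c <- int_c[-1L]
  f <- pmin(1, pmax(0, params$k_cat / params$atp_pool * int_c))
  timecourse(times, f, kind = "atp")
}

#' Predicted termination zone from recruitment kinetics
#'
#' Decomposes the rut-to-termination distance into the two times the
#' kinetic framework identifies: the time to form a translocase-competent
#' Rho at the rut site and the time to dislodge the EC. RNAP is
#' `start_offset` nt past the rut 3' end when the commitment clock starts
#' and elongates at `rnap_speed`; after a random commitment time T, Rho
#' translocates at `rho_speed` and catches up at
#' \deqn{x = (start\_offset + v_{RNAP} T) \rho / (\rho - v_{RNAP}),}
#' after which RNAP runs on for an Exp(`k_dislodge`) dislodging time. The
#' analytic mean distance is
#' \deqn{(start\_offset + v_{RNAP} E[T]) \rho/(\rho - v_{RNAP}) + v_{RNAP}/k_{dislodge}.}
#' Increasing `k_iso` (or adding NusG) shortens E[T] and hence moves the
#' termination zone closer to the rut site -- the model's account of
#' NusG-induced early termination and of the long termination distances of
#' slowly isomerizing, t_rac-like terminators.
#'
#' @inheritParams simulate_release_analytic
#' @param rnap_speed RNAP elongation speed (nt/s).
#' @param rho_speed Rho translocation speed (nt/s); must exceed
#'   `rnap_speed` or Rho never catches up.
#' @param start_offset nt head start of RNAP past the rut 3' end.
#' @param n_traj Monte-Carlo sample size.
#' @param seed optional integer seed.
#' @param commitment_times optional numeric vector of commitment times to
#'   use instead of sampling (e.g. a degenerate deterministic T).
#' @return A list of class `"termination_zone_pred"` with `mean_distance`
#'   (analytic), `distances` (Monte-Carlo sample, nt) and `mc_mean`.
#' @export
predict_termination_zone <- function(params, rnap_speed = 20, rho_speed = 60,
                                     start_offset = 0, n_traj = 10000L,
                                     seed = NULL, nusg = FALSE,
                                     commitment_times = NULL) {
  validate_rate_params(params)
  if (!(rnap_speed > 0)) stop("rnap_speed must be > 0", call. = FALSE)
  if (rho_speed <= rnap_speed)
    stop("no catch-up: rho_speed must exceed rnap_speed", call. = FALSE)
  if (start_offset < 0) stop("start_offset must be >= 0", call. = FALSE)
  gain <- rho_speed / (rho_speed - rnap_speed)
  drift <- if (is.finite(params$k_dislodge))
    rnap_speed / params$k_dislodge else 0
  if (is.null(commitment_times)) {
    if (!is.null(seed)) set.seed(seed)
    tt <- sample_commitment_times(params, n_traj, nusg)
    e_t <- mean_commitment_time(params, nusg)
  } else {
    tt <- commitment_times
    e_t <- mean(commitment_times)
  }
  tau <- if (is.finite(params$k_dislodge))
    rexp(length(tt), params$k_dislodge) else 0
  d <- (start_offset + rnap_speed * tt) * gain + rnap_speed * tau
  structure(list(
    mean_distance = (start_offset + rnap_speed * e_t) * gain + drift,
    distances = d,
    mc_mean = mean(d),
    rnap_speed = rnap_speed, rho_speed = rho_speed,
    start_offset = start_offset),
    class = "termination_zone_pred")
}

#' @export
print.termination_zone_pred <- function(x, ...) {
  cat(sprintf(
    "Predicted termination zone: mean distance %.1f nt (MC %.1f nt, n = %d)\n",
    x$mean_distance, x$mc_mean, length(x$distances)))
  invisible(x)
}
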
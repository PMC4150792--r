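#' Fraction of released RNA from gel band intensities
#'
#' In the release assay, half of the supernatant (S) is loaded in one lane
#' and the rest of the sample -- the other supernatant half plus the pellet
#' (S+P) -- in another. The released fraction is then 2S / (S + (S+P)).
#' An alternative reading of the denominator, 2(S+P), is available via
#' `denominator = "twice_rest"`.
#'
#' @param s_half band intensity of the loaded supernatant half (>= 0).
#' @param s_plus_p band intensity of the remaining sample (>= 0).
#' @param denominator `"sum"` for S + (S+P) (default) or `"twice_rest"`
#'   for 2(S+P).
#' @param clip clip the result into \[0, 1\]? Clipping is reported through
#'   a `"clipped"` attribute.
#' @return Released fraction(s) in \[0, 1\] (vectorized).
#' @examples
#' release_fraction(30, 90)  # 0.5
#' @export
release_fraction <- function(s_half, s_plus_p,
                             denominator = c("sum", "twice_rest"),
                             clip = TRUE) {
  denominator <- match.arg(denominator)
  if (any(s_half < 0) || any(s_plus_p < 0))
    stop("band intensities must be non-negative", call. = FALSE)
  if (any(s_half + s_plus_p == 0))
    stop("undefined fraction: both band intensities are zero",
         call. = FALSE)
  den <- switch(denominator, sum = s_half + s_plus_p,
                twice_rest = 2 * s_plus_p)
  f <- 2 * s_half / den
  clipped <- f < 0 | f > 1
  if (clip) f <- pmin(pmax(f, 0), 1)
  attr(f, "clipped") <- clipped
  f
}

# Corrected Akaike information criterion for a Gaussian least-squares fit
# with p mean parameters (k = p + 1 counts the error variance). When the
# small-sample correction is undefined (n <= k + 1) the criterion is +Inf
# and the candidate cannot win.
aicc_ls <- function(rss, n, p) {
  k <- p + 1
  if (n <= k + 1) return(Inf)
  if (rss <= 0) rss <- .Machine$double.xmin
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

as_fit_data <- function(tc) {
  if (inherits(tc, "timecourse") || is.data.frame(tc)) {
    data.frame(x = tc$time, y = tc$value)
  } else if (is.list(tc) && !is.null(tc$time)) {
    data.frame(x = tc$time, y = tc$value)
  } else stop("expected a timecourse (columns time, value)", call. = FALSE)
}

fit_failure <- function(msg, diagnostics = NULL) {
  stop(structure(class = c("rhoterm_fit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      diagnostics = diagnostics)))
}

# Run nlsLM over a list of deterministic starts; keep the converged fit
# with the lowest RSS.
multi_start_nls <- function(formula, data, starts, lower, upper) {
  best <- NULL; errs <- character()
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) { errs <- c(errs, conditionMessage(fit)); next }
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    fit_failure("nonlinear least squares failed from all starts",
                diagnostics = errs)
  best
}

#' Fit an exponential-rise model to a release time course
#'
#' Fits `y = a (1 - exp(-b x))` or, with `with_offset = TRUE`,
#' `y = y0 + a (1 - exp(-b x))` by multi-start Levenberg--Marquardt least
#' squares. `a` is the amplitude of the release process and `b` its rate;
#' exponential forms have no lag by construction, so the `lag` element is
#' 0.
#'
#' @param tc a [timecourse()] (or data frame with columns `time`,
#'   `value`).
#' @param with_offset include the baseline parameter `y0`?
#' @return A list of class `"kin_curve_fit"` with elements `form`, `coef`,
#'   `rss`, `n`, `aicc`, `lag` and `fitted_fun`.
#' @export
fit_exponential_rise <- function(tc, with_offset = FALSE) {
  d <- as_fit_data(tc)
  need <- if (with_offset) 5L else 4L
  if (nrow(d) < need)
    stop(sprintf("need at least %d points for this form", need),
         call. = FALSE)
  a0 <- max(d$y) - if (with_offset) min(d$y) else 0
  if (a0 <= 0) a0 <- max(max(d$y), 1e-3)
  y00 <- min(d$y)
  half <- if (with_offset) y00 + a0 / 2 else a0 / 2
  xh <- d$x[which(d$y >= half)[1]]
  if (is.na(xh) || xh <= 0) xh <- max(stats::median(d$x), 1e-6)
  b0 <- log(2) / xh
  mk <- function(a, b) {
    if (with_offset) list(a = a, b = b, y0 = y00) else list(a = a, b = b)
  }
  starts <- list(mk(a0, b0), mk(a0, 3 * b0), mk(a0, b0 / 3),
                 mk(1.25 * a0, b0), mk(0.8 * a0, 5 * b0))
  if (with_offset) {
    form <- y ~ y0 + a * (1 - exp(-b * x))
    lower <- c(a = 1e-10, b = 1e-10, y0 = -Inf)
    upper <- c(a = Inf, b = Inf, y0 = Inf)
  } else {
    form <- y ~ a * (1 - exp(-b * x))
    lower <- c(a = 1e-10, b = 1e-10)
    upper <- c(a = Inf, b = Inf)
  }
  best <- multi_start_nls(form, d, starts, lower, upper)
  cf <- coef(best$fit)
  fitted_fun <- if (with_offset) {
    function(x) cf[["y0"]] + cf[["a"]] * (1 - exp(-cf[["b"]] * x))
  } else {
    function(x) cf[["a"]] * (1 - exp(-cf[["b"]] * x))
  }
  structure(list(
    form = if (with_offset) "exp_rise_offset" else "exp_rise",
    coef = cf, rss = best$rss, n = nrow(d),
    aicc = aicc_ls(best$rss, nrow(d), length(cf)),
    lag = 0, fitted_fun = fitted_fun),
    class = "kin_curve_fit")
}

#' Fit a sigmoid (logistic-type) model to a release time course
#'
#' Fits `y = y0 + a / (1 + (x/x0)^b)` by multi-start least squares. Under
#' this parameterization a *rising* curve has `b < 0` (as x grows past the
#' inflection point `x0`, `(x/x0)^b` vanishes and y approaches `y0 + a`);
#' both signs of `b` are supported and reported. Times must be strictly
#' positive because `(x/x0)^b` is undefined at `x = 0` for negative `b`.
#'
#' @inheritParams fit_exponential_rise
#' @return A `"kin_curve_fit"` list; its `lag` element is the
#'   tangent-intercept lag (see [fit_kinetics()]).
#' @export
fit_sigmoid <- function(tc) {
  d <- as_fit_data(tc)
  if (nrow(d) < 6L)
    stop("need at least 6 points for the sigmoid form", call. = FALSE)
  if (any(d$x <= 0))
    stop("sigmoid form requires strictly positive times", call. = FALSE)
  y00 <- min(d$y); a0 <- max(d$y) - y00
  if (a0 <= 0) a0 <- max(max(d$y), 1e-3)
  half <- y00 + a0 / 2
  x00 <- d$x[which(d$y >= half)[1]]
  if (is.na(x00)) x00 <- stats::median(d$x)
  rising <- stats::cor(d$x, d$y) >= 0
  b_starts <- if (rising) c(-2, -4, -8, -1, 3) else c(2, 4, 8, 1, -3)
  starts <- lapply(b_starts, function(b)
    list(y0 = y00, a = a0, x0 = x00, b = b))
  best <- multi_start_nls(
    y ~ y0 + a / (1 + (x / x0)^b), d, starts,
    lower = c(y0 = -Inf, a = 1e-10, x0 = 1e-10, b = -Inf),
    upper = c(y0 = Inf, a = Inf, x0 = Inf, b = Inf))
  cf <- coef(best$fit)
  fitted_fun <- function(x)
    cf[["y0"]] + cf[["a"]] / (1 + (x / cf[["x0"]])^cf[["b"]])
  lag <- sigmoid_tangent_lag(cf, range(d$x))
  structure(list(
    form = "sigmoid", coef = cf, rss = best$rss, n = nrow(d),
    aicc = aicc_ls(best$rss, nrow(d), length(cf)),
    lag = lag, fitted_fun = fitted_fun),
    class = "kin_curve_fit")
}

# Tangent-intercept lag (standard growth-curve convention): locate the
# point of maximal slope of the fitted sigmoid inside the observed time
# range, draw the tangent there and intersect it with the baseline y0.
sigmoid_tangent_lag <- function(cf, xr) {
  y0 <- cf[["y0"]]; a <- cf[["a"]]; x0 <- cf[["x0"]]; b <- cf[["b"]]
  f <- function(x) y0 + a / (1 + (x / x0)^b)
  df <- function(x) {
    u <- (x / x0)^b
    -a * b * u / (x * (1 + u)^2)
  }
  lo <- max(xr[1], 1e-9); hi <- xr[2]
  opt <- stats::optimize(function(x) abs(df(x)), c(lo, hi), maximum = TRUE)
  xs <- opt$maximum; slope <- df(xs)
  if (!is.finite(slope) || slope == 0) return(0)
  max(0, xs - (f(xs) - y0) / slope)
}

#' @export
print.kin_curve_fit <- function(x, ...) {
  cat(sprintf("%s fit: rss %.4g, AICc %.2f, lag %.2f s\n",
              x$form, x$rss, x$aicc, x$lag))
  print(signif(x$coef, 5))
  invisible(x)
}

#' Fit release/ATPase kinetics with model selection and lag extraction
#'
#' Fits the candidate empirical forms used for release and ATP-hydrolysis
#' time courses -- exponential rise `a(1 - exp(-bx))`, exponential rise
#' with offset `y0 + a(1 - exp(-bx))`, and the sigmoid
#' `y0 + a/(1 + (x/x0)^b)` -- and selects among them by the
#' small-sample-corrected Akaike criterion. The exponential forms compete
#' by plain AICc (ties favour fewer parameters); the sigmoid, being the
#' most flexible form, is selected -- and a kinetic lag declared -- only
#' when it beats the best exponential form by an AICc margin of at least
#' `aic_margin` (the conventional "substantial support" cutoff of 2, which
#' keeps false lag calls on truly exponential data rare). The lag is the
#' tangent-intercept of the fitted sigmoid at its steepest point with the
#' baseline `y0`, and is 0 for exponential forms. This mirrors how lag
#' phases of slowly isomerizing terminators show up as a flat initial
#' slope in release assays, which disappears when NusG accelerates the
#' isomerization.
#'
#' @param tc a [timecourse()] or data frame with columns `time`, `value`.
#' @param forms character vector of candidate forms to consider.
#' @param aic_margin AICc margin by which the sigmoid must beat the best
#'   exponential form for a lag to be declared (default 2).
#' @param clip clip values into \[0, 1\] before fitting? Clipping is
#'   recorded in the returned object.
#' @return An object of class `"kinfit"` with the selected `form`,
#'   coefficients, the per-form fit table, `lag` (seconds) and
#'   `lag_detected`. Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot` and `simulate`.
#' @examples
#' p <- rate_parameters(k_iso = 5)
#' tc <- simulate_release_analytic(p, chain_spec(200),
#'                                 times = seq(15, 600, by = 45))
#' fit <- fit_kinetics(tc)
#' coef(fit)
#' @export
fit_kinetics <- function(tc,
                         forms = c("exp_rise", "exp_rise_offset", "sigmoid"),
                         aic_margin = 2, clip = TRUE) {
  forms <- match.arg(forms, several.ok = TRUE)
  d <- as_fit_data(tc)
  n_clipped <- 0L
  if (clip) {
    n_clipped <- sum(d$y < 0 | d$y > 1)
    d$y <- pmin(pmax(d$y, 0), 1)
  }
  tc2 <- data.frame(time = d$x, value = d$y)
  fits <- list(); errs <- list()
  for (f in forms) {
    res <- tryCatch(switch(
      f,
      exp_rise = fit_exponential_rise(tc2, with_offset = FALSE),
      exp_rise_offset = fit_exponential_rise(tc2, with_offset = TRUE),
      sigmoid = fit_sigmoid(tc2)),
      error = function(e) e)
    if (inherits(res, "error")) errs[[f]] <- conditionMessage(res)
    else fits[[f]] <- res
  }
  if (length(fits) == 0L)
    fit_failure("all candidate fits failed", diagnostics = errs)
  npar <- vapply(fits, function(f) length(f$coef), numeric(1))
  aicc <- vapply(fits, function(f) f$aicc, numeric(1))
  other <- aicc[names(fits) != "sigmoid"]
  margin <- if ("sigmoid" %in% names(fits) && length(other))
    min(other) - aicc[["sigmoid"]] else -Inf
  # Parsimony rule: the 4-parameter sigmoid must carry substantially more
  # support (dAICc >= aic_margin) than the best exponential form to be
  # selected; otherwise the exponential candidates compete by plain AICc
  # (ties towards fewer parameters).
  if (is.finite(margin) && margin >= aic_margin) {
    sel <- fits[["sigmoid"]]
  } else {
    cand <- names(fits)[names(fits) != "sigmoid"]
    if (length(cand) == 0L) cand <- names(fits)
    ord <- order(aicc[cand], npar[cand])
    sel <- fits[[cand[ord[1]]]]
  }
  lag_detected <- identical(sel$form, "sigmoid")
  lag <- if (identical(sel$form, "sigmoid")) sel$lag else 0
  structure(list(
    form = sel$form, coef = sel$coef, fit = sel, fits = fits,
    aicc = aicc, errors = errs, lag = lag, lag_detected = lag_detected,
    sigmoid_margin = margin, n_clipped = n_clipped,
    data = tc2), class = "kinfit")
}

#' @export
print.kinfit <- function(x, ...) {
  cat(sprintf("Kinetic curve fit (%d points): selected form '%s'\n",
              nrow(x$data), x$form))
  cat("  coefficients: ",
      paste(sprintf("%s = %.4g", names(x$coef), x$coef), collapse = ", "),
      "\n", sep = "")
  if (x$lag_detected)
    cat(sprintf("  lag detected: %.1f s (sigmoid beats exponential by AICc %.1f)\n",
                x$lag, x$sigmoid_margin))
  else
    cat("  no lag detected (lag = 0 s)\n")
  invisible(x)
}

#' @export
summary.kinfit <- function(object, ...) {
  tab <- data.frame(
    form = names(object$fits),
    n_par = vapply(object$fits, function(f) length(f$coef), numeric(1)),
    rss = vapply(object$fits, function(f) f$rss, numeric(1)),
    aicc = object$aicc,
    row.names = NULL)
  tab <- tab[order(tab$aicc), ]
  out <- list(table = tab, form = object$form, coef = object$coef,
              lag = object$lag, lag_detected = object$lag_detected,
              n_clipped = object$n_clipped)
  class(out) <- "summary.kinfit"
  out
}

#' @export
print.summary.kinfit <- function(x, ...) {
  cat("Candidate fits (best first):\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Selected: %s; lag %.2f s (%sdetected)\n", x$form, x$lag,
              if (x$lag_detected) "" else "not "))
  if (x$n_clipped > 0)
    cat(sprintf("Note: %d value(s) clipped into [0, 1] before fitting\n",
                x$n_clipped))
  invisible(x)
}

#' @export
coef.kinfit <- function(object, ...) object$coef

#' @export
predict.kinfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$time
       else if (is.data.frame(newdata)) newdata$time
       else as.numeric(newdata)
  object$fit$fitted_fun(x)
}

#' @export
fitted.kinfit <- function(object, ...) predict(object)

#' @export
residuals.kinfit <- function(object, ...) object$data$value - fitted(object)

#' @export
simulate.kinfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sdr <- sqrt(object$fit$rss / max(1, object$fit$n - length(object$coef)))
  out <- replicate(nsim, mu + rnorm(length(mu), 0, sdr))
  as.data.frame(out)
}

#' @export
plot.kinfit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$time, d$value, pch = 16, xlab = "time (s)",
                 ylab = "fraction", ylim = range(0, 1, d$value), ...)
  xx <- seq(min(d$time), max(d$time), length.out = 200)
  graphics::lines(xx, x$fit$fitted_fun(xx), col = "firebrick", lwd = 2)
  if (x$lag_detected && x$lag > 0)
    graphics::abline(v = x$lag, lty = 2, col = "grey40")
  invisible(x)
}

#' Tangent-intercept lag of a sampled monotone trace
#'
#' Model-free lag estimate for a sampled, monotonically rising trace (for
#' instance an ATP-hydrolysis time course): locate the steepest rise by
#' central finite differences, draw the tangent there, and intersect it
#' with the baseline (the minimum of the trace). Useful where the
#' trace is not well described by any of the [fit_kinetics()] forms but a
#' delay before the signal takes off is still of interest.
#'
#' @param tc a [timecourse()] or data frame with `time` and `value`.
#' @return Lag time in seconds (>= 0).
#' @export
tangent_lag <- function(tc) {
  d <- as_fit_data(tc)
  if (nrow(d) < 3L) stop("need at least 3 points", call. = FALSE)
  x <- d$x; y <- d$y
  n <- length(x)
  slope <- (y[-(1:2)] - y[1:(n - 2)]) / (x[-(1:2)] - x[1:(n - 2)])
  i <- which.max(slope) + 1L  # centre of the steepest secant
  if (slope[i - 1L] <= 0) return(0)
  max(0, x[i] - (y[i] - min(y)) / slope[i - 1L])
}
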
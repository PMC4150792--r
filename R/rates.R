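#' Rate constants of the Rho recruitment scheme
#'
#' Bundles the rate constants of the multi-step Rho recruitment model:
#' reversible (pseudo-first-order) binding of Rho to the rut site, the
#' isomerization of the open hexamer (OH) into the closed,
#' translocase-competent hexamer (CH), per-nucleotide ATP-driven
#' translocation towards the stalled elongation complex (EC), and finally
#' dislodging of the EC. NusG acts purely on the isomerization step: when
#' the NusG flag of a downstream operation is set, the effective
#' isomerization rate becomes `k_iso * nusg_factor`.
#'
#' No rate constant of this scheme has been measured directly; the defaults
#' below are illustrative values chosen to reproduce the qualitative
#' behaviour of weak, lag-prone terminators on the minutes time scale of
#' in vitro release assays (see the package vignette). The default
#' `k_iso = 0.05`/s describes a slowly isomerizing (t_rac-like) terminator;
#' `k_iso = 5`/s is a convenient choice for a fast, t_R1-like one.
#'
#' @param k_on pseudo-first-order Rho--rut association rate (1/s).
#' @param k_off dissociation rate of the open-hexamer complex (1/s);
#'   `0` makes binding irreversible.
#' @param k_iso isomerization rate OH -> CH (often written k2; 1/s). The
#'   OH -> CH transition commits Rho: the model treats everything from the
#'   closed hexamer onward as irreversible.
#' @param k_step translocation stepping rate per nucleotide (1/s).
#' @param k_dislodge rate of EC dissociation once Rho has caught up (1/s).
#'   `Inf` is accepted as the instant-dislodging limit.
#' @param nusg_factor dimensionless multiplier applied to `k_iso` when NusG
#'   is present; must be > 0. Values > 1 encode the NusG acceleration of
#'   the isomerization step.
#' @param k_cat ATP-hydrolysis rate per committed Rho (ATP/s).
#' @param atp_pool total ATP available (same units as `k_cat * t`;
#'   `1` for a normalized pool).
#'
#' @return An object of class `"rate_params"` (a named list).
#' @examples
#' p <- rate_parameters(k_on = 1, k_off = 1, k_iso = 1)
#' mean_commitment_time(p)
#' @export
rate_parameters <- function(k_on = 0.05, k_off = 0.005, k_iso = 0.05,
                            k_step = 60, k_dislodge = 2,
                            nusg_factor = 100, k_cat = 0.002,
                            atp_pool = 1) {
  p <- list(k_on = k_on, k_off = k_off, k_iso = k_iso, k_step = k_step,
            k_dislodge = k_dislodge, nusg_factor = nusg_factor,
            k_cat = k_cat, atp_pool = atp_pool)
  validate_rate_params(p)
  structure(p, class = "rate_params")
}

validate_rate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (nm in c("k_on", "k_off", "k_iso", "k_step", "k_dislodge",
               "nusg_factor", "k_cat", "atp_pool")) {
    if (!num1(p[[nm]]))
      stop("rate parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  strict <- c("k_on", "k_iso", "k_step", "nusg_factor", "k_cat", "atp_pool")
  for (nm in strict)
    if (p[[nm]] <= 0 || !is.finite(p[[nm]]))
      stop("rate parameter '", nm, "' must be strictly positive and finite",
           call. = FALSE)
  if (p$k_off < 0 || !is.finite(p$k_off))
    stop("rate parameter 'k_off' must be finite and >= 0", call. = FALSE)
  if (p$k_dislodge <= 0)
    stop("rate parameter 'k_dislodge' must be > 0 (Inf allowed)",
         call. = FALSE)
  invisible(p)
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Rho recruitment rate constants:\n")
  cat(sprintf("  k_on       %g /s   (rut binding)\n", x$k_on))
  cat(sprintf("  k_off      %g /s   (unbinding)\n", x$k_off))
  cat(sprintf("  k_iso      %g /s   (OH -> CH isomerization, k2)\n", x$k_iso))
  cat(sprintf("  k_step     %g /s   (translocation, per nt)\n", x$k_step))
  cat(sprintf("  k_dislodge %g /s   (EC dissociation)\n", x$k_dislodge))
  cat(sprintf("  nusg_factor %g     (k_iso multiplier with NusG)\n",
              x$nusg_factor))
  cat(sprintf("  k_cat      %g ATP/s, atp_pool %g\n", x$k_cat, x$atp_pool))
  invisible(x)
}

# Effective isomerization rate, honouring the NusG flag.
effective_k_iso <- function(params, nusg = FALSE) {
  if (isTRUE(nusg)) params$k_iso * params$nusg_factor else params$k_iso
}

#' Translocation chain specification
#'
#' Describes the irreversible part of the recruitment chain: after the
#' committed (closed-hexamer) state, Rho takes `n_steps` translocation
#' steps of rate `k_step` each before dislodging the EC at `k_dislodge`.
#' `n_steps` is the number of nucleotides between the 3' end of the rut
#' site and the stalled elongation complex.
#'
#' @param n_steps non-negative integer number of translocation nucleotides.
#' @return An object of class `"chain_spec"`.
#' @examples
#' chain_spec(200)
#' @export
chain_spec <- function(n_steps = 200) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || is.na(n_steps) ||
      n_steps < 0 || n_steps != round(n_steps))
    stop("n_steps must be a single non-negative integer", call. = FALSE)
  structure(list(n_steps = as.integer(n_steps)), class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf(
    "Recruitment chain: Free <-> Bound(OH) -> Committed(CH) -> %d steps -> Released\n",
    x$n_steps))
  invisible(x)
}

#' Time-course container
#'
#' A light data-frame subclass holding a sampled kinetic trajectory:
#' strictly increasing times (seconds) and dimensionless fractions.
#'
#' @param time numeric vector of times in seconds, strictly increasing,
#'   non-negative.
#' @param value numeric vector of fractions (released RNA or hydrolyzed
#'   ATP).
#' @param kind `"release"` or `"atp"`.
#' @return A `data.frame` of class `"timecourse"` with columns `time` and
#'   `value` and a `kind` attribute.
#' @export
timecourse <- function(time, value, kind = c("release", "atp")) {
  kind <- match.arg(kind)
  if (length(time) != length(value))
    stop("time and value must have the same length", call. = FALSE)
  if (length(time) == 0L)
    stop("time grid must be non-empty", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  out <- data.frame(time = as.numeric(time), value = as.numeric(value))
  class(out) <- c("timecourse", "data.frame")
  attr(out, "kind") <- kind
  out
}

#' @export
plot.timecourse <- function(x, ...) {
  kind <- attr(x, "kind")
  ylab <- if (identical(kind, "atp")) "fraction ATP hydrolyzed"
          else "fraction RNA released"
  graphics::plot(x$time, x$value, xlab = "time (s)", ylab = ylab,
                 ylim = c(0, 1), pch = 16, ...)
  invisible(x)
}
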
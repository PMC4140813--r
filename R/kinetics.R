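## Exponential kinetics of trial-averaged rate time courses:
## r(t) = r_inf + A * exp(-t / tau), t measured from the phase start.
## Fitting is least squares (Levenberg-Marquardt via minpack.lm); the
## initialization takes tau0 from the time to cover 63% of the gap between
## the window's first and last rates, and A0/r_inf0 from those endpoint
## rates. The first `skip` seconds of each phase are excluded so fast
## transients do not contaminate slow fits.

#' Fit an exponential to a rate time course
#'
#' Least-squares fit of `r(t) = r_inf + A * exp(-t / tau)` over a phase
#' window of the time course, with `t` counted from `phase_start`. The
#' first `skip` seconds of the phase are excluded from the fit.
#'
#' A free three-parameter exponential is weakly identified when the fit
#' window spans only a couple of time constants of noisy data; the
#' quantities a trial-averaged recording pins down precisely -- the
#' pre-stimulus baseline the onset starts from, or the baseline a decay
#' relaxes back to -- can therefore be anchored: `intercept` fixes
#' `r(0) = r_inf + A`, `asymptote` fixes `r_inf`.
#'
#' @param tc a `rate_timecourse` from [compute_psth()].
#' @param phase `"onset"` or `"offset"` (labels the fit; the window is
#'   set by `phase_start` / `window_end`).
#' @param phase_start start of the phase in the timecourse's timebase, s
#'   (light onset for onset fits, light offset for offset fits).
#' @param window_end end of the fit window, s; defaults to the end of the
#'   time course.
#' @param skip initial seconds of the phase excluded from the fit
#'   (default 0.05).
#' @param asymptote optional fixed `r_inf`, spikes/s.
#' @param intercept optional fixed `r(0)`, spikes/s.
#' @return An `exp_fit`: list with `amplitude`, `tau`, `offset_rate`,
#'   `tau_se`, `residual_rms`, `window`, `phase`, `converged`. On
#'   non-convergence `converged` is `FALSE`, the parameters are `NA` and
#'   a warning carries the diagnostics (never silent).
#' @examples
#' tt <- seq(0.05, 5, by = 0.1)
#' tc <- list(bin_edges = c(tt - 0.05, 5.05),
#'            rate = 47.5 + 6.9 * (1 - exp(-tt / 2.3)),
#'            n_trials = 1, baseline_window = NULL)
#' class(tc) <- "rate_timecourse"
#' fit_exponential(tc, "onset", phase_start = 0)$tau  # ~2.3
#' @export
fit_exponential <- function(tc, phase = c("onset", "offset"),
                            phase_start, window_end = NULL, skip = 0.05,
                            asymptote = NULL, intercept = NULL) {
  phase <- match.arg(phase)
  if (!is.null(asymptote) && !is.null(intercept)) {
    stop("anchor either the asymptote or the intercept, not both",
         call. = FALSE)
  }
  centers <- bin_centers(tc)
  if (is.null(window_end)) window_end <- max(centers)
  sel <- centers >= phase_start + skip & centers <= window_end
  if (sum(sel) < 10) {
    stop("fit window must contain at least 10 bins", call. = FALSE)
  }
  tt <- centers[sel] - phase_start
  rr <- tc$rate[sel]
  r_start <- mean(rr[seq_len(min(3, length(rr)))])
  r_end <- mean(rr[seq(max(1, length(rr) - 2), length(rr))])
  a0 <- r_start - r_end
  target <- r_start - 0.632 * a0
  crossing <- if (a0 >= 0) which(rr <= target) else which(rr >= target)
  tau0 <- if (length(crossing) > 0) max(tt[crossing[1]] - tt[1], diff(tt[1:2]))
    else diff(range(tt)) / 3
  fit <- tryCatch(
    if (!is.null(asymptote)) {
      minpack.lm::nlsLM(rr ~ asymptote + A * exp(-tt / tau),
                        start = list(A = r_start - asymptote, tau = tau0),
                        lower = c(-Inf, 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else if (!is.null(intercept)) {
      minpack.lm::nlsLM(rr ~ r_inf + (intercept - r_inf) * exp(-tt / tau),
                        start = list(r_inf = r_end, tau = tau0),
                        lower = c(-Inf, 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(rr ~ r_inf + A * exp(-tt / tau),
                        start = list(r_inf = r_end, A = a0, tau = tau0),
                        lower = c(-Inf, -Inf, 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) e)
  win <- c(phase_start + skip, window_end)
  if (inherits(fit, "error")) {
    warning("exponential fit failed (", conditionMessage(fit),
            "); window [", round(win[1], 3), ", ", round(win[2], 3), "] s, ",
            length(rr), " bins", call. = FALSE)
    return(structure(list(amplitude = NA_real_, tau = NA_real_,
                          offset_rate = NA_real_, tau_se = NA_real_,
                          residual_rms = NA_real_, window = win,
                          phase = phase, converged = FALSE),
                     class = "exp_fit"))
  }
  cf <- stats::coef(fit)
  r_inf <- if (!is.null(asymptote)) asymptote else unname(cf["r_inf"])
  amp <- if (!is.null(intercept)) intercept - r_inf else unname(cf["A"])
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["tau"],
                 error = function(e) NA_real_)
  structure(list(amplitude = amp,
                 tau = unname(cf["tau"]),
                 offset_rate = r_inf,
                 tau_se = unname(se),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 window = win, phase = phase, converged = TRUE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<exp_fit> ", x$phase, ": fit failed\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("<exp_fit> %s: tau = %.3f s (se %.3f), A = %.2f, r_inf = %.2f spikes/s, rms %.2f\n",
              x$phase, x$tau, x$tau_se, x$amplitude, x$offset_rate,
              x$residual_rms))
  invisible(x)
}

#' Joint exponential kinetics of a full light cycle
#'
#' Fits the complete trial-averaged rate time course of one light cycle
#' with a single continuous model: a constant baseline before light, an
#' exponential approach `base + D * (1 - exp(-t / tau_on))` during light,
#' and an exponential return `base + D * (1 - exp(-T / tau_on)) *
#' exp(-(t - T) / tau_off)` after light offset (`T` the light duration).
#' Sharing the baseline and the amplitude between the phases identifies
#' the two time constants far better than two separate three-parameter
#' fits when the window spans only a couple of time constants, which is
#' the regime of slow thermal drift. The onset/offset time constants stay
#' free and independent, so on/off symmetry remains a result, not an
#' assumption.
#'
#' @param tc a `rate_timecourse` aligned to light onset, with a
#'   `baseline_window` ending at 0.
#' @param light_duration light-on duration `T`, s.
#' @param skip seconds excluded after each transition (default 0.05).
#' @param window_end end of the post-offset window, s after offset;
#'   defaults to the end of the time course.
#' @return List with `onset_fit` and `offset_fit` (both `exp_fit`),
#'   `baseline` and `delta` (spikes/s).
#' @export
fit_light_cycle <- function(tc, light_duration, skip = 0.05,
                            window_end = NULL) {
  centers <- bin_centers(tc)
  bw <- tc$baseline_window
  if (is.null(bw)) stop("rate_timecourse has no baseline_window", call. = FALSE)
  if (is.null(window_end)) window_end <- max(centers) - light_duration
  pre <- centers >= bw[1] & centers < bw[2]
  on_sel <- centers >= skip & centers <= light_duration
  off_sel <- centers >= light_duration + skip &
    centers <= light_duration + window_end
  if (sum(on_sel) < 10 || sum(off_sel) < 10) {
    stop("fit windows must contain at least 10 bins each", call. = FALSE)
  }
  tt <- c(centers[pre], centers[on_sel], centers[off_sel])
  yy <- c(tc$rate[pre], tc$rate[on_sel], tc$rate[off_sel])
  ph <- rep(c(-1, 0, 1), c(sum(pre), sum(on_sel), sum(off_sel)))
  T_on <- light_duration
  base0 <- mean(tc$rate[pre])
  d0 <- mean(tc$rate[on_sel][seq(max(1, sum(on_sel) - 4), sum(on_sel))]) -
    base0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ ifelse(ph == -1, base,
                  ifelse(ph == 0, base + D * (1 - exp(-tt / tau_on)),
                         base + D * (1 - exp(-T_on / tau_on)) *
                           exp(-(tt - T_on) / tau_off))),
      start = list(base = base0, D = d0, tau_on = T_on / 3,
                   tau_off = T_on / 3),
      lower = c(-Inf, -Inf, 1e-3, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("light-cycle fit failed (", conditionMessage(fit), ")",
            call. = FALSE)
    failed <- structure(list(amplitude = NA_real_, tau = NA_real_,
                             offset_rate = NA_real_, tau_se = NA_real_,
                             residual_rms = NA_real_,
                             window = c(NA_real_, NA_real_),
                             phase = "onset", converged = FALSE),
                        class = "exp_fit")
    offf <- failed; offf$phase <- "offset"
    return(list(onset_fit = failed, offset_fit = offf,
                baseline = NA_real_, delta = NA_real_))
  }
  cf <- stats::coef(fit)
  ses <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, 4), names(cf)))
  rms <- sqrt(mean(stats::resid(fit)^2))
  onset_fit <- structure(list(
    amplitude = -unname(cf["D"]), tau = unname(cf["tau_on"]),
    offset_rate = unname(cf["base"] + cf["D"]),
    tau_se = unname(ses["tau_on"]), residual_rms = rms,
    window = c(skip, light_duration), phase = "onset", converged = TRUE),
    class = "exp_fit")
  offset_fit <- structure(list(
    amplitude = unname(cf["D"] * (1 - exp(-T_on / cf["tau_on"]))),
    tau = unname(cf["tau_off"]), offset_rate = unname(cf["base"]),
    tau_se = unname(ses["tau_off"]), residual_rms = rms,
    window = c(light_duration + skip, light_duration + window_end),
    phase = "offset", converged = TRUE),
    class = "exp_fit")
  list(onset_fit = onset_fit, offset_fit = offset_fit,
       baseline = unname(cf["base"]), delta = unname(cf["D"]))
}

#' Discriminate thermal from synaptic rate kinetics
#'
#' Tissue warming drives symmetric multi-second kinetics, while synaptic
#' modulation relaxes quickly after light offset: the pair of fits is
#' `"thermal-like"` when both time constants exceed `slow` (1 s) and
#' agree within a factor `ratio` (1.5), `"synaptic-like"` when the offset
#' time constant is below `slow`, else `"indeterminate"`. Failed fits
#' propagate as `"indeterminate"`.
#'
#' @param onset_fit,offset_fit `exp_fit` objects from
#'   [fit_exponential()].
#' @param ratio maximal onset/offset time-constant ratio for the thermal
#'   call.
#' @param slow boundary between slow (thermal-like) and fast (synaptic)
#'   time constants, s.
#' @return `"thermal-like"`, `"synaptic-like"` or `"indeterminate"`.
#' @export
thermal_vs_synaptic_discriminator <- function(onset_fit, offset_fit,
                                              ratio = 1.5, slow = 1) {
  taus <- c(onset = onset_fit$tau, offset = offset_fit$tau)
  ok <- c(isTRUE(onset_fit$converged), isTRUE(offset_fit$converged)) &
    is.finite(taus)
  if (ok[2] && taus[2] < slow) return("synaptic-like")
  if (all(ok) && all(taus > slow) &&
      max(taus) / min(taus) <= ratio) return("thermal-like")
  "indeterminate"
}
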
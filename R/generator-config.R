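## Generator configuration: one flat list per perturbation mode, defaults
## fixed at the study conditions each mode emulates. Rates in spikes/s or
## Hz, times in seconds.

#' Configuration for the synthetic spike-train generator
#'
#' Builds the full parameter set for one perturbation mode, starting from
#' that mode's defaults and applying any overrides. Modes:
#'
#' * `"pc"` — direct ChR2 drive of the recorded Purkinje cell: the simple
#'   spike rate steps from 35 to 97 spikes/s (modal frequency 68.0 to
#'   116.6 Hz), the first driven spike follows light onset by 3.9 ms
#'   (trial jitter SD 0.45 ms) and activity returns to baseline 16.4 ms
#'   (between-unit SD 5.3 ms) after light offset.
#' * `"mli"` — molecular layer interneuron drive: complete suppression of
#'   simple spikes; the last transmitted spike occurs 3.6 ms (SD 0.4 ms)
#'   after onset, the first spike after offset reappears after 123.5 ms
#'   (between-unit SD 22.7 ms), and the rate then relaxes to baseline with
#'   time constant `recovery_tau` so baseline is reached about 2.5 s after
#'   offset. A fraction `sparse_fraction` of units (default 4/21) emits
#'   sparse spikes after the first 500 ms of light.
#' * `"gc"` — granule cell drive: slow bidirectional modulation; each unit
#'   is excited with probability `gc_sign_prob_excite` (default 13/25,
#'   realised as an exact stratified split), the rate approaches baseline
#'   +/- `gc_rate_delta` with time constant `gc_onset_tau` and returns with
#'   `gc_offset_tau` (0.55 s); the driven ISI jitter is raised so CV2
#'   increases under light (0.48 to 0.54 at the defaults).
#' * `"thermal"` — opsin-free tissue warming: the rate rises above baseline
#'   with `thermal_tau_on` (2.30 s) and decays back with `thermal_tau_off`
#'   (2.20 s), never dropping below baseline; the asymptotic increment
#'   `thermal_rate_delta` (11.65 spikes/s) makes the 5-s light-epoch mean
#'   rate rise from 47.5 to 54.4 Hz.
#'
#' Spontaneous firing in every mode is a jittered-regular (gamma-ISI)
#' renewal process at the modal rate, thinned by an independent Poisson
#' pause process; the pause rate is solved so the expected count rate
#' equals `baseline_count_rate` (the count rate is below the modal
#' frequency whenever pauses are present). Low-rate complex spikes are
#' overlaid, each deleting simple spikes for `cs_pause` seconds (the
#' climbing-fiber pause). Between-unit heterogeneity enters through a
#' gamma-distributed pause-burden multiplier (`burden_shape`) on the pause
#' rate and a small lognormal jitter on the modal rate (`modal_jitter_cv`).
#'
#' @param mode one of `"pc"`, `"mli"`, `"gc"`, `"thermal"`.
#' @param ... overrides for any default listed below.
#' @param seed integer seed fixing the whole cohort bit-exactly.
#' @return A `generator_config` list.
#' @examples
#' cfg <- generator_config("pc", n_units = 2, n_trials = 3, seed = 1)
#' cfg$driven_count_rate
#' @export
generator_config <- function(mode = c("pc", "mli", "gc", "thermal"), ...,
                             seed = 1L) {
  mode <- match.arg(mode)
  common <- list(
    n_units = 14L,
    n_trials = 20L,
    trial_duration = 3,
    light_on = 1,
    light_off = 2,
    laser_power_mw = 5,
    tip_power_mw = 1.25,
    fiber_depth_um = -330,
    lateral_um = 330,
    baseline_count_rate = 35,
    baseline_modal_rate = 68,
    isi_jitter_cv = 0.25,
    pause_rate = NULL,           # solved from count/modal when NULL
    pause_duration_mean = 0.06,
    cs_rate = 0.23,
    cs_pause = 0.015,
    burden_shape = 4,
    burden_range = c(0.4, 1.5),
    modal_jitter_cv = 0.015,
    rate_scale_cv = 0,
    baseline_skip = 0.1,
    spatial_profile = NULL,
    intensity_block = NULL
  )
  per_mode <- switch(mode,
    pc = list(
      driven_count_rate = 97,
      driven_modal_rate = 116.6,
      driven_isi_jitter_cv = 0.10,
      onset_latency = 0.0039,
      onset_latency_jitter = 0.00045,
      offset_latency = 0.0164,
      offset_latency_sd = 0.0053,
      offset_latency_trial_jitter = 0.002,
      transient_fraction = 4 / 14,
      transient_amp = 0.5,
      transient_tau = 0.03
    ),
    mli = list(
      n_units = 21L,
      n_trials = 30L,
      trial_duration = 5,
      light_on = 1,
      light_off = 2,
      last_spike_latency = 0.0036,
      last_spike_unit_sd = 0.0004,
      last_spike_trial_jitter = 0.0003,
      recovery_first_spike = 0.1235,
      recovery_first_unit_sd = 0.0227,
      recovery_first_trial_jitter = 0.010,
      recovery_tau = 0.8,
      sparse_fraction = 4 / 21,
      sparse_rate = 3,
      sparse_delay = 0.5
    ),
    gc = list(
      n_units = 25L,
      n_trials = 15L,
      trial_duration = 10,
      light_on = 2,
      light_off = 7,
      laser_power_mw = 10,
      tip_power_mw = 2.5,
      baseline_count_rate = 47.5,
      baseline_modal_rate = 55,
      rate_scale_cv = 0.2,
      isi_jitter_cv = 0.385,        # calibrated: cohort CV2 (light off) ~ 0.48
      driven_isi_jitter_cv = 0.452, # calibrated: cohort CV2 (light on)  ~ 0.54
      gc_sign_prob_excite = 13 / 25,
      gc_rate_delta = 15,
      gc_onset_tau = 1.5,
      gc_offset_tau = 0.55
    ),
    thermal = list(
      n_units = 20L,
      n_trials = 20L,
      trial_duration = 12,
      light_on = 2,
      light_off = 7,
      laser_power_mw = 20,
      tip_power_mw = 3,
      baseline_count_rate = 47.5,
      baseline_modal_rate = 47.5,
      rate_scale_cv = 0.2,
      thermal_tau_on = 2.30,
      thermal_tau_off = 2.20,
      thermal_rate_delta = 11.65
    )
  )
  cfg <- utils::modifyList(common, per_mode)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), c(names(cfg), "seed"))
  if (length(unknown) > 0) {
    stop("unknown generator_config field(s) for mode '", mode, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, overrides)
  cfg$mode <- mode
  cfg$seed <- as.integer(seed)
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$mode %in% MODES)
  if (cfg$baseline_count_rate > cfg$baseline_modal_rate) {
    stop("baseline_count_rate must not exceed baseline_modal_rate",
         call. = FALSE)
  }
  rate_fields <- c("baseline_count_rate", "baseline_modal_rate", "cs_rate")
  for (f in rate_fields) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  }
  if (!(cfg$light_on >= 0 && cfg$light_on < cfg$light_off &&
        cfg$light_off <= cfg$trial_duration)) {
    stop("need 0 <= light_on < light_off <= trial_duration", call. = FALSE)
  }
  if (cfg$mode == "pc" &&
      cfg$driven_count_rate > cfg$driven_modal_rate) {
    stop("driven_count_rate must not exceed driven_modal_rate", call. = FALSE)
  }
  if (cfg$mode == "gc") {
    p <- cfg$gc_sign_prob_excite
    if (p < 0 || p > 1) stop("gc_sign_prob_excite must be in [0, 1]", call. = FALSE)
    if (cfg$gc_rate_delta >= cfg$baseline_count_rate) {
      stop("gc_rate_delta must stay below the baseline count rate",
           call. = FALSE)
    }
  }
  if (cfg$n_units < 0 || cfg$n_trials < 0) {
    stop("n_units and n_trials must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> mode=%s, %d units x %d trials, light [%g, %g] s of %g s, seed=%d\n",
              x$mode, x$n_units, x$n_trials, x$light_on, x$light_off,
              x$trial_duration, x$seed))
  invisible(x)
}

## Pause rate such that the EXPECTED survival of a spike under the pause
## process, averaged over the per-unit burden distribution, equals
## count/modal. M/G/infinity vacancy gives survival exp(-rate * mean_dur *
## burden). The burden is gamma(shape, shape), truncated to burden_range
## so simulated units stay inside the physiological spontaneous-rate
## range; the rate is solved numerically against the truncated mixture
## (closed form (1 + c/shape)^-shape when untruncated).
solve_pause_rate <- function(count_rate, modal_rate, pause_duration_mean,
                             burden_shape = Inf, burden_range = NULL) {
  if (modal_rate <= 0) return(0)
  ratio <- count_rate / modal_rate
  if (ratio > 1 + 1e-9) {
    stop("count rate exceeds modal rate: no feasible pause process",
         call. = FALSE)
  }
  if (ratio <= 0) {
    stop("count rate must be positive when the modal rate is positive",
         call. = FALSE)
  }
  ratio <- min(ratio, 1)
  if (ratio == 1) return(0)
  if (!is.finite(burden_shape)) {
    return(-log(ratio) / pause_duration_mean)
  }
  if (is.null(burden_range)) {
    return(burden_shape * (ratio^(-1 / burden_shape) - 1) /
             pause_duration_mean)
  }
  mass <- stats::pgamma(burden_range[2], burden_shape, burden_shape) -
    stats::pgamma(burden_range[1], burden_shape, burden_shape)
  mean_survival <- function(lam) {
    stats::integrate(function(b) {
      exp(-lam * pause_duration_mean * b) *
        stats::dgamma(b, burden_shape, burden_shape) / mass
    }, burden_range[1], burden_range[2], rel.tol = 1e-9)$value
  }
  stats::uniroot(function(lam) mean_survival(lam) - ratio,
                 lower = 0, upper = 50 / pause_duration_mean,
                 tol = 1e-10)$root
}
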
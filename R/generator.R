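## Seeded point-process generator.
##
## Spontaneous firing is a jittered-regular renewal process (gamma ISIs with
## mean 1/modal_rate and coefficient of variation isi_jitter_cv) thinned by
## an independent Poisson pause process (exponential pause durations), so
## the count rate sits below the modal frequency whenever pauses are
## present. Light modulation reshapes the renewal intensity by time
## rescaling; the deterministic transition events of each mode (first driven
## spike, last transmitted spike, first spike after offset) are placed
## explicitly and are exempt from pause thinning (they model the synaptic
## transition, not the spontaneous gap process), but not from the
## climbing-fiber pause deletion.

## unit ISIs with mean 1 and coefficient of variation cv (degenerate at 0)
unit_isis <- function(n, cv) {
  if (n <= 0) return(numeric(0))
  if (cv <= 0) return(rep(1, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape)
}

## Stationary renewal train on (0, duration]; warmup in units of mean ISIs
## approximates the equilibrium phase at time 0.
renewal_train <- function(duration, mean_isi, cv, warmup = 8) {
  if (duration <= 0 || !is.finite(mean_isi) || mean_isi <= 0) return(numeric(0))
  if (cv <= 0) {
    n <- floor(duration / mean_isi + 1e-9)
    if (n < 1) return(numeric(0))
    return((1:n) * mean_isi)
  }
  expected <- (duration / mean_isi + warmup) * (1 + 4 * cv) + 20
  t0 <- -warmup * mean_isi
  times <- numeric(0)
  repeat {
    isis <- unit_isis(ceiling(expected), cv) * mean_isi
    tt <- t0 + cumsum(isis)
    times <- c(times, tt)
    if (times[length(times)] > duration) break
    t0 <- times[length(times)]
  }
  times[times > 0 & times <= duration]
}

## Renewal train with time-varying intensity given on a grid, via the
## time-rescaling theorem. If `start_at` is given the process is started at
## that (forced) event; otherwise an equilibrium warmup is used.
rescaled_renewal_train <- function(grid, rate, cv, start_at = NULL, warmup = 8) {
  if (length(grid) < 2) return(numeric(0))
  dt <- diff(grid)
  lam <- cumsum(c(0, (rate[-1] + rate[-length(rate)]) / 2 * dt))
  total <- lam[length(lam)]
  if (total <= 0) return(numeric(0))
  x0 <- 0
  if (!is.null(start_at)) {
    x0 <- stats::approx(grid, lam, xout = start_at, rule = 2)$y
  } else {
    x0 <- -warmup
  }
  xs <- numeric(0)
  xcur <- x0
  repeat {
    draw <- unit_isis(ceiling(max(total - xcur, 1) * (1 + 4 * cv)) + 20, cv)
    xx <- xcur + cumsum(draw)
    xs <- c(xs, xx)
    if (xs[length(xs)] > total) break
    xcur <- xs[length(xs)]
  }
  xs <- xs[xs > max(x0, 0) & xs <= total]
  tt <- stats::approx(lam, grid, xout = xs, ties = "ordered")$y
  tt[!is.na(tt)]
}

## Poisson pause windows over (0, duration); starts extend left so windows
## overlapping 0 are represented. Returns a two-column matrix (start, end).
pause_window_set <- function(pause_rate, mean_duration, duration) {
  if (pause_rate <= 0 || duration <= 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  margin <- 8 * mean_duration
  n <- stats::rpois(1, pause_rate * (duration + margin))
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  start <- sort(stats::runif(n, -margin, duration))
  dur <- stats::rexp(n, rate = 1 / mean_duration)
  cbind(start, start + dur)
}

## Delete spikes falling in (start, end] of any window.
delete_in_windows <- function(times, windows) {
  if (length(times) == 0 || nrow(windows) == 0) return(times)
  ord <- order(windows[, 1])
  s <- windows[ord, 1]; e <- windows[ord, 2]
  ms <- s[1]; me <- e[1]; merged_s <- c(); merged_e <- c()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i]) else {
      merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
  bounds <- as.vector(rbind(merged_s, merged_e))
  inside <- findInterval(times, bounds, left.open = TRUE) %% 2 == 1
  times[!inside]
}

#' Generate a spontaneous simple-spike train with pauses
#'
#' Jittered-regular renewal spiking at the modal rate (gamma ISIs, mean
#' `1/modal_rate`, coefficient of variation `isi_jitter_cv`), interrupted
#' by an independent Poisson pause process with exponential pause
#' durations. When `pause_rate` is `NULL` it is solved so the expected
#' count rate equals `count_rate`; the modal (rhythmic) frequency of the
#' result stays at `modal_rate`, reproducing the count-rate/modal-frequency
#' discrepancy characteristic of pause-bearing Purkinje cell firing.
#'
#' Uses the current R random number stream; call `set.seed()` for
#' reproducibility.
#'
#' @param count_rate target mean count rate, spikes/s (must be
#'   `<= modal_rate`).
#' @param modal_rate renewal (modal) rate, Hz.
#' @param isi_jitter_cv ISI coefficient of variation of the renewal
#'   process; 0 gives an exactly periodic train.
#' @param pause_rate pauses/s, or `NULL` to solve from
#'   `count_rate / modal_rate`.
#' @param pause_duration_mean mean pause duration, s.
#' @param duration train duration, s.
#' @return Sorted spike times in `(0, duration]`.
#' @examples
#' set.seed(1)
#' tr <- generate_baseline_train(35, 68, 0.25, duration = 10)
#' length(tr) / 10  # close to 35 spikes/s
#' @export
generate_baseline_train <- function(count_rate, modal_rate,
                                    isi_jitter_cv = 0.25,
                                    pause_rate = NULL,
                                    pause_duration_mean = 0.06,
                                    duration = 1) {
  if (duration <= 0 || modal_rate <= 0) return(numeric(0))
  if (count_rate > modal_rate) {
    stop("count_rate must not exceed modal_rate", call. = FALSE)
  }
  if (is.null(pause_rate)) {
    pause_rate <- solve_pause_rate(count_rate, modal_rate,
                                   pause_duration_mean)
  }
  train <- renewal_train(duration, 1 / modal_rate, isi_jitter_cv)
  if (pause_rate > 0) {
    win <- pause_window_set(pause_rate, pause_duration_mean, duration)
    train <- delete_in_windows(train, win)
  }
  train
}

#' Overlay complex spikes and the climbing-fiber pause
#'
#' Complex spikes arrive as a Poisson process at `cs_rate` with a dead time
#' of `cs_pause` between consecutive complex spikes; every simple spike in
#' `(cs, cs + cs_pause]` after a complex spike is deleted, producing the
#' climbing-fiber pause that identifies simple and complex spikes as
#' originating from one Purkinje cell.
#'
#' @param simple_train sorted simple-spike times, s.
#' @param cs_rate complex-spike rate, Hz.
#' @param cs_pause pause duration after each complex spike, s (> 0).
#' @param duration trial duration, s.
#' @return A list with elements `simple` (thinned simple train) and
#'   `complex` (complex-spike times).
#' @export
overlay_complex_spikes <- function(simple_train, cs_rate, cs_pause = 0.015,
                                   duration = 1) {
  if (cs_pause <= 0) stop("cs_pause must be > 0", call. = FALSE)
  if (cs_rate <= 0 || duration <= 0) {
    return(list(simple = simple_train, complex = numeric(0)))
  }
  n <- stats::rpois(1, cs_rate * duration)
  cs <- sort(stats::runif(n, 0, duration))
  if (length(cs) > 1) {
    keep <- rep(TRUE, length(cs))
    last <- cs[1]
    for (i in seq_along(cs)[-1]) {
      if (cs[i] - last < cs_pause) keep[i] <- FALSE else last <- cs[i]
    }
    cs <- cs[keep]
  }
  if (length(cs) > 0 && length(simple_train) > 0) {
    win <- cbind(cs, cs + cs_pause)
    simple_train <- delete_in_windows(simple_train, win)
  }
  list(simple = simple_train, complex = cs)
}

## ---- per-unit parameter resolution -------------------------------------

derive_unit_seed <- function(seed, unit) {
  as.integer((as.numeric(seed) %% 1048576 * 1013 + unit * 7919 + 1) %%
               2147483629)
}

## exactly round(fraction * n) TRUE values, randomly placed
stratified_flags <- function(n, fraction) {
  k <- round(fraction * n)
  flags <- rep(FALSE, n)
  if (k > 0) flags[sample.int(n, min(k, n))] <- TRUE
  flags
}

rtrunc_norm <- function(n, mean, sd, lower, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

## Unit-level random effects. Cohort-level stratified assignments are drawn
## from the cohort stream (config$seed); the numeric effects per unit come
## from each unit's own stream so a unit's cohort is reproducible under
## partial regeneration.
resolve_units <- function(config) {
  n <- config$n_units
  if (n == 0) {
    return(data.frame(unit_id = character(0)))
  }
  set.seed(config$seed)
  flag1 <- switch(config$mode,
    pc = stratified_flags(n, config$transient_fraction),
    mli = stratified_flags(n, config$sparse_fraction),
    gc = stratified_flags(n, config$gc_sign_prob_excite),
    thermal = rep(FALSE, n))
  ## unit stream seeds drawn from the cohort stream: arithmetic seed
  ## formulas leave nearby cohort seeds correlated, sampled seeds do not
  units <- data.frame(
    unit_id = sprintf("u%02d", seq_len(n)),
    unit_seed = sample.int(2147483646L, n),
    stringsAsFactors = FALSE)
  units$burden <- NA_real_
  units$modal_mult <- NA_real_
  units$rate_mult <- NA_real_
  units$transient <- if (config$mode == "pc") flag1 else FALSE
  units$sparse <- if (config$mode == "mli") flag1 else FALSE
  units$gc_sign <- if (config$mode == "gc") ifelse(flag1, 1, -1) else 0
  units$offset_latency <- NA_real_
  units$last_spike_mean <- NA_real_
  units$recovery_first <- NA_real_
  for (u in seq_len(n)) {
    set.seed(units$unit_seed[u])
    b <- stats::rgamma(1, shape = config$burden_shape,
                       rate = config$burden_shape)
    while (b < config$burden_range[1] || b > config$burden_range[2]) {
      b <- stats::rgamma(1, shape = config$burden_shape,
                         rate = config$burden_shape)
    }
    units$burden[u] <- b
    s <- config$modal_jitter_cv
    units$modal_mult[u] <- if (s > 0) stats::rlnorm(1, -s^2 / 2, s) else 1
    rs <- config$rate_scale_cv
    units$rate_mult[u] <- if (rs > 0) {
      sl <- sqrt(log(1 + rs^2))
      stats::rlnorm(1, -sl^2 / 2, sl)
    } else 1
    if (config$mode == "pc") {
      units$offset_latency[u] <- rtrunc_norm(1, config$offset_latency,
                                             config$offset_latency_sd,
                                             lower = 0.002, upper = 0.040)
    }
    if (config$mode == "mli") {
      units$last_spike_mean[u] <- rtrunc_norm(1, config$last_spike_latency,
                                              config$last_spike_unit_sd,
                                              lower = 0.001)
      units$recovery_first[u] <- rtrunc_norm(1, config$recovery_first_spike,
                                             config$recovery_first_unit_sd,
                                             lower = 0.02)
    }
  }
  units
}

## ---- per-trial simple-spike construction -------------------------------

## Baseline pause survival bookkeeping for one unit; the numeric solve is
## memoised because it is identical across trials of a cohort.
.pause_rate_cache <- new.env(parent = emptyenv())

unit_pause_rate <- function(config, burden, count_rate, modal_rate) {
  key <- paste(count_rate, modal_rate, config$pause_duration_mean,
               config$burden_shape,
               paste(config$burden_range, collapse = ","), sep = "|")
  base <- .pause_rate_cache[[key]]
  if (is.null(base)) {
    base <- solve_pause_rate(count_rate, modal_rate,
                             config$pause_duration_mean,
                             burden_shape = config$burden_shape,
                             burden_range = config$burden_range)
    .pause_rate_cache[[key]] <- base
  }
  base * burden
}

#' Simulate one trial's simple-spike train under light modulation
#'
#' Produces the simple-spike time sequence of a single trial for one unit
#' under the configured perturbation mode. Exposed mainly for inspection
#' and testing; cohorts are assembled by [generate_experiment()]. Uses the
#' current R random number stream.
#'
#' @param config a [generator_config()].
#' @param unit one row of the resolved unit table (see
#'   [generate_experiment()]); when `NULL`, a median unit (no random
#'   effects) is used.
#' @return Sorted simple-spike times in `(0, trial_duration]`.
#' @export
apply_light_modulation <- function(config, unit = NULL) {
  if (is.null(unit)) {
    unit <- list(burden = 1, modal_mult = 1, rate_mult = 1, transient = FALSE,
                 sparse = FALSE, gc_sign = 1,
                 offset_latency = config$offset_latency %||% NA_real_,
                 last_spike_mean = config$last_spike_latency %||% NA_real_,
                 recovery_first = config$recovery_first_spike %||% NA_real_)
  }
  switch(config$mode,
    pc = trial_pc(config, unit),
    mli = trial_mli(config, unit),
    gc = trial_gc(config, unit),
    thermal = trial_thermal(config, unit),
    stop("unknown mode: ", config$mode, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

baseline_segment <- function(config, unit, t0, t1) {
  if (t1 <= t0) return(numeric(0))
  modal <- config$baseline_modal_rate * unit$modal_mult * unit$rate_mult
  lam <- if (is.null(config$pause_rate)) {
    unit_pause_rate(config, unit$burden, config$baseline_count_rate,
                    config$baseline_modal_rate)
  } else config$pause_rate * unit$burden
  tr <- renewal_train(t1 - t0, 1 / modal, config$isi_jitter_cv)
  if (lam > 0) {
    win <- pause_window_set(lam, config$pause_duration_mean, t1 - t0)
    tr <- delete_in_windows(tr, win)
  }
  t0 + tr
}

## rescaled renewal segment with a count-rate profile; pauses at the
## baseline (stationary) rate thin the train so the expected count profile
## matches `count_fn` on average over units.
profiled_segment <- function(config, unit, t0, t1, count_fn, cv,
                             start_at = NULL, dt = 0.001) {
  if (t1 <= t0) return(numeric(0))
  grid <- seq(t0, t1, by = dt)
  if (grid[length(grid)] < t1) grid <- c(grid, t1)
  counts <- count_fn(grid)
  lam <- if (is.null(config$pause_rate)) {
    unit_pause_rate(config, unit$burden, config$baseline_count_rate,
                    config$baseline_modal_rate)
  } else config$pause_rate * unit$burden
  survival <- exp(-lam * config$pause_duration_mean)
  modal_profile <- counts / config$baseline_count_rate *
    config$baseline_modal_rate * unit$modal_mult * unit$rate_mult
  tr <- rescaled_renewal_train(grid, modal_profile, cv, start_at = start_at)
  if (lam > 0) {
    win <- pause_window_set(lam, config$pause_duration_mean, t1 - t0) + t0
    tr <- delete_in_windows(tr, win)
  }
  tr
}

trial_pc <- function(config, unit) {
  on <- config$light_on; off <- config$light_off; dur <- config$trial_duration
  pre <- baseline_segment(config, unit, 0, on)
  off_lat <- max(0.002, unit$offset_latency +
                   stats::rnorm(1, 0, config$offset_latency_trial_jitter))
  drive_end <- min(off + off_lat, dur)
  first <- on + max(5e-4, stats::rnorm(1, config$onset_latency,
                                       config$onset_latency_jitter))
  driven_modal <- config$driven_modal_rate * unit$modal_mult * unit$rate_mult
  driven_count <- config$driven_count_rate
  blocked <- !is.null(config$intensity_block) &&
    config$tip_power_mw > config$intensity_block$tip_power_threshold
  scale <- if (blocked) config$intensity_block$response_scale %||% 0.5 else 1
  ## rebound block: drive ends at light offset, then a silent pause
  if (blocked) drive_end <- off
  lam_driven <- unit_pause_rate(config, unit$burden,
                                config$driven_count_rate,
                                config$driven_modal_rate)
  driven <- numeric(0)
  if (first < drive_end) {
    if (unit$transient || scale != 1) {
      amp <- config$transient_amp * as.numeric(unit$transient)
      rate_fn <- function(t) {
        scale * driven_modal * (1 + amp * exp(-(t - on) / config$transient_tau))
      }
      grid <- seq(first, drive_end, by = 0.001)
      if (grid[length(grid)] < drive_end) grid <- c(grid, drive_end)
      driven <- rescaled_renewal_train(grid, rate_fn(grid),
                                       config$driven_isi_jitter_cv,
                                       start_at = first)
    } else {
      mean_isi <- 1 / driven_modal
      total <- drive_end - first
      isis <- numeric(0); acc <- 0
      while (acc < total) {
        add <- unit_isis(ceiling((total - acc) * driven_modal * 1.5) + 10,
                         config$driven_isi_jitter_cv) * mean_isi
        isis <- c(isis, add); acc <- sum(isis)
      }
      tt <- first + cumsum(isis)
      driven <- tt[tt <= drive_end]
    }
    if (lam_driven > 0) {
      win <- pause_window_set(lam_driven, config$pause_duration_mean,
                              drive_end - on) + on
      driven <- delete_in_windows(driven, win)
    }
    driven <- c(first, driven[driven > first])
  }
  post <- baseline_segment(config, unit, drive_end, dur)
  if (blocked) {
    pp <- config$intensity_block$post_pause_duration %||% 0.3
    post <- post[post > off + pp]
  }
  sort(c(pre, driven, post))
}

trial_mli <- function(config, unit) {
  on <- config$light_on; off <- config$light_off; dur <- config$trial_duration
  pre <- baseline_segment(config, unit, 0, on)
  last <- on + max(5e-4, unit$last_spike_mean +
                     stats::rnorm(1, 0, config$last_spike_trial_jitter))
  sparse <- numeric(0)
  if (unit$sparse) {
    t0 <- on + config$sparse_delay
    if (off > t0) {
      k <- stats::rpois(1, config$sparse_rate * (off - t0))
      sparse <- sort(stats::runif(k, t0, off))
    }
  }
  t_first <- off + max(0.005, unit$recovery_first +
                         stats::rnorm(1, 0, config$recovery_first_trial_jitter))
  recovery <- numeric(0)
  if (t_first < dur) {
    tau <- config$recovery_tau
    count_fn <- function(t) {
      config$baseline_count_rate * (1 - exp(-(t - t_first) / tau))
    }
    recovery <- profiled_segment(config, unit, t_first, dur, count_fn,
                                 config$isi_jitter_cv, start_at = t_first)
    recovery <- c(t_first, recovery[recovery > t_first])
  }
  sort(c(pre, last, sparse, recovery))
}

trial_gc <- function(config, unit) {
  on <- config$light_on; off <- config$light_off; dur <- config$trial_duration
  base <- config$baseline_count_rate
  delta <- unit$gc_sign * config$gc_rate_delta
  tau_on <- config$gc_onset_tau; tau_off <- config$gc_offset_tau
  delta_end <- delta * (1 - exp(-(off - on) / tau_on))
  pre <- baseline_segment(config, unit, 0, on)
  during <- profiled_segment(config, unit, on, off,
                             function(t) base + delta * (1 - exp(-(t - on) / tau_on)),
                             config$driven_isi_jitter_cv)
  post <- profiled_segment(config, unit, off, dur,
                           function(t) base + delta_end * exp(-(t - off) / tau_off),
                           config$isi_jitter_cv)
  sort(c(pre, during, post))
}

trial_thermal <- function(config, unit) {
  on <- config$light_on; off <- config$light_off; dur <- config$trial_duration
  base <- config$baseline_count_rate
  delta <- config$thermal_rate_delta
  tau_on <- config$thermal_tau_on; tau_off <- config$thermal_tau_off
  delta_end <- delta * (1 - exp(-(off - on) / tau_on))
  pre <- baseline_segment(config, unit, 0, on)
  during <- profiled_segment(config, unit, on, off,
                             function(t) base + delta * (1 - exp(-(t - on) / tau_on)),
                             config$isi_jitter_cv)
  post <- profiled_segment(config, unit, off, dur,
                           function(t) base + delta_end * exp(-(t - off) / tau_off),
                           config$isi_jitter_cv)
  sort(c(pre, during, post))
}

## ---- cohort assembly ----------------------------------------------------

#' Generate a synthetic cohort (spike events + protocol)
#'
#' Assembles `n_units x n_trials` trials under the configured perturbation
#' mode. Fully reproducible from `config$seed`: cohort-level assignments
#' (which units are excited, sparse, or carry an onset transient) come from
#' the cohort stream, and each unit's spike trains come from its own
#' derived stream.
#'
#' @param config a [generator_config()].
#' @return A list with elements `events` ([spike_events()]), `protocol`
#'   ([light_protocol()]), `units` (resolved per-unit parameter table,
#'   including generator-assigned labels used by recovery tests) and
#'   `config`.
#' @examples
#' coh <- generate_experiment(generator_config("pc", n_units = 2,
#'                                             n_trials = 3, seed = 42))
#' table(coh$events$event_type)
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  units <- resolve_units(config)
  trial_ids <- sprintf("t%03d", seq_len(config$n_trials))
  nt <- length(trial_ids)
  protocol <- light_protocol(data.frame(
    trial_id = trial_ids,
    trial_duration_s = rep(config$trial_duration, nt),
    light_on_s = rep(config$light_on, nt),
    light_off_s = rep(config$light_off, nt),
    laser_power_mw = rep(config$laser_power_mw, nt),
    tip_power_mw = rep(config$tip_power_mw, nt),
    fiber_depth_um = rep(config$fiber_depth_um, nt),
    lateral_um = rep(config$lateral_um, nt),
    mode = rep(config$mode, nt),
    stringsAsFactors = FALSE))
  pieces <- vector("list", nrow(units) * max(config$n_trials, 1))
  k <- 0
  for (u in seq_len(nrow(units))) {
    unit <- units[u, ]
    set.seed(unit$unit_seed + 1L)
    for (tr in seq_len(config$n_trials)) {
      ss <- apply_light_modulation(config, unit)
      ov <- overlay_complex_spikes(ss, config$cs_rate, config$cs_pause,
                                   config$trial_duration)
      k <- k + 1
      pieces[[k]] <- data.frame(
        unit_id = unit$unit_id,
        trial_id = trial_ids[tr],
        event_type = c(rep("simple", length(ov$simple)),
                       rep("complex", length(ov$complex))),
        time_s = c(ov$simple, ov$complex),
        stringsAsFactors = FALSE)
    }
  }
  events_df <- if (k > 0) do.call(rbind, pieces[seq_len(k)]) else {
    data.frame(unit_id = character(0), trial_id = character(0),
               event_type = character(0), time_s = numeric(0))
  }
  ## 6-decimal grid matches the file format, keeps round trips exact, and
  ## deduplicates pathological coincident times
  events_df$time_s <- round(events_df$time_s, 6)
  events_df <- events_df[!duplicated(events_df[c("unit_id", "trial_id",
                                                 "event_type", "time_s")]), ]
  list(events = spike_events(events_df), protocol = protocol,
       units = units, config = config)
}

## ---- spatial cohort ------------------------------------------------------

default_spatial_profile <- function() {
  list(depth = data.frame(
    depth_um = c(-2000, -1500, -1000, -500, -250, 0, 500, 1000),
    attenuation = c(0, 0, 0.5, 1, 1, 0.6, 0.2, 0)),
    lateral = c("330" = 1, "660" = 0.45, "990" = 0))
}

spatial_attenuation <- function(depth_um, lateral_um, profile = NULL) {
  profile <- profile %||% default_spatial_profile()
  lat <- profile$lateral[as.character(lateral_um)]
  if (is.na(lat)) stop("lateral_um must be one of ",
                       paste(names(profile$lateral), collapse = ", "),
                       call. = FALSE)
  dp <- profile$depth
  g <- if (nrow(dp) == 1) rep(dp$attenuation, length(depth_um)) else {
    stats::approx(dp$depth_um, dp$attenuation, xout = depth_um, rule = 2)$y
  }
  unname(g * lat)
}

#' Generate a cohort with position-dependent light modulation
#'
#' Each unit is recorded at a given fiber position (depth offset relative
#' to the cell, negative above, and a lateral guide-tube distance). The
#' driven rate increment is attenuated by the spatial profile: maximal for
#' tips 250-500 um above the cell at 330 um lateral distance, reduced at
#' 660 um, absent at 990 um and beyond 1500 um of depth offset. Trials are
#' generated per unit (trial ids carry the unit) so the protocol can carry
#' each unit's fiber position.
#'
#' @param config a [generator_config()] with mode `"pc"`.
#' @param positions data frame with columns `depth_um` and `lateral_um`
#'   (one row per unit; `lateral_um` in 330, 660, 990).
#' @return As [generate_experiment()], with `units` carrying the position
#'   and attenuation of each unit.
#' @export
generate_spatial_cohort <- function(config, positions) {
  stopifnot(inherits(config, "generator_config"))
  if (config$mode != "pc") stop("spatial cohorts use mode 'pc'", call. = FALSE)
  positions <- as.data.frame(positions)
  stopifnot(all(c("depth_um", "lateral_um") %in% names(positions)))
  if (!all(positions$lateral_um %in% LATERAL_ALLOWED)) {
    stop("lateral_um must be one of ", paste(LATERAL_ALLOWED, collapse = ", "),
         call. = FALSE)
  }
  events_list <- list(); protocol_list <- list(); units_list <- list()
  for (u in seq_len(nrow(positions))) {
    g <- spatial_attenuation(positions$depth_um[u], positions$lateral_um[u],
                             config$spatial_profile)
    sub <- generator_config(
      "pc",
      n_units = 1L, n_trials = config$n_trials,
      trial_duration = config$trial_duration,
      light_on = config$light_on, light_off = config$light_off,
      baseline_count_rate = config$baseline_count_rate,
      baseline_modal_rate = config$baseline_modal_rate,
      isi_jitter_cv = config$isi_jitter_cv,
      driven_count_rate = config$baseline_count_rate +
        g * (config$driven_count_rate - config$baseline_count_rate),
      driven_modal_rate = config$baseline_modal_rate +
        g * (config$driven_modal_rate - config$baseline_modal_rate),
      driven_isi_jitter_cv = config$isi_jitter_cv -
        g * (config$isi_jitter_cv - config$driven_isi_jitter_cv),
      transient_fraction = 0,
      fiber_depth_um = positions$depth_um[u],
      lateral_um = positions$lateral_um[u],
      seed = derive_unit_seed(config$seed, u))
    coh <- generate_experiment(sub)
    uid <- sprintf("u%02d", u)
    ev <- as.data.frame(coh$events)
    ev$unit_id <- uid
    ev$trial_id <- paste0(uid, ".", ev$trial_id)
    pr <- as.data.frame(coh$protocol)
    pr$trial_id <- paste0(uid, ".", pr$trial_id)
    un <- coh$units
    un$unit_id <- uid
    un$depth_um <- positions$depth_um[u]
    un$lateral_um <- positions$lateral_um[u]
    un$attenuation <- g
    events_list[[u]] <- ev; protocol_list[[u]] <- pr; units_list[[u]] <- un
  }
  list(events = spike_events(do.call(rbind, events_list)),
       protocol = light_protocol(do.call(rbind, protocol_list)),
       units = do.call(rbind, units_list),
       config = config)
}
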
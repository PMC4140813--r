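## PSTHs, epoch rates, modulation multiples, spatial profiles, and the
## latency estimators. All PSTH-based latency estimation follows the same
## convention: 1 ms bins for millisecond latency resolution, thresholds at the
## baseline mean +/- k standard deviations of the binned baseline rate.

#' Peri-stimulus time histogram
#'
#' Bins spike times over `window` and converts counts to rates:
#' `rate[i] = count[i] / (n_trials * bin_width)`, so
#' `sum(rate * bin_width * n_trials)` equals the number of spikes inside
#' the window (mass conservation).
#'
#' @param events a [spike_events()] table (typically aligned to light
#'   onset, simple spikes only) or a numeric vector of spike times.
#' @param bin_width bin width, s (> 0).
#' @param window `c(start, end)` of the histogram, s.
#' @param n_trials number of trials averaged; defaults to the number of
#'   distinct `trial_id` values in `events`.
#' @param baseline_window optional `c(start, end)` marking the baseline
#'   epoch used by the latency estimators.
#' @return A `rate_timecourse`: list with `bin_edges`, `rate`, `n_trials`,
#'   `baseline_window`.
#' @examples
#' ev <- rep(0.01, 5)  # 5 spikes in one 20 ms bin
#' tc <- compute_psth(ev, 0.02, c(0, 0.1), n_trials = 10)
#' tc$rate[1]  # 5 / (10 * 0.02) = 25 spikes/s
#' @export
compute_psth <- function(events, bin_width, window, n_trials = NULL,
                         baseline_window = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("window must be c(start, end) with end > start", call. = FALSE)
  }
  if (is.numeric(events)) {
    times <- events
    if (is.null(n_trials)) n_trials <- 1L
  } else {
    times <- events$time_s[events$event_type == "simple"]
    if (is.null(n_trials)) n_trials <- max(1L, length(unique(events$trial_id)))
  }
  if (n_trials < 1) stop("need >= 1 trial", call. = FALSE)
  edges <- seq(window[1], window[2], by = bin_width)
  if (edges[length(edges)] < window[2] - 1e-12) {
    edges <- c(edges, edges[length(edges)] + bin_width)
  }
  keep <- times >= edges[1] & times < edges[length(edges)]
  counts <- if (any(keep)) {
    tabulate(findInterval(times[keep], edges, left.open = FALSE),
             nbins = length(edges) - 1)
  } else rep(0L, length(edges) - 1)
  structure(list(bin_edges = edges,
                 rate = counts / (n_trials * bin_width),
                 n_trials = n_trials,
                 baseline_window = baseline_window),
            class = "rate_timecourse")
}

#' @export
print.rate_timecourse <- function(x, ...) {
  cat(sprintf("<rate_timecourse> %d bins of %g ms over [%g, %g] s, %d trial(s)\n",
              length(x$rate), 1000 * diff(x$bin_edges[1:2]),
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)], x$n_trials))
  invisible(x)
}

#' @export
plot.rate_timecourse <- function(x, ...) {
  centers <- x$bin_edges[-length(x$bin_edges)] + diff(x$bin_edges) / 2
  plot(centers, x$rate, type = "s", xlab = "time (s)",
       ylab = "rate (spikes/s)", ...)
  invisible(x)
}

bin_centers <- function(tc) {
  tc$bin_edges[-length(tc$bin_edges)] + diff(tc$bin_edges) / 2
}

#' Light-on and light-off firing rates per unit
#'
#' Counts simple spikes in the light-on epoch `[on, off)` and the
#' spontaneous (pre-onset) epoch `[skip, on)` of each trial, and divides
#' by the summed epoch durations across trials.
#'
#' @param events a [spike_events()] table (unaligned, trial-relative
#'   times).
#' @param protocol a [light_protocol()] table.
#' @param skip seconds dropped at each trial start (default 0.1).
#' @return Data frame with `unit_id`, `rate_off`, `rate_on` (spikes/s).
#' @export
epoch_rates <- function(events, protocol, skip = 0.1) {
  if (is_aligned(events)) {
    stop("epoch_rates expects unaligned (trial-relative) events", call. = FALSE)
  }
  protocol <- light_protocol(protocol)
  idx <- match(events$trial_id, protocol$trial_id)
  if (anyNA(idx)) stop("trial_id not found in protocol", call. = FALSE)
  ss <- events$event_type == "simple"
  on_of <- protocol$light_on_s[idx]
  off_of <- protocol$light_off_s[idx]
  units <- sort(unique(events$unit_id))
  out <- data.frame(unit_id = units, rate_off = 0, rate_on = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(units)) {
    sel <- events$unit_id == units[i]
    trials <- protocol[protocol$trial_id %in% unique(events$trial_id[sel]), ]
    dur_off <- sum(pmax(trials$light_on_s - skip, 0))
    dur_on <- sum(trials$light_off_s - trials$light_on_s)
    if (dur_off <= 0 || dur_on <= 0) {
      stop("zero-duration epoch for unit ", units[i], call. = FALSE)
    }
    n_off <- sum(sel & ss & events$time_s >= skip & events$time_s < on_of)
    n_on <- sum(sel & ss & events$time_s >= on_of & events$time_s < off_of)
    out$rate_off[i] <- n_off / dur_off
    out$rate_on[i] <- n_on / dur_on
  }
  out
}

#' Modulation expressed as a multiple of spontaneous activity
#'
#' @param rate_on,rate_off firing rates, spikes/s.
#' @return `rate_on / rate_off`; `NA` with a warning when the baseline
#'   rate is zero (undefined, not infinite).
#' @export
modulation_multiple <- function(rate_on, rate_off) {
  out <- rate_on / rate_off
  zero <- rate_off == 0
  if (any(zero)) {
    warning("zero baseline rate: modulation multiple undefined", call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Depth profile of light-driven modulation
#'
#' Bins per-unit modulation multiples into depth intervals (edges aligned
#' to multiples of `bin`, so a depth of -250 um falls in [-400, -200) for
#' the default 200 um bin), separately per lateral distance, and returns
#' means with standard errors.
#'
#' @param units data frame with columns `depth_um`, `lateral_um`,
#'   `multiple`.
#' @param bin depth bin width, um (> 0).
#' @return Data frame with `lateral_um`, `depth_lo`, `depth_hi`, `n`,
#'   `mean_multiple`, `sem` (`NA` for singleton bins).
#' @export
spatial_profile <- function(units, bin = 200) {
  if (bin <= 0) stop("bin must be > 0", call. = FALSE)
  units <- as.data.frame(units)
  stopifnot(all(c("depth_um", "lateral_um", "multiple") %in% names(units)))
  if (nrow(units) == 0) stop("empty input", call. = FALSE)
  lo <- floor(units$depth_um / bin) * bin
  key <- paste(units$lateral_um, lo, sep = "@")
  agg <- lapply(split(seq_len(nrow(units)), key), function(ix) {
    m <- units$multiple[ix]
    data.frame(lateral_um = units$lateral_um[ix[1]],
               depth_lo = lo[ix[1]], depth_hi = lo[ix[1]] + bin,
               n = length(m), mean_multiple = mean(m),
               sem = if (length(m) > 1) stats::sd(m) / sqrt(length(m)) else NA_real_)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$lateral_um, out$depth_lo), ]
  rownames(out) <- NULL
  out
}

## baseline mean/SD of a PSTH over its baseline window (optionally of a
## smoothed copy); used by the threshold-crossing latency estimators
baseline_rate_stats <- function(tc, rate = tc$rate) {
  bw <- tc$baseline_window
  if (is.null(bw)) stop("rate_timecourse has no baseline_window", call. = FALSE)
  centers <- bin_centers(tc)
  sel <- centers >= bw[1] & centers < bw[2]
  if (!any(sel)) stop("baseline window contains no bins", call. = FALSE)
  list(mean = mean(rate[sel]), sd = stats::sd(rate[sel]))
}

## centered moving average, width in bins (odd)
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  k <- rep(1 / width, width)
  y <- stats::filter(x, k, sides = 2)
  as.numeric(ifelse(is.na(y), x, y))
}

## vertex of the parabola through a bin and its neighbours; the shift is
## clamped to one bin so flat plateaus cannot blow up the estimate
parabolic_peak <- function(x, y, i) {
  if (i <= 1 || i >= length(y)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(denom) < 1e-12 * max(abs(y[i]), 1)) return(x[i])
  shift <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  x[i] + max(-1, min(1, shift)) * (x[2] - x[1])
}

#' Latency of the first post-onset response peak
#'
#' Finds the first PSTH bin after time 0 (light onset) whose rate exceeds
#' the baseline mean by `k` baseline SDs, exceeds every baseline bin (so
#' chance fluctuations of a flat trace are not reported as peaks), and is
#' a local maximum within a `lookahead` window; the peak position is then
#' refined by parabolic interpolation across the neighbouring bins.
#'
#' @param tc a `rate_timecourse` from [compute_psth()] built on events
#'   aligned to light onset (1 ms bins recommended), with a
#'   `baseline_window`.
#' @param k threshold in baseline SDs (default 2).
#' @param lookahead local-maximum lookahead, s (default 0.005).
#' @return Latency in ms, or `NA` when no bin crosses the threshold.
#' @export
onset_peak_latency <- function(tc, k = 2, lookahead = 0.005) {
  bs <- baseline_rate_stats(tc)
  centers <- bin_centers(tc)
  base_sel <- centers >= tc$baseline_window[1] &
    centers < tc$baseline_window[2]
  thr <- max(bs$mean + k * bs$sd, max(tc$rate[base_sel]))
  bin <- diff(tc$bin_edges[1:2])
  look <- max(1L, round(lookahead / bin))
  cand <- which(centers > 0 & tc$rate > thr)
  for (i in cand) {
    upper <- min(length(tc$rate), i + look)
    if (tc$rate[i] >= max(tc$rate[i:upper])) {
      return(1000 * parabolic_peak(centers, tc$rate, i))
    }
  }
  NA_real_
}

#' Latency of the rate returning to baseline after light offset
#'
#' Smooths the PSTH with a centered moving average (`smooth` seconds
#' wide) and takes the baseline band as smoothed-baseline mean +/- `k`
#' SDs of the smoothed baseline. The return is the first time at or
#' after `offset_time` where the smoothed rate is inside the band and
#' the median over the following `hold` seconds stays inside (a median
#' dwell tolerates single-bin excursions of low-trial-count PSTHs). The
#' returned latency is then refined to the point where the smoothed
#' trace crosses the midpoint between the pre-return (driven) plateau
#' and the baseline mean, which centres the estimate on the underlying
#' rate step instead of the band edge.
#'
#' @param tc a `rate_timecourse` with a `baseline_window` (1 ms bins
#'   recommended).
#' @param offset_time time of light offset in the timecourse's timebase, s.
#' @param k band half-width in baseline SDs (default 2).
#' @param hold dwell time inside the band, s (default 0.010).
#' @param smooth moving-average width, s (default 0.011).
#' @return Return latency in ms after `offset_time`, or `NA` when the
#'   rate never re-enters the band.
#' @export
offset_return_latency <- function(tc, offset_time, k = 2, hold = 0.010,
                                  smooth = 0.011) {
  bin <- diff(tc$bin_edges[1:2])
  width <- max(1L, 2L * floor(smooth / bin / 2) + 1L)
  sm <- moving_average(tc$rate, width)
  bs <- baseline_rate_stats(tc, rate = sm)
  lowr <- bs$mean - k * bs$sd
  uppr <- bs$mean + k * bs$sd
  centers <- bin_centers(tc)
  inside <- sm >= lowr & sm <= uppr
  hold_bins <- max(1L, round(hold / bin))
  start <- which(centers >= offset_time)
  if (length(start) == 0) return(NA_real_)
  entry <- NA_integer_
  for (i in start[1]:length(inside)) {
    upper <- min(length(inside), i + hold_bins - 1L)
    if (upper - i + 1L < hold_bins) break
    med <- stats::median(sm[i:upper])
    if (inside[i] && med >= lowr && med <= uppr) {
      entry <- i
      break
    }
  }
  if (is.na(entry)) return(NA_real_)
  ## plateau = driven level just before offset; refine to the midpoint
  ## crossing when the plateau is clearly above the band
  pre <- centers >= offset_time - 0.02 & centers < offset_time
  plateau <- if (any(pre)) stats::median(sm[pre]) else NA_real_
  if (is.finite(plateau) && plateau > uppr) {
    mid <- (plateau + bs$mean) / 2
    seg <- start[1]:entry
    above <- which(sm[seg] >= mid)
    if (length(above) > 0) {
      j <- seg[above[length(above)]]
      if (j < length(sm) && sm[j + 1] < mid && sm[j] > sm[j + 1]) {
        frac <- (sm[j] - mid) / (sm[j] - sm[j + 1])
        return(1000 * (centers[j] + frac * bin - offset_time))
      }
      return(1000 * (centers[min(j + 1, length(sm))] - offset_time))
    }
    return(1000 * max(centers[start[1]] - offset_time, 0))
  }
  1000 * (centers[entry] - offset_time)
}

#' Latency of the last transmitted spike after light onset
#'
#' Per trial, the time (minus onset) of the last simple spike before the
#' first sustained silence of the light-on epoch: the first spike in
#' `(on, off]` whose gap to the following spike (or to light offset)
#' exceeds `min_silence`. This isolates the suppression transmission
#' latency even when a unit resumes sparse firing later in the light
#' epoch. When no spike is followed by such a silence, the plain last
#' spike in `(on, off]` is used; trials with no spike after onset
#' contribute 0 by convention. The per-unit value is the median over
#' trials, which is robust to the rare trial where the transmitted spike
#' coincides with a climbing-fiber pause and is deleted.
#'
#' @param events a [spike_events()] table (unaligned).
#' @param protocol a [light_protocol()] table.
#' @param min_silence minimal silence qualifying as suppression, s
#'   (default 0.1).
#' @return Data frame with `unit_id`, `last_spike_ms` (trial mean),
#'   `n_trials`.
#' @export
last_spike_latency <- function(events, protocol, min_silence = 0.1) {
  protocol <- light_protocol(protocol)
  units <- sort(unique(events$unit_id))
  out <- data.frame(unit_id = units, last_spike_ms = NA_real_,
                    n_trials = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(units)) {
    sel <- events$unit_id == units[i] & events$event_type == "simple"
    per_trial <- vapply(protocol$trial_id, function(tr) {
      pr <- protocol[protocol$trial_id == tr, ]
      tt <- events$time_s[sel & events$trial_id == tr]
      tt <- sort(tt[tt > pr$light_on_s & tt <= pr$light_off_s])
      if (length(tt) == 0) return(0)
      gaps <- diff(c(tt, pr$light_off_s))
      silent <- which(gaps > min_silence)
      if (length(silent) > 0) tt[silent[1]] - pr$light_on_s
      else tt[length(tt)] - pr$light_on_s
    }, numeric(1))
    out$last_spike_ms[i] <- 1000 * stats::median(per_trial)
    out$n_trials[i] <- length(per_trial)
  }
  out
}

#' First simple spike after light offset (complete-block trials)
#'
#' Restricted to complete-block trials (no simple spike in
#' `[on + grace, off]`); per qualifying trial the first simple spike after
#' `off` minus the offset time is taken, trials with no post-offset spike
#' are censored (excluded), and the per-trial latencies are averaged per
#' unit.
#'
#' @param events a [spike_events()] table (unaligned).
#' @param protocol a [light_protocol()] table.
#' @param grace allowance after onset for the last transmitted spike, s
#'   (default 0.010).
#' @return Data frame with `unit_id`, `first_after_offset_ms`,
#'   `n_block_trials`, `n_censored`; latency `NA` for units without any
#'   qualifying trial.
#' @export
first_spike_after_offset <- function(events, protocol, grace = 0.010) {
  protocol <- light_protocol(protocol)
  units <- sort(unique(events$unit_id))
  out <- data.frame(unit_id = units, first_after_offset_ms = NA_real_,
                    n_block_trials = 0L, n_censored = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(units)) {
    sel <- events$unit_id == units[i] & events$event_type == "simple"
    lats <- numeric(0); blocks <- 0L; censored <- 0L
    for (tr in protocol$trial_id) {
      pr <- protocol[protocol$trial_id == tr, ]
      tt <- events$time_s[sel & events$trial_id == tr]
      if (any(tt >= pr$light_on_s + grace & tt <= pr$light_off_s)) next
      blocks <- blocks + 1L
      post <- tt[tt > pr$light_off_s]
      if (length(post) == 0) censored <- censored + 1L
      else lats <- c(lats, min(post) - pr$light_off_s)
    }
    out$n_block_trials[i] <- blocks
    out$n_censored[i] <- censored
    if (length(lats) > 0) out$first_after_offset_ms[i] <- 1000 * mean(lats)
  }
  out
}

#' Check for complete suppression during light
#'
#' `TRUE` for a unit when no simple spike falls in
#' `[on + grace, on + window]` in any trial.
#'
#' @param events a [spike_events()] table (unaligned).
#' @param protocol a [light_protocol()] table.
#' @param window suppression window measured from onset, s (default 0.5).
#' @param grace allowance for the last transmitted spike, s (default
#'   0.010).
#' @return Data frame with `unit_id`, `suppressed` (logical).
#' @export
suppression_check <- function(events, protocol, window = 0.5, grace = 0.010) {
  protocol <- light_protocol(protocol)
  idx <- match(events$trial_id, protocol$trial_id)
  if (anyNA(idx)) stop("trial_id not found in protocol", call. = FALSE)
  on_of <- protocol$light_on_s[idx]
  hit <- events$event_type == "simple" &
    events$time_s >= on_of + grace & events$time_s <= on_of + window
  units <- sort(unique(events$unit_id))
  data.frame(unit_id = units,
             suppressed = !vapply(units, function(u) any(hit[events$unit_id == u]),
                                  logical(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
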
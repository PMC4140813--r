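## End-to-end orchestration: simulate -> classify -> analyze -> report.
## run_condition() assembles the per-unit summary table (rates, modal
## frequencies, CV/CV2, latencies) and the cohort-level condition report
## for one perturbation mode, deterministic given the config seed.

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Classify a unit's response to granule-cell drive
#'
#' Sign of `rate_on - rate_off` where the absolute difference exceeds
#' `k` standard errors of the baseline rate; otherwise `"unmodulated"`.
#'
#' @param rate_on,rate_off firing rates, spikes/s.
#' @param baseline_se standard error of the baseline rate estimate,
#'   spikes/s.
#' @param k threshold multiple (default 2).
#' @return `"excited"`, `"inhibited"` or `"unmodulated"` (vectorised).
#' @export
classify_gc_response <- function(rate_on, rate_off, baseline_se, k = 2) {
  d <- rate_on - rate_off
  out <- rep("unmodulated", length(d))
  out[d > k * baseline_se] <- "excited"
  out[d < -k * baseline_se] <- "inhibited"
  out
}

## per-unit baseline rate SE across trials (pre-onset epoch)
baseline_rate_se <- function(events, protocol, skip = 0.1) {
  protocol <- light_protocol(protocol)
  units <- sort(unique(events$unit_id))
  vapply(units, function(u) {
    sel <- events$unit_id == u & events$event_type == "simple"
    rates <- vapply(unique(events$trial_id[events$unit_id == u]), function(tr) {
      pr <- protocol[protocol$trial_id == tr, ]
      dur <- pr$light_on_s - skip
      if (dur <= 0) return(NA_real_)
      sum(sel & events$trial_id == tr &
            events$time_s >= skip & events$time_s < pr$light_on_s) / dur
    }, numeric(1))
    sem(rates)
  }, numeric(1))
}

#' Per-unit summary statistics for a cohort
#'
#' Computes, for every unit: light-off/on epoch rates and the modulation
#' multiple, modal frequencies and rhythmicity flags from per-epoch ACHs,
#' CV and CV2 per epoch, the Purkinje cell classification, and the
#' mode-appropriate latencies.
#'
#' @param cohort a list with `events`, `protocol` (and optionally
#'   `config`), as returned by [generate_experiment()].
#' @param psth_bin PSTH bin width for the latency estimators, s.
#' @param ach_bin,ach_max_lag ACH parameters, s.
#' @return A data frame with one row per unit (the `UnitSummary` fields).
#' @export
summarize_units <- function(cohort, psth_bin = 0.001, ach_bin = 0.001,
                            ach_max_lag = 0.1) {
  events <- cohort$events
  protocol <- light_protocol(cohort$protocol)
  mode <- protocol$mode[1]
  rates <- epoch_rates(events, protocol)
  units <- rates$unit_id
  out <- data.frame(unit_id = units, stringsAsFactors = FALSE)
  out$rate_off <- rates$rate_off
  out$rate_on <- rates$rate_on
  out$modulation_multiple <- suppressWarnings(
    modulation_multiple(out$rate_on, out$rate_off))
  out$modal_off <- NA_real_; out$modal_on <- NA_real_
  out$rhythmic_off <- NA; out$rhythmic_on <- NA
  out$cv_off <- NA_real_; out$cv_on <- NA_real_
  out$cv2_off <- NA_real_; out$cv2_on <- NA_real_
  out$onset_peak_latency_ms <- NA_real_
  out$offset_return_latency_ms <- NA_real_
  out$last_spike_latency_ms <- NA_real_
  out$first_spike_after_offset_ms <- NA_real_
  out$is_pc <- NA
  on_s <- protocol$light_on_s[1]; off_s <- protocol$light_off_s[1]
  dur_s <- protocol$trial_duration_s[1]
  for (i in seq_along(units)) {
    ue <- events[events$unit_id == units[i], , drop = FALSE]
    ue <- spike_events(ue)
    out$is_pc[i] <- tryCatch(classify_unit(ue, protocol),
                             error = function(e) NA)
    for (ep in c("off", "on")) {
      win <- if (ep == "on") c(on_s, off_s) else c(0.1, on_s)
      ss <- ue[ue$event_type == "simple" &
                 ue$time_s >= win[1] & ue$time_s < win[2], , drop = FALSE]
      if (nrow(ss) >= 10) {
        a <- tryCatch(autocorrelation_histogram(as.data.frame(ss), ach_bin,
                                                ach_max_lag),
                      error = function(e) NULL)
        if (!is.null(a)) {
          out[[paste0("modal_", ep)]][i] <- modal_frequency(a)
          out[[paste0("rhythmic_", ep)]][i] <- rhythmicity_flag(a)
        }
      }
      runs <- epoch_isis(ue, protocol, epoch = ep)
      isis <- unlist(runs)
      if (length(isis) >= 2) {
        out[[paste0("cv_", ep)]][i] <- cv_isi(isis)
        out[[paste0("cv2_", ep)]][i] <- cv2_pooled(runs)
      }
    }
    if (mode == "pc") {
      aligned <- align_to_light(ue, protocol)
      tc <- compute_psth(aligned, psth_bin, c(-on_s, dur_s - on_s),
                         baseline_window = c(-(on_s - 0.1), 0))
      out$onset_peak_latency_ms[i] <- onset_peak_latency(tc)
      out$offset_return_latency_ms[i] <-
        offset_return_latency(tc, offset_time = off_s - on_s)
    }
  }
  if (mode == "mli") {
    ls <- last_spike_latency(events, protocol)
    out$last_spike_latency_ms <- ls$last_spike_ms[match(units, ls$unit_id)]
    fs <- first_spike_after_offset(events, protocol)
    out$first_spike_after_offset_ms <-
      fs$first_after_offset_ms[match(units, fs$unit_id)]
  }
  if (mode == "gc") {
    se <- baseline_rate_se(events, protocol)
    out$gc_response <- classify_gc_response(out$rate_on, out$rate_off,
                                            se[match(units, names(se))])
  }
  out
}

#' Run one experimental condition end to end
#'
#' Generates (or accepts) a cohort, computes the per-unit summary, and
#' aggregates the cohort-level condition report: means with SEM for every
#' summary field, fraction rhythmic, and the mode-specific statistics
#' (suppression fraction for mli; excited/inhibited split, paired CV2
#' Wilcoxon test and offset time constant for gc; onset/offset time
#' constants and the thermal/synaptic call for thermal).
#'
#' @param x a [generator_config()] (the cohort is generated) or a cohort
#'   list with `events` and `protocol`.
#' @return A list of class `condition_report` with elements `mode`,
#'   `n_units`, `summary` (per-unit table), `cohort_means` (mean and SEM
#'   per field), and mode-specific entries.
#' @examples
#' \donttest{
#' rep <- run_condition(generator_config("pc", n_units = 3, n_trials = 5,
#'                                       seed = 1))
#' rep$cohort_means["rate_on", ]
#' }
#' @export
run_condition <- function(x) {
  cohort <- if (inherits(x, "generator_config")) generate_experiment(x) else x
  stopifnot(is.list(cohort), !is.null(cohort$events), !is.null(cohort$protocol))
  protocol <- light_protocol(cohort$protocol)
  mode <- protocol$mode[1]
  summary_df <- summarize_units(cohort)
  num_cols <- names(summary_df)[vapply(summary_df, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "unit_id")
  means <- data.frame(
    mean = vapply(num_cols, function(cc) mean(summary_df[[cc]], na.rm = TRUE),
                  numeric(1)),
    sem = vapply(num_cols, function(cc) sem(summary_df[[cc]]), numeric(1)),
    n = vapply(num_cols, function(cc) sum(!is.na(summary_df[[cc]])),
               numeric(1)))
  rownames(means) <- num_cols
  report <- list(mode = mode, n_units = nrow(summary_df),
                 summary = summary_df, cohort_means = means,
                 fraction_rhythmic_off = mean(summary_df$rhythmic_off,
                                              na.rm = TRUE),
                 fraction_rhythmic_on = mean(summary_df$rhythmic_on,
                                             na.rm = TRUE))
  on_s <- protocol$light_on_s[1]; off_s <- protocol$light_off_s[1]
  dur_s <- protocol$trial_duration_s[1]
  if (mode == "mli") {
    sup <- suppression_check(cohort$events, protocol)
    report$fraction_suppressed <- mean(sup$suppressed)
  }
  if (mode == "gc") {
    report$fraction_excited <- mean(summary_df$gc_response == "excited")
    report$fraction_inhibited <- mean(summary_df$gc_response == "inhibited")
    for (lab in c("excited", "inhibited")) {
      sel <- summary_df$gc_response == lab
      if (sum(sel) >= 5) {
        report[[paste0("cv2_test_", lab)]] <-
          paired_regularity_test(summary_df$cv2_on[sel],
                                 summary_df$cv2_off[sel])
      }
    }
    tc <- grand_modulation_timecourse(cohort, bin = 0.1)
    ## the averaged |modulation| carries a noise floor that adds to the
    ## decaying signal in quadrature (E[m^2] = s^2 + sigma^2); estimate
    ## the floor power from the tail (> 4 time constants out) and remove
    ## it before fitting the decay towards zero
    off_rel <- off_s - on_s
    tail_end <- dur_s - on_s
    centers <- bin_centers(tc)
    tail_sel <- centers >= tail_end - 0.5 & centers <= tail_end
    floor_p <- if (any(tail_sel)) mean(tc$rate[tail_sel]^2) else 0
    tc$rate <- sqrt(pmax(tc$rate^2 - floor_p, 0))
    report$offset_fit <- fit_exponential(tc, "offset",
                                         phase_start = off_rel,
                                         window_end = off_rel +
                                           min(2.5, dur_s - off_s),
                                         asymptote = 0)
    report$tau_off_s <- report$offset_fit$tau
  }
  if (mode == "thermal") {
    tc <- grand_rate_timecourse(cohort, bin = 0.1)
    cycle <- fit_light_cycle(tc, light_duration = off_s - on_s)
    onset_fit <- cycle$onset_fit
    offset_fit <- cycle$offset_fit
    report$onset_fit <- onset_fit
    report$offset_fit <- offset_fit
    report$tau_on_s <- onset_fit$tau
    report$tau_off_s <- offset_fit$tau
    report$kinetics_class <- thermal_vs_synaptic_discriminator(onset_fit,
                                                               offset_fit)
  }
  structure(report, class = "condition_report")
}

#' Grand-average rate time course of a cohort
#'
#' Average of the per-unit PSTHs (equal unit weighting), aligned to light
#' onset.
#'
#' @param cohort a cohort list with `events` and `protocol`.
#' @param bin bin width, s.
#' @return A `rate_timecourse`.
#' @export
grand_rate_timecourse <- function(cohort, bin = 0.1) {
  protocol <- light_protocol(cohort$protocol)
  on_s <- protocol$light_on_s[1]; dur_s <- protocol$trial_duration_s[1]
  units <- sort(unique(cohort$events$unit_id))
  acc <- NULL
  for (u in units) {
    ue <- spike_events(as.data.frame(
      cohort$events[cohort$events$unit_id == u, , drop = FALSE]))
    aligned <- align_to_light(ue, protocol)
    tc <- compute_psth(aligned, bin, c(-on_s, dur_s - on_s),
                       baseline_window = c(-(on_s - 0.1), 0))
    acc <- if (is.null(acc)) tc else {
      tc0 <- acc; tc0$rate <- tc0$rate + tc$rate; tc0
    }
  }
  acc$rate <- acc$rate / length(units)
  acc
}

#' Grand-average absolute rate-modulation time course
#'
#' Per unit, the signed deviation of the PSTH from that unit's pre-onset
#' baseline rate. Units are pooled within their modulation sign group
#' (excited / inhibited, by the sign of the light-on rate change) before
#' the magnitude is taken, so that the within-group average cancels
#' counting noise instead of rectifying it; the group magnitudes are then
#' combined weighted by group size. Used to pool excited and inhibited
#' responses when fitting relaxation kinetics.
#'
#' @inheritParams grand_rate_timecourse
#' @return A `rate_timecourse` of the mean `|rate - baseline|`, spikes/s.
#' @export
grand_modulation_timecourse <- function(cohort, bin = 0.1) {
  protocol <- light_protocol(cohort$protocol)
  on_s <- protocol$light_on_s[1]; dur_s <- protocol$trial_duration_s[1]
  rates <- epoch_rates(cohort$events, protocol)
  sign_of <- ifelse(rates$rate_on >= rates$rate_off, 1, -1)
  names(sign_of) <- rates$unit_id
  groups <- split(rates$unit_id, sign_of)
  acc <- NULL
  total <- 0
  for (grp in groups) {
    gacc <- NULL
    for (u in grp) {
      ue <- spike_events(as.data.frame(
        cohort$events[cohort$events$unit_id == u, , drop = FALSE]))
      aligned <- align_to_light(ue, protocol)
      tc <- compute_psth(aligned, bin, c(-on_s, dur_s - on_s),
                         baseline_window = c(-(on_s - 0.1), 0))
      base <- baseline_rate_stats(tc)$mean
      tc$rate <- tc$rate - base
      gacc <- if (is.null(gacc)) tc else {
        tc0 <- gacc; tc0$rate <- tc0$rate + tc$rate; tc0
      }
    }
    gacc$rate <- abs(gacc$rate)  # |sum of signed deviations| per group
    acc <- if (is.null(acc)) gacc else {
      tc0 <- acc; tc0$rate <- tc0$rate + gacc$rate; tc0
    }
    total <- total + length(grp)
  }
  acc$rate <- acc$rate / total
  acc
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> mode=%s, %d units\n", x$mode, x$n_units))
  key <- intersect(c("rate_off", "rate_on", "modal_off", "modal_on",
                     "cv2_off", "cv2_on", "onset_peak_latency_ms",
                     "offset_return_latency_ms", "last_spike_latency_ms",
                     "first_spike_after_offset_ms"),
                   rownames(x$cohort_means))
  cm <- x$cohort_means[key, ]
  for (k in seq_len(nrow(cm))) {
    if (is.finite(cm$mean[k])) {
      cat(sprintf("  %-28s %8.2f +/- %.2f (n=%d)\n", rownames(cm)[k],
                  cm$mean[k], cm$sem[k], as.integer(cm$n[k])))
    }
  }
  if (!is.null(x$fraction_suppressed)) {
    cat(sprintf("  fraction suppressed >= 500 ms: %.2f\n", x$fraction_suppressed))
  }
  if (!is.null(x$fraction_excited)) {
    cat(sprintf("  excited %.2f / inhibited %.2f; offset tau %.2f s\n",
                x$fraction_excited, x$fraction_inhibited, x$tau_off_s))
  }
  if (!is.null(x$kinetics_class)) {
    cat(sprintf("  tau_on %.2f s, tau_off %.2f s -> %s\n",
                x$tau_on_s, x$tau_off_s, x$kinetics_class))
  }
  invisible(x)
}
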
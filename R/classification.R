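## Purkinje cell identification: joint occurrence of simple and complex
## spikes plus the climbing-fiber pause (no simple spike for ~15 ms after
## each complex spike), with spontaneous-rate gates on both spike types.

#' Climbing-fiber pause statistics for one unit
#'
#' For every complex spike, the gap to the next simple spike in the same
#' trial is computed. Complex spikes with no later simple spike in their
#' trial are censored (excluded). A gap shorter than `pause_threshold`
#' counts as a violation of the climbing-fiber pause.
#'
#' @param events a [spike_events()] table for a single unit.
#' @param pause_threshold pause duration, s (default 0.015).
#' @return List with `min_gap`, `median_gap` (s), `n_violations`,
#'   `n_gaps` and `n_censored`.
#' @examples
#' ev <- spike_events(data.frame(unit_id = "u1", trial_id = "t1",
#'   event_type = c("complex", "simple"), time_s = c(1.0, 1.016)))
#' climbing_fiber_pause_stats(ev)$min_gap
#' @export
climbing_fiber_pause_stats <- function(events, pause_threshold = 0.015) {
  if (length(unique(events$unit_id)) > 1) {
    stop("pause stats are per unit; got multiple unit_id values", call. = FALSE)
  }
  cs <- events[events$event_type == "complex", ]
  if (nrow(cs) == 0) {
    stop("unit has no complex spikes: pause statistics undefined", call. = FALSE)
  }
  gaps <- numeric(0)
  censored <- 0L
  for (tr in unique(cs$trial_id)) {
    ss_t <- events$time_s[events$event_type == "simple" & events$trial_id == tr]
    for (ct in cs$time_s[cs$trial_id == tr]) {
      nxt <- ss_t[ss_t > ct]
      if (length(nxt) == 0) censored <- censored + 1L
      else gaps <- c(gaps, min(nxt) - ct)
    }
  }
  list(min_gap = if (length(gaps)) min(gaps) else NA_real_,
       median_gap = if (length(gaps)) stats::median(gaps) else NA_real_,
       n_violations = sum(gaps < pause_threshold),
       n_gaps = length(gaps),
       n_censored = censored)
}

## total duration and spike count of the spontaneous (pre-onset) epochs,
## skipping the first `skip` seconds of each trial
spontaneous_epoch <- function(events, protocol, skip = 0.1) {
  protocol <- light_protocol(protocol)
  idx <- match(events$trial_id, protocol$trial_id)
  if (anyNA(idx)) {
    stop("trial_id not found in protocol: ",
         paste(unique(events$trial_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  trials <- protocol[protocol$trial_id %in% unique(events$trial_id), ]
  dur <- sum(pmax(trials$light_on_s - skip, 0))
  list(duration = dur, trials = trials)
}

#' Classify one unit as a Purkinje cell
#'
#' A unit is a Purkinje cell when (i) both simple and complex spikes are
#' present, (ii) the complex-spike rate is below `cs_rate_max` (1 Hz),
#' (iii) the spontaneous simple-spike rate lies in `ss_rate_range`
#' (20-150 Hz), both rates measured over the light-off (pre-onset) epochs,
#' and (iv) the fraction of climbing-fiber pause violations does not
#' exceed `tolerance` (default 0: strict). Degenerate units (one event
#' type missing) classify as `FALSE`; units without any light-off epoch
#' are unclassifiable and raise an error.
#'
#' @param events a [spike_events()] table for a single unit.
#' @param protocol a [light_protocol()] table.
#' @param pause_threshold climbing-fiber pause duration, s.
#' @param tolerance maximal tolerated fraction of pause violations.
#' @param ss_rate_range admissible spontaneous simple-spike rate, Hz.
#' @param cs_rate_max maximal complex-spike rate, Hz.
#' @param skip seconds dropped at each trial start before rate estimation.
#' @return Logical.
#' @export
classify_unit <- function(events, protocol, pause_threshold = 0.015,
                          tolerance = 0, ss_rate_range = c(20, 150),
                          cs_rate_max = 1, skip = 0.1) {
  if (nrow(events) == 0) return(FALSE)
  if (length(unique(events$unit_id)) > 1) {
    stop("classification is per unit; got multiple unit_id values",
         call. = FALSE)
  }
  ep <- spontaneous_epoch(events, protocol, skip)
  if (ep$duration <= 0) {
    stop("unit '", events$unit_id[1],
         "' has no light-off epoch: unclassifiable", call. = FALSE)
  }
  has_simple <- any(events$event_type == "simple")
  has_complex <- any(events$event_type == "complex")
  if (!has_simple || !has_complex) return(FALSE)
  on_of <- ep$trials$light_on_s[match(events$trial_id, ep$trials$trial_id)]
  in_spont <- events$time_s >= skip & events$time_s < on_of
  ss_rate <- sum(in_spont & events$event_type == "simple") / ep$duration
  cs_rate <- sum(in_spont & events$event_type == "complex") / ep$duration
  if (cs_rate >= cs_rate_max) return(FALSE)
  if (ss_rate < ss_rate_range[1] || ss_rate > ss_rate_range[2]) return(FALSE)
  ps <- climbing_fiber_pause_stats(events, pause_threshold)
  if (ps$n_gaps == 0) return(TRUE)
  (ps$n_violations / ps$n_gaps) <= tolerance
}
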
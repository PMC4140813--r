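# Cohorts are expensive; cache them per (mode, seed) across test files.
cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(mode, seed = 1) {
  key <- paste(mode, seed, sep = "_")
  if (is.null(cohort_cache[[key]])) {
    cohort_cache[[key]] <- generate_experiment(generator_config(mode,
                                                                seed = seed))
  }
  cohort_cache[[key]]
}

cached_summary <- function(mode, seed = 1) {
  key <- paste("su", mode, seed, sep = "_")
  if (is.null(cohort_cache[[key]])) {
    cohort_cache[[key]] <- summarize_units(cached_cohort(mode, seed))
  }
  cohort_cache[[key]]
}

# small valid event/protocol pair used by io and analysis unit tests
toy_events <- function() {
  spike_events(data.frame(
    unit_id = rep(c("u1", "u2"), each = 4),
    trial_id = rep(c("t1", "t2"), times = 4),
    event_type = c("simple", "simple", "complex", "simple",
                   "simple", "simple", "simple", "complex"),
    time_s = c(0.10, 0.20, 0.50, 0.90, 0.15, 0.25, 0.35, 0.60)))
}

toy_protocol <- function(n_trials = 2, on = 1, off = 2, dur = 3,
                         mode = "pc") {
  light_protocol(data.frame(
    trial_id = sprintf("t%d", seq_len(n_trials)),
    trial_duration_s = dur, light_on_s = on, light_off_s = off,
    laser_power_mw = 5, tip_power_mw = 1.25,
    fiber_depth_um = -330, lateral_um = 330, mode = mode))
}

sem_of <- function(x) {
  x <- x[!is.na(x)]
  sd(x) / sqrt(length(x))
}
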
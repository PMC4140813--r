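test_that("pause gaps are measured per trial with censoring", {
  ev <- spike_events(data.frame(
    unit_id = "u1",
    trial_id = c("t1", "t1", "t1", "t2", "t2"),
    event_type = c("complex", "simple", "complex", "simple", "complex"),
    time_s = c(1.0, 1.016, 2.5, 0.5, 0.9)))
  ps <- climbing_fiber_pause_stats(ev)
  # cs at 1.0 -> next ss 1.016 (16 ms); cs at 2.5 and 0.9 have no later ss
  expect_equal(ps$min_gap, 0.016)
  expect_equal(ps$n_gaps, 1)
  expect_equal(ps$n_censored, 2)
  expect_equal(ps$n_violations, 0)
  no_cs <- spike_events(data.frame(unit_id = "u1", trial_id = "t1",
                                   event_type = "simple", time_s = 0.1))
  expect_error(climbing_fiber_pause_stats(no_cs), "no complex spikes")
})

test_that("gap statistics agree with a brute-force enumeration", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    df <- data.frame(
      unit_id = "u",
      trial_id = sample(c("t1", "t2", "t3"), n, replace = TRUE),
      event_type = sample(c("simple", "complex"), n, replace = TRUE,
                          prob = c(0.85, 0.15)),
      time_s = round(runif(n, 0, 3), 4))
    df <- df[!duplicated(df[c("trial_id", "event_type", "time_s")]), ]
    if (!any(df$event_type == "complex")) next
    ev <- spike_events(df)
    ps <- climbing_fiber_pause_stats(ev, pause_threshold = 0.05)
    # oracle: nested loops over every complex spike
    gaps <- c()
    for (i in which(ev$event_type == "complex")) {
      later <- ev$time_s[ev$trial_id == ev$trial_id[i] &
                           ev$event_type == "simple" &
                           ev$time_s > ev$time_s[i]]
      if (length(later)) gaps <- c(gaps, min(later) - ev$time_s[i])
    }
    if (length(gaps)) {
      expect_equal(ps$min_gap, min(gaps))
      expect_equal(ps$n_gaps, length(gaps))
      expect_equal(ps$n_violations, sum(gaps < 0.05))
    }
  }
})

test_that("an injected spike inside the pause adds exactly one violation", {
  coh <- cached_cohort("pc")
  u <- coh$events$unit_id[coh$events$event_type == "complex"][1]
  ue <- spike_events(as.data.frame(coh$events[coh$events$unit_id == u, ]))
  before <- climbing_fiber_pause_stats(ue)
  cs_row <- which(ue$event_type == "complex")[1]
  inject <- data.frame(unit_id = u, trial_id = ue$trial_id[cs_row],
                       event_type = "simple",
                       time_s = ue$time_s[cs_row] + 0.005)
  ue2 <- spike_events(rbind(as.data.frame(ue), inject))
  after <- climbing_fiber_pause_stats(ue2)
  expect_equal(after$n_violations, before$n_violations + 1)
  expect_equal(after$min_gap, 0.005)
})

test_that("units are classified by both spike types, rates and the pause", {
  pr <- toy_protocol()
  only_simple <- spike_events(data.frame(
    unit_id = "u1", trial_id = rep(c("t1", "t2"), each = 30),
    event_type = "simple",
    time_s = rep(seq(0.11, 0.98, length.out = 30), 2)))
  expect_false(classify_unit(only_simple, pr))
  # complex spikes above 1 Hz disqualify
  fast_cs <- rbind(as.data.frame(only_simple),
                   data.frame(unit_id = "u1",
                              trial_id = rep(c("t1", "t2"), each = 2),
                              event_type = "complex",
                              time_s = rep(c(0.4, 0.85), 2) + 0.003))
  expect_false(classify_unit(spike_events(fast_cs), pr))
  # synthetic pc units classify as PCs
  su <- cached_summary("pc")
  expect_gte(mean(su$is_pc, na.rm = TRUE), 13 / 14)
  # no light-off epoch -> unclassifiable, not FALSE
  pr0 <- light_protocol(data.frame(
    trial_id = c("t1", "t2"), trial_duration_s = 3, light_on_s = 0.05,
    light_off_s = 2, laser_power_mw = 5, tip_power_mw = 1.25,
    fiber_depth_um = -330, lateral_um = 330, mode = "pc"))
  expect_error(classify_unit(only_simple, pr0), "unclassifiable")
})

test_that("classification is invariant to trial order and common time shifts", {
  coh <- cached_cohort("pc")
  u <- unique(coh$events$unit_id)[2]
  ue <- as.data.frame(coh$events[coh$events$unit_id == u, ])
  base <- classify_unit(spike_events(ue), coh$protocol)
  shuffled <- spike_events(ue[sample(nrow(ue)), ])
  expect_identical(classify_unit(shuffled, coh$protocol), base)
  shifted <- ue
  shifted$time_s <- shifted$time_s + 0.25
  pr <- as.data.frame(coh$protocol)
  pr$light_on_s <- pr$light_on_s + 0.25
  pr$light_off_s <- pr$light_off_s + 0.25
  pr$trial_duration_s <- pr$trial_duration_s + 0.25
  expect_identical(classify_unit(spike_events(shifted), light_protocol(pr)),
                   base)
})
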
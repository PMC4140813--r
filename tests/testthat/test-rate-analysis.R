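test_that("PSTH rates follow count / (n_trials * bin_width)", {
  tc <- compute_psth(rep(0.01, 5), 0.02, c(0, 0.1), n_trials = 10)
  expect_equal(tc$rate[1], 25)  # 5 / (10 * 0.02)
  expect_equal(sum(tc$rate[-1]), 0)
  empty <- compute_psth(numeric(0), 0.02, c(0, 0.1), n_trials = 4)
  expect_true(all(empty$rate == 0))
  expect_error(compute_psth(1, 0, c(0, 1)), "bin_width")
})

test_that("PSTH mass is conserved on random inputs", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(50:500, 1)
    times <- runif(n, -0.5, 2.5)
    bw <- sample(c(0.001, 0.02, 0.13), 1)
    nt <- sample(1:30, 1)
    tc <- compute_psth(times, bw, c(-0.5, 2.5), n_trials = nt)
    inside <- sum(times >= tc$bin_edges[1] &
                    times < tc$bin_edges[length(tc$bin_edges)])
    expect_equal(sum(tc$rate) * bw * nt, inside)
  }
})

test_that("epoch rates and modulation multiples behave at the edges", {
  coh <- cached_cohort("pc")
  er <- epoch_rates(coh$events, coh$protocol)
  expect_true(all(er$rate_off >= 0 & er$rate_on >= 0))
  expect_equal(modulation_multiple(80, 40), 2)
  expect_equal(modulation_multiple(35, 35), 1)
  expect_warning(mm <- modulation_multiple(10, 0), "undefined")
  expect_true(is.na(mm))
})

test_that("spatial profile bins align to multiples of the bin width", {
  units <- data.frame(depth_um = c(-250, -250, -150, 300),
                      lateral_um = c(330, 330, 330, 660),
                      multiple = c(2, 3, 1.5, 1))
  sp <- spatial_profile(units, bin = 200)
  row <- sp[sp$depth_lo == -400 & sp$lateral_um == 330, ]
  expect_equal(row$n, 2)           # both -250 um units in [-400, -200)
  expect_equal(row$mean_multiple, 2.5)
  single <- sp[sp$lateral_um == 660, ]
  expect_equal(single$mean_multiple, 1)
  expect_true(is.na(single$sem))
  expect_error(spatial_profile(units[0, ]), "empty")
})

test_that("onset peak latency finds the first significant local peak", {
  # deterministic: every trial's first driven spike at exactly 4 ms
  times <- c(runif(400, -0.9, 0), rep(0.004, 20),
             rep(seq(0.012, 0.5, by = 0.008), each = 1))
  tc <- compute_psth(times, 0.001, c(-1, 0.5), n_trials = 20,
                     baseline_window = c(-0.9, 0))
  expect_equal(onset_peak_latency(tc), 4, tolerance = 0.15)
  # flat trace -> no response
  set.seed(5)
  flat <- compute_psth(runif(300, -1, 0.5), 0.001, c(-1, 0.5),
                       n_trials = 20, baseline_window = c(-0.9, 0))
  expect_true(is.na(onset_peak_latency(flat)))
})

test_that("offset return latency matches a clean rate step and censors", {
  set.seed(8)
  # driven at 100 Hz until 16 ms after offset (t=0), baseline 35 Hz after
  tr <- lapply(1:40, function(i) {
    c(runif(rpois(1, 35 * 0.9), -1, -0.1),        # pre baseline 35 Hz
      runif(rpois(1, 100 * 0.116), -0.1, 0.016),  # driven plateau
      runif(rpois(1, 35 * 1.984), 0.016, 2))      # return to baseline
  })
  tc <- compute_psth(unlist(tr), 0.001, c(-1, 2), n_trials = 40,
                     baseline_window = c(-0.9, -0.1))
  est <- offset_return_latency(tc, offset_time = 0)
  expect_equal(est, 16, tolerance = 5)
  # a step that never returns -> NA
  never <- lapply(1:40, function(i) {
    c(runif(rpois(1, 35 * 0.9), -1, -0.1), runif(rpois(1, 200), -0.1, 2))
  })
  tcn <- compute_psth(unlist(never), 0.001, c(-1, 2), n_trials = 40,
                      baseline_window = c(-0.9, -0.1))
  expect_true(is.na(offset_return_latency(tcn, offset_time = 0)))
})

test_that("latency estimators are invariant to a common time translation", {
  coh <- cached_cohort("pc")
  pr <- coh$protocol
  u <- unique(coh$events$unit_id)[1]
  ue <- spike_events(as.data.frame(coh$events[coh$events$unit_id == u, ]))
  # fixed-length windows relative to onset: translation must then leave
  # the estimates exactly unchanged
  mk_tc <- function(ev, p) {
    al <- align_to_light(ev, p)
    compute_psth(al, 0.001, c(-0.9, 2), baseline_window = c(-0.8, 0))
  }
  t1 <- mk_tc(ue, pr)
  shifted <- as.data.frame(ue); shifted$time_s <- shifted$time_s + 0.4
  pr2 <- as.data.frame(pr)
  pr2$light_on_s <- pr2$light_on_s + 0.4
  pr2$light_off_s <- pr2$light_off_s + 0.4
  pr2$trial_duration_s <- pr2$trial_duration_s + 0.4
  t2 <- mk_tc(spike_events(shifted), light_protocol(pr2))
  expect_equal(onset_peak_latency(t1), onset_peak_latency(t2))
  expect_equal(offset_return_latency(t1, 1), offset_return_latency(t2, 1))
})

test_that("last-spike and first-after-offset latencies follow the events", {
  pr <- toy_protocol(n_trials = 1)
  ev <- spike_events(data.frame(
    unit_id = "u1", trial_id = "t1", event_type = "simple",
    time_s = c(0.5, 1.002, 1.0035, 2.4)))
  ls <- last_spike_latency(ev, pr)
  expect_equal(ls$last_spike_ms, 3.5)
  fs <- first_spike_after_offset(ev, pr)
  expect_equal(fs$first_after_offset_ms, 400)
  expect_equal(fs$n_block_trials, 1)
  # trial with no post-offset spike is censored
  ev2 <- spike_events(data.frame(unit_id = "u1", trial_id = "t1",
                                 event_type = "simple",
                                 time_s = c(0.5, 1.003)))
  fs2 <- first_spike_after_offset(ev2, pr)
  expect_true(is.na(fs2$first_after_offset_ms))
  expect_equal(fs2$n_censored, 1)
})

test_that("suppression check fails on a single counterexample spike", {
  coh <- cached_cohort("mli")
  pr <- coh$protocol
  u <- unique(coh$events$unit_id)[1]
  ue <- as.data.frame(coh$events[coh$events$unit_id == u, ])
  expect_true(suppression_check(spike_events(ue), pr)$suppressed)
  on <- pr$light_on_s[1]
  spiked <- rbind(ue, data.frame(unit_id = u, trial_id = "t001",
                                 event_type = "simple", time_s = on + 0.4))
  expect_false(suppression_check(spike_events(spiked), pr)$suppressed)
  # pc cohorts keep firing under light
  pc <- cached_cohort("pc")
  expect_false(any(suppression_check(pc$events, pc$protocol)$suppressed))
})
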
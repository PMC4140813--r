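test_that("noise-free baseline train is exactly periodic", {
  tr <- generate_baseline_train(100, 100, isi_jitter_cv = 0, duration = 1)
  expect_length(tr, 100)
  expect_equal(tr, (1:100) * 0.01)
  expect_length(generate_baseline_train(100, 100, 0, duration = 0), 0)
  expect_error(generate_baseline_train(80, 68, duration = 1),
               "must not exceed")
})

test_that("pause thinning calibrates the count rate to within 2%", {
  set.seed(7)
  rates <- replicate(10, {
    length(generate_baseline_train(35, 68, 0.25, duration = 300)) / 300
  })
  expect_lt(abs(mean(rates) - 35) / 35, 0.02)
  # the solved pause fraction matches the count/modal accounting
  expect_equal(mean(rates) / 68, 35 / 68, tolerance = 0.02)
})

test_that("complex-spike overlay enforces the climbing-fiber pause", {
  set.seed(11)
  dense <- seq(0.005, 10, by = 0.005)  # 200 Hz periodic
  ov <- overlay_complex_spikes(dense, cs_rate = 2, cs_pause = 0.015,
                               duration = 10)
  expect_gt(length(ov$complex), 0)
  for (cs in ov$complex) {
    expect_length(ov$simple[ov$simple > cs & ov$simple <= cs + 0.015], 0)
  }
  if (length(ov$complex) > 1) {
    expect_true(all(diff(ov$complex) >= 0.015))
  }
  # degenerate rate leaves the train untouched
  ov0 <- overlay_complex_spikes(dense, cs_rate = 0, duration = 10)
  expect_identical(ov0$simple, dense)
  expect_length(ov0$complex, 0)
  expect_error(overlay_complex_spikes(dense, 1, cs_pause = 0), "cs_pause")
})

test_that("identical configs generate identical cohorts", {
  cfg <- generator_config("pc", n_units = 3, n_trials = 4, seed = 99)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  expect_identical(as.data.frame(a$protocol), as.data.frame(b$protocol))
  expect_identical(a$units, b$units)
})

test_that("zero-trial configs give empty events and a valid protocol", {
  coh <- generate_experiment(generator_config("pc", n_units = 2,
                                              n_trials = 0, seed = 1))
  expect_equal(nrow(coh$events), 0)
  expect_s3_class(coh$protocol, "light_protocol")
  expect_equal(nrow(coh$protocol), 0)
})

test_that("mli suppression is complete when the sparse fraction is zero", {
  coh <- generate_experiment(generator_config("mli", n_units = 5,
                                              n_trials = 10,
                                              sparse_fraction = 0,
                                              seed = 3))
  pr <- coh$protocol
  on <- pr$light_on_s[1]; off <- pr$light_off_s[1]
  ss <- coh$events[coh$events$event_type == "simple", ]
  expect_equal(sum(ss$time_s >= on + 0.0105 & ss$time_s <= off), 0)
  sup <- suppression_check(coh$events, pr)
  expect_true(all(sup$suppressed))
})

test_that("thermal rate trace never drops below baseline", {
  coh <- cached_cohort("thermal")
  tc <- grand_rate_timecourse(coh, bin = 0.1)
  centers <- tc$bin_edges[-length(tc$bin_edges)] + 0.05
  base <- mean(tc$rate[centers > -1.9 & centers < 0])
  base_se <- sd(tc$rate[centers > -1.9 & centers < 0]) /
    sqrt(sum(centers > -1.9 & centers < 0))
  expect_true(all(tc$rate[centers > 0] >= base - 3 * sd(tc$rate[centers < 0])))
  expect_gt(min(tc$rate), 0.8 * base)
})

test_that("pc drive with baseline parameters reduces to the baseline process", {
  cfg <- generator_config("pc", n_units = 4, n_trials = 10,
                          driven_count_rate = 35, driven_modal_rate = 68,
                          driven_isi_jitter_cv = 0.25,
                          transient_fraction = 0, cs_rate = 0, seed = 21)
  coh <- generate_experiment(cfg)
  er <- epoch_rates(coh$events, coh$protocol)
  # null modulation: light-on rate within a few percent of light-off rate
  expect_equal(mean(er$rate_on), mean(er$rate_off), tolerance = 0.08)
  # and ISI distributions indistinguishable by a KS test
  on_isis <- unlist(lapply(unique(coh$events$unit_id), function(u) {
    unlist(epoch_isis(spike_events(as.data.frame(
      coh$events[coh$events$unit_id == u, ])), coh$protocol, "on"))
  }))
  off_isis <- unlist(lapply(unique(coh$events$unit_id), function(u) {
    unlist(epoch_isis(spike_events(as.data.frame(
      coh$events[coh$events$unit_id == u, ])), coh$protocol, "off"))
  }))
  expect_gt(suppressWarnings(ks.test(on_isis, off_isis)$p.value), 0.01)
})

test_that("spatial cohorts follow the depth/lateral attenuation profile", {
  cfg <- generator_config("pc", n_trials = 8, seed = 5)
  pos <- data.frame(depth_um = rep(c(-500, -250, 0), 2),
                    lateral_um = rep(c(330, 990), each = 3))
  coh <- generate_spatial_cohort(cfg, pos)
  er <- epoch_rates(coh$events, coh$protocol)
  mm <- modulation_multiple(er$rate_on, er$rate_off)
  lat <- coh$units$lateral_um[match(er$unit_id, coh$units$unit_id)]
  # no modulation at 990 um lateral distance
  expect_equal(mean(mm[lat == 990]), 1, tolerance = 0.12)
  # strong modulation up to 500 um above the cell at 330 um
  expect_gt(mean(mm[lat == 330 & coh$units$depth_um %in% c(-500, -250)]), 2)
  expect_error(generate_spatial_cohort(cfg,
                 data.frame(depth_um = 0, lateral_um = 100)), "lateral")
  # single-row profile degenerates to a constant attenuation
  flat <- list(depth = data.frame(depth_um = 0, attenuation = 0.5),
               lateral = c("330" = 1, "660" = 0.45, "990" = 0))
  g <- cbopto:::spatial_attenuation(c(-1000, 0, 500), 330, flat)
  expect_equal(g, rep(0.5, 3))
})

test_that("high light intensity triggers response block and post-light pause", {
  blk <- list(tip_power_threshold = 1, response_scale = 0.4,
              post_pause_duration = 0.3)
  cfg <- generator_config("pc", n_units = 4, n_trials = 10,
                          intensity_block = blk, tip_power_mw = 1.25,
                          transient_fraction = 0, cs_rate = 0, seed = 13)
  coh <- generate_experiment(cfg)
  er <- epoch_rates(coh$events, coh$protocol)
  # response reduced relative to the unblocked drive
  expect_lt(mean(er$rate_on), 0.6 * 97)
  # silence right after light offset
  off <- coh$protocol$light_off_s[1]
  ss <- coh$events[coh$events$event_type == "simple", ]
  expect_equal(sum(ss$time_s > off + 0.017 & ss$time_s <= off + 0.3), 0)
})
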
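test_that("CV matches the hand formula with the n-1 denominator", {
  expect_equal(cv_isi(c(0.01, 0.01, 0.01)), 0)
  expect_equal(cv_isi(c(0.01, 0.02)), sd(c(0.01, 0.02)) / 0.015)
  expect_error(cv_isi(0.01), "2 intervals")
  set.seed(3)
  expect_equal(cv_isi(rexp(1e4, 50)), 1, tolerance = 0.05)
})

test_that("CV2 matches hand values and stays in [0, 2]", {
  expect_equal(cv2_isi(c(0.01, 0.01)), 0)
  expect_equal(cv2_isi(c(0.01, 0.03)), 1)  # 2*0.02/0.04
  expect_error(cv2_isi(c(0.01, -0.01)), "positive")
  expect_error(cv2_isi(0.02), "2 intervals")
  set.seed(4)
  expect_equal(cv2_isi(rexp(1e4, 40)), 1, tolerance = 0.05)
  for (rep in 1:5) {
    isis <- rgamma(200, shape = runif(1, 0.3, 8), rate = 50)
    v <- cv2_isi(isis)
    expect_gte(v, 0); expect_lte(v, 2)
  }
  # periodic trains have CV2 exactly 0
  expect_equal(cv2_isi(rep(0.0125, 50)), 0)
})

test_that("epoch ISIs exclude transition-spanning and pause-inflated intervals", {
  pr <- toy_protocol(n_trials = 1)
  # spikes straddling light onset: that interval must not appear
  ev <- spike_events(data.frame(
    unit_id = "u1", trial_id = "t1", event_type = "simple",
    time_s = c(0.97, 0.99, 1.01, 1.05)))
  off_runs <- epoch_isis(ev, pr, "off")
  on_runs <- epoch_isis(ev, pr, "on")
  expect_equal(unlist(off_runs), 0.02)
  expect_equal(unlist(on_runs), 0.04)
  # single spike per epoch -> nothing
  lone <- spike_events(data.frame(unit_id = "u1", trial_id = "t1",
                                  event_type = "simple", time_s = 1.5))
  expect_length(unlist(epoch_isis(lone, pr, "on")), 0)
  # an interval containing a complex spike is excluded and CV2 pairs
  # never straddle the exclusion
  with_cs <- spike_events(data.frame(
    unit_id = "u1", trial_id = "t1",
    event_type = c(rep("simple", 5), "complex"),
    time_s = c(1.10, 1.12, 1.20, 1.22, 1.24, 1.15)))
  runs <- epoch_isis(with_cs, pr, "on")
  expect_equal(length(runs), 2)              # split at the excluded ISI
  expect_equal(runs[[1]], 0.02, tolerance = 1e-9)
  expect_equal(runs[[2]], c(0.02, 0.02), tolerance = 1e-9)
  expect_false(any(unlist(runs) < 0))
})

test_that("epoch ISI exclusion never produces negative intervals", {
  set.seed(19)
  pr <- toy_protocol(n_trials = 3)
  for (rep in 1:3) {
    n <- 120
    df <- data.frame(
      unit_id = "u1",
      trial_id = sample(c("t1", "t2", "t3"), n, replace = TRUE),
      event_type = sample(c("simple", "complex"), n, replace = TRUE,
                          prob = c(0.9, 0.1)),
      time_s = round(runif(n, 0, 3), 5))
    df <- df[!duplicated(df[c("trial_id", "event_type", "time_s")]), ]
    ev <- spike_events(df)
    for (ep in c("on", "off")) {
      isis <- unlist(epoch_isis(ev, pr, ep))
      if (length(isis)) expect_true(all(isis > 0))
    }
  }
})

test_that("the paired Wilcoxon test is two-sided and sign-symmetric", {
  set.seed(6)
  off <- runif(13, 0.4, 0.5)
  on <- off + rnorm(13, 0.06, 0.02)
  a <- paired_regularity_test(on, off)
  b <- paired_regularity_test(off, on)  # flip all differences
  expect_equal(a$p_value, b$p_value)
  expect_lt(a$p_value, 0.05)
  expect_warning(z <- paired_regularity_test(rep(1, 6), rep(1, 6)),
                 "zero")
  expect_true(is.na(z$p_value))
  expect_error(paired_regularity_test(1:3, 1:3), "5 pairs")
})
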
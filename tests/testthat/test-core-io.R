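test_that("event tables are validated on construction", {
  expect_error(spike_events(data.frame(unit_id = "u1", time_s = 0.1)),
               "missing column")
  bad <- data.frame(unit_id = "u1", trial_id = "t1",
                    event_type = "cs", time_s = 0.1)
  expect_error(spike_events(bad), "invalid event_type")
  dup <- data.frame(unit_id = "u1", trial_id = "t1",
                    event_type = c("simple", "simple"),
                    time_s = c(0.2, 0.2))
  expect_error(spike_events(dup), "non-monotone.*u1.*t1")
  neg <- data.frame(unit_id = "u1", trial_id = "t1",
                    event_type = "simple", time_s = -0.1)
  expect_error(spike_events(neg), "negative")
})

test_that("protocol invariants are enforced", {
  base <- data.frame(trial_id = "t1", trial_duration_s = 3,
                     light_on_s = 1, light_off_s = 2, laser_power_mw = 5,
                     tip_power_mw = 1.25, fiber_depth_um = -330,
                     lateral_um = 330, mode = "pc")
  expect_s3_class(light_protocol(base), "light_protocol")
  bad_epoch <- transform(base, light_off_s = 0.5)
  expect_error(light_protocol(bad_epoch), "light_on < light_off")
  bad_lat <- transform(base, lateral_um = 400)
  expect_error(light_protocol(bad_lat), "lateral_um")
  bad_pow <- transform(base, tip_power_mw = 10)
  expect_error(light_protocol(bad_pow), "tip_power")
})

test_that("write/read round-trips are exact and deterministic", {
  ev <- toy_events()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(as.data.frame(back), as.data.frame(ev))
  # byte-identical on rewrite
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_events(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # 6-decimal formatting contract
  one <- spike_events(data.frame(unit_id = "u1", trial_id = "t1",
                                 event_type = "simple", time_s = 0.0039))
  write_events(one, f)
  expect_match(readLines(f)[2], "0\\.003900$")
  # empty collection -> header only
  empty <- spike_events(data.frame(unit_id = character(0),
                                   trial_id = character(0),
                                   event_type = character(0),
                                   time_s = numeric(0)))
  write_events(empty, f)
  expect_length(readLines(f), 1)
})

test_that("round-trip holds for random valid tables and output is sorted", {
  set.seed(42)
  for (rep in 1:3) {
    n <- sample(5:40, 1)
    df <- data.frame(
      unit_id = sample(c("a", "b", "c"), n, replace = TRUE),
      trial_id = sample(c("t1", "t2"), n, replace = TRUE),
      event_type = sample(c("simple", "complex"), n, replace = TRUE),
      time_s = round(runif(n, 0, 5), 6))
    df <- df[!duplicated(df[c("unit_id", "trial_id", "event_type",
                              "time_s")]), ]
    shuffled <- df[sample(nrow(df)), ]
    ev <- spike_events(shuffled)
    # sorted by unit, trial, time
    expect_false(is.unsorted(order(ev$unit_id, ev$trial_id, ev$time_s)))
    f <- withr::local_tempfile(fileext = ".tsv")
    write_events(ev, f)
    expect_equal(as.data.frame(read_events(f)), as.data.frame(ev))
  }
  # protocol round trip
  pr <- toy_protocol()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_protocol(pr, f)
  expect_equal(as.data.frame(read_protocol(f)), as.data.frame(pr))
})

test_that("alignment re-references to light onset and guards idempotence", {
  ev <- spike_events(data.frame(unit_id = "u1", trial_id = c("t1", "t1"),
                                event_type = "simple",
                                time_s = c(1.0, 1.2)))
  pr <- toy_protocol()
  al <- align_to_light(ev, pr)
  expect_equal(al$time_s, c(0, 0.2))
  # intervals preserved exactly
  expect_equal(diff(al$time_s), diff(ev$time_s))
  expect_error(align_to_light(al, pr), "already aligned")
  stranger <- spike_events(data.frame(unit_id = "u1", trial_id = "t9",
                                      event_type = "simple", time_s = 1))
  expect_error(align_to_light(stranger, pr), "t9")
})
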
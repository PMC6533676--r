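# Trip segmentation, centered durations and QC filters.

nest <- c(0, 0)

# A hand-built track: colony -> excursion -> colony, at given distances.
make_track <- function(dists, dt = 300, t0 = 0) {
  data.frame(bird_id = "b1", t = t0 + seq_along(dists) * dt,
             x = dists, y = 0, has_acc = TRUE)
}

test_that("thinning keeps the first fix of each target bin", {
  fx <- data.frame(t = seq(0, 3000, by = 60), x = 0, y = 0)
  thin <- resample_track(fx, 300)
  expect_equal(thin$t, seq(0, 3000, by = 300))   # every 5th fix
  # already at target: identity
  fx300 <- data.frame(t = seq(0, 3000, by = 300), x = 0, y = 0)
  expect_equal(resample_track(fx300, 300), fx300)
  # mixed stream: no two retained fixes closer than the target
  set.seed(3)
  tmix <- cumsum(sample(c(60, 300), 200, replace = TRUE))
  thin <- resample_track(data.frame(t = tmix, x = 0, y = 0), 300)
  expect_true(all(diff(thin$t) >= 300 - 1))
  # empty input passes through
  expect_equal(nrow(resample_track(fx[0, ], 300)), 0)
})

test_that("centered durations average backward and forward intervals", {
  cd <- compute_centered_durations(c(0, 300, 600, 900, 1200))
  expect_equal(cd, c(150, 300, 300, 300, 150))
  # intervals 300 then 600: middle fix gets their mean
  expect_equal(compute_centered_durations(c(0, 300, 900))[2], 450)
  expect_error(compute_centered_durations(1000), "at least 2")
  expect_error(compute_centered_durations(c(0, 0, 300)), "strictly increasing")
})

test_that("centered durations telescope to the elapsed time", {
  set.seed(8)
  for (i in 1:50) {
    t <- cumsum(c(0, runif(sample(2:40, 1), 1, 1200)))
    expect_equal(sum(compute_centered_durations(t)), t[length(t)] - t[1])
  }
})

test_that("a track never leaving the colony yields no trips", {
  fx <- make_track(runif(20, 0, 99))
  out <- segment_trips(fx, nest)
  expect_equal(nrow(out$trips), 0)
})

test_that("a single excursion yields one trip bounded by colony fixes", {
  fx <- make_track(c(50, 30, 500, 2000, 2500, 800, 40, 20))
  out <- segment_trips(fx, nest)
  expect_equal(nrow(out$trips), 1)
  expect_true(out$trips$kept)
  # bounds: last colony fix before and first colony fix after
  tf <- out$fixes
  expect_equal(tf$t[1], fx$t[2])
  expect_equal(tf$t[nrow(tf)], fx$t[7])
  expect_equal(out$trips$duration_h, (fx$t[7] - fx$t[2]) / 3600)
  expect_equal(sum(tf$centered_dur_s), fx$t[7] - fx$t[2])
})

test_that("two excursions separated by a nest visit yield two trips", {
  fx <- make_track(c(10, 400, 900, 20, 30, 1500, 600, 5))
  out <- segment_trips(fx, nest)
  expect_equal(nrow(out$trips), 2)
  expect_true(all(out$trips$kept))
  # the shared colony visit closes trip 1 and opens trip 2
  expect_equal(out$trips$end_t[1], fx$t[4])
  expect_equal(out$trips$start_t[2], fx$t[5])
})

test_that("an excursion truncated by data end is emitted but flagged", {
  fx <- make_track(c(10, 20, 500, 1500, 2000))
  out <- segment_trips(fx, nest)
  expect_equal(nrow(out$trips), 1)
  expect_false(out$trips$kept)
  expect_equal(out$trips$reason, "unclosed")
})

test_that("segmentation is idempotent on a trip's own fixes", {
  fx <- make_track(c(50, 500, 2000, 800, 40))
  out <- segment_trips(fx, nest)
  again <- segment_trips(out$fixes[, c("bird_id", "t", "x", "y", "has_acc")],
                         nest)
  expect_equal(nrow(again$trips), 1)
  expect_equal(again$trips$start_t, out$trips$start_t)
  expect_equal(again$trips$end_t, out$trips$end_t)
})

test_that("the exact 100 m boundary is not an excursion", {
  fx <- make_track(c(10, 100, 100, 10))   # never strictly beyond 100 m
  expect_equal(nrow(segment_trips(fx, nest)$trips), 0)
  fx2 <- make_track(c(10, 100.1, 10))
  expect_equal(nrow(segment_trips(fx2, nest)$trips), 1)
})

test_that("missing nest coordinates are an error", {
  fx <- make_track(c(10, 400, 10))
  expect_error(segment_trips(fx, NULL), "nest")
  expect_error(segment_trips(fx, c(1, NA)), "nest")
})

test_that("gap filter drops trips with away gaps over 20 min, strictly", {
  base <- data.frame(bird_id = "b1",
                     t = c(0, 300, 600, 2100, 2400, 2700),
                     x = c(10, 400, 800, 900, 500, 20), y = 0,
                     has_acc = TRUE)
  # 600 -> 2100 is a 25-min away gap
  out <- filter_trips(segment_trips(base, nest))
  expect_false(out$trips$kept)
  expect_match(out$trips$reason, "gap_exceeded")
  # exactly 20 min is kept
  base20 <- base
  base20$t <- c(0, 300, 600, 1800, 2100, 2400)
  out20 <- filter_trips(segment_trips(base20, nest))
  expect_true(out20$trips$kept)
})

test_that("gaps at the colony between trips do not drop trips", {
  fx <- data.frame(bird_id = "b1",
                   t = c(0, 300, 600, 900, 6000, 6300, 6600, 6900),
                   x = c(10, 500, 900, 20, 10, 700, 1100, 30), y = 0,
                   has_acc = TRUE)
  out <- filter_trips(segment_trips(fx, nest))
  expect_equal(nrow(out$trips), 2)
  expect_true(all(out$trips$kept))   # the 85-min gap is colony residence
})

test_that("acceleration coverage filter drops below 80%, inclusive keep at 80%", {
  fx <- make_track(c(10, 400, 900, 1200, 800, 600, 450, 700, 300, 20))
  fx$has_acc <- c(rep(TRUE, 7), FALSE, FALSE, FALSE)   # 7/10 = 70%
  out <- filter_trips(segment_trips(fx, nest))
  expect_false(out$trips$kept)
  expect_match(out$trips$reason, "low_acc_coverage")
  fx$has_acc <- c(rep(TRUE, 8), FALSE, FALSE)          # exactly 80%
  out80 <- filter_trips(segment_trips(fx, nest))
  expect_true(out80$trips$kept)
})

test_that("kept-trip count matches the generator's intent when gap_prob = 0", {
  cfg <- fixture_config()
  ls <- fixture_landscape()
  sim <- simulate_bird_days(cfg, n_birds = 2, n_days = 2, landscape = ls,
                            bursts = FALSE)
  for (b in unique(sim$fixes$bird_id)) {
    out <- filter_trips(segment_trips(sim$fixes[sim$fixes$bird_id == b, ],
                                      ls$nest))
    intended <- sum(sim$truth_trips$bird_id == b)
    expect_equal(sum(out$trips$kept), intended)
  }
})
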
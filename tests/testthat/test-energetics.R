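# Allometric metabolic model and per-trip energy.

test_that("basal metabolic rate follows the mass allometry", {
  expect_equal(bmr(1), 2.3)                       # mass^0.774 = 1
  expect_equal(bmr(1000), 2.3 * exp(0.774 * log(1000)), tolerance = 1e-12)
  expect_equal(bmr(1000) / 24, 20.1148, tolerance = 1e-4)
  expect_error(bmr(0), "positive")
  expect_error(bmr(-5), "positive")
})

test_that("a ~969 g bird has the study-mean hourly BMR of 19.64 kJ/h", {
  # independent inversion of the allometry by root finding
  mass <- uniroot(function(m) bmr(m) / 24 - 19.64,
                  c(500, 1500), tol = 1e-10)$root
  expect_equal(mass, 969, tolerance = 0.001)
  expect_equal(bmr(969.3) / 24, 19.64, tolerance = 1e-3)
})

test_that("resting metabolic rate is 1.7 x BMR", {
  expect_equal(rmr_h(19.64), 33.39, tolerance = 1e-3)
  expect_equal(rmr_h(0), 0)
  expect_equal(rmr_h(bmr(1000) / 24), 34.195, tolerance = 1e-3)
  expect_error(rmr_h(-1))
})

test_that("treadmill locomotion formula evaluates and brackets 2 x BMR", {
  # direct arithmetic on the printed formula, W = 1 kg, v = 0.4 m/s
  expect_equal(bautista_terrestrial(1, 0.4), (5.6 + 11.4 * 0.4) * 86.4)
  expect_equal(bautista_terrestrial(1, 0.4), 877.824)
  # postural component only at v = 0
  expect_equal(bautista_terrestrial(2, 0), 5.6 * 2^0.246 * 86.4)
  # the 2 x BMR simplification agrees within 15% at walking speed
  b_h <- bautista_terrestrial(1, 0.4) / 24
  two_bmr_h <- 2 * bmr(1000) / 24
  expect_lt(abs(b_h - two_bmr_h) / two_bmr_h, 0.15)
})

test_that("behavior rates use the documented multipliers", {
  rates <- behavior_rates(energetic_profile(1000))
  expect_equal(unname(rates["inactive"]), 34.195, tolerance = 1e-3)
  expect_equal(unname(rates["terrestrial_movement"]), 40.230, tolerance = 1e-3)
  expect_equal(unname(rates["soaring_flight"]), 68.390, tolerance = 1e-3)
  expect_equal(unname(rates["flapping_flight"]), 239.367, tolerance = 1e-3)
  # ratios are mass-free
  for (m in c(600, 969, 1400)) {
    r <- behavior_rates(energetic_profile(m))
    expect_equal(unname(r["flapping_flight"] / r["inactive"]), 7)
    expect_equal(unname(r["soaring_flight"] / r["terrestrial_movement"]), 1.7)
  }
})

test_that("rate ordering flap > soar > terrestrial > inactive holds over masses", {
  for (m in seq(600, 1400, by = 50)) {
    r <- behavior_rates(energetic_profile(m))
    expect_true(r[["flapping_flight"]] > r[["soaring_flight"]])
    expect_true(r[["soaring_flight"]] > r[["terrestrial_movement"]])
    expect_true(r[["terrestrial_movement"]] > r[["inactive"]])
  }
})

test_that("trip energy sums class durations times class rates", {
  p <- energetic_profile(1000)
  te <- trip_energy(c(3600, 3600), c("flapping_flight", "inactive"), p)
  expect_equal(te$total_kJ, unname(p$rates["flapping_flight"] +
                                     p$rates["inactive"]))
  expect_equal(te$total_kJ, 273.56, tolerance = 1e-2)
  expect_equal(te$rate_kJ_h, 136.78, tolerance = 1e-2)
  expect_equal(te$flapping_h, 1)

  all_inactive <- trip_energy(rep(1800, 4), rep("inactive", 4), p)
  expect_equal(all_inactive$rate_kJ_h, p$rmr_h)

  expect_error(trip_energy(numeric(0), character(0), p), "zero-duration")
  expect_error(trip_energy(c(3600), c("hovering"), p), "unknown")
})

test_that("trip energy is homogeneous and rates are convex combinations", {
  p <- energetic_profile(969)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    dur <- runif(n, 100, 900)
    cls <- sample(aggregate_classes(), n, replace = TRUE)
    te <- trip_energy(dur, cls, p)
    te2 <- trip_energy(2 * dur, cls, p)
    expect_equal(te2$total_kJ, 2 * te$total_kJ)
    expect_equal(te2$rate_kJ_h, te$rate_kJ_h)
    expect_gte(te$rate_kJ_h, min(p$rates) - 1e-9)
    expect_lte(te$rate_kJ_h, max(p$rates) + 1e-9)
  }
})

test_that("unannotated time is handled per policy and reported", {
  p <- energetic_profile(1000)
  dur <- c(1800, 1800, 1800)
  cls <- c("flapping_flight", "inactive", "unannotated")
  redis <- trip_energy(dur, cls, p, "redistribute")
  rmr_p <- trip_energy(dur, cls, p, "rmr")
  # redistribution scales annotated time up to the full duration
  expect_equal(redis$total_kJ,
               1.5 * 0.5 * unname(p$rates["flapping_flight"] +
                                    p$rates["inactive"]))
  # RMR policy prices the gap at resting rate
  expect_equal(rmr_p$total_kJ,
               0.5 * unname(p$rates["flapping_flight"] + p$rates["inactive"]) +
                 0.5 * p$rmr_h)
  expect_gt(redis$total_kJ, rmr_p$total_kJ)  # here flapping > RMR share
  expect_equal(redis$durations_h[["unannotated"]], 0.5)
  # NA classes count as unannotated
  na_cls <- trip_energy(dur, c("flapping_flight", "inactive", NA), p)
  expect_equal(na_cls$total_kJ, redis$total_kJ)
})

test_that("trip energy on true synthetic labels matches the generator oracle", {
  fx <- fixture_single_trip(seed = 9)
  sim <- fx$sim
  trips <- filter_trips(segment_trips(sim$fixes, fx$landscape$nest))
  expect_equal(nrow(trips$trips), 1)
  tf <- trips$fixes
  m <- match(paste(tf$bird_id, tf$t),
             paste(sim$truth_fixes$bird_id, sim$truth_fixes$t))
  te <- trip_energy(tf$centered_dur_s, sim$truth_fixes$class[m],
                    energetic_profile(fx$config$mass_g))
  expect_equal(te$total_kJ, sim$truth_trips$energy_kJ, tolerance = 1e-9)
  expect_equal(te$flapping_h, sim$truth_trips$flapping_h, tolerance = 1e-9)
})
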
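# The synthetic-data generator: determinism, construction invariants
# and ground-truth consistency.

test_that("landscape generation is deterministic and inside the extent", {
  a <- generate_landscape(seed = 7)
  b <- generate_landscape(seed = 7)
  expect_identical(a, b)
  ext <- a$extent
  for (nm in names(a$layers)) {
    for (p in a$layers[[nm]]) {
      expect_true(all(p[, 1] >= ext[1] & p[, 1] <= ext[3]))
      expect_true(all(p[, 2] >= ext[2] & p[, 2] <= ext[4]))
    }
  }
  # the behavior-conditional mudflat rule must be exercisable
  expect_gte(length(a$layers$mudflat), 1)
  expect_error(generate_landscape(1, extent = c(0, 0, 0, 100)), "degenerate")
})

test_that("trip simulation is deterministic under a fixed seed", {
  fx1 <- fixture_single_trip(seed = 3, bursts = TRUE)
  fx2 <- fixture_single_trip(seed = 3, bursts = TRUE)
  expect_identical(fx1$sim$fixes, fx2$sim$fixes)
  expect_identical(fx1$sim$bursts, fx2$sim$bursts)
  expect_identical(fx1$sim$truth_trips, fx2$sim$truth_trips)
})

test_that("simulated trips start and end at the nest with a real excursion", {
  fx <- fixture_single_trip(seed = 4)
  sim <- fx$sim
  nest <- fx$landscape$nest
  d <- sqrt((sim$fixes$x - nest[1])^2 + (sim$fixes$y - nest[2])^2)
  expect_lt(d[1], 100)
  expect_lt(d[nrow(sim$fixes)], 100)
  expect_gt(max(d), 100)
  # exactly one segmentable trip
  out <- filter_trips(segment_trips(sim$fixes, nest))
  expect_equal(sum(out$trips$kept), 1)
})

test_that("schedules without away-time or colony anchoring are rejected", {
  cfg <- fixture_config()
  colony_only <- data.frame(behavior = "sit", duration_s = 3600,
                            habitat = "colony")
  expect_error(simulate_trip(cfg, colony_only, fixture_landscape()),
               "zero away-time")
  no_nest <- data.frame(behavior = c("flap", "sit"),
                        duration_s = c(600, 600),
                        habitat = c("marine", "colony"))
  expect_error(simulate_trip(cfg, no_nest, fixture_landscape()),
               "start and end at the nest")
  bad_dur <- data.frame(behavior = "sit", duration_s = c(600, -1, 600),
                        habitat = c("colony", "marine", "colony"))
  expect_error(simulate_trip(cfg, bad_dur, fixture_landscape()), "> 0")
})

test_that("gap_prob = 0 gives full acceleration coverage, > 0 opens gaps", {
  fx <- fixture_single_trip(seed = 6, bursts = TRUE)
  expect_true(all(fx$sim$fixes$has_acc))
  expect_equal(nrow(fx$sim$bursts) / 3, nrow(fx$sim$fixes))
  cfg_gap <- sim_config(seed = 101, gap_prob = 0.4)
  ls <- fixture_landscape()
  sch <- withr::with_seed(8, make_trip_schedule(cfg_gap, ls, "terrestrial",
                                                away_h = 3))
  sim_full <- simulate_trip(sim_config(seed = 101), sch, ls, seed = 8)
  sim_gap <- simulate_trip(cfg_gap, sch, ls, seed = 8)
  expect_lt(nrow(sim_gap$fixes), nrow(sim_full$fixes))
})

test_that("flapping commute speeds match the configured mean", {
  fx <- fixture_single_trip(seed = 10, habitat = "marine", away_h = 3)
  sim <- fx$sim
  trips <- segment_trips(sim$fixes, fx$landscape$nest)
  kin <- derive_kinematics(trips$fixes)
  m <- match(paste(trips$fixes$bird_id, trips$fixes$t),
             paste(sim$truth_fixes$bird_id, sim$truth_fixes$t))
  com <- sim$truth_fixes$commuting[m]
  v <- kin$speed[com]
  v_cfg <- fx$config$behavior_speed_means[["flap"]]
  expect_lt(abs(mean(v) - v_cfg), 2 * max(sd(v), 0.05 * v_cfg))
})

test_that("ground-truth classes equal the fixed 11-to-4 map of fine labels", {
  fx <- fixture_single_trip(seed = 14)
  tf <- fx$sim$truth_fixes
  expect_identical(tf$class, aggregate_behavior(tf$behavior))
})

test_that("bird-days honor the strategy mix and are reproducible", {
  cfg <- fixture_config()
  ls <- fixture_landscape()
  sim <- simulate_bird_days(cfg, n_birds = 2, n_days = 2,
                            strategy_mix = c(intertidal = 1),
                            landscape = ls, bursts = FALSE)
  expect_true(all(sim$truth_trips$habitat == "intertidal"))
  sim2 <- simulate_bird_days(cfg, n_birds = 2, n_days = 2,
                             strategy_mix = c(intertidal = 1),
                             landscape = ls, bursts = FALSE)
  expect_identical(sim, sim2)
  expect_error(simulate_bird_days(cfg, 0, 1), ">= 1")
  expect_error(simulate_bird_days(cfg, 1, 1, strategy_mix = c(urban = 0)),
               "not all zero")
})

test_that("bird masses scatter around 969 g so hourly BMR is near 19.6", {
  cfg <- fixture_config()
  sim <- simulate_bird_days(cfg, n_birds = 12, n_days = 1,
                            landscape = fixture_landscape(), bursts = FALSE)
  bmr_h <- bmr(sim$birds$mass_g) / 24
  expect_lt(abs(mean(bmr_h) - 19.6), 1.5)
  expect_gt(min(sim$birds$mass_g), 600)
})

test_that("fixes and bursts round-trip through their CSV formats", {
  fx <- fixture_single_trip(seed = 15, bursts = TRUE)
  fp <- tempfile(fileext = ".csv")
  bp <- tempfile(fileext = ".csv")
  write_fixes_csv(fx$sim$fixes, fp)
  back <- read_fixes_csv(fp)
  expect_equal(back$t, fx$sim$fixes$t)
  expect_equal(back$x, fx$sim$fixes$x, tolerance = 1e-6)
  write_bursts_csv(fx$sim$bursts, bp)
  bb <- read_bursts_csv(bp)
  expect_equal(bb$s1, fx$sim$bursts$s1, tolerance = 1e-9)
  expect_equal(bb$axis, fx$sim$bursts$axis)
  unlink(c(fp, bp))
})

test_that("high and low flapping-fraction trips produce the planted rate gap", {
  cfg <- fixture_config()
  ls <- fixture_landscape()
  sim <- simulate_bird_days(cfg, n_birds = 8, n_days = 2, landscape = ls,
                            bursts = FALSE)
  res <- run_teb_pipeline(
    sim$fixes, landscape = ls,
    masses = sim$birds[, c("bird_id", "mass_g")],
    behaviors = data.frame(bird_id = sim$truth_fixes$bird_id,
                           t = sim$truth_fixes$t,
                           fine = sim$truth_fixes$behavior,
                           class = sim$truth_fixes$class),
    commuting = sim$truth_fixes[, c("bird_id", "t", "commuting")])
  m <- match(res$trip_id, sim$truth_trips$trip_id)
  # pipeline-estimated mean hourly rate per true habitat group vs the
  # ground-truth rates computed from the generator's own energies
  truth_rate <- sim$truth_trips$energy_kJ / sim$truth_trips$duration_h
  grp <- ifelse(sim$truth_trips$habitat %in% c("urban", "marine"),
                "high", "low")
  truth_ratio <- mean(truth_rate[grp == "high"]) /
    mean(truth_rate[grp == "low"])
  est_grp <- ifelse(sim$truth_trips$habitat[m] %in% c("urban", "marine"),
                    "high", "low")
  est_ratio <- mean(res$rate_kJ_h[est_grp == "high"]) /
    mean(res$rate_kJ_h[est_grp == "low"])
  expect_lt(abs(est_ratio - truth_ratio) / truth_ratio, 0.05)
})
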
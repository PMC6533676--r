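# Habitat assignment rules and trip categorization.

test_that("the rule order maps every membership x behavior x distance case", {
  ls <- grid_landscape()
  rules <- habitat_rules(ls)
  cases <- rbind(
    # x, y, class, fine, expected
    data.frame(x = 500, y = 500, class = "flapping_flight",
               fine = "flap", expected = "urban"),        # urban beats all
    data.frame(x = 500, y = 2500, class = "inactive",
               fine = "sit", expected = "terrestrial"),
    data.frame(x = 2250, y = 1500, class = "terrestrial_movement",
               fine = "look-for-food-moving", expected = "intertidal"),
    # sea point 30 m from the beach edge (x = 2500): buffer rule
    data.frame(x = 2530, y = 100, class = "inactive",
               fine = "float", expected = "intertidal"),
    # sea point 60 m from the beach: plain marine
    data.frame(x = 2560, y = 100, class = "inactive",
               fine = "float", expected = "marine"),
    # sea point 30 m from the breakwater at (5000, 1500)
    data.frame(x = 4970, y = 1500, class = "soaring_flight",
               fine = "soar", expected = "intertidal"),
    # on the breakwater itself
    data.frame(x = 5025, y = 1500, class = "inactive",
               fine = "stand", expected = "intertidal"),
    # mudflat: flying or floating -> marine, else foraging -> intertidal
    data.frame(x = 7500, y = 1500, class = "flapping_flight",
               fine = "flap", expected = "marine"),
    data.frame(x = 7500, y = 1500, class = "soaring_flight",
               fine = "soar", expected = "marine"),
    data.frame(x = 7500, y = 1500, class = "inactive",
               fine = "float", expected = "marine"),
    data.frame(x = 7500, y = 1500, class = "terrestrial_movement",
               fine = "terrestrial-locomotion", expected = "intertidal"),
    data.frame(x = 7500, y = 1500, class = "inactive",
               fine = "sit", expected = "intertidal"),
    # unannotated class on a mudflat counts as foraging
    data.frame(x = 7500, y = 1500, class = "unannotated",
               fine = NA, expected = "intertidal"),
    # tidal sea point 30 m from the mudflat edge (x = 8000)
    data.frame(x = 8030, y = 1500, class = "inactive",
               fine = "float", expected = "intertidal"),
    data.frame(x = 11000, y = 1500, class = "flapping_flight",
               fine = "flap", expected = "marine"),
    # outside every polygon
    data.frame(x = 1500, y = 1500, class = "inactive",
               fine = "sit", expected = "unassigned")
  )
  got <- assign_habitat(cases, rules)
  expect_equal(got, cases$expected)
})

test_that("every class is assigned deterministically across the grid", {
  ls <- grid_landscape()
  rules <- habitat_rules(ls)
  pts <- expand.grid(x = seq(100, 11900, by = 590),
                     y = seq(100, 2900, by = 560))
  for (cls in c(aggregate_classes(), "unannotated")) {
    df <- data.frame(pts, class = cls,
                     fine = if (cls == "inactive") "sit" else NA)
    h1 <- assign_habitat(df, rules)
    h2 <- assign_habitat(df, rules)
    expect_identical(h1, h2)
    expect_true(all(h1 %in% c("urban", "marine", "intertidal",
                              "terrestrial", "unassigned")))
  }
})

test_that("commuting fixes are skipped and bad coordinates rejected", {
  ls <- grid_landscape()
  rules <- habitat_rules(ls)
  df <- data.frame(x = c(500, 500), y = c(500, 500),
                   class = "inactive", fine = "sit",
                   commuting = c(TRUE, FALSE))
  h <- assign_habitat(df, rules)
  expect_true(is.na(h[1]))
  expect_equal(h[2], "urban")
  expect_error(assign_habitat(data.frame(x = NA, y = 1, class = "inactive"),
                              rules), "non-finite")
})

test_that("shrinking the buffer to zero never increases intertidal fraction", {
  ls <- grid_landscape()
  set.seed(31)
  pts <- data.frame(x = runif(400, 2500, 6000), y = runif(400, 0, 3000),
                    class = "inactive", fine = "float")
  frac_at <- function(buffer) {
    h <- assign_habitat(pts, habitat_rules(ls, intertidal_buffer = buffer))
    mean(h == "intertidal")
  }
  f0 <- frac_at(0)
  f50 <- frac_at(50)
  f500 <- frac_at(500)
  expect_lte(f0, f50)
  expect_lte(f50, f500)
})

test_that("trip categorization follows the 50% threshold with precedence ties", {
  rules <- habitat_rules(grid_landscape())
  s <- summarize_trip_habitat(c(rep("intertidal", 6), rep("marine", 4)), rules)
  expect_equal(s$category, "intertidal")
  expect_equal(unname(s$fractions["intertidal"]), 0.6)
  # nothing reaches 50%: mixed
  s2 <- summarize_trip_habitat(c(rep("urban", 4), rep("marine", 3),
                                 rep("intertidal", 2), "terrestrial"), rules)
  expect_equal(s2$category, "mixed")
  # exact 50/50 tie: marine beats intertidal by precedence, tie recorded
  s3 <- summarize_trip_habitat(c(rep("marine", 5), rep("intertidal", 5)), rules)
  expect_equal(s3$category, "marine")
  expect_true(s3$tie)
  # commuting (NA) and unassigned are excluded from the denominator
  s4 <- summarize_trip_habitat(c(NA, NA, "unassigned", rep("urban", 3)), rules)
  expect_equal(s4$category, "urban")
  expect_equal(s4$n_noncommuting, 4)
  expect_equal(s4$n_unassigned, 1)
  expect_equal(unname(s4$fractions["urban"]), 1)
  # no usable fixes: flagged, category NA
  s5 <- summarize_trip_habitat(c(NA, "unassigned"), rules)
  expect_true(s5$flagged)
  expect_true(is.na(s5$category))
})

test_that("trip categories are recovered on a 2-bird 2-day simulation", {
  cfg <- fixture_config()
  ls <- fixture_landscape()
  sim <- simulate_bird_days(cfg, n_birds = 2, n_days = 2, landscape = ls,
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
  expect_gte(mean(res$category == sim$truth_trips$habitat[m]), 0.95)
})

test_that("landscape GeoJSON round-trips and habitat rules survive it", {
  ls <- fixture_landscape()
  path <- tempfile(fileext = ".geojson")
  write_landscape_geojson(ls, path)
  back <- read_landscape_geojson(path)
  expect_equal(back$nest, ls$nest)
  expect_setequal(names(back$layers), names(ls$layers))
  for (nm in names(ls$layers)) {
    expect_equal(back$layers[[nm]], lapply(ls$layers[[nm]], unname))
  }
  set.seed(13)
  pts <- data.frame(x = runif(100, ls$extent[1], ls$extent[3]),
                    y = runif(100, ls$extent[2], ls$extent[4]),
                    class = "inactive", fine = "sit")
  expect_identical(assign_habitat(pts, habitat_rules(ls)),
                   assign_habitat(pts, habitat_rules(back)))
  unlink(path)
})
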
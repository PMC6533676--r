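# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture_landscape <- function() {
  if (is.null(.fixtures$landscape)) {
    .fixtures$landscape <- generate_landscape(seed = 101)
  }
  .fixtures$landscape
}

fixture_config <- function() sim_config(seed = 101)

# Labeled burst features: `n_per` bursts per fine behavior.
make_labeled_features <- function(n_per = 40, seed = 202,
                                  config = fixture_config()) {
  withr::with_seed(seed, {
    rows <- list()
    labs <- character()
    for (b in fine_behaviors()) {
      for (i in seq_len(n_per)) {
        rows[[length(rows) + 1]] <- extract_features(
          simulate_acc_burst(b, config))
        labs <- c(labs, b)
      }
    }
    df <- do.call(rbind, rows)
    df$bird_id <- "train"
    df$t <- seq_len(nrow(df))
    list(features = df, labels = labs)
  })
}

fixture_classifier <- function() {
  if (is.null(.fixtures$classifier)) {
    lf <- make_labeled_features()
    .fixtures$classifier <- train_classifier(lf$features, lf$labels,
                                             seed = 303)
  }
  .fixtures$classifier
}

# A single-trip simulation with one intertidal foraging bout.
fixture_single_trip <- function(seed = 5, habitat = "intertidal",
                                away_h = 2, bursts = FALSE) {
  cfg <- fixture_config()
  ls <- fixture_landscape()
  sch <- withr::with_seed(seed, make_trip_schedule(cfg, ls, habitat,
                                                   away_h = away_h))
  sim <- simulate_trip(cfg, sch, ls, seed = seed, bursts = bursts)
  list(config = cfg, landscape = ls, schedule = sch, sim = sim)
}

# A small grid landscape with hand-placed rectangles for rule tests.
# Layout (meters):
#   urban        [0, 1000]  x [0, 1000]
#   agri_natural [0, 1000]  x [2000, 3000]
#   beach        [2000, 2500] x [0, 3000]
#   north_sea    [2500, 6000] x [0, 3000]   (touches the beach)
#   mudflat      [7000, 8000] x [0, 3000]
#   wadden_sea   [8000, 12000] x [0, 3000]
grid_landscape <- function() {
  rp <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  structure(list(
    extent = c(0, 0, 12000, 3000),
    nest = c(1500, 1500),
    layers = list(
      urban = list(rp(0, 0, 1000, 1000)),
      agri_natural = list(rp(0, 2000, 1000, 3000)),
      beach = list(rp(2000, 0, 2500, 3000)),
      north_sea = list(rp(2500, 0, 6000, 3000)),
      mudflat = list(rp(7000, 0, 8000, 3000)),
      wadden_sea = list(rp(8000, 0, 12000, 3000)),
      breakwater = list(rp(5000, 1400, 5050, 1600))
    )
  ), class = "gull_landscape")
}

expect_rate_close <- function(x, y, tol = 1e-8) {
  expect_true(all(abs(x - y) < tol))
}
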
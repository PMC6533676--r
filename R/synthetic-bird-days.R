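## Full synthetic gull-days: several birds tracked over several days,
## each day alternating colony residence and foraging trips, with a
## bird-level habitat strategy bias.

#' Simulate tracked gull-days for several birds
#'
#' Each bird gets a body mass (normal around `config$mass_g`) and a
#' preferred foraging habitat sampled from `strategy_mix`; each day it
#' makes 1-3 trips (85% to the preferred habitat), with away-durations
#' drawn lognormally around ~2.5 h, framed by colony residence. Trips
#' follow [trip_composition()]: flight-heavy to urban/marine, ground-
#' heavy to intertidal/terrestrial.
#'
#' @param config A [sim_config()].
#' @param n_birds,n_days Positive integers.
#' @param strategy_mix Named non-negative weights over habitats
#'   (urban/marine/intertidal/terrestrial); default equal weights.
#' @param landscape Optional `gull_landscape` (default from
#'   `config$seed`).
#' @param preference Probability that a trip targets the bird's
#'   preferred habitat (default 0.6); the remainder is drawn from
#'   `strategy_mix`. A moderate preference keeps individual habitat
#'   specialization while still crossing birds with habitats, so
#'   bird-level traits (body mass) are not confounded with habitat
#'   category.
#' @param bursts Generate acceleration bursts (default TRUE).
#' @return List with `fixes`, `bursts`, `truth_fixes`, `truth_trips`
#'   (as in [simulate_trip()], concatenated over birds), `birds`
#'   (`bird_id`, `mass_g`, `preferred`), `landscape`, `config`.
#' @export
simulate_bird_days <- function(config, n_birds, n_days,
                               strategy_mix = c(urban = 1, marine = 1,
                                                intertidal = 1,
                                                terrestrial = 1),
                               landscape = NULL, preference = 0.6,
                               bursts = TRUE) {
  if (n_birds < 1 || n_days < 1) stop("n_birds and n_days must be >= 1",
                                      call. = FALSE)
  if (any(strategy_mix < 0) || sum(strategy_mix) == 0) {
    stop("strategy_mix weights must be >= 0 and not all zero", call. = FALSE)
  }
  if (is.null(landscape)) landscape <- generate_landscape(config$seed)
  with_seed(config$seed, {
    out <- list(fixes = list(), bursts = list(),
                truth_fixes = list(), truth_trips = list())
    birds <- list()
    for (b in seq_len(n_birds)) {
      bird_id <- sprintf("bird%02d", b)
      mass <- max(600, rnorm(1, config$mass_g, config$mass_sd))
      preferred <- sample(names(strategy_mix), 1,
                          prob = strategy_mix / sum(strategy_mix))
      birds[[b]] <- data.frame(bird_id = bird_id, mass_g = mass,
                               preferred = preferred)
      schedule <- build_day_schedules(config, landscape, strategy_mix,
                                      preferred, n_days, preference)
      sim <- simulate_trip(config, schedule, landscape, seed = NULL,
                           bird_id = bird_id, t0 = 0, mass_g = mass,
                           bursts = bursts)
      out$fixes[[b]] <- sim$fixes
      out$bursts[[b]] <- sim$bursts
      out$truth_fixes[[b]] <- sim$truth_fixes
      out$truth_trips[[b]] <- sim$truth_trips
    }
    list(fixes = do.call(rbind, out$fixes),
         bursts = do.call(rbind, out$bursts),
         truth_fixes = do.call(rbind, out$truth_fixes),
         truth_trips = do.call(rbind, out$truth_trips),
         birds = do.call(rbind, birds),
         landscape = landscape, config = config)
  })
}

## One multi-day schedule: colony legs interleaved with trip schedules.
build_day_schedules <- function(config, landscape, strategy_mix,
                                preferred, n_days, preference = 0.6) {
  parts <- list()
  for (d in seq_len(n_days)) {
    n_trips <- sample(1:3, 1, prob = c(0.3, 0.5, 0.2))
    for (k in seq_len(n_trips)) {
      habitat <- if (runif(1) < preference) preferred else
        sample(names(strategy_mix), 1, prob = strategy_mix / sum(strategy_mix))
      away_h <- min(6, max(1, rlnorm(1, log(2.2), 0.4)))
      parts[[length(parts) + 1]] <- make_trip_schedule(
        config, landscape, habitat, away_h = away_h,
        colony_before_s = runif(1, 1800, 5400),
        colony_after_s = runif(1, 1800, 5400)
      )
    }
  }
  ## merge consecutive schedules; interior colony legs remain between trips
  do.call(rbind, parts)
}

#' Write / read the generator's CSV tables
#'
#' `write_fixes_csv()` writes `bird_id`, ISO-8601 UTC `timestamp`
#' (from the numeric `t` seconds treated as an epoch offset), `x`, `y`,
#' `has_acc`; `read_fixes_csv()` restores the numeric `t` column.
#' `write_bursts_csv()` / `read_bursts_csv()` round-trip the long burst
#' table.
#'
#' @param fixes,bursts Tables as produced by [simulate_trip()].
#' @param path File path.
#' @return The path (writers) or the table (readers).
#' @export
write_fixes_csv <- function(fixes, path) {
  out <- data.frame(
    bird_id = fixes$bird_id,
    timestamp = format(as.POSIXct(fixes$t, origin = "2016-06-01",
                                  tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ"),
    x = fixes$x, y = fixes$y, has_acc = fixes$has_acc
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes_csv
#' @export
read_fixes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$t <- as.numeric(as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                                tz = "UTC")) -
    as.numeric(as.POSIXct("2016-06-01", tz = "UTC"))
  df[, c("bird_id", "t", "x", "y", "has_acc")]
}

#' @rdname write_fixes_csv
#' @export
write_bursts_csv <- function(bursts, path) {
  write.csv(bursts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes_csv
#' @export
read_bursts_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
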
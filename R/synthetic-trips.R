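## Synthetic gull tracks with ground truth.
##
## Trips are driven by a schedule of behavioral legs. Commuting legs fly
## straight (small heading noise) between the nest and a foraging
## anchor; foraging legs wander around the anchor inside the target
## habitat polygon; colony legs jitter within ~30 m of the nest.
## Every fix carries its true fine behavior, aggregate class, commuting
## flag and habitat; per-trip true energy is computed inside the
## generator with its own arithmetic (not via trip_energy()), so it can
## serve as an independent oracle for the energetics stage.

## map trip habitat -> candidate landscape layers for the foraging anchor
anchor_layers <- list(
  urban = "urban",
  marine = c("north_sea", "wadden_sea"),
  intertidal = c("beach", "mudflat"),
  terrestrial = "agri_natural"
)

## Sample a foraging anchor for a habitat. Marine anchors keep well
## clear of intertidal features so the 50 m buffer rule cannot flip
## their fixes; anchors sit inside their polygon with a small margin.
sample_anchor <- function(landscape, habitat, margin = 300) {
  layers <- anchor_layers[[habitat]]
  if (is.null(layers)) stop("no anchor layers for habitat: ", habitat,
                            call. = FALSE)
  layer <- if (length(layers) == 1) layers else sample(layers, 1)
  polys <- landscape$layers[[layer]]
  poly <- polys[[sample.int(length(polys), 1)]]
  shrunk <- shrink_rect(poly, margin)
  reject <- if (habitat == "marine") {
    function(px, py) {
      dist_to_layers(landscape, intertidal_feature_layers, px, py) < 2500
    }
  } else {
    NULL
  }
  list(xy = sample_point_in_poly(shrunk, reject), layer = layer, poly = poly)
}

shrink_rect <- function(poly, margin) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  m <- min(margin, diff(xr) / 4, diff(yr) / 4)
  rect_poly(xr[1] + m, yr[1] + m, xr[2] - m, yr[2] - m)
}

## Pick a fine label for a class-level leg in a habitat.
fine_for_class <- function(class, habitat) {
  switch(class,
    inactive = if (identical(habitat, "marine")) "float" else
      sample(c("sit", "stand"), 1, prob = c(0.6, 0.4)),
    terrestrial_movement = sample(
      c("look-for-food-moving", "look-for-food-standing",
        "terrestrial-locomotion", "handle-prey"), 1,
      prob = c(0.4, 0.2, 0.3, 0.1)),
    soaring_flight = sample(c("soar", "manoeuvre"), 1, prob = c(0.8, 0.2)),
    flapping_flight = sample(c("flap", "extreme-flap"), 1,
                             prob = c(0.85, 0.15)),
    stop("unknown class: ", class, call. = FALSE)
  )
}

#' Behavior-time composition of a trip by habitat group
#'
#' Fraction of away-time per behavior class. Trips to the high-caloric
#' habitats (urban, marine) are flight-heavy (flapping fraction 0.30);
#' trips to the low-caloric habitats (intertidal, terrestrial) spend
#' more time foraging on the ground (flapping fraction 0.17).
#'
#' @param habitat Trip habitat.
#' @return Named numeric fractions over the four classes (sum 1).
#' @export
trip_composition <- function(habitat) {
  if (habitat %in% c("urban", "marine")) {
    c(flapping_flight = 0.30, soaring_flight = 0.05,
      terrestrial_movement = 0.10, inactive = 0.55)
  } else {
    c(flapping_flight = 0.17, soaring_flight = 0.05,
      terrestrial_movement = 0.30, inactive = 0.48)
  }
}

#' Build a trip schedule for a habitat
#'
#' Samples a foraging anchor in the habitat, sizes the out/return
#' commutes from the anchor distance and the flapping speed, and fills
#' the remaining away-time with foraging legs following the habitat's
#' behavior composition (see [trip_composition()]). The away duration is
#' raised if needed so the commutes fit inside the flapping budget.
#'
#' @param config A [sim_config()].
#' @param landscape A `gull_landscape`.
#' @param habitat Trip habitat (urban/marine/intertidal/terrestrial).
#' @param away_h Target hours away from the colony.
#' @param composition Class-time fractions (default
#'   `trip_composition(habitat)`).
#' @param colony_before_s,colony_after_s Colony residence (s) framing
#'   the trip (defaults 1800).
#' @return Schedule data frame: `behavior`, `duration_s`, `habitat`,
#'   `commute`, `ax`, `ay` (anchor).
#' @export
make_trip_schedule <- function(config, landscape, habitat, away_h = 2.5,
                               composition = trip_composition(habitat),
                               colony_before_s = 1800,
                               colony_after_s = 1800) {
  nest <- config$nest_xy %||% landscape$nest
  anchor <- sample_anchor(landscape, habitat)
  d <- sqrt(sum((anchor$xy - nest)^2))
  v_flap <- config$behavior_speed_means[["flap"]]
  ## 10% + one-fix margin so the bird reliably arrives before the leg
  ## ends despite speed noise and fix-count rounding
  commute_s <- d / v_flap * 1.1 + config$fix_interval_away
  away_s <- away_h * 3600
  flap_frac <- composition[["flapping_flight"]]
  min_away <- 2 * commute_s / flap_frac * 1.02
  away_s <- max(away_s, min_away)
  budget <- composition * away_s
  budget[["flapping_flight"]] <- budget[["flapping_flight"]] - 2 * commute_s

  legs <- list(data.frame(behavior = "sit", duration_s = colony_before_s,
                          habitat = "colony", commute = FALSE,
                          ax = NA_real_, ay = NA_real_))
  legs <- c(legs, list(data.frame(behavior = "flap", duration_s = commute_s,
                                  habitat = habitat, commute = TRUE,
                                  ax = anchor$xy[1], ay = anchor$xy[2])))
  ## foraging bout: split each class budget into ~15-min legs
  bout <- list()
  for (cls in names(budget)) {
    remaining <- budget[[cls]]
    while (remaining > 1) {
      leg_s <- min(remaining, runif(1, 600, 1200))
      bout[[length(bout) + 1]] <- data.frame(
        behavior = fine_for_class(cls, habitat), duration_s = leg_s,
        habitat = habitat, commute = FALSE,
        ax = anchor$xy[1], ay = anchor$xy[2])
      remaining <- remaining - leg_s
    }
  }
  bout <- bout[sample.int(length(bout))]
  legs <- c(legs, bout)
  legs <- c(legs, list(data.frame(behavior = "flap", duration_s = commute_s,
                                  habitat = habitat, commute = TRUE,
                                  ax = NA_real_, ay = NA_real_)))  # to nest
  legs <- c(legs, list(data.frame(behavior = "sit", duration_s = colony_after_s,
                                  habitat = "colony", commute = FALSE,
                                  ax = NA_real_, ay = NA_real_)))
  do.call(rbind, legs)
}

#' Simulate one foraging trip
#'
#' Runs the track engine over a schedule of behavioral legs. The
#' schedule must start and end with a colony leg and contain at least
#' one away leg.
#'
#' @param config A [sim_config()].
#' @param schedule Schedule data frame as from [make_trip_schedule()]
#'   (columns `behavior`, `duration_s`, `habitat`, `commute`, `ax`,
#'   `ay`; commute legs with NA anchor fly to the nest).
#' @param landscape A `gull_landscape` (default: generated from the
#'   config seed).
#' @param seed Integer seed, or NULL to draw from the current RNG
#'   stream.
#' @param bird_id Bird identifier.
#' @param t0 Start timestamp (s).
#' @param mass_g Body mass for the true-energy oracle (default
#'   `config$mass_g`).
#' @param bursts Generate acceleration bursts (default TRUE); FALSE
#'   skips them (fixes and truth only), which is much faster when the
#'   downstream analysis uses the true labels.
#' @return List with `fixes` (`bird_id`, `t`, `x`, `y`, `has_acc`),
#'   `bursts` (long table with `s1..sN` sample columns), `truth_fixes`
#'   (per-fix `behavior`, `class`, `commuting`, `habitat`, `trip_id`)
#'   and `truth_trips` (per-trip habitat, duration, flapping hours and
#'   independently computed energy).
#' @export
simulate_trip <- function(config, schedule, landscape = NULL, seed = NULL,
                          bird_id = "bird01", t0 = 0,
                          mass_g = config$mass_g, bursts = TRUE) {
  if (is.null(landscape)) landscape <- generate_landscape(config$seed)
  check_schedule(schedule)
  run <- function() {
    sim <- run_track_engine(config, schedule, landscape, bird_id, t0,
                            make_bursts = bursts)
    sim <- inject_gaps(sim, config)
    finalize_sim(sim, config, landscape, mass_g)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

check_schedule <- function(schedule) {
  need <- c("behavior", "duration_s", "habitat")
  if (!all(need %in% names(schedule))) {
    stop("schedule needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(schedule$duration_s <= 0)) stop("leg durations must be > 0",
                                          call. = FALSE)
  if (schedule$habitat[1] != "colony" ||
      schedule$habitat[nrow(schedule)] != "colony") {
    stop("schedule must start and end at the nest (habitat = 'colony')",
         call. = FALSE)
  }
  if (all(schedule$habitat == "colony")) {
    stop("schedule has zero away-time: no trip", call. = FALSE)
  }
  invisible(schedule)
}

## The track engine: walks the schedule leg by leg emitting fixes,
## bursts and per-fix truth.
run_track_engine <- function(config, schedule, landscape, bird_id, t0,
                             make_bursts = TRUE) {
  nest <- config$nest_xy %||% landscape$nest
  speeds <- config$behavior_speed_means
  if (!"commute" %in% names(schedule)) schedule$commute <- FALSE
  if (!"ax" %in% names(schedule)) schedule$ax <- NA_real_
  if (!"ay" %in% names(schedule)) schedule$ay <- NA_real_

  pos <- nest + runif(2, -20, 20)
  t <- t0
  rows <- list()
  bursts <- list()
  n_samp <- round(config$burst_rate * config$burst_length)
  for (k in seq_len(nrow(schedule))) {
    leg <- schedule[k, ]
    at_colony <- leg$habitat == "colony"
    dt <- if (at_colony) config$fix_interval_colony else config$fix_interval_away
    n_fix <- max(1L, round(leg$duration_s / dt))
    target <- if (leg$commute) {
      if (is.na(leg$ax)) nest else c(leg$ax, leg$ay)
    } else if (!at_colony) {
      c(leg$ax, leg$ay)
    } else {
      nest
    }
    arrived <- FALSE
    poly <- if (!at_colony && !leg$commute) {
      find_containing_poly(landscape, leg$habitat, target)
    } else NULL
    v_mean <- speeds[[leg$behavior]]
    ## the first fix of a commute leg that follows a foraging bout has
    ## its turning angle contaminated by the bout's last (random)
    ## heading; ground truth marks sustained directed transit only
    prev_is_bout <- k > 1 && !schedule$commute[k - 1] &&
      schedule$habitat[k - 1] != "colony"
    last_commuting_row <- NA_integer_
    for (f in seq_len(n_fix)) {
      t <- t + dt
      commuting_fix <- FALSE
      if (at_colony) {
        pos <- nest + runif(2, -30, 30)
      } else if (leg$commute && !arrived) {
        v <- max(0, rnorm(1, v_mean, 0.05 * v_mean))
        step <- v * dt
        delta <- target - pos
        remaining <- sqrt(sum(delta^2))
        if (step >= remaining) {
          pos <- target + runif(2, -30, 30)
          arrived <- TRUE
        } else {
          ang <- atan2(delta[2], delta[1]) + rnorm(1, 0, 0.05)
          pos <- pos + step * c(cos(ang), sin(ang))
          commuting_fix <- !(f == 1 && prev_is_bout)
          if (commuting_fix) last_commuting_row <- length(rows) + 1L
        }
      } else if (!is.null(poly)) {
        ## foraging wander inside the habitat polygon
        v <- max(0, rnorm(1, v_mean, 0.1 * v_mean + 0.01))
        ang <- runif(1, 0, 2 * pi)
        prop <- pos + v * dt * c(cos(ang), sin(ang))
        ok <- point_in_poly(prop[1], prop[2], poly) &&
          sqrt(sum((prop - target)^2)) < 3000
        pos <- if (ok) prop else target + runif(2, -150, 150)
      } else {
        ## post-arrival loiter on a commute leg (or anchor-less bout)
        pos <- target + runif(2, -30, 30)
      }
      rows[[length(rows) + 1]] <- data.frame(
        bird_id = bird_id, t = t, x = pos[1], y = pos[2],
        behavior = leg$behavior, commuting = commuting_fix && leg$commute,
        habitat = if (at_colony || leg$commute) NA_character_ else leg$habitat
      )
      if (make_bursts) {
        burst <- simulate_acc_burst(leg$behavior, config)
        b <- data.frame(bird_id = bird_id, t = t, axis = burst_axes)
        b[paste0("s", seq_len(n_samp))] <- unname(burst)
        bursts[[length(bursts) + 1]] <- b
      }
    }
    ## a commute leg that ran out of fixes before reaching its target
    ## hands over to a bout jump; the turn at its final marked fix is
    ## contaminated, so it is not ground-truth commuting
    if (leg$commute && !arrived && !is.na(last_commuting_row)) {
      rows[[last_commuting_row]]$commuting <- FALSE
    }
  }
  fixes <- do.call(rbind, rows)
  rownames(fixes) <- NULL
  list(fixes = fixes, bursts = do.call(rbind, bursts), nest = nest)
}

find_containing_poly <- function(landscape, habitat, pt) {
  for (layer in anchor_layers[[habitat]]) {
    for (p in landscape$layers[[layer]] %||% list()) {
      if (point_in_poly(pt[1], pt[2], p)) return(p)
    }
  }
  NULL
}

## Fix deletion: each away fix that is not the first or last of its
## away run may be dropped with gap_prob; bursts may be dropped with
## acc_gap_prob.
inject_gaps <- function(sim, config) {
  fx <- sim$fixes
  away <- !is.na(fx$habitat) | fx$commuting
  if (config$gap_prob > 0) {
    r <- rle(away)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    deletable <- rep(FALSE, nrow(fx))
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      idx <- starts[i]:ends[i]
      if (length(idx) > 2) deletable[idx[-c(1, length(idx))]] <- TRUE
    }
    drop <- deletable & runif(nrow(fx)) < config$gap_prob
    fx <- fx[!drop, , drop = FALSE]
  }
  fx$has_acc <- TRUE
  if (config$acc_gap_prob > 0) {
    fx$has_acc <- runif(nrow(fx)) >= config$acc_gap_prob
  }
  key <- paste(fx$bird_id, fx$t)
  bursts <- sim$bursts
  if (!is.null(bursts)) {
    bursts <- bursts[paste(bursts$bird_id, bursts$t) %in%
                       key[fx$has_acc], , drop = FALSE]
  }
  sim$fixes <- fx
  sim$bursts <- bursts
  sim
}

## Assemble output tables and per-trip ground truth. Trip membership is
## derived from positions exactly as the segmenter defines it (away =
## strictly > 100 m from the nest, extended by one colony fix on each
## side); the true energy is computed with the generator's own
## arithmetic.
finalize_sim <- function(sim, config, landscape, mass_g,
                         nest_radius = 100) {
  fx <- sim$fixes
  nest <- sim$nest
  away <- dist_to_point(fx$x, fx$y, nest) > nest_radius
  trip_id <- rep(NA_character_, nrow(fx))
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  truth_trips <- list()
  trip_no <- 0L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    trip_no <- trip_no + 1L
    i0 <- starts[i]; i1 <- ends[i]
    lo <- if (i0 > 1) i0 - 1L else i0
    hi <- if (i1 < nrow(fx)) i1 + 1L else i1
    id <- sprintf("%s_trip%03d", fx$bird_id[1], trip_no)
    trip_id[lo:hi] <- id
    seg <- fx[lo:hi, , drop = FALSE]
    cls <- aggregate_behavior(seg$behavior)
    e <- truth_energy(mass_g, seg$t, cls)
    hab_counts <- table(seg$habitat[!is.na(seg$habitat)])
    truth_trips[[trip_no]] <- data.frame(
      trip_id = id, bird_id = fx$bird_id[1],
      habitat = if (length(hab_counts))
        names(hab_counts)[which.max(hab_counts)] else NA_character_,
      start_t = seg$t[1], end_t = seg$t[nrow(seg)],
      duration_h = (seg$t[nrow(seg)] - seg$t[1]) / 3600,
      flapping_h = e$flapping_h, energy_kJ = e$total_kJ,
      mass_g = mass_g, n_fixes = nrow(seg)
    )
  }
  truth_fixes <- data.frame(
    bird_id = fx$bird_id, t = fx$t,
    behavior = fx$behavior, class = aggregate_behavior(fx$behavior),
    commuting = fx$commuting, habitat = fx$habitat, trip_id = trip_id
  )
  fixes <- fx[, c("bird_id", "t", "x", "y", "has_acc")]
  rownames(fixes) <- rownames(truth_fixes) <- NULL
  list(fixes = fixes, bursts = sim$bursts, truth_fixes = truth_fixes,
       truth_trips = do.call(rbind, truth_trips), nest = nest)
}

## Independent energy arithmetic for the ground truth: allometric BMR,
## per-class rates and centered-duration weighting written out in full
## (deliberately not calling the energetics module).
truth_energy <- function(mass_g, t, classes) {
  bmr_hour <- 2.3 * mass_g^0.774 / 24
  rate <- c(inactive = 1.7 * bmr_hour,
            terrestrial_movement = 2 * bmr_hour,
            soaring_flight = 2 * 1.7 * bmr_hour,
            flapping_flight = 7 * 1.7 * bmr_hour)
  n <- length(t)
  d <- diff(t)
  cd <- c(d[1] / 2, if (n > 2) (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
  list(total_kJ = sum(cd / 3600 * rate[classes]),
       flapping_h = sum(cd[classes == "flapping_flight"]) / 3600)
}
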
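## End-to-end convenience: from raw fixes + bursts (+ per-bird masses)
## to per-trip habitat categories and energy expenditure.

#' Run the full time-energy-budget pipeline
#'
#' Segments and QC-filters trips per bird, attaches behavior classes
#' (from a trained classifier, or the supplied pre-labeled behaviors),
#' annotates movement modes and commuting, assigns habitat and trip
#' categories, and computes per-trip energy.
#'
#' @param fixes Fix table: `bird_id`, `t`, `x`, `y`, `has_acc`.
#' @param bursts Burst table (long, `s1..sN` columns), or NULL when
#'   `behaviors` is given.
#' @param landscape A `gull_landscape`.
#' @param masses Data frame `bird_id`, `mass_g` (or a single number for
#'   all birds).
#' @param classifier A [train_classifier()] result; ignored when
#'   `behaviors` is given.
#' @param behaviors Optional pre-labeled behavior table `bird_id`, `t`,
#'   `fine`, `class` (bypasses the classifier so downstream stages can
#'   be tested in isolation).
#' @param commuting Optional pre-labeled commuting table `bird_id`,
#'   `t`, `commuting` (bypasses the mode clustering).
#' @param seg_config A [segmentation_config()].
#' @param rules_args Extra arguments for [habitat_rules()].
#' @param unannotated_policy Passed to [trip_energy()].
#' @param seed Seed for the mode clustering.
#' @return Data frame with one row per kept trip: `trip_id`, `bird_id`,
#'   `category`, `duration_h`, `flapping_h`, `total_kJ`, `rate_kJ_h`,
#'   habitat fractions and QC counts.
#' @export
run_teb_pipeline <- function(fixes, bursts = NULL, landscape, masses,
                             classifier = NULL, behaviors = NULL,
                             commuting = NULL,
                             seg_config = segmentation_config(),
                             rules_args = list(),
                             unannotated_policy = "redistribute",
                             seed = 1L) {
  rules <- do.call(habitat_rules, c(list(landscape = landscape), rules_args))
  if (is.numeric(masses)) {
    masses <- data.frame(bird_id = unique(fixes$bird_id), mass_g = masses)
  }
  if (is.null(behaviors)) {
    if (is.null(bursts) || is.null(classifier)) {
      stop("supply either `behaviors` or `bursts` + `classifier`",
           call. = FALSE)
    }
    feats <- extract_features_table(bursts)
    behaviors <- classify_and_aggregate(feats, classifier,
                                        fix_keys = fixes[, c("bird_id", "t")])
  }
  results <- list()
  for (bird in unique(fixes$bird_id)) {
    bf <- fixes[fixes$bird_id == bird, , drop = FALSE]
    trips <- segment_trips(bf, landscape$nest, seg_config)
    trips <- filter_trips(trips)
    key <- paste(trips$fixes$bird_id, trips$fixes$t)
    bkey <- paste(behaviors$bird_id, behaviors$t)
    m <- match(key, bkey)
    trips$fixes$fine <- behaviors$fine[m]
    trips$fixes$class <- ifelse(is.na(m), "unannotated", behaviors$class[m])
    if (is.null(commuting)) {
      trips <- annotate_movement_modes(trips, seed = seed)
    } else {
      ckey <- paste(commuting$bird_id, commuting$t)
      trips$fixes$commuting <- commuting$commuting[match(key, ckey)]
    }
    cat_df <- categorize_trips(trips, rules)
    mass <- masses$mass_g[match(bird, masses$bird_id)]
    profile <- energetic_profile(mass)
    kept <- trips$trips[trips$trips$kept, , drop = FALSE]
    for (k in seq_len(nrow(kept))) {
      id <- kept$trip_id[k]
      tf <- trips$fixes[trips$fixes$trip_id == id, , drop = FALSE]
      te <- trip_energy(tf$centered_dur_s, tf$class, profile,
                        unannotated_policy = unannotated_policy)
      row <- data.frame(
        trip_id = id, bird_id = bird,
        start_t = kept$start_t[k], end_t = kept$end_t[k],
        duration_h = te$duration_h, flapping_h = te$flapping_h,
        total_kJ = te$total_kJ, rate_kJ_h = te$rate_kJ_h
      )
      results[[length(results) + 1]] <-
        merge(row, cat_df[cat_df$trip_id == id, ], by = "trip_id")
    }
  }
  out <- do.call(rbind, results)
  out$bird_id <- out$bird_id.x %||% out$bird_id
  out$bird_id.x <- out$bird_id.y <- NULL
  rownames(out) <- NULL
  out
}

#' Mean hourly expenditure per habitat category
#'
#' @param trip_results Output of [run_teb_pipeline()].
#' @return Named numeric: mean `rate_kJ_h` per category.
#' @export
category_rates <- function(trip_results) {
  agg <- aggregate(rate_kJ_h ~ category, data = trip_results, FUN = mean)
  setNames(agg$rate_kJ_h, agg$category)
}
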
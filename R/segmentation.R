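## Trip segmentation and quality control.
##
## A foraging trip is the continuous period starting when a bird travels
## more than `nest_radius` (default 100 m) from its nest and ending when
## it returns within that radius. Trip bounds include the last fix at
## the colony before departure and the first fix back, so trip time is
## conserved. Per-fix time weights use the "centered duration": the mean
## of the backward and forward inter-fix intervals (half the single
## adjacent interval at the trip edges), which makes the weights
## telescope to exactly the elapsed trip time.

#' Segmentation configuration
#'
#' @param nest_radius Colony radius in meters (default 100): a bird is
#'   "away" when strictly farther than this from the nest.
#' @param max_gap Maximum tolerated inter-fix gap (s) while away
#'   (default 1200 = 20 min); trips with a strictly larger gap are
#'   dropped by [filter_trips()].
#' @param min_acc_coverage Minimum fraction of trip fixes with an
#'   acceleration burst (default 0.8, inclusive).
#' @param standard_interval_colony,standard_interval_away Nominal fix
#'   intervals (s) at the colony and away (600 / 300).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(nest_radius = 100, max_gap = 1200,
                                min_acc_coverage = 0.8,
                                standard_interval_colony = 600,
                                standard_interval_away = 300) {
  stopifnot_scalar_pos(nest_radius, "nest_radius")
  stopifnot_scalar_pos(max_gap, "max_gap")
  if (min_acc_coverage <= 0 || min_acc_coverage > 1) {
    stop("min_acc_coverage must be in (0, 1]", call. = FALSE)
  }
  structure(list(nest_radius = nest_radius, max_gap = max_gap,
                 min_acc_coverage = min_acc_coverage,
                 standard_interval_colony = standard_interval_colony,
                 standard_interval_away = standard_interval_away),
            class = "segmentation_config")
}

#' Thin a track to a target fix interval
#'
#' Resamples over-frequent segments to the standard measurement
#' frequency by keeping the first fix of each target-interval bin
#' (thinning, no interpolation): a fix is retained iff it is at least
#' `target_interval - tol` seconds after the last retained fix.
#'
#' @param fixes Time-sorted fix data frame with column `t` (seconds).
#' @param target_interval Target interval (s).
#' @param tol Tolerance (s) for clock jitter; default 1.
#' @return The thinned fix data frame.
#' @export
resample_track <- function(fixes, target_interval, tol = 1) {
  if (nrow(fixes) == 0) return(fixes)
  if (is.unsorted(fixes$t)) stop("`fixes` must be time-sorted", call. = FALSE)
  keep <- logical(nrow(fixes))
  keep[1] <- TRUE
  last_t <- fixes$t[1]
  for (i in seq_len(nrow(fixes))[-1]) {
    if (fixes$t[i] - last_t >= target_interval - tol) {
      keep[i] <- TRUE
      last_t <- fixes$t[i]
    }
  }
  fixes[keep, , drop = FALSE]
}

#' Centered durations of a fix sequence
#'
#' Interior fix i is weighted by the mean of its backward and forward
#' intervals; the first and last fix get half their single adjacent
#' interval. The weights sum exactly to the elapsed time.
#'
#' @param t Strictly increasing timestamps (s), length >= 2.
#' @return Per-fix centered durations (s).
#' @examples
#' compute_centered_durations(c(0, 300, 900))  # 150 450 300
#' @export
compute_centered_durations <- function(t) {
  n <- length(t)
  if (n < 2) stop("need at least 2 fixes", call. = FALSE)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  d <- diff(t)
  c(d[1] / 2, if (n > 2) (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

#' Segment a bird's fixes into foraging trips
#'
#' Splits a time-sorted single-bird fix table into alternating colony
#' residence and foraging trips. A trip runs from the last fix within
#' `nest_radius` before an excursion (strictly beyond the radius) to the
#' first fix back within it. An excursion still open at the end of the
#' data is emitted with `kept = FALSE`, reason `"unclosed"`.
#'
#' @param fixes Data frame with `t` (s), `x`, `y` (projected m),
#'   optional `bird_id` and `has_acc`.
#' @param nest_xy Numeric length-2 nest coordinates (projected m).
#' @param config A [segmentation_config()].
#' @return A `gull_trips` object: list with `trips` (one row per trip:
#'   `trip_id`, `bird_id`, `start_t`, `end_t`, `duration_h`, `n_fixes`,
#'   `kept`, `reason`) and `fixes` (input rows of trips, plus `trip_id`,
#'   `dist_to_nest`, `centered_dur_s`).
#' @export
segment_trips <- function(fixes, nest_xy, config = segmentation_config()) {
  if (is.null(nest_xy) || length(nest_xy) != 2 || any(!is.finite(nest_xy))) {
    stop("`nest_xy` must be finite coordinates of length 2", call. = FALSE)
  }
  stopifnot(inherits(config, "segmentation_config"))
  if (nrow(fixes) == 0) {
    return(structure(list(trips = empty_trip_table(), fixes = fixes,
                          nest_xy = nest_xy, config = config),
                     class = "gull_trips"))
  }
  if (is.unsorted(fixes$t)) stop("`fixes` must be time-sorted", call. = FALSE)
  bird <- if (!is.null(fixes$bird_id)) as.character(fixes$bird_id[1]) else "bird1"
  dist <- dist_to_nest <- dist_to_point(fixes$x, fixes$y, nest_xy)
  away <- dist > config$nest_radius

  trips <- list()
  trip_fixes <- list()
  i <- 1L
  n <- nrow(fixes)
  trip_no <- 0L
  while (i <= n) {
    if (!away[i]) { i <- i + 1L; next }
    ## excursion starting at i; trip starts at previous colony fix if any
    start_i <- if (i > 1L && !away[i - 1L]) i - 1L else i
    j <- i
    while (j <= n && away[j]) j <- j + 1L
    closed <- j <= n
    end_i <- if (closed) j else n
    trip_no <- trip_no + 1L
    idx <- start_i:end_i
    tf <- fixes[idx, , drop = FALSE]
    tf$trip_id <- sprintf("%s_trip%03d", bird, trip_no)
    tf$dist_to_nest <- dist[idx]
    tf$centered_dur_s <- if (length(idx) >= 2) {
      compute_centered_durations(tf$t)
    } else {
      NA_real_
    }
    trips[[trip_no]] <- data.frame(
      trip_id = tf$trip_id[1], bird_id = bird,
      start_t = tf$t[1], end_t = tf$t[length(idx)],
      duration_h = (tf$t[length(idx)] - tf$t[1]) / 3600,
      n_fixes = length(idx),
      kept = closed, reason = if (closed) "" else "unclosed"
    )
    trip_fixes[[trip_no]] <- tf
    i <- end_i + if (closed) 0L else 1L
    i <- max(i, j)          # continue after the excursion
  }
  trips_df <- if (length(trips)) do.call(rbind, trips) else empty_trip_table()
  fixes_df <- if (length(trip_fixes)) do.call(rbind, trip_fixes) else fixes[0, ]
  rownames(trips_df) <- rownames(fixes_df) <- NULL
  structure(list(trips = trips_df, fixes = fixes_df,
                 nest_xy = nest_xy, config = config),
            class = "gull_trips")
}

empty_trip_table <- function() {
  data.frame(trip_id = character(), bird_id = character(),
             start_t = numeric(), end_t = numeric(),
             duration_h = numeric(), n_fixes = integer(),
             kept = logical(), reason = character())
}

#' @export
print.gull_trips <- function(x, ...) {
  cat(sprintf("gull_trips: %d trips (%d kept) from %d fixes\n",
              nrow(x$trips), sum(x$trips$kept), nrow(x$fixes)))
  invisible(x)
}

#' Quality-control filter for segmented trips
#'
#' Drops a trip when any away-from-colony inter-fix gap strictly exceeds
#' `max_gap`, or when the fraction of its fixes carrying an acceleration
#' burst falls below `min_acc_coverage` (inclusive keep at the
#' boundary). Gap checking uses only intervals with at least one
#' endpoint beyond the nest radius, i.e. time at the colony between
#' trips is never penalized.
#'
#' @param trips A `gull_trips` object from [segment_trips()].
#' @param config A [segmentation_config()]; defaults to the one stored
#'   in `trips`.
#' @return The `gull_trips` object with updated `kept`/`reason` columns
#'   (reasons: `"gap_exceeded"`, `"low_acc_coverage"`, `"unclosed"`).
#' @export
filter_trips <- function(trips, config = trips$config) {
  stopifnot(inherits(trips, "gull_trips"))
  tdf <- trips$trips
  for (k in seq_len(nrow(tdf))) {
    if (!tdf$kept[k]) next
    tf <- trips$fixes[trips$fixes$trip_id == tdf$trip_id[k], , drop = FALSE]
    away <- tf$dist_to_nest > config$nest_radius
    gaps <- diff(tf$t)
    away_gap <- away[-length(away)] | away[-1]
    reasons <- character()
    if (any(gaps[away_gap] > config$max_gap)) reasons <- c(reasons, "gap_exceeded")
    if (!is.null(tf$has_acc)) {
      if (mean(tf$has_acc) < config$min_acc_coverage) {
        reasons <- c(reasons, "low_acc_coverage")
      }
    }
    if (length(reasons)) {
      tdf$kept[k] <- FALSE
      tdf$reason[k] <- paste(reasons, collapse = ";")
    }
  }
  trips$trips <- tdf
  trips
}
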
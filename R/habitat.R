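## Habitat assignment for non-commuting fixes and trip categorization.
##
## Polygon layers: north_sea, wadden_sea (marine), urban, breakwater,
## beach (intertidal), mudflat (conditional), agri_natural
## (terrestrial). The assignment rule order is:
##   1. urban polygon                                  -> urban
##   2. breakwater or beach polygon                    -> intertidal
##   3. sea polygon within `buffer` (50 m) of a
##      breakwater/beach/mudflat polygon               -> intertidal
##   4. mudflat polygon: flying (flapping or soaring
##      class) or floating fine behavior               -> marine
##      otherwise (resting / terrestrial movement,
##      i.e. foraging on the flat)                     -> intertidal
##   5. sea polygon                                    -> marine
##   6. agri_natural polygon                           -> terrestrial
##   7. no polygon                                     -> unassigned

intertidal_feature_layers <- c("breakwater", "beach", "mudflat")
sea_layers <- c("north_sea", "wadden_sea")

#' Habitat assignment rules
#'
#' @param landscape A `gull_landscape` (see [generate_landscape()] or
#'   [read_landscape_geojson()]).
#' @param intertidal_buffer Distance (m) from sea positions to
#'   breakwater/beach/mudflat features within which the position counts
#'   as intertidal (default 50).
#' @param category_threshold Minimum fraction of assigned non-commuting
#'   fixes in one habitat for the trip to take that category (default
#'   0.5, inclusive); below it the trip is `mixed`.
#' @param precedence Tie-break order for trip categories at exactly the
#'   threshold.
#' @return A `habitat_rules` list.
#' @export
habitat_rules <- function(landscape,
                          intertidal_buffer = 50,
                          category_threshold = 0.5,
                          precedence = c("urban", "marine",
                                         "intertidal", "terrestrial")) {
  stopifnot(inherits(landscape, "gull_landscape"))
  if (intertidal_buffer < 0) stop("buffer must be >= 0", call. = FALSE)
  if (category_threshold <= 0 || category_threshold > 1) {
    stop("category_threshold must be in (0, 1]", call. = FALSE)
  }
  structure(list(landscape = landscape,
                 intertidal_buffer = intertidal_buffer,
                 category_threshold = category_threshold,
                 precedence = precedence),
            class = "habitat_rules")
}

## TRUE when (x, y) lies in any polygon of the named layer.
in_layer <- function(landscape, layer, x, y) {
  polys <- landscape$layers[[layer]]
  if (is.null(polys)) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (p in polys) hit <- hit | point_in_poly(x, y, p)
  hit
}

## Minimum distance from one point to any polygon of the named layers.
dist_to_layers <- function(landscape, layers, x, y) {
  d <- Inf
  for (layer in layers) {
    for (p in landscape$layers[[layer]] %||% list()) {
      d <- min(d, dist_to_poly(x, y, p))
    }
  }
  d
}

#' Assign habitat to non-commuting fixes
#'
#' Applies the rule order documented above to each fix. Commuting fixes
#' should be excluded by the caller (they do not contribute to habitat
#' use); rows with `commuting = TRUE` are returned as NA.
#'
#' @param fixes Data frame with `x`, `y`, `class` (aggregate behavior
#'   class or `"unannotated"`), optional `fine` (fine label, used for
#'   the floating rule) and optional `commuting`.
#' @param rules A [habitat_rules()].
#' @return Character vector: `"urban"`, `"marine"`, `"intertidal"`,
#'   `"terrestrial"` or `"unassigned"` per fix (NA for commuting rows).
#' @export
assign_habitat <- function(fixes, rules) {
  stopifnot(inherits(rules, "habitat_rules"))
  ls <- rules$landscape
  n <- nrow(fixes)
  if (any(!is.finite(fixes$x)) || any(!is.finite(fixes$y))) {
    stop("fixes contain non-finite coordinates", call. = FALSE)
  }
  out <- rep(NA_character_, n)
  commuting <- fixes$commuting %||% rep(FALSE, n)
  commuting[is.na(commuting)] <- FALSE
  cls <- fixes$class %||% rep("unannotated", n)
  fine <- fixes$fine %||% rep(NA_character_, n)
  in_urban <- in_layer(ls, "urban", fixes$x, fixes$y)
  in_bw <- in_layer(ls, "breakwater", fixes$x, fixes$y)
  in_beach <- in_layer(ls, "beach", fixes$x, fixes$y)
  in_mud <- in_layer(ls, "mudflat", fixes$x, fixes$y)
  in_sea <- in_layer(ls, "north_sea", fixes$x, fixes$y) |
    in_layer(ls, "wadden_sea", fixes$x, fixes$y)
  in_agri <- in_layer(ls, "agri_natural", fixes$x, fixes$y)
  for (i in seq_len(n)) {
    if (commuting[i]) next
    out[i] <- if (in_urban[i]) {
      "urban"
    } else if (in_bw[i] || in_beach[i]) {
      "intertidal"
    } else if (in_sea[i] &&
               dist_to_layers(ls, intertidal_feature_layers,
                              fixes$x[i], fixes$y[i]) < rules$intertidal_buffer) {
      "intertidal"
    } else if (in_mud[i]) {
      flying <- cls[i] %in% c("flapping_flight", "soaring_flight")
      floating <- !is.na(fine[i]) && fine[i] == "float"
      if (flying || floating) "marine" else "intertidal"
    } else if (in_sea[i]) {
      "marine"
    } else if (in_agri[i]) {
      "terrestrial"
    } else {
      "unassigned"
    }
  }
  out
}

#' Summarize habitat use of one trip and categorize it
#'
#' Computes the fraction of assigned non-commuting fixes per habitat and
#' assigns the trip category: the habitat holding at least
#' `category_threshold` of those fixes (inclusive), else `"mixed"`.
#' Exact ties at the threshold are broken by the rules' precedence order
#' and recorded.
#'
#' @param habitats Per-fix habitat labels from [assign_habitat()] for
#'   the trip's fixes (NAs = commuting fixes).
#' @param rules A [habitat_rules()].
#' @return List with `fractions` (over assigned non-commuting fixes),
#'   `category`, `tie` (logical), `n_noncommuting`, `n_unassigned`.
#'   Zero usable fixes give category NA with `flagged = TRUE`.
#' @export
summarize_trip_habitat <- function(habitats, rules) {
  stopifnot(inherits(rules, "habitat_rules"))
  noncom <- habitats[!is.na(habitats)]
  assigned <- noncom[noncom != "unassigned"]
  out <- list(
    fractions = setNames(numeric(0), character(0)),
    category = NA_character_, tie = FALSE,
    n_noncommuting = length(noncom),
    n_unassigned = sum(noncom == "unassigned"),
    flagged = FALSE
  )
  if (!length(assigned)) {
    out$flagged <- TRUE
    return(out)
  }
  frac <- table(assigned) / length(assigned)
  fractions <- setNames(as.numeric(frac), names(frac))
  out$fractions <- fractions
  thr <- rules$category_threshold
  eligible <- fractions[fractions >= thr]
  if (!length(eligible)) {
    out$category <- "mixed"
  } else {
    ord <- intersect(rules$precedence, names(eligible))
    out$category <- ord[1]
    out$tie <- length(eligible) > 1 ||
      (abs(max(fractions) - thr) < 1e-12 && sum(fractions >= thr - 1e-12) > 1)
  }
  out
}

#' Categorize every kept trip of a pipeline run
#'
#' Convenience wrapper: assigns habitat per fix (excluding commuting
#' fixes) and summarizes each kept trip.
#'
#' @param trips A `gull_trips` whose `$fixes` carry `class`, optional
#'   `fine`, and `commuting` columns.
#' @param rules A [habitat_rules()].
#' @return Data frame: `trip_id`, `category`, `tie`, `n_noncommuting`,
#'   `n_unassigned`, plus one `frac_*` column per habitat.
#' @export
categorize_trips <- function(trips, rules) {
  stopifnot(inherits(trips, "gull_trips"))
  fx <- trips$fixes
  fx$habitat <- assign_habitat(fx, rules)
  kept_ids <- trips$trips$trip_id[trips$trips$kept]
  rows <- lapply(kept_ids, function(id) {
    s <- summarize_trip_habitat(fx$habitat[fx$trip_id == id], rules)
    r <- data.frame(trip_id = id, category = s$category, tie = s$tie,
                    n_noncommuting = s$n_noncommuting,
                    n_unassigned = s$n_unassigned)
    for (h in c("urban", "marine", "intertidal", "terrestrial")) {
      r[[paste0("frac_", h)]] <- unname(s$fractions[h] %||% NA_real_)
      if (is.na(r[[paste0("frac_", h)]]) && length(s$fractions)) {
        r[[paste0("frac_", h)]] <- 0
      }
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
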
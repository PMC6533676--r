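## Behavior vocabulary: 11 fine behaviors aggregated into 4 energetic
## classes. Fine-label names are configurable (annotation vocabularies
## differ between labs) but the default cardinality is 11 and the
## fine-to-class map is fixed:
##   sitting/standing/floating            -> inactive
##   walking, searching, prey handling    -> terrestrial_movement
##   soaring, manoeuvring                 -> soaring_flight
##   regular + extreme flapping           -> flapping_flight

#' Default fine behavior labels
#'
#' The default 11-label vocabulary: three inactive postures (`sit`,
#' `stand`, `float`), four ground activities (`terrestrial-locomotion`,
#' `look-for-food-moving`, `look-for-food-standing`, `handle-prey`),
#' two gliding-flight labels (`soar`, `manoeuvre`) and two powered-flight
#' labels (`flap`, `extreme-flap`).
#'
#' @return Character vector of the 11 fine behavior labels.
#' @export
fine_behaviors <- function() {
  c("sit", "stand", "float",
    "terrestrial-locomotion", "look-for-food-moving",
    "look-for-food-standing", "handle-prey",
    "soar", "manoeuvre",
    "flap", "extreme-flap")
}

#' The four aggregate behavior classes
#' @return Character vector of the 4 class labels.
#' @export
aggregate_classes <- function() {
  c("inactive", "terrestrial_movement", "soaring_flight", "flapping_flight")
}

#' Default 11-to-4 aggregation map
#' @return Named character vector fine label -> class.
#' @export
default_aggregate_map <- function() {
  c("sit" = "inactive", "stand" = "inactive", "float" = "inactive",
    "terrestrial-locomotion" = "terrestrial_movement",
    "look-for-food-moving" = "terrestrial_movement",
    "look-for-food-standing" = "terrestrial_movement",
    "handle-prey" = "terrestrial_movement",
    "soar" = "soaring_flight", "manoeuvre" = "soaring_flight",
    "flap" = "flapping_flight", "extreme-flap" = "flapping_flight")
}

#' Behavior scheme: fine labels and their aggregation
#'
#' @param fine_labels Character vector of fine labels (default the
#'   11-label vocabulary of [fine_behaviors()]).
#' @param aggregate_map Named character: for every fine label, its
#'   aggregate class. Must be total over `fine_labels`.
#' @return A `behavior_scheme` list with `fine_labels` and
#'   `aggregate_map`.
#' @export
behavior_scheme <- function(fine_labels = fine_behaviors(),
                            aggregate_map = default_aggregate_map()) {
  missing <- setdiff(fine_labels, names(aggregate_map))
  if (length(missing)) {
    stop("aggregate_map is not total; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unname(aggregate_map[fine_labels]), aggregate_classes())
  if (length(bad)) {
    stop("aggregate_map targets unknown class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(fine_labels = fine_labels,
                 aggregate_map = aggregate_map[fine_labels]),
            class = "behavior_scheme")
}

#' Aggregate fine behavior labels to classes
#'
#' @param fine Character vector of fine labels (NA allowed).
#' @param scheme A [behavior_scheme()].
#' @return Character vector of aggregate classes; NA stays NA.
#' @export
aggregate_behavior <- function(fine, scheme = behavior_scheme()) {
  stopifnot(inherits(scheme, "behavior_scheme"))
  fine <- as.character(fine)
  known <- is.na(fine) | fine %in% scheme$fine_labels
  if (!all(known)) {
    stop("fine label(s) outside the scheme: ",
         paste(unique(fine[!known]), collapse = ", "), call. = FALSE)
  }
  unname(scheme$aggregate_map[fine])
}
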
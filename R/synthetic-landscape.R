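## Synthetic habitat landscape.
##
## The landscape is deliberately abstract: axis-aligned rectangles in a
## projected (UTM-like) plane, laid out like a barrier-island colony --
## open sea to the west behind a breakwater and beach strip, a tidal sea
## to the east fringed by mudflats, an urban block to the north and
## agricultural/natural land to the south, with the colony in the
## middle. The habitat-assignment rules, not real geography, are what
## the generator needs to exercise.

rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Generate a synthetic habitat landscape
#'
#' @param seed Integer seed; the layout is jittered deterministically.
#' @param extent Numeric length 4: `c(xmin, ymin, xmax, ymax)` in
#'   projected meters; must be non-degenerate. Default 40 x 30 km.
#' @return A `gull_landscape`: list with `extent`, `nest` (colony
#'   coordinates) and `layers`, a named list of polygon lists
#'   (`north_sea`, `wadden_sea`, `urban`, `breakwater`, `beach`,
#'   `mudflat`, `agri_natural`). Polygons are n x 2 matrices
#'   (unclosed rings) and are mutually non-overlapping.
#' @export
generate_landscape <- function(seed = 1L,
                               extent = c(0, 0, 40000, 30000)) {
  if (length(extent) != 4 || extent[3] <= extent[1] || extent[4] <= extent[2]) {
    stop("degenerate extent", call. = FALSE)
  }
  w <- extent[3] - extent[1]
  h <- extent[4] - extent[2]
  if (w < 20000 || h < 15000) {
    stop("extent too small for the landscape template (need >= 20 x 15 km)",
         call. = FALSE)
  }
  with_seed(seed, {
    j <- function(scale) runif(1, -scale, scale)
    x0 <- extent[1]; y0 <- extent[2]; x1 <- extent[3]; y1 <- extent[4]
    nest <- c(x0 + 0.50 * w + j(0.01 * w), y0 + 0.50 * h + j(0.01 * h))
    coast_w <- x0 + 0.30 * w + j(0.01 * w)    # west coastline
    coast_e <- x0 + 0.70 * w + j(0.01 * w)    # east coastline
    bw_w <- 200 + j(50)                       # breakwater strip width
    beach_w <- 1000 + j(200)                  # beach strip width
    mud_w <- 2000 + j(300)                    # mudflat fringe width
    layers <- list(
      north_sea = list(rect_poly(x0, y0, coast_w - bw_w, y1)),
      breakwater = list(rect_poly(coast_w - bw_w, y0 + 0.2 * h,
                                  coast_w, y0 + 0.8 * h)),
      beach = list(rect_poly(coast_w, y0, coast_w + beach_w, y1)),
      mudflat = list(
        rect_poly(coast_e - mud_w, y0, coast_e, y1),
        ## a detached flat inside the tidal sea
        rect_poly(coast_e + 0.12 * w + j(0.01 * w), y0 + 0.10 * h,
                  coast_e + 0.17 * w + j(0.01 * w), y0 + 0.25 * h)
      ),
      wadden_sea = list(rect_poly(coast_e, y0, x1, y1)),
      urban = list(rect_poly(nest[1] - 0.05 * w + j(0.005 * w),
                             y0 + 0.80 * h,
                             nest[1] + 0.05 * w + j(0.005 * w),
                             y0 + 0.95 * h)),
      agri_natural = list(rect_poly(nest[1] - 0.12 * w, y0 + 0.05 * h,
                                    nest[1] + 0.12 * w, y0 + 0.30 * h))
    )
    ## carve the detached mudflat out of the tidal sea so layers stay
    ## non-overlapping: split the wadden_sea rectangle around it
    det <- layers$mudflat[[2]]
    ws <- layers$wadden_sea[[1]]
    layers$wadden_sea <- subtract_rect(ws, det)
    structure(list(extent = extent, nest = nest, layers = layers),
              class = "gull_landscape")
  })
}

## Subtract an axis-aligned rectangle from an axis-aligned rectangle,
## returning up to 4 rectangles (the frame around the hole).
subtract_rect <- function(outer, hole) {
  ox <- range(outer[, 1]); oy <- range(outer[, 2])
  hx <- range(hole[, 1]); hy <- range(hole[, 2])
  hx <- c(max(hx[1], ox[1]), min(hx[2], ox[2]))
  hy <- c(max(hy[1], oy[1]), min(hy[2], oy[2]))
  if (hx[1] >= hx[2] || hy[1] >= hy[2]) return(list(outer))
  out <- list()
  if (hx[1] > ox[1]) out <- c(out, list(rect_poly(ox[1], oy[1], hx[1], oy[2])))
  if (hx[2] < ox[2]) out <- c(out, list(rect_poly(hx[2], oy[1], ox[2], oy[2])))
  if (hy[1] > oy[1]) out <- c(out, list(rect_poly(hx[1], oy[1], hx[2], hy[1])))
  if (hy[2] < oy[2]) out <- c(out, list(rect_poly(hx[1], hy[2], hx[2], oy[2])))
  out
}

#' @export
print.gull_landscape <- function(x, ...) {
  cat(sprintf("gull_landscape: extent [%g, %g] x [%g, %g], nest (%.0f, %.0f)\n",
              x$extent[1], x$extent[3], x$extent[2], x$extent[4],
              x$nest[1], x$nest[2]))
  for (nm in names(x$layers)) {
    cat(sprintf("  %-12s %d polygon(s)\n", nm, length(x$layers[[nm]])))
  }
  invisible(x)
}

#' Write a landscape to GeoJSON
#'
#' One Polygon feature per polygon with property `habitat_layer`, plus
#' a Point feature for the colony (`habitat_layer = "colony"`).
#'
#' @param landscape A `gull_landscape`.
#' @param path Output file path.
#' @export
write_landscape_geojson <- function(landscape, path) {
  stopifnot(inherits(landscape, "gull_landscape"))
  feats <- list()
  for (nm in names(landscape$layers)) {
    for (p in landscape$layers[[nm]]) {
      ring <- rbind(p, p[1, , drop = FALSE])  # closed ring
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(habitat_layer = nm),
        geometry = list(type = "Polygon",
                        coordinates = list(unname(apply(ring, 1, as.list))))
      )
    }
  }
  feats[[length(feats) + 1]] <- list(
    type = "Feature",
    properties = list(habitat_layer = "colony"),
    geometry = list(type = "Point",
                    coordinates = as.list(unname(landscape$nest)))
  )
  gj <- list(type = "FeatureCollection",
             extent = landscape$extent,
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landscape from GeoJSON
#'
#' @param path GeoJSON file written by [write_landscape_geojson()] (or
#'   any FeatureCollection of Polygons with a `habitat_layer` property
#'   and a colony Point).
#' @return A `gull_landscape`.
#' @export
read_landscape_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  layers <- list()
  nest <- NULL
  for (f in gj$features) {
    nm <- f$properties$habitat_layer
    if (f$geometry$type == "Point") {
      nest <- as.numeric(unlist(f$geometry$coordinates))
      next
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(pt) as.numeric(unlist(pt))))
    ## drop the closing vertex
    if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
    layers[[nm]] <- c(layers[[nm]] %||% list(), list(ring))
  }
  extent <- if (!is.null(gj$extent)) {
    as.numeric(unlist(gj$extent))
  } else {
    allv <- do.call(rbind, unlist(layers, recursive = FALSE))
    c(min(allv[, 1]), min(allv[, 2]), max(allv[, 1]), max(allv[, 2]))
  }
  structure(list(extent = extent, nest = nest, layers = layers),
            class = "gull_landscape")
}
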
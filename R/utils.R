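## Internal geometry and misc helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean distance between points and a reference point
#' @noRd
dist_to_point <- function(x, y, ref) {
  sqrt((x - ref[1])^2 + (y - ref[2])^2)
}

## Point-in-polygon membership; polygon is an n x 2 matrix (not closed).
## Boundary points count as inside.
point_in_poly <- function(x, y, poly) {
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

## Minimum distance from point (px, py) to segment (ax,ay)-(bx,by).
seg_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 == 0, 0, ((px - ax) * dx + (py - ay) * dy) / len2)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx
  qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

## Distance from a single point to a polygon (0 if inside or on boundary).
dist_to_poly <- function(px, py, poly) {
  if (point_in_poly(px, py, poly)) return(0)
  n <- nrow(poly)
  ring <- rbind(poly, poly[1, , drop = FALSE])
  min(seg_dist(px, py, ring[-(n + 1), 1], ring[-(n + 1), 2],
               ring[-1, 1], ring[-1, 2]))
}

## Wrap an angle difference to (-pi, pi].
wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

## Run code with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

## Sample a uniform point inside a polygon by rejection in its bbox.
sample_point_in_poly <- function(poly, reject = NULL, max_tries = 2000) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  for (i in seq_len(max_tries)) {
    px <- runif(1, xr[1], xr[2])
    py <- runif(1, yr[1], yr[2])
    if (point_in_poly(px, py, poly) &&
        (is.null(reject) || !reject(px, py))) {
      return(c(px, py))
    }
  }
  stop("could not sample a point inside the polygon")
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
}
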
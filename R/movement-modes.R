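## Movement modes from speed and turning angle.
##
## Each interior fix of a trip gets a speed (step displacement over step
## duration) and an absolute turning angle in [0, pi]. An
## expectation-maximization binary clustering splits each variable into
## a low (L) and a high (H) regime; the four quadrant combinations give
## the modes HL, HH, LL, LH. HL (fast and straight) is interpreted as
## commuting between the colony and a foraging patch.
##
## The mixture is quadrant-constrained: one low and one high Gaussian
## per variable, shared across quadrants, with free quadrant weights
## pi_ij. Component (i, j) has density N(speed; s_i) * N(turn; t_j).
## This structured model keeps the quadrant semantics identifiable while
## remaining a proper EM (monotone log-likelihood).

#' Speed and turning angle along a trip
#'
#' @param fixes Time-sorted data frame with `t` (s), `x`, `y` (m),
#'   >= 3 rows.
#' @return Data frame with per-fix `speed` (m/s) and `turn` (rad in
#'   `[0, pi]`). Speed at fix i uses the step arriving at i (the first
#'   fix uses the first step); turning angle is defined at interior
#'   fixes and copied to the endpoints from the nearest interior fix.
#' @export
derive_kinematics <- function(fixes) {
  n <- nrow(fixes)
  if (n < 3) stop("need at least 3 fixes", call. = FALSE)
  dt <- diff(fixes$t)
  if (any(dt == 0)) stop("duplicate timestamps", call. = FALSE)
  dx <- diff(fixes$x)
  dy <- diff(fixes$y)
  step_speed <- sqrt(dx^2 + dy^2) / dt
  speed <- c(step_speed[1], step_speed)
  heading <- atan2(dy, dx)
  turn_int <- abs(wrap_angle(diff(heading)))   # at fixes 2..n-1
  ## stationary steps have undefined heading; treat their turn as 0
  moved <- sqrt(dx^2 + dy^2) > 1e-9
  ok <- moved[-length(moved)] & moved[-1]
  turn_int[!ok] <- 0
  turn <- c(turn_int[1], turn_int, turn_int[length(turn_int)])
  data.frame(speed = speed, turn = turn)
}

#' Expectation-maximization binary clustering of speed and turn
#'
#' Fits the quadrant-constrained Gaussian mixture described above and
#' labels each point HL, HH, LL or LH by the fitted binary delimiters:
#' the midpoints between the low and high component means of each
#' variable. The delimiters carry the quadrant semantics, so labels are
#' invariant to component re-indexing.
#'
#' @param points Data frame with columns `speed` and `turn` (finite,
#'   >= 8 rows).
#' @param seed Integer seed (initialization is deterministic, the seed
#'   guards any tie-breaking).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations (default 200).
#' @return An `embc_fit` object: `modes` (per-point labels),
#'   `commuting` (modes == "HL"), `delimiters` (speed_split, turn_split),
#'   `params`, `loglik_trace`, `converged`, `degenerate`.
#' @export
embc_fit <- function(points, seed = 1L, tol = 1e-6, max_iter = 200) {
  s <- points$speed
  u <- points$turn
  if (length(s) < 8 || any(!is.finite(s)) || any(!is.finite(u))) {
    stop("need >= 8 points with finite speed and turn", call. = FALSE)
  }
  ## degenerate data: a single repeated point cannot be split
  if (sd(s) < 1e-12 && sd(u) < 1e-12) {
    return(structure(list(
      modes = rep("LL", length(s)), commuting = rep(FALSE, length(s)),
      delimiters = c(speed_split = s[1], turn_split = u[1]),
      params = NULL, loglik_trace = numeric(), converged = TRUE,
      degenerate = TRUE
    ), class = "embc_fit"))
  }
  fit <- with_seed(seed, embc_em(s, u, tol, max_iter))
  structure(fit, class = "embc_fit")
}

embc_em <- function(s, u, tol, max_iter) {
  n <- length(s)
  ## variance floor per variable: components may not shrink below 5% of
  ## the overall spread, so a mass of identical values (e.g. exact-zero
  ## turns at stationary fixes) cannot collapse a regime to a point
  floor_s <- max(0.05 * sd(s), 1e-6)
  floor_u <- max(0.05 * sd(u), 1e-6)
  init1d <- function(v, fl) {
    med <- median(v)
    lo <- v[v <= med]; hi <- v[v > med]
    if (!length(hi)) hi <- max(v)
    list(mu = c(mean(lo), mean(hi)),
         sd = pmax(c(sd(lo), sd(hi)), fl, na.rm = TRUE))
  }
  ps <- init1d(s, floor_s)   # speed low/high
  pu <- init1d(u, floor_u)   # turn low/high
  w <- matrix(0.25, 2, 2)  # weights [speed regime, turn regime]
  loglik <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## E step: responsibilities over the 4 quadrants
    dens <- array(0, c(n, 2, 2))
    for (i in 1:2) for (j in 1:2) {
      dens[, i, j] <- w[i, j] *
        dnorm(s, ps$mu[i], ps$sd[i]) * dnorm(u, pu$mu[j], pu$sd[j])
    }
    tot <- pmax(apply(dens, 1, sum), 1e-300)
    loglik[it] <- sum(log(tot))
    r <- dens / array(tot, c(n, 2, 2))
    ## M step
    for (i in 1:2) for (j in 1:2) w[i, j] <- mean(r[, i, j])
    rs <- apply(r, c(1, 2), sum)   # marginal responsibility, speed regime
    ru <- apply(r, c(1, 3), sum)   # marginal responsibility, turn regime
    upd <- function(v, rm, p, fl) {
      for (k in 1:2) {
        wk <- rm[, k]
        sw <- sum(wk)
        if (sw < 1e-8) next
        p$mu[k] <- sum(wk * v) / sw
        p$sd[k] <- max(sqrt(sum(wk * (v - p$mu[k])^2) / sw), fl)
      }
      if (p$mu[1] > p$mu[2]) { p$mu <- rev(p$mu); p$sd <- rev(p$sd) }
      p
    }
    ps <- upd(s, rs, ps, floor_s)
    pu <- upd(u, ru, pu, floor_u)
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  ## label by the fitted binary delimiters (midpoints between the low
  ## and high component means): the delimiters, not component indices,
  ## carry the quadrant semantics
  s_split <- mean(ps$mu)
  u_split <- mean(pu$mu)
  modes <- paste0(ifelse(s > s_split, "H", "L"),
                  ifelse(u > u_split, "H", "L"))
  list(
    modes = modes, commuting = modes == "HL",
    delimiters = c(speed_split = mean(ps$mu), turn_split = mean(pu$mu)),
    params = list(speed = ps, turn = pu, weights = w),
    loglik_trace = loglik,
    converged = converged, degenerate = FALSE
  )
}

#' @export
print.embc_fit <- function(x, ...) {
  cat(sprintf("EMbC fit: %d points, splits speed %.2f m/s, turn %.2f rad%s\n",
              length(x$modes), x$delimiters[1], x$delimiters[2],
              if (x$degenerate) " (degenerate)" else ""))
  print(table(x$modes))
  invisible(x)
}

#' Modal smoothing of mode labels
#'
#' Replaces each label by the modal label in a centered window of
#' `window` fixes, to absorb single-fix mode flickers; ties keep the
#' original label.
#'
#' @param modes Character vector of mode labels.
#' @param window Odd window size >= 1 (default 3); 1 is the identity.
#' @return Smoothed label vector.
#' @export
smooth_modes <- function(modes, window = 3) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd, >= 1", call. = FALSE)
  if (window == 1 || length(modes) < 2) return(modes)
  half <- (window - 1) / 2
  n <- length(modes)
  out <- modes
  for (i in seq_len(n)) {
    w <- modes[max(1, i - half):min(n, i + half)]
    tab <- table(w)
    best <- names(tab)[tab == max(tab)]
    if (length(best) == 1) out[i] <- best
    ## ties keep the original label
  }
  out
}

#' Annotate fixes of segmented trips with movement modes
#'
#' Derives kinematics per trip, pools the points per bird (clustering is
#' fit per bird so individual gait differences do not bleed across
#' animals), fits [embc_fit()], smooths per trip and flags commuting
#' (HL) fixes.
#'
#' @param trips A `gull_trips` object (kept trips with >= 3 fixes are
#'   annotated; others get NA modes).
#' @param seed Integer seed.
#' @param window Smoothing window (default 3).
#' @return The `gull_trips` object with `speed`, `turn`, `mode`,
#'   `commuting` columns added to `$fixes`.
#' @export
annotate_movement_modes <- function(trips, seed = 1L, window = 3) {
  stopifnot(inherits(trips, "gull_trips"))
  fx <- trips$fixes
  fx$speed <- NA_real_; fx$turn <- NA_real_
  fx$mode <- NA_character_; fx$commuting <- NA
  kept_ids <- trips$trips$trip_id[trips$trips$kept]
  for (id in kept_ids) {
    idx <- which(fx$trip_id == id)
    if (length(idx) < 3) next
    kin <- derive_kinematics(fx[idx, ])
    fx$speed[idx] <- kin$speed
    fx$turn[idx] <- kin$turn
  }
  for (bird in unique(fx$bird_id)) {
    idx <- which(fx$bird_id == bird & !is.na(fx$speed))
    if (length(idx) < 8) next
    fit <- embc_fit(fx[idx, c("speed", "turn")], seed = seed)
    fx$mode[idx] <- fit$modes
    for (id in unique(fx$trip_id[idx])) {
      tix <- idx[fx$trip_id[idx] == id]
      fx$mode[tix] <- smooth_modes(fx$mode[tix], window)
    }
  }
  fx$commuting <- fx$mode == "HL"
  trips$fixes <- fx
  trips
}
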
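## Simulation configuration: measurement regime, behavior-dependent
## speed and acceleration statistics, and dropout rates.
##
## Defaults emulate a solar GPS/accelerometer tracker on a breeding
## herring gull: fixes every 10 min inside the breeding territory and
## every 5 min away, a 20 Hz x 1 s tri-axial burst after each fix, and
## a ~969 g bird (which puts hourly BMR near 19.6 kJ/h). Behavior speeds
## are editorial except walking (0.4 m/s, the tracked-gull average):
## flapping ~11 m/s, soaring ~8 m/s, inactive ~0.

#' Default behavior speed means (m/s)
#' @return Named numeric over the 11 fine behaviors.
#' @export
default_speed_means <- function() {
  c("sit" = 0, "stand" = 0, "float" = 0.1,
    "terrestrial-locomotion" = 0.4, "look-for-food-moving" = 0.4,
    "look-for-food-standing" = 0.05, "handle-prey" = 0.05,
    "soar" = 8, "manoeuvre" = 6,
    "flap" = 11, "extreme-flap" = 13)
}

#' Default per-behavior acceleration parameters
#'
#' For each fine behavior: static per-axis means (surge, sway, heave in
#' g), white-noise sd (g), dominant heave frequency (Hz) and heave
#' oscillation amplitude (g). Parameter vectors are well separated
#' between behaviors (mean gaps are several noise sds), emulating the
#' separability that makes accelerometer behavior classification work.
#'
#' @return Named list over the 11 fine behaviors, each with `mean`
#'   (length 3), `sd`, `freq`, `amp`.
#' @export
default_acc_params <- function() {
  p <- function(mean, sd, freq, amp) list(mean = mean, sd = sd,
                                          freq = freq, amp = amp)
  list(
    "sit" = p(c(0.05, 0.00, 0.95), 0.02, 0, 0),
    "stand" = p(c(0.35, 0.00, 1.00), 0.03, 0, 0),
    "float" = p(c(0.15, 0.00, 0.98), 0.04, 1, 0.10),
    "terrestrial-locomotion" = p(c(0.30, 0.05, 1.00), 0.08, 2, 0.25),
    "look-for-food-moving" = p(c(0.10, 0.05, 1.00), 0.10, 2, 0.12),
    "look-for-food-standing" = p(c(0.55, 0.00, 1.00), 0.06, 0, 0),
    "handle-prey" = p(c(0.20, 0.10, 1.05), 0.15, 3, 0.15),
    "soar" = p(c(-0.20, 0.00, 1.00), 0.04, 0, 0),
    "manoeuvre" = p(c(-0.10, 0.15, 1.05), 0.10, 1, 0.20),
    "flap" = p(c(0.00, 0.00, 1.00), 0.10, 4, 0.60),
    "extreme-flap" = p(c(0.10, 0.00, 1.10), 0.15, 6, 1.00)
  )
}

#' Simulation configuration
#'
#' @param seed Integer seed.
#' @param nest_xy Nest coordinates (projected m); NULL = landscape nest.
#' @param fix_interval_colony Fix interval at the colony (s, default 600).
#' @param fix_interval_away Fix interval away (s, default 300).
#' @param burst_rate Burst sampling rate (Hz, default 20).
#' @param burst_length Burst duration (s, default 1).
#' @param behavior_speed_means Named m/s per fine behavior.
#' @param behavior_acc_params Named list per fine behavior (see
#'   [default_acc_params()]); must cover all 11 fine behaviors.
#' @param gap_prob Probability that an away fix is dropped (fix
#'   deletion, so downstream gap filters are exercisable); default 0.
#' @param acc_gap_prob Probability that a retained fix lacks its burst;
#'   default 0.
#' @param mass_g Body mass (g, default 969).
#' @param mass_sd Between-bird mass sd (g) used by
#'   [simulate_bird_days()]; default 85 (keeps hourly BMR near
#'   19.6 +/- 1.3 kJ/h across birds).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, nest_xy = NULL,
                       fix_interval_colony = 600, fix_interval_away = 300,
                       burst_rate = 20, burst_length = 1,
                       behavior_speed_means = default_speed_means(),
                       behavior_acc_params = default_acc_params(),
                       gap_prob = 0, acc_gap_prob = 0,
                       mass_g = 969, mass_sd = 85) {
  for (v in c(fix_interval_colony, fix_interval_away, burst_rate,
              burst_length, mass_g)) {
    if (!is.numeric(v) || v <= 0) stop("intervals, rates and mass must be > 0",
                                       call. = FALSE)
  }
  for (pr in c(gap_prob, acc_gap_prob)) {
    if (pr < 0 || pr > 1) stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  missing <- setdiff(fine_behaviors(), names(behavior_acc_params))
  if (length(missing)) {
    stop("behavior_acc_params missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    seed = seed, nest_xy = nest_xy,
    fix_interval_colony = fix_interval_colony,
    fix_interval_away = fix_interval_away,
    burst_rate = burst_rate, burst_length = burst_length,
    behavior_speed_means = behavior_speed_means,
    behavior_acc_params = behavior_acc_params,
    gap_prob = gap_prob, acc_gap_prob = acc_gap_prob,
    mass_g = mass_g, mass_sd = mass_sd
  ), class = "sim_config")
}

#' Simulate one acceleration burst
#'
#' Heave carries the behavior's oscillation (amplitude `amp` at
#' frequency `freq`) on top of its static mean; all axes get white
#' noise. Inactive behaviors are low-noise around a ~1 g resultant;
#' flapping behaviors show strong periodic heave.
#'
#' @param behavior One of the 11 fine behavior labels.
#' @param config A [sim_config()].
#' @param seed Integer seed, or NULL to draw from the current RNG
#'   stream.
#' @return 3 x n matrix (surge, sway, heave rows) in g.
#' @export
simulate_acc_burst <- function(behavior, config = sim_config(), seed = NULL) {
  p <- config$behavior_acc_params[[behavior]]
  if (is.null(p)) stop("unknown behavior label: ", behavior, call. = FALSE)
  gen <- function() {
    n <- round(config$burst_rate * config$burst_length)
    tt <- (seq_len(n) - 1) / config$burst_rate
    phase <- runif(1, 0, 2 * pi)
    m <- matrix(rnorm(3 * n, sd = p$sd), 3, n) + p$mean
    m[3, ] <- m[3, ] + p$amp * sin(2 * pi * p$freq * tt + phase)
    rownames(m) <- burst_axes
    m
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
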
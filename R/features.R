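## Burst-level feature extraction for behavior classification.
##
## A burst is a short tri-axial acceleration recording (default 20 Hz for
## 1 s, i.e. a 3 x 20 matrix in g-units with rows surge, sway, heave)
## taken directly after a GPS fix. Features summarize static posture
## (per-axis means), movement intensity (per-axis sd, min, max and ODBA)
## and wingbeat periodicity (dominant heave frequency and its share of
## spectral power).

burst_axes <- c("surge", "sway", "heave")

#' Extract features from one acceleration burst
#'
#' @param burst Numeric 3 x n matrix (n >= 2), rows surge/sway/heave,
#'   values in g.
#' @param rate_hz Sampling rate of the burst (Hz); default 20.
#' @return A 1-row data frame: per-axis `mean`, `sd`, `min`, `max`
#'   (columns like `heave_sd`), `odba` (sum over axes of mean absolute
#'   deviation from the axis mean), `dom_freq_hz` (dominant heave
#'   frequency from a periodogram; 0 for a constant burst) and
#'   `dom_power_frac` (fraction of heave spectral power at that
#'   frequency).
#' @examples
#' b <- rbind(0, 0, sin(2 * pi * 4 * (0:19) / 20))
#' extract_features(b)$dom_freq_hz  # 4
#' @export
extract_features <- function(burst, rate_hz = 20) {
  if (!is.matrix(burst) || nrow(burst) != 3 || ncol(burst) < 2) {
    stop("`burst` must be a 3 x n matrix with n >= 2", call. = FALSE)
  }
  out <- list()
  for (i in 1:3) {
    v <- burst[i, ]
    ax <- burst_axes[i]
    out[[paste0(ax, "_mean")]] <- mean(v)
    out[[paste0(ax, "_sd")]] <- sd(v)
    out[[paste0(ax, "_min")]] <- min(v)
    out[[paste0(ax, "_max")]] <- max(v)
  }
  out$odba <- sum(apply(burst, 1, function(v) mean(abs(v - mean(v)))))
  sp <- heave_spectrum(burst[3, ], rate_hz)
  out$dom_freq_hz <- sp$dom_freq
  out$dom_power_frac <- sp$power_frac
  as.data.frame(out)
}

## Periodogram of the (demeaned) heave axis; returns the frequency bin
## with maximum power and its power share. A constant signal has no
## power anywhere and reports frequency 0.
heave_spectrum <- function(v, rate_hz) {
  n <- length(v)
  v <- v - mean(v)
  if (all(abs(v) < 1e-12)) return(list(dom_freq = 0, power_frac = 0))
  pw <- Mod(fft(v))^2 / n
  k <- seq_len(floor(n / 2))          # positive frequencies
  pw <- pw[k + 1]
  freqs <- k * rate_hz / n
  i <- which.max(pw)
  list(dom_freq = freqs[i], power_frac = pw[i] / sum(pw))
}

#' Extract features for a table of bursts
#'
#' @param bursts Burst table as produced by the synthetic generator or
#'   read from CSV: columns `bird_id`, `t`, `axis`
#'   (surge/sway/heave) and sample columns `s1`, `s2`, ... (g-units).
#' @param rate_hz Sampling rate (Hz).
#' @return Data frame keyed by `bird_id`, `t` with one feature row per
#'   burst.
#' @export
extract_features_table <- function(bursts, rate_hz = 20) {
  scols <- grep("^s[0-9]+$", names(bursts), value = TRUE)
  if (!length(scols)) stop("no sample columns (s1, s2, ...) found", call. = FALSE)
  key <- paste(bursts$bird_id, bursts$t)
  out <- lapply(split(seq_len(nrow(bursts)), key), function(idx) {
    rows <- bursts[idx, , drop = FALSE]
    m <- as.matrix(rows[match(burst_axes, rows$axis), scols])
    cbind(data.frame(bird_id = rows$bird_id[1], t = rows$t[1]),
          extract_features(unname(m), rate_hz))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$bird_id, out$t), , drop = FALSE]
}
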
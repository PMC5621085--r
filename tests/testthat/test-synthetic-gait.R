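test_that("default configuration carries the experimental constants", {
  cfg <- build_default_config(1)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$n_emg_channels, 7L)
  expect_equal(cfg$n_mech_channels, 6L)
  expect_equal(cfg$sample_rate, 1000)
  expect_equal(dim(cfg$envelope_table), c(5, 5, 7))
  expect_true(all(cfg$envelope_table >= 0))
  expect_length(cfg$mode_sequence, 9)
  expect_identical(build_default_config(1), build_default_config(1))
  expect_false(identical(build_default_config(1)$envelope_table,
                         build_default_config(2)$envelope_table))
})

test_that("drift schedules advance the state with the stated semantics", {
  st <- drift_state()
  none <- drift_schedule("none")
  expect_identical(advance_drift(st, none, 1), st)

  zero <- drift_schedule("gradual", gradual_rate = 0)
  expect_identical(advance_drift(st, zero, 3), st)

  ab <- drift_schedule("abrupt", abrupt_trial_index = 6, gradual_rate = 0,
                       seed = 2)
  expect_identical(advance_drift(st, ab, 3), st)
  stepped <- advance_drift(st, ab, 6)
  expect_equal(stepped$amp_scale, st$amp_scale * ab$abrupt_magnitude$amp)
  expect_equal(stepped$offset_mech,
               st$offset_mech + ab$abrupt_magnitude$offset_mech)

  expect_error(advance_drift(st, none, 0), "trial_index")
})

test_that("gradual drift moves amplitude scales monotonically per channel", {
  sch <- drift_schedule("gradual", gradual_rate = 0.05, seed = 11)
  st <- drift_state()
  path <- matrix(NA_real_, 8, 7)
  for (k in 1:8) {
    st <- advance_drift(st, sch, k)
    path[k, ] <- st$amp_scale
  }
  for (ch in 1:7) {
    d <- diff(log(path[, ch]))
    expect_true(all(d > 0) || all(d < 0))
  }
})

test_that("generated trials have consistent labels and transition events", {
  trial <- tiny_trial()
  expect_equal(nrow(trial$transition_events), 8)
  # mode labels change exactly at the recorded transition samples
  n <- length(trial$mode_labels)
  changes <- which(trial$mode_labels[-1] != trial$mode_labels[-n]) + 1L
  expect_identical(changes, as.integer(trial$transition_events$sample))
  # phases cycle 1..5 (each phase-1 onset follows a phase-5 sample)
  ph <- trial$phase_labels
  steps <- unique(cbind(ph[-n], ph[-1]))
  ok <- steps[, 1] == steps[, 2] |
    steps[, 2] == steps[, 1] + 1L |
    (steps[, 1] == 5L & steps[, 2] == 1L)
  expect_true(all(ok))
  # every transition sits at a phase-1 onset
  expect_true(all(ph[trial$transition_events$sample] == 1L))
})

test_that("trial generation is deterministic and responds to drift scaling", {
  cfg <- build_default_config(3, cycles_per_mode = 2L)
  t1 <- generate_trial(cfg, seed = 7)
  t2 <- generate_trial(cfg, seed = 7)
  expect_identical(t1, t2)

  # with a negligible noise floor, doubling a channel's amplitude scale
  # doubles that channel's sample s.d. and leaves the others untouched
  cfg_q <- build_default_config(3, cycles_per_mode = 2L, noise_floor = 0.02)
  tq <- generate_trial(cfg_q, seed = 7)
  dr <- drift_state(amp_scale = c(2, rep(1, 6)))
  td <- generate_trial(cfg_q, dr, seed = 7)
  ratio <- sd(td$emg[, 1]) / sd(tq$emg[, 1])
  expect_lt(abs(ratio - 2) / 2, 0.05)
  expect_lt(abs(sd(td$emg[, 2]) / sd(tq$emg[, 2]) - 1), 0.05)
})

test_that("sessions have the protocol shape and derive from one seed", {
  cfg <- build_default_config(5, cycles_per_mode = 2L)
  ses <- generate_session(cfg, drift_schedule("none"), 3, 10)
  expect_length(ses$training, 3)
  expect_length(ses$testing, 10)
  expect_length(generate_session(cfg, drift_schedule("none"), 3, 0)$testing, 0)
  ses2 <- generate_session(cfg, drift_schedule("none"), 3, 10)
  expect_identical(ses, ses2)
})

test_that("stationary trials are statistically exchangeable", {
  cfg <- build_default_config(6, cycles_per_mode = 2L)
  ses <- generate_session(cfg, drift_schedule("none"), 1, 3)
  sds <- sapply(ses$testing, function(tr) apply(tr$emg, 2, sd))
  # per-channel s.d. ratios across trials stay near 1
  for (ch in 1:7) {
    r <- sds[ch, ] / mean(sds[ch, ])
    expect_true(all(abs(r - 1) < 0.15))
  }
})
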
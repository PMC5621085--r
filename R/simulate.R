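#' @keywords internal
"_PACKAGE"

#' Locomotion mode codes
#'
#' The five ambulation tasks recognised by the system: level-ground walking
#' (`W`), ramp ascent (`RA`), ramp descent (`RD`), stair ascent (`SA`) and
#' stair descent (`SD`).
#' @export
lmr_modes <- c("W", "RA", "RD", "SA", "SD")

#' Number of gait phases per cycle
#'
#' The gait cycle is segmented into five controller-defined phases; by the
#' simulator's convention phases 1-3 are stance (1 = initial double support at
#' foot contact, 2 = single stance, 3 = terminal double support) and 4-5 are
#' swing.
#' @export
lmr_n_phases <- 5L

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All simulator randomness flows through this.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream of sub-seeds (< 2^31) derived from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Build the default simulation configuration
#'
#' Creates a [simulation_config()] with the experimental constants of the
#' study design this simulator emulates: 7 EMG channels and 6 load-cell
#' channels sampled at 1000 Hz, five locomotion modes, five gait phases, and
#' the 9-segment task sequence W-SA-W-SD-W-RA-W-RD-W (8 mode transitions per
#' trial). Mode/phase-specific EMG activation envelopes and mechanical
#' profiles are drawn deterministically from `seed` so that the five modes
#' are moderately separable in feature space.
#'
#' @param seed Integer master seed; drives envelope/profile generation and
#'   every per-trial random draw derived from this config.
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config` object.
#' @export
build_default_config <- function(seed, ...) {
  simulation_config(seed = seed, ...)
}

#' Simulation configuration
#'
#' Full constructor for the synthetic gait-signal generator. The defaults are
#' the package's standard operating point: amplitude envelopes are drawn as a
#' shared per-(phase, channel) activation pattern plus mode-specific
#' deviations scaled by `mode_separation`, which places a static classifier
#' in the mid-90s accuracy regime without drift.
#'
#' @param seed Integer master seed.
#' @param n_emg_channels,n_mech_channels Channel counts (defaults 7 and 6).
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @param mode_sequence Ordered character vector of locomotion modes executed
#'   in one trial. Default is the 9-segment sequence with 8 transitions.
#' @param cycles_per_mode Gait cycles spent in each segment of the sequence.
#' @param phase_durations_ms Nominal duration of each of the 5 gait phases in
#'   ms; jittered per cycle by `phase_jitter`.
#' @param phase_jitter Fractional uniform jitter applied to each phase
#'   duration per cycle (default 0.1, i.e. +/-10%).
#' @param mode_separation Scale of mode-specific envelope and load-profile
#'   deviations around the shared per-(phase, channel) patterns; larger
#'   values make modes easier to tell apart.
#' @param cycle_variability Log-normal s.d. of the per-gait-cycle amplitude
#'   factor applied to each channel (stride-to-stride variability).
#' @param noise_floor Baseline (envelope-independent) EMG noise amplitude, in
#'   the same arbitrary units as the envelopes.
#' @param emg_band Pass band (Hz) of the band-limited EMG carrier noise.
#' @param mech_noise_sd Additive white-noise s.d. on mechanical channels.
#' @return A `simulation_config` object (a classed list).
#' @export
simulation_config <- function(seed,
                              n_emg_channels = 7L,
                              n_mech_channels = 6L,
                              sample_rate = 1000,
                              mode_sequence = c("W", "SA", "W", "SD", "W",
                                                "RA", "W", "RD", "W"),
                              cycles_per_mode = 3L,
                              phase_durations_ms = rep(80, 5),
                              phase_jitter = 0.1,
                              mode_separation = 0.11,
                              cycle_variability = 0.1,
                              noise_floor = 0.4,
                              emg_band = c(20, 400),
                              mech_noise_sd = 0.3) {
  stopifnot(length(phase_durations_ms) == lmr_n_phases,
            all(phase_durations_ms > 0),
            all(mode_sequence %in% lmr_modes),
            n_emg_channels >= 1, n_mech_channels >= 1,
            sample_rate > 2 * emg_band[2])
  seed <- as.integer(seed)
  sub <- derive_seeds(seed, 2L)

  # Rows are mode-deviation patterns; orthonormalising them (then rescaling
  # to the norm of a typical Gaussian draw) guarantees the five modes are
  # pairwise separable in expectation for every seed, instead of relying on
  # random draws staying apart.
  ortho_rows <- function(n_rows, n_cols) {
    M <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    Q <- t(qr.Q(qr(t(M))))[seq_len(n_rows), , drop = FALSE]
    Q * sqrt(n_cols)
  }

  # Envelope table: modes x phases x emg channels, all >= 0. A shared
  # per-(phase, channel) activation pattern makes phases heterogeneous; the
  # mode-specific deviation (scaled by mode_separation) carries the class
  # information.
  env <- with_seed(sub[1], {
    common <- matrix(stats::runif(lmr_n_phases * n_emg_channels, 0.6, 2.0),
                     lmr_n_phases, n_emg_channels)
    dev <- ortho_rows(5L, lmr_n_phases * n_emg_channels)
    a <- array(0, dim = c(5, lmr_n_phases, n_emg_channels),
               dimnames = list(lmr_modes, NULL, NULL))
    for (m in 1:5) {
      dm <- matrix(dev[m, ], lmr_n_phases, n_emg_channels)
      a[m, , ] <- pmax(common * (1 + mode_separation * dm), 0.05)
    }
    a
  })

  # Mechanical profiles: a shared per-channel load profile (offset plus two
  # phase-locked harmonics of the gait cycle) with mode-specific deviations
  # of the same relative magnitude as the EMG envelope deviations, so the
  # modes overlap realistically in both signal families.
  mech <- with_seed(sub[2], {
    dimn <- list(lmr_modes, NULL)
    base_off <- stats::rnorm(n_mech_channels, 0, 0.8)
    base_a1 <- stats::runif(n_mech_channels, 0.5, 1.2)
    base_p1 <- stats::runif(n_mech_channels, 0, 2 * pi)
    base_a2 <- stats::runif(n_mech_channels, 0.2, 0.6)
    base_p2 <- stats::runif(n_mech_channels, 0, 2 * pi)
    D <- ortho_rows(5L, 5L * n_mech_channels)  # joint deviation patterns
    dev <- function(j) matrix(D[, ((j - 1) * n_mech_channels + 1):
                                   (j * n_mech_channels)], 5,
                              n_mech_channels, dimnames = dimn)
    rowmat <- function(v) matrix(v, 5, n_mech_channels, byrow = TRUE,
                                 dimnames = dimn)
    list(
      offset = rowmat(base_off) + mode_separation * dev(1),
      amp1   = pmax(rowmat(base_a1) * (1 + mode_separation * dev(2)), 0.05),
      phi1   = rowmat(base_p1) + mode_separation * dev(3),
      amp2   = pmax(rowmat(base_a2) * (1 + mode_separation * dev(4)), 0.02),
      phi2   = rowmat(base_p2) + mode_separation * dev(5)
    )
  })

  structure(list(
    seed = seed,
    n_emg_channels = as.integer(n_emg_channels),
    n_mech_channels = as.integer(n_mech_channels),
    sample_rate = sample_rate,
    mode_sequence = mode_sequence,
    cycles_per_mode = as.integer(cycles_per_mode),
    phase_durations_ms = phase_durations_ms,
    phase_jitter = phase_jitter,
    mode_separation = mode_separation,
    cycle_variability = cycle_variability,
    noise_floor = noise_floor,
    emg_band = emg_band,
    mech_noise_sd = mech_noise_sd,
    envelope_table = env,
    mech_profile_table = mech
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> seed", x$seed, "|", x$n_emg_channels, "EMG +",
      x$n_mech_channels, "mech @", x$sample_rate, "Hz |",
      length(x$mode_sequence), "segments x", x$cycles_per_mode, "cycles\n")
  invisible(x)
}

#' Signal-drift state
#'
#' Describes the current deviation of the recording conditions from those of
#' the initial training session: per-EMG-channel amplitude scaling (electrode
#' shift / impedance analog), baseline-noise scaling, a fractional shift of
#' the EMG carrier's upper band corner (tissue filtering analog), and
#' additive biases on the mechanical channels (load-cell mounting analog).
#' The identity state (all scales 1, biases 0, shift 0) reproduces training
#' conditions.
#'
#' @param n_emg,n_mech Channel counts.
#' @param amp_scale Per-EMG-channel amplitude multipliers (> 0).
#' @param baseline_noise_scale Baseline-noise multiplier (> 0).
#' @param spectral_shift Fractional change of the carrier's upper corner;
#'   bounded below so the band stays valid.
#' @param offset_mech Additive bias per mechanical channel.
#' @return A `drift_state` object.
#' @export
drift_state <- function(n_emg = 7L, n_mech = 6L,
                        amp_scale = rep(1, n_emg),
                        baseline_noise_scale = 1,
                        spectral_shift = 0,
                        offset_mech = rep(0, n_mech)) {
  stopifnot(all(amp_scale > 0), baseline_noise_scale > 0,
            spectral_shift > -0.9,
            length(amp_scale) == n_emg, length(offset_mech) == n_mech)
  structure(list(amp_scale = amp_scale,
                 baseline_noise_scale = baseline_noise_scale,
                 spectral_shift = spectral_shift,
                 offset_mech = offset_mech),
            class = "drift_state")
}

is_identity_drift <- function(state) {
  all(state$amp_scale == 1) && state$baseline_noise_scale == 1 &&
    state$spectral_shift == 0 && all(state$offset_mech == 0)
}

#' Drift schedule
#'
#' Describes how the [drift_state()] evolves over a testing session.
#' `"none"` keeps recording conditions stationary; `"gradual"` emulates the
#' slow per-trial signal variation of a user adapting to the device
#' (per-channel amplitude drift with persistent direction, growing baseline
#' noise, a slow spectral shift and creeping mechanical biases); `"abrupt"`
#' applies a single step change at `abrupt_trial_index`, emulating a socket
#' don/doff plus temperature change during a session break.
#'
#' @param kind One of `"none"`, `"gradual"`, `"abrupt"`.
#' @param gradual_rate Per-trial fractional amplitude change (>= 0). The
#'   default is calibrated so that a non-adaptive classifier loses roughly
#'   5-10 accuracy points over 10 trials, the qualitative regime the package
#'   targets.
#' @param abrupt_trial_index Trial index at which the step applies.
#' @param abrupt_magnitude Optional list with elements `amp` (per-channel
#'   multipliers), `noise` (multiplier), `spectral` (additive shift) and
#'   `offset_mech` (additive biases); drawn from `seed` when `NULL`.
#' @param seed Integer seed for drift-direction and jitter draws.
#' @param n_emg,n_mech Channel counts (used for drawn defaults).
#' @return A `drift_schedule` object.
#' @export
drift_schedule <- function(kind = c("none", "gradual", "abrupt"),
                           gradual_rate = 0.015,
                           abrupt_trial_index = 6L,
                           abrupt_magnitude = NULL,
                           seed = 1L, n_emg = 7L, n_mech = 6L) {
  kind <- match.arg(kind)
  stopifnot(gradual_rate >= 0, abrupt_trial_index >= 1)
  seed <- as.integer(seed)
  # Persistent per-channel drift directions so gradual drift is monotone in
  # expectation rather than a random walk.
  dirs <- with_seed(seed, list(
    amp = sample(c(-1, 1), n_emg, replace = TRUE),
    mech = sample(c(-1, 1), n_mech, replace = TRUE)
  ))
  if (kind == "abrupt" && is.null(abrupt_magnitude)) {
    # The step leans on components whose effect is uniform across envelope
    # geometries (baseline noise, spectral shift) plus a fixed-size
    # random-direction amplitude/bias shift, so the severity of the don/doff
    # analog is consistent across seeds rather than a lottery.
    abrupt_magnitude <- with_seed(seed + 1L, list(
      amp = exp(sample(c(-1, 1), n_emg, TRUE) * 0.05 *
                  stats::runif(n_emg, 0.9, 1.1)),
      noise = 1.6,
      spectral = -0.12,
      offset_mech = sample(c(-1, 1), n_mech, TRUE) * 0.12
    ))
  }
  structure(list(kind = kind, gradual_rate = gradual_rate,
                 abrupt_trial_index = as.integer(abrupt_trial_index),
                 abrupt_magnitude = abrupt_magnitude,
                 seed = seed, directions = dirs),
            class = "drift_schedule")
}

#' Advance the drift state to the next trial
#'
#' Applies one step of the schedule. `kind = "none"` returns the state
#' unchanged; `"gradual"` multiplies each EMG amplitude scale by
#' `1 + rate * direction * u` with seeded per-channel jitter `u`, inflates
#' the baseline noise, shifts the carrier corner and lets mechanical biases
#' creep; `"abrupt"` applies the step bundle only when
#' `trial_index == abrupt_trial_index`.
#'
#' @param state A [drift_state()].
#' @param schedule A [drift_schedule()].
#' @param trial_index Testing-trial index being advanced to (>= 1).
#' @return The updated `drift_state`.
#' @export
advance_drift <- function(state, schedule, trial_index) {
  stopifnot(inherits(state, "drift_state"),
            inherits(schedule, "drift_schedule"))
  if (trial_index < 1) stop("trial_index must be >= 1")
  if (schedule$kind == "none" || (schedule$kind == "gradual" &&
                                  schedule$gradual_rate == 0))
    return(state)
  if (schedule$kind == "gradual") {
    n_emg <- length(state$amp_scale)
    n_mech <- length(state$offset_mech)
    jit <- with_seed(schedule$seed + 7919L * as.integer(trial_index), list(
      amp = stats::runif(n_emg, 0.8, 1.2),
      mech = stats::runif(n_mech, 0.8, 1.2)
    ))
    rate <- schedule$gradual_rate
    state$amp_scale <- state$amp_scale *
      (1 + rate * schedule$directions$amp * jit$amp)
    state$baseline_noise_scale <- state$baseline_noise_scale * (1 + rate)
    state$spectral_shift <- max(state$spectral_shift - 1.5 * rate, -0.6)
    state$offset_mech <- state$offset_mech +
      0.6 * rate * schedule$directions$mech * jit$mech
    return(state)
  }
  # abrupt: identity before the break, the step bundle at the break, and
  # continued slow signal variation afterwards (a re-donned socket keeps
  # settling; temperature and moisture keep changing).
  if (trial_index == schedule$abrupt_trial_index) {
    mag <- schedule$abrupt_magnitude
    state$amp_scale <- state$amp_scale * mag$amp
    state$baseline_noise_scale <- state$baseline_noise_scale * mag$noise
    state$spectral_shift <- max(state$spectral_shift + mag$spectral, -0.6)
    state$offset_mech <- state$offset_mech + mag$offset_mech
  } else if (trial_index > schedule$abrupt_trial_index &&
             schedule$gradual_rate > 0) {
    grad <- schedule
    grad$kind <- "gradual"
    state <- advance_drift(state, grad, trial_index)
  }
  state
}

# Band-limited unit-variance Gaussian carrier. The upper corner moves with
# the drift state's spectral shift.
emg_carrier <- function(n, rate, band, spectral_shift) {
  hi <- min(band[2] * (1 + spectral_shift), 0.95 * rate / 2)
  hi <- max(hi, band[1] * 1.5)
  bf <- signal::butter(4, c(band[1], hi) / (rate / 2), type = "pass")
  y <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  y / stats::sd(y)
}

#' Generate one synthetic trial
#'
#' Simulates one continuous multichannel recording of the configured task
#' sequence under the given drift state. EMG channel `c` during (mode m,
#' phase p) is `envelope[m, p, c] * amp_scale[c] * carrier + noise_floor *
#' baseline_noise_scale * white`, where the carrier is band-limited Gaussian
#' noise; mechanical channels follow the mode's smooth periodic profile plus
#' drift bias and white noise. Mode changes occur at phase-1 onsets (foot
#' contact), so each segment boundary is a well-defined transition event.
#'
#' @param config A [simulation_config()].
#' @param drift A [drift_state()]; defaults to identity.
#' @param seed Integer seed for this trial's noise and phase-jitter draws.
#' @return A `trial_recording`: list with `emg` (samples x channels matrix),
#'   `mech` (samples x channels), `phase_labels`, `mode_labels` (character),
#'   `cycle_pos` (position in cycle, `[0, 1)`), `transition_events`
#'   (data.frame `sample`, `from`, `to`), and `sample_rate`.
#' @export
generate_trial <- function(config, drift = NULL, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(drift))
    drift <- drift_state(config$n_emg_channels, config$n_mech_channels)
  if (length(config$mode_sequence) == 0) stop("empty mode_sequence")

  rate <- config$sample_rate
  with_seed(seed, {
    # Lay out phases cycle by cycle with jittered durations.
    phase <- integer(0); pos <- numeric(0); cycle_idx <- integer(0)
    mode_lab <- character(0); trans <- list()
    n_before <- 0L; n_cycles <- 0L
    for (s in seq_along(config$mode_sequence)) {
      m <- config$mode_sequence[s]
      if (s > 1) {
        trans[[length(trans) + 1L]] <- data.frame(
          sample = n_before + 1L,
          from = config$mode_sequence[s - 1], to = m,
          stringsAsFactors = FALSE)
      }
      for (cy in seq_len(config$cycles_per_mode)) {
        dur <- config$phase_durations_ms *
          stats::runif(lmr_n_phases, 1 - config$phase_jitter,
                       1 + config$phase_jitter)
        nsamp <- pmax(1L, as.integer(round(dur * rate / 1000)))
        ph <- rep.int(seq_len(lmr_n_phases), nsamp)
        ncyc <- length(ph)
        n_cycles <- n_cycles + 1L
        phase <- c(phase, ph)
        pos <- c(pos, (seq_len(ncyc) - 1) / ncyc)
        cycle_idx <- c(cycle_idx, rep.int(n_cycles, ncyc))
        mode_lab <- c(mode_lab, rep.int(m, ncyc))
        n_before <- n_before + ncyc
      }
    }
    n <- length(phase)
    transition_events <- if (length(trans)) do.call(rbind, trans) else
      data.frame(sample = integer(0), from = character(0), to = character(0))

    # EMG: envelope x stride-to-stride factor x band-limited carrier,
    # plus baseline noise.
    emg <- matrix(0, n, config$n_emg_channels)
    mode_idx <- match(mode_lab, lmr_modes)
    cv <- config$cycle_variability
    for (ch in seq_len(config$n_emg_channels)) {
      carrier <- emg_carrier(n, rate, config$emg_band, drift$spectral_shift)
      cyc_fac <- exp(stats::rnorm(n_cycles, 0, cv))[cycle_idx]
      envel <- config$envelope_table[cbind(mode_idx, phase, ch)] * cyc_fac
      emg[, ch] <- envel * drift$amp_scale[ch] * carrier +
        config$noise_floor * drift$baseline_noise_scale * stats::rnorm(n)
    }

    # Mechanical: mode profile with per-cycle amplitude variability.
    mech <- matrix(0, n, config$n_mech_channels)
    mp <- config$mech_profile_table
    for (ch in seq_len(config$n_mech_channels)) {
      cyc_fac <- exp(stats::rnorm(n_cycles, 0, cv))[cycle_idx]
      mech[, ch] <- mp$offset[cbind(mode_idx, ch)] +
        cyc_fac * (mp$amp1[cbind(mode_idx, ch)] *
                     sin(2 * pi * pos + mp$phi1[cbind(mode_idx, ch)]) +
                   mp$amp2[cbind(mode_idx, ch)] *
                     sin(4 * pi * pos + mp$phi2[cbind(mode_idx, ch)])) +
        config$mech_noise_sd * stats::rnorm(n) + drift$offset_mech[ch]
    }

    structure(list(emg = emg, mech = mech,
                   phase_labels = phase,
                   mode_labels = mode_lab,
                   cycle_pos = pos,
                   transition_events = transition_events,
                   sample_rate = rate),
              class = "trial_recording")
  })
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("<trial_recording>", nrow(x$emg), "samples @", x$sample_rate, "Hz |",
      ncol(x$emg), "EMG +", ncol(x$mech), "mech |",
      nrow(x$transition_events), "transitions\n")
  invisible(x)
}

#' Generate a full session of trials
#'
#' Training trials are generated at identity drift (the initial training
#' session); testing trial `k` is generated with the drift state advanced
#' through schedule steps `1..k`. All per-trial seeds derive
#' deterministically from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param schedule A [drift_schedule()].
#' @param n_training_reps Number of training repetitions of the task
#'   sequence (default 3).
#' @param n_testing_trials Number of testing trials (default 10).
#' @return List with `training` and `testing` (lists of trials) and
#'   `drift_states` (the per-testing-trial states used).
#' @export
generate_session <- function(config, schedule = drift_schedule("none"),
                             n_training_reps = 3L, n_testing_trials = 10L) {
  stopifnot(n_training_reps >= 1, n_testing_trials >= 0)
  seeds <- derive_seeds(config$seed, n_training_reps + n_testing_trials)
  identity <- drift_state(config$n_emg_channels, config$n_mech_channels)
  training <- lapply(seq_len(n_training_reps), function(i)
    generate_trial(config, identity, seed = seeds[i]))
  testing <- vector("list", n_testing_trials)
  states <- vector("list", n_testing_trials)
  st <- identity
  for (k in seq_len(n_testing_trials)) {
    st <- advance_drift(st, schedule, k)
    states[[k]] <- st
    testing[[k]] <- generate_trial(config, st, seed = seeds[n_training_reps + k])
  }
  list(training = training, testing = testing, drift_states = states)
}
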
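# Shared fixtures. Heavy session-level objects are computed lazily and
# memoised for the lifetime of the test run, so several test files can share
# one simulation/training without recomputation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A small trial for windowing/feature/evaluation tests.
tiny_trial <- function(seed = 42) {
  memo(paste0("tiny_trial_", seed), {
    cfg <- build_default_config(seed, cycles_per_mode = 2L)
    generate_trial(cfg, seed = seed)
  })
}

# Hand-built zero-signal trial (known feature values).
zero_trial <- function(n = 1000) {
  ph <- rep_len(rep(1:5, each = 80), n)
  structure(list(emg = matrix(0, n, 7), mech = matrix(0, n, 6),
                 phase_labels = ph, mode_labels = rep("W", n),
                 cycle_pos = rep(0, n),
                 transition_events = data.frame(sample = integer(0),
                                                from = character(0),
                                                to = character(0)),
                 sample_rate = 1000),
            class = "trial_recording")
}

# Separable toy training set: five phases x five modes, `n_per` rows per
# cell, `d` features with a mode-specific shifted block. Easy by design.
toy_features <- function(n_per = 6, d = 10, shift = 4, seed = 99) {
  set.seed(seed)
  rows <- list()
  for (ph in 1:5) for (m in seq_along(lmr_modes)) {
    X <- matrix(rnorm(n_per * d, sd = 0.5), n_per, d)
    X[, ((m - 1) %% d) + 1] <- X[, ((m - 1) %% d) + 1] + shift
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(d))
    df$phase <- ph
    df$true_mode <- lmr_modes[m]
    df$window <- seq_len(n_per)
    df$start_sample <- seq_len(n_per)
    df$end_sample <- seq_len(n_per) + 10L
    rows[[length(rows) + 1L]] <- df
  }
  do.call(rbind, rows)
}

toy_bank <- function() {
  memo("toy_bank", {
    train_phase_bank(toy_features(),
                     search_spec(cost = 4, gamma = 0.05, seed = 1))
  })
}

# Part-1 style experiments, memoised per (seed, schedule kind).
part1_gradual <- function(seed) {
  memo(paste0("p1g_", seed), {
    cfg <- build_default_config(seed)
    run_part1_experiment(cfg, strategies = c("none", "eba", "lift"))
  })
}

part1_stationary <- function(seed) {
  memo(paste0("p1s_", seed), {
    cfg <- build_default_config(seed)
    run_part1_experiment(cfg, drift_schedule("none", seed = seed),
                         n_testing_trials = 6L)
  })
}

part2_run <- function(seed) {
  memo(paste0("p2_", seed), {
    cfg <- build_default_config(seed)
    run_part2_experiment(cfg)
  })
}

strategy_acc <- function(report, s) report$accuracy[report$strategy == s]
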
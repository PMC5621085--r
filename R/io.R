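# Trial files are plain delimited text: one row per sample with columns
# time_ms, emg_1..emg_E, mech_1..mech_M, phase, mode. Numbers are written at
# full (17 significant digit) precision so a round trip is bit-exact.

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a trial recording to a delimited-text file
#' @param trial A `trial_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  n <- nrow(trial$emg)
  time_ms <- (seq_len(n) - 1) * 1000 / trial$sample_rate
  df <- data.frame(time_ms = fmt_full(time_ms))
  for (ch in seq_len(ncol(trial$emg)))
    df[[paste0("emg_", ch)]] <- fmt_full(trial$emg[, ch])
  for (ch in seq_len(ncol(trial$mech)))
    df[[paste0("mech_", ch)]] <- fmt_full(trial$mech[, ch])
  df$phase <- trial$phase_labels
  df$mode <- trial$mode_labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial recording from a delimited-text file
#'
#' Reconstructs transition events from the mode-label column; the cycle
#' position is recovered from the phase-1 onsets.
#'
#' @param path Trial file written by [write_trial()].
#' @param sample_rate Sampling rate in Hz (default 1000); cross-checked
#'   against the time column.
#' @return A `trial_recording`.
#' @export
read_trial <- function(path, sample_rate = 1000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  emg_cols <- grep("^emg_", names(df), value = TRUE)
  mech_cols <- grep("^mech_", names(df), value = TRUE)
  n <- nrow(df)
  if (n > 1) {
    dt <- df$time_ms[2] - df$time_ms[1]
    if (abs(dt - 1000 / sample_rate) > 1e-6)
      stop("time column inconsistent with sample_rate ", sample_rate)
  }
  mode_lab <- df$mode
  ch <- which(mode_lab[-1] != mode_lab[-n]) + 1L
  transition_events <- data.frame(sample = ch,
                                  from = mode_lab[ch - 1L], to = mode_lab[ch],
                                  stringsAsFactors = FALSE)
  ph <- df$phase
  onsets <- which(ph == 1L & c(TRUE, ph[-n] != 1L))
  cyc <- findInterval(seq_len(n), onsets)
  cyc_start <- onsets[pmax(cyc, 1L)]
  nxt <- c(onsets[-1], n + 1L)
  cyc_len <- (nxt - onsets)[pmax(cyc, 1L)]
  pos <- ifelse(cyc >= 1L, (seq_len(n) - cyc_start) / cyc_len, 0)
  structure(list(emg = as.matrix(df[, emg_cols]),
                 mech = as.matrix(df[, mech_cols]),
                 phase_labels = as.integer(ph),
                 mode_labels = mode_lab,
                 cycle_pos = pos,
                 transition_events = transition_events,
                 sample_rate = sample_rate),
            class = "trial_recording")
}

#' Write a session manifest
#'
#' A JSON file listing the trial files of a session with their roles and
#' drift metadata, plus the configuration hash for provenance.
#'
#' @param trials Data.frame with columns `file`, `role`
#'   (training/testing), `trial_index` and optionally drift descriptors.
#' @param path Output path.
#' @param config_hash Provenance hash of the generating configuration.
#' @param sample_rate Session sampling rate.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(trials, path, config_hash = NA_character_,
                           sample_rate = 1000, extra = list()) {
  obj <- c(list(format = "lmradapt-manifest", version = 1L,
                config_hash = config_hash, sample_rate = sample_rate,
                trials = trials), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a session manifest
#' @param path Manifest path.
#' @return Named list with `trials` as a data.frame.
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lmradapt-manifest"))
    stop("not an lmradapt manifest: ", path)
  obj
}

#' Write per-trial decisions to delimited text
#' @param decisions Voted decision data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  utils::write.csv(decisions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a decisions file
#' @param path Path written by [write_decisions()].
#' @return Decision data.frame.
#' @export
read_decisions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Save / load a trained classifier bank
#'
#' Banks hold fitted kernel machines and are stored in R's native
#' serialization with a format/version header so compatibility can be
#' checked on load.
#'
#' @param bank A `phase_bank`.
#' @param path File path.
#' @return `path` (save) or the `phase_bank` (load).
#' @export
save_bank <- function(bank, path) {
  stopifnot(inherits(bank, "phase_bank"))
  saveRDS(list(format = "lmradapt-bank", version = bank$version, bank = bank),
          path)
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "lmradapt-bank"))
    stop("not an lmradapt bank file: ", path)
  obj$bank
}

# ---- run configuration ----

run_config_defaults <- function() {
  list(window_ms = 160, increment_ms = 20, tau = 0.6, m = 5L, vote_len = 5L,
       deadzone_frac = 0.01, strategy = "eba", seed = 1L,
       n_training_reps = 3L, n_testing_trials = 10L,
       schedule = "gradual", gradual_rate = 0.015, abrupt_trial_index = 6L,
       cycles_per_mode = 3L, mode_separation = 0.11, noise_floor = 0.4,
       experiment = "part1")
}

run_config_ranges <- list(
  window_ms = c(1, Inf), increment_ms = c(1, Inf), tau = c(0, Inf),
  m = c(1, Inf), vote_len = c(1, Inf), deadzone_frac = c(0, Inf),
  seed = c(1, .Machine$integer.max), n_training_reps = c(1, Inf),
  n_testing_trials = c(0, Inf), gradual_rate = c(0, Inf),
  abrupt_trial_index = c(1, Inf), cycles_per_mode = c(2, Inf),
  mode_separation = c(0, Inf), noise_floor = c(0, Inf)
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, range-checks numeric
#' values and fills in defaults (window 160 ms, increment 20 ms, tau 0.6,
#' m 5, vote length 5).
#'
#' @param path YAML file; an empty file yields all defaults.
#' @return A named list (class `run_config`) with a `hash` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- run_config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  for (key in names(run_config_ranges)) {
    v <- cfg[[key]]
    r <- run_config_ranges[[key]]
    if (!is.numeric(v) || length(v) != 1 || v < r[1] || v > r[2])
      stop(sprintf("config key '%s' out of range [%g, %g]: %s",
                   key, r[1], r[2], format(v)))
  }
  if (!cfg$strategy %in% c("none", "eba", "lift", "tsvm"))
    stop("config key 'strategy' must be none/eba/lift/tsvm")
  if (!cfg$schedule %in% c("none", "gradual", "abrupt"))
    stop("config key 'schedule' must be none/gradual/abrupt")
  if (!cfg$experiment %in% c("part1", "part2"))
    stop("config key 'experiment' must be part1/part2")
  if (cfg$vote_len %% 2 == 0) stop("config key 'vote_len' must be odd")
  structure(cfg, class = "run_config", hash = rlang::hash(cfg))
}

config_hash <- function(cfg) {
  h <- attr(cfg, "hash")
  if (is.null(h)) rlang::hash(unclass(cfg)) else h
}

# Provenance record written next to every CLI output.
write_provenance <- function(dir, cfg, extra = list()) {
  obj <- c(list(package = "lmradapt",
                version = as.character(utils::packageVersion("lmradapt")),
                config_hash = config_hash(cfg),
                seed = cfg$seed,
                written = "run"), extra)
  jsonlite::write_json(obj, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
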
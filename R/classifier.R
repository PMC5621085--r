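#' Fit per-feature standardization statistics
#'
#' Centers and scales by the per-feature mean and population standard
#' deviation. Zero-variance features get scale 1 (pass-through) and are
#' flagged as constant.
#'
#' @param X Numeric matrix, >= 2 rows.
#' @return An `lmr_standardizer` with `center`, `scale`, `constant`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to fit a standardizer")
  center <- colMeans(X)
  scale <- sqrt(pmax(colMeans(X^2) - center^2, 0))
  constant <- scale <= .Machine$double.eps^0.5 * pmax(abs(center), 1)
  scale[constant] <- 1
  structure(list(center = center, scale = scale, constant = constant),
            class = "lmr_standardizer")
}

#' Apply a fitted standardizer
#' @param std An `lmr_standardizer`.
#' @param X Numeric matrix with the same columns as the fit input.
#' @return The standardized matrix.
#' @export
apply_standardizer <- function(std, X) {
  sweep(sweep(as.matrix(X), 2, std$center, `-`), 2, std$scale, `/`)
}

# Platt sigmoid fit: p(y = 1 | f) = 1 / (1 + exp(a f + b)), fitted by
# Newton steps on the regularized negative log-likelihood with the
# prior-corrected targets t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2), which keep
# the fit finite on separable margin sets. Deterministic.
platt_fit <- function(margins, positive, max_iter = 200) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  t <- ifelse(positive, t_pos, t_neg)
  a <- 0; b <- log((n_neg + 1) / (n_pos + 1))
  f <- margins
  # With p = P(y = 1 | f) = 1/(1 + e^z), z = a f + b:
  #   -log p = log(1 + e^z),  -log(1 - p) = log(1 + e^z) - z,
  # so the cross-entropy is sum t*lse + (1 - t)*(lse - z), lse computed stably.
  obj <- function(par) {
    z <- par[1] * f + par[2]
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  gr <- function(par) {
    z <- par[1] * f + par[2]
    p <- 1 / (1 + exp(pmin(pmax(z, -35), 35)))
    # d/dz of objective = (1 - p) - (1 - t) = t - p ... with p = P(y=1)
    dz <- (1 - p) - (1 - t)
    c(sum(dz * f), sum(dz))
  }
  fit <- stats::optim(c(a, b), obj, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-10))
  list(a = fit$par[1], b = fit$par[2])
}

platt_apply <- function(cal, margins) {
  z <- cal$a * margins + cal$b
  1 / (1 + exp(pmin(pmax(z, -35), 35)))
}

#' Hyperparameter search specification
#'
#' Log-spaced (cost, gamma) grid searched by stratified cross-validation on
#' each phase's training data, scored by one-against-all multiclass accuracy.
#'
#' @param cost,gamma Candidate values. Defaults are a coarse 3x3 log grid
#'   centered on `gamma ~ 1/n_features`.
#' @param n_folds Stratified CV folds (default 3).
#' @param calib How the Platt calibrators are fit: `"train"` (default) on
#'   training-set margins with Platt's prior-corrected targets, or
#'   `"holdout"` on margins from a stratified held-out split (an extra
#'   round of machine fits per phase).
#' @param calib_frac Held-out fraction for `calib = "holdout"` (default 0.3).
#' @param seed Seed for fold and split assignment.
#' @param tolerance libsvm termination tolerance.
#' @return A `search_spec` object.
#' @export
search_spec <- function(cost = 2^c(0, 3, 6),
                        gamma = 2^c(-8, -6, -4),
                        n_folds = 3L, calib = c("train", "holdout"),
                        calib_frac = 0.3, seed = 1L,
                        tolerance = 0.01) {
  calib <- match.arg(calib)
  structure(list(cost = cost, gamma = gamma, n_folds = as.integer(n_folds),
                 calib = calib, calib_frac = calib_frac,
                 seed = as.integer(seed), tolerance = tolerance),
            class = "search_spec")
}

# Seeded stratified fold assignment.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

fit_binary_svms <- function(Z, y, modes, cost, gamma, tolerance) {
  lapply(stats::setNames(modes, modes), function(m) {
    lab <- factor(ifelse(y == m, "this", "rest"), levels = c("this", "rest"))
    e1071::svm(Z, lab, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE,
               tolerance = tolerance)
  })
}

# Signed decision value f(x) = sum_i coef_i K(sv_i, x) - rho of a fitted
# binary RBF machine, computed directly from the support vectors with one
# BLAS call. Equivalent to predict(..., decision.values = TRUE) (asserted in
# the test suite) but without its per-call data-frame overhead, which
# dominates the transductive loop.
svm_decision_values <- function(model, Z) {
  Z <- as.matrix(Z)
  sv <- model$SV
  d2 <- matrix(rowSums(Z^2), nrow(Z), nrow(sv)) +
    matrix(rowSums(sv^2), nrow(Z), nrow(sv), byrow = TRUE) -
    2 * Z %*% t(sv)
  dv <- as.numeric(exp(-model$gamma * pmax(d2, 0)) %*% model$coefs[, 1]) -
    model$rho
  # libsvm orients the decision value toward the first label it encounters;
  # flip if that is not the first factor level.
  if (model$labels[1] != 1L) -dv else dv
}

# Signed margins (positive = the classifier's own mode) for each of the five
# one-against-all machines; rows align with Z.
binary_margins <- function(svms, Z) {
  Z <- as.matrix(Z)
  mg <- vapply(svms, svm_decision_values, numeric(nrow(Z)), Z = Z)
  if (is.null(dim(mg))) mg <- matrix(mg, nrow = nrow(Z))
  mg
}

oaa_cv_accuracy <- function(Z, y, modes, cost, gamma, folds, tolerance) {
  pred <- character(length(y))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    svms <- fit_binary_svms(Z[tr, , drop = FALSE], y[tr], modes,
                            cost, gamma, tolerance)
    mg <- binary_margins(svms, Z[!tr, , drop = FALSE])
    pred[!tr] <- modes[max.col(mg, ties.method = "first")]
  }
  mean(pred == y)
}

# Fit one phase: standardizer, five OAA binary machines, five Platt
# calibrators. calib = "holdout" fits the sigmoids on margins from a
# stratified held-out split (an extra round of machine fits); "train" fits
# them on the training-set margins, relying on the prior-corrected Platt
# targets to damp the optimism — at half the fitting cost.
fit_phase_model <- function(X, y, modes, cost, gamma, calib_frac, seed,
                            tolerance, calib = "train") {
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  n <- nrow(Z)
  svms <- fit_binary_svms(Z, y, modes, cost, gamma, tolerance)
  if (calib == "holdout") {
    hold <- stratified_folds(y, max(2L, round(1 / calib_frac)), seed) == 1L
    if (sum(hold) < 2 || sum(!hold) < 2)
      hold <- rep(c(TRUE, FALSE), length.out = n)
    svms_tr <- fit_binary_svms(Z[!hold, , drop = FALSE], y[!hold], modes,
                               cost, gamma, tolerance)
    mg <- binary_margins(svms_tr, Z[hold, , drop = FALSE])
    yc <- y[hold]
  } else {
    mg <- binary_margins(svms, Z)
    yc <- y
  }
  cal <- lapply(seq_along(modes), function(i)
    platt_fit(mg[, i], yc == modes[i]))
  names(cal) <- modes
  list(std = std, svms = svms, calibrators = cal,
       cost = cost, gamma = gamma, n_train = n)
}

#' Train the five-phase classifier bank
#'
#' For each gait phase: standardizes that phase's training features, selects
#' (cost, gamma) by stratified cross-validated one-against-all accuracy,
#' fits five binary RBF-kernel machines (one locomotion mode vs rest) and a
#' Platt sigmoid calibrator per machine on held-out margins. Deterministic
#' given the search spec's seed.
#'
#' @param features Feature data.frame as produced by [extract_features()]
#'   (possibly row-bound over trials) with `phase` and `true_mode` columns.
#' @param spec A [search_spec()].
#' @param modes Mode label set (default [lmr_modes]).
#' @return A `phase_bank` object.
#' @export
train_phase_bank <- function(features, spec = search_spec(),
                             modes = lmr_modes) {
  stopifnot(is.data.frame(features))
  for (ph in seq_len(lmr_n_phases)) {
    present <- unique(features$true_mode[features$phase == ph])
    missing <- setdiff(modes, present)
    if (length(missing))
      stop(sprintf("training set has no samples for (phase %d, mode %s)",
                   ph, paste(missing, collapse = ",")))
  }
  X <- feature_matrix(features)
  search_record <- list()
  phases <- vector("list", lmr_n_phases)
  grid <- expand.grid(cost = spec$cost, gamma = spec$gamma)
  for (ph in seq_len(lmr_n_phases)) {
    sel <- features$phase == ph
    Xp <- X[sel, , drop = FALSE]
    yp <- features$true_mode[sel]
    std0 <- fit_standardizer(Xp)
    Zp <- apply_standardizer(std0, Xp)
    if (nrow(grid) > 1) {
      folds <- stratified_folds(yp, spec$n_folds, spec$seed + ph)
      acc <- vapply(seq_len(nrow(grid)), function(g)
        oaa_cv_accuracy(Zp, yp, modes, grid$cost[g], grid$gamma[g], folds,
                        spec$tolerance), numeric(1))
      best <- which.max(acc)  # ties resolve to the first grid entry
    } else {
      acc <- NA_real_; best <- 1L
    }
    search_record[[ph]] <- list(grid = grid, accuracy = acc, best = best)
    phases[[ph]] <- fit_phase_model(Xp, yp, modes,
                                    grid$cost[best], grid$gamma[best],
                                    spec$calib_frac, spec$seed + 100L + ph,
                                    spec$tolerance, spec$calib)
  }
  structure(list(phases = phases, modes = modes,
                 feature_names = colnames(X),
                 search = search_record, spec = spec,
                 fingerprint = rlang::hash(list(X, features$phase,
                                                features$true_mode,
                                                spec[c("cost", "gamma",
                                                       "n_folds", "seed")])),
                 version = 1L),
            class = "phase_bank")
}

#' @export
print.phase_bank <- function(x, ...) {
  hp <- vapply(x$phases, function(p) sprintf("C=%g g=%g", p$cost, p$gamma),
               character(1))
  cat("<phase_bank>", length(x$phases), "phases x", length(x$modes),
      "OAA machines |", paste(hp, collapse = " "), "\n")
  invisible(x)
}

#' Shannon entropy of a decision posterior
#'
#' `E = -sum_k p_k ln p_k` in nats, with `0 ln 0 = 0`. Low entropy means a
#' confident decision; the maximum over 5 classes is `ln 5`.
#'
#' @param p Non-negative numeric vector summing to 1 (tolerance 1e-6).
#' @return Entropy in nats.
#' @export
entropy <- function(p) {
  if (any(p < 0)) stop("posterior entries must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("posterior must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

row_entropy <- function(P) {
  Pl <- ifelse(P > 0, log(P), 0)
  -rowSums(P * Pl)
}

#' Calibrated 5-class posteriors for feature vectors
#'
#' Passes each one-against-all margin through its Platt sigmoid and
#' renormalizes the five per-class scores to sum to one.
#'
#' @param bank A trained `phase_bank`.
#' @param phase Gait phase id (1-5).
#' @param X Feature matrix rows (unstandardized).
#' @return List with `posterior` (n x 5), `sigmoid` (n x 5, per-binary
#'   calibrated scores before renormalization) and `margins` (n x 5).
#' @export
calibrated_posteriors <- function(bank, phase, X) {
  pm <- bank$phases[[phase]]
  Z <- apply_standardizer(pm$std, X)
  mg <- binary_margins(pm$svms, Z)
  s <- vapply(seq_along(bank$modes), function(i)
    platt_apply(pm$calibrators[[i]], mg[, i]), numeric(nrow(Z)))
  if (is.null(dim(s))) s <- matrix(s, nrow = nrow(Z))
  s <- pmax(s, 1e-12)
  p <- s / rowSums(s)
  colnames(p) <- colnames(s) <- colnames(mg) <- bank$modes
  list(posterior = p, sigmoid = s, margins = mg)
}

decision_frame <- function(n) {
  data.frame(n = integer(n), window = integer(n), phase = integer(n),
             true_mode = character(n), raw_label = character(n),
             voted_label = character(n), entropy = numeric(n),
             stringsAsFactors = FALSE)
}

#' Classify every window of a trial
#'
#' Routes each feature vector to its gait phase's classifier, producing the
#' raw (pre-vote) label, the calibrated 5-class posterior, its entropy and
#' the five signed margins. `voted_label` is `NA` until [majority_vote()] is
#' applied.
#'
#' @param bank A trained `phase_bank`.
#' @param features Feature data.frame for one trial.
#' @return A decision data.frame (one row per window, in window order) with
#'   posterior columns `p_<mode>`, per-binary sigmoid scores `s_<mode>` and
#'   margins `d_<mode>`.
#' @export
classify_trial <- function(bank, features) {
  X <- feature_matrix(features)
  stopifnot(identical(colnames(X), bank$feature_names))
  if (any(!features$phase %in% seq_len(lmr_n_phases)))
    stop("unknown gait phase in features")
  n <- nrow(X)
  P <- matrix(NA_real_, n, length(bank$modes))
  S <- matrix(NA_real_, n, length(bank$modes))
  M <- matrix(NA_real_, n, length(bank$modes))
  for (ph in sort(unique(features$phase))) {
    sel <- features$phase == ph
    cp <- calibrated_posteriors(bank, ph, X[sel, , drop = FALSE])
    P[sel, ] <- cp$posterior; S[sel, ] <- cp$sigmoid; M[sel, ] <- cp$margins
  }
  raw <- bank$modes[max.col(P, ties.method = "first")]
  out <- data.frame(n = seq_len(n), window = features$window,
                    phase = features$phase, true_mode = features$true_mode,
                    raw_label = raw, voted_label = NA_character_,
                    entropy = row_entropy(P), stringsAsFactors = FALSE)
  colnames(P) <- paste0("p_", bank$modes)
  colnames(S) <- paste0("s_", bank$modes)
  colnames(M) <- paste0("d_", bank$modes)
  cbind(out, P, S, M)
}

#' Classify a single analysis window
#'
#' @param bank A trained `phase_bank`.
#' @param fv One-row feature data.frame (as one row of [extract_features()]).
#' @return A one-row decision data.frame; see [classify_trial()].
#' @export
classify_window <- function(bank, fv) {
  stopifnot(nrow(fv) == 1)
  if (!fv$phase %in% seq_len(lmr_n_phases))
    stop("unknown gait phase: ", fv$phase)
  classify_trial(bank, fv)
}

#' Majority-vote post-processing
#'
#' Replaces each raw label by the modal label over the trailing `vote_len`
#' decisions of the same trial (the window shrinks at the trial start). Ties
#' are broken toward the most recent raw label among the tied candidates.
#'
#' @param labels Character vector of raw labels in decision order.
#' @param vote_len Odd vote length >= 1 (default 5).
#' @return Character vector of voted labels.
#' @export
majority_vote <- function(labels, vote_len = 5L) {
  if (vote_len < 1 || vote_len %% 2 == 0)
    stop("vote_len must be odd and >= 1")
  n <- length(labels)
  if (vote_len == 1L || n == 0) return(labels)
  out <- character(n)
  for (i in seq_len(n)) {
    win <- labels[max(1L, i - vote_len + 1L):i]
    tab <- table(win)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) out[i] <- winners
    else {
      # most recent occurrence among tied labels
      recency <- vapply(winners, function(w) max(which(win == w)), integer(1))
      out[i] <- winners[which.max(recency)]
    }
  }
  out
}

#' Apply majority voting to a decision stream
#' @param decisions Decision data.frame from [classify_trial()].
#' @param vote_len Odd vote length (default 5).
#' @return The decisions with `voted_label` filled in.
#' @export
vote_decisions <- function(decisions, vote_len = 5L) {
  decisions$voted_label <- majority_vote(decisions$raw_label, vote_len)
  decisions
}
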
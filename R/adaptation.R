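#' Adaptation state
#'
#' Carries the base training set (from the initial training session), the
#' pseudo-labeled augmented set accumulated across testing trials, and the
#' strategy parameters. The augmented set keeps provenance (trial, window)
#' and is disjoint from the base set by construction.
#'
#' @param base_features Feature data.frame of the initial training session
#'   (with `phase` and `true_mode`).
#' @param strategy One of `"none"`, `"eba"`, `"lift"`, `"tsvm"`.
#' @param tau Entropy threshold in nats for EBA (default 0.6; selection is
#'   strict, `E < tau`).
#' @param m TSVM transductive batch size per class per iteration (default 5).
#' @param retrain_seed Seed for retraining (calibration splits).
#' @param max_augmented Optional cap on augmented rows per phase with FIFO
#'   eviction (default `Inf`, i.e. unlimited, the package's standard
#'   behaviour).
#' @return An `adaptation_state` object.
#' @export
adaptation_state <- function(base_features,
                             strategy = c("none", "eba", "lift", "tsvm"),
                             tau = 0.6, m = 5L, retrain_seed = 1L,
                             max_augmented = Inf) {
  strategy <- match.arg(strategy)
  stopifnot(tau >= 0, m >= 1)
  structure(list(base = base_features,
                 augmented = NULL,
                 strategy = strategy, tau = tau, m = as.integer(m),
                 retrain_seed = as.integer(retrain_seed),
                 max_augmented = max_augmented,
                 history = data.frame(trial = integer(0),
                                      n_selected = integer(0),
                                      n_augmented_total = integer(0))),
            class = "adaptation_state")
}

#' Entropy-based selection of retraining windows
#'
#' Selects exactly the decisions with entropy strictly below `tau` and
#' pseudo-labels their feature vectors with the raw (pre-vote) label.
#'
#' @param decisions Decision data.frame from [classify_trial()].
#' @param features The matching feature data.frame.
#' @param tau Entropy threshold in nats (default 0.6).
#' @return Feature rows of the selected windows with a `pseudo_label`
#'   column; zero rows if nothing qualifies.
#' @export
eba_select <- function(decisions, features, tau = 0.6) {
  sel <- decisions$entropy < tau
  out <- features[sel, , drop = FALSE]
  out$pseudo_label <- decisions$raw_label[sel]
  out
}

#' LIFT unanimity selection
#'
#' A window is selected iff exactly one of the five one-against-all binary
#' classifiers claims it (exactly one positive binary decision); its
#' pseudo-label is that classifier's mode. The binary decision is the
#' calibrated per-binary score exceeding 1/2 (equivalently, a positive
#' calibrated margin).
#'
#' @param binary Binary-decision matrix (n x 5 of 0/1), e.g.
#'   `lift_binary_decisions(decisions, modes)`.
#' @param modes Mode labels for the five columns.
#' @return List with `selected` (logical vector) and `label` (character,
#'   `NA` where unselected).
#' @export
lift_select <- function(binary, modes = lmr_modes) {
  binary <- as.matrix(binary)
  if (ncol(binary) != length(modes) || !all(binary %in% c(0, 1)))
    stop("binary decision matrix must be n x 5 of 0/1")
  claims <- rowSums(binary)
  selected <- claims == 1
  label <- rep(NA_character_, nrow(binary))
  label[selected] <- modes[max.col(binary[selected, , drop = FALSE],
                                   ties.method = "first")]
  list(selected = selected, label = label)
}

#' Binary OAA decisions for LIFT
#' @param decisions Decision data.frame (with `s_<mode>` columns).
#' @param modes Mode labels.
#' @return n x 5 matrix of 0/1 binary claims.
#' @export
lift_binary_decisions <- function(decisions, modes = lmr_modes) {
  S <- as.matrix(decisions[, paste0("s_", modes)])
  (S > 0.5) + 0
}

#' Transductive adaptation of one binary margin classifier
#'
#' Iteratively: fit the hyperplane on the labeled set; among unlabeled
#' points whose signed distance to the hyperplane lies strictly in (0, 1) on
#' either side (inside the margin but on a definite side), select up to `m`
#' per side with distance closest to 1; move them, labeled by their side,
#' into the labeled set; refit. Stops when the unlabeled set is empty or no
#' point satisfies the criterion — remaining points are then labeled by the
#' current hyperplane's sign — or when `max_iter` is reached (flagged).
#'
#' @param X_labeled,y_labeled Labeled set; `y_labeled` is a factor with two
#'   levels, the first being the positive ("this mode") class.
#' @param X_unlabeled Unlabeled points (possibly zero rows).
#' @param cost,gamma RBF machine hyperparameters.
#' @param m Batch size per class per iteration (default 5).
#' @param max_iter Iteration cap (default 200).
#' @param tolerance libsvm termination tolerance.
#' @return List with `model` (the final e1071 machine), `labels` (factor,
#'   one label per unlabeled point, in input order), `iterations`,
#'   `moved_per_iter`, `converged`.
#' @export
tsvm_adapt <- function(X_labeled, y_labeled, X_unlabeled,
                       cost = 1, gamma = NULL, m = 5L, max_iter = 200L,
                       tolerance = 0.001) {
  X_labeled <- as.matrix(X_labeled)
  y_labeled <- as.factor(y_labeled)
  if (nlevels(droplevels(y_labeled)) < 2)
    stop("labeled set must contain both classes")
  lev <- levels(y_labeled)
  if (is.null(gamma)) gamma <- 1 / ncol(X_labeled)
  X_unlabeled <- as.matrix(X_unlabeled)
  n_u <- nrow(X_unlabeled)
  labels <- factor(rep(NA_character_, n_u), levels = lev)
  fit <- function(X, y) e1071::svm(X, y, type = "C-classification",
                                   kernel = "radial", cost = cost,
                                   gamma = gamma, scale = FALSE,
                                   tolerance = tolerance)
  model <- fit(X_labeled, y_labeled)
  moved <- rep(FALSE, n_u)
  if (n_u == 0)
    return(list(model = model, labels = labels, moved = moved,
                iterations = 0L, moved_per_iter = integer(0),
                converged = TRUE))

  remaining <- seq_len(n_u)
  moved_per_iter <- integer(0)
  iter <- 0L
  converged <- TRUE
  while (length(remaining) > 0) {
    if (iter >= max_iter) { converged <- FALSE; break }
    dv <- svm_decision_values(model, X_unlabeled[remaining, , drop = FALSE])
    # positive decision value = first level (the positive class)
    pos_cand <- which(dv > 0 & dv < 1)
    neg_cand <- which(dv < 0 & dv > -1)
    if (length(pos_cand) == 0 && length(neg_cand) == 0) break
    take_pos <- pos_cand[order(dv[pos_cand], decreasing = TRUE)][
      seq_len(min(m, length(pos_cand)))]
    take_neg <- neg_cand[order(dv[neg_cand])][seq_len(min(m, length(neg_cand)))]
    take <- c(take_pos, take_neg)
    idx <- remaining[take]
    labels[idx] <- lev[c(rep(1L, length(take_pos)), rep(2L, length(take_neg)))]
    moved[idx] <- TRUE
    X_labeled <- rbind(X_labeled, X_unlabeled[idx, , drop = FALSE])
    y_labeled <- factor(c(as.character(y_labeled), as.character(labels[idx])),
                        levels = lev)
    remaining <- remaining[-take]
    moved_per_iter <- c(moved_per_iter, length(take))
    model <- fit(X_labeled, y_labeled)
    iter <- iter + 1L
  }
  if (length(remaining) > 0) {
    dv <- svm_decision_values(model, X_unlabeled[remaining, , drop = FALSE])
    labels[remaining] <- lev[ifelse(dv > 0, 1L, 2L)]
  }
  list(model = model, labels = labels, moved = moved, iterations = iter,
       moved_per_iter = moved_per_iter, converged = converged)
}

#' Transductive adaptation of the full phase bank
#'
#' Runs [tsvm_adapt()] independently for each of the five one-against-all
#' binary problems of each phase with unlabeled data, replacing that phase's
#' binary machines with the transductively updated ones. The final
#' multiclass label of each unlabeled window is the argmax of the updated
#' calibrated posteriors.
#'
#' @param bank A trained `phase_bank`.
#' @param labeled Feature data.frame of the current training data (base plus
#'   augmented); its labels come from `pseudo_label` where present, else
#'   `true_mode`.
#' @param unlabeled Feature data.frame of the new trial's windows.
#' @param m Batch size per class per iteration (default 5).
#' @param max_iter Per-binary-problem iteration cap.
#' @return List with `bank` (updated), `labels` (character, per unlabeled
#'   row) and `iterations` (5 x 5 matrix of per-problem counts).
#' @export
tsvm_multiclass <- function(bank, labeled, unlabeled, m = 5L,
                            max_iter = 200L) {
  modes <- bank$modes
  labels <- rep(NA_character_, nrow(unlabeled))
  moved <- rep(FALSE, nrow(unlabeled))
  iters <- matrix(0L, lmr_n_phases, length(modes),
                  dimnames = list(NULL, modes))
  if (nrow(unlabeled) == 0)
    return(list(bank = bank, labels = character(0), moved = logical(0),
                iterations = iters))
  Xl_all <- feature_matrix(labeled)
  yl_all <- training_labels(labeled)
  Xu_all <- feature_matrix(unlabeled)
  for (ph in sort(unique(unlabeled$phase))) {
    pm <- bank$phases[[ph]]
    l_sel <- labeled$phase == ph
    u_sel <- unlabeled$phase == ph
    Zl <- apply_standardizer(pm$std, Xl_all[l_sel, , drop = FALSE])
    Zu <- apply_standardizer(pm$std, Xu_all[u_sel, , drop = FALSE])
    yl <- yl_all[l_sel]
    binary_lab <- matrix(FALSE, sum(u_sel), length(modes))
    for (i in seq_along(modes)) {
      yb <- factor(ifelse(yl == modes[i], "this", "rest"),
                   levels = c("this", "rest"))
      res <- tsvm_adapt(Zl, yb, Zu, cost = pm$cost, gamma = pm$gamma,
                        m = m, max_iter = max_iter,
                        tolerance = bank$spec$tolerance)
      bank$phases[[ph]]$svms[[modes[i]]] <- res$model
      binary_lab[, i] <- res$labels == "this"
      moved[which(u_sel)[res$moved]] <- TRUE
      iters[ph, i] <- res$iterations
    }
    # The updated hyperplanes have new margin scales, so the sigmoid
    # calibrators are refit on the updated margins against the (true or
    # transductively assigned) binary labels before taking the posterior
    # argmax.
    svms_new <- bank$phases[[ph]]$svms
    Ml <- binary_margins(svms_new, Zl)
    Mu <- binary_margins(svms_new, Zu)
    for (i in seq_along(modes)) {
      bank$phases[[ph]]$calibrators[[i]] <- platt_fit(
        c(Ml[, i], Mu[, i]), c(yl == modes[i], binary_lab[, i]))
    }
    cp <- calibrated_posteriors(bank, ph, Xu_all[u_sel, , drop = FALSE])
    labels[u_sel] <- modes[max.col(cp$posterior, ties.method = "first")]
  }
  list(bank = bank, labels = labels, moved = moved, iterations = iters)
}

training_labels <- function(features) {
  if (!is.null(features$pseudo_label))
    ifelse(is.na(features$pseudo_label), features$true_mode,
           features$pseudo_label)
  else features$true_mode
}

#' Retrain the bank on base plus augmented data
#'
#' Refits, per phase, the standardizer, the five binary machines and the
#' Platt calibrators on the union of the base training set and the
#' phase-routed augmented set, reusing each phase's original (cost, gamma)
#' from the initial hyperparameter search (no re-search). Deterministic
#' given the state's `retrain_seed`.
#'
#' @param bank The current `phase_bank`.
#' @param state An `adaptation_state`.
#' @return A refitted `phase_bank`.
#' @export
retrain <- function(bank, state) {
  aug <- state$augmented
  if (!is.null(aug) && nrow(aug) > 0 &&
      any(!aug$phase %in% seq_len(lmr_n_phases)))
    stop("augmented sample with unknown phase")
  data <- if (is.null(aug) || nrow(aug) == 0) state$base else {
    base <- state$base
    base$pseudo_label <- NA_character_
    rbind(base[, names(aug)], aug)
  }
  X <- feature_matrix(data)
  y <- training_labels(data)
  modes <- bank$modes
  split_seed <- state$retrain_seed + nrow(data)
  for (ph in seq_len(lmr_n_phases)) {
    sel <- data$phase == ph
    pm <- bank$phases[[ph]]
    bank$phases[[ph]] <- fit_phase_model(X[sel, , drop = FALSE], y[sel],
                                         modes, pm$cost, pm$gamma,
                                         bank$spec$calib_frac,
                                         split_seed + ph,
                                         bank$spec$tolerance,
                                         bank$spec$calib)
  }
  bank$fingerprint <- rlang::hash(list(X, data$phase, y, split_seed))
  bank
}

append_augmented <- function(state, new_rows) {
  if (nrow(new_rows) == 0) return(state)
  state$augmented <- if (is.null(state$augmented)) new_rows
                     else rbind(state$augmented, new_rows)
  if (is.finite(state$max_augmented)) {
    # FIFO eviction per phase
    keep <- unlist(lapply(split(seq_len(nrow(state$augmented)),
                                state$augmented$phase), function(idx) {
      if (length(idx) > state$max_augmented)
        idx[(length(idx) - state$max_augmented + 1L):length(idx)]
      else idx
    }), use.names = FALSE)
    state$augmented <- state$augmented[sort(keep), , drop = FALSE]
  }
  state
}

#' Run an adaptive testing session
#'
#' Classifies the ordered testing trials one by one. Trial `k` is classified
#' with the bank as updated after trial `k - 1` (trial 1 uses the initial
#' bank). After each trial the strategy's selection runs on that trial's
#' pre-vote decisions and the bank is retrained on base plus augmented data;
#' `strategy = "none"` skips both. Decisions are majority-voted within each
#' trial.
#'
#' @param strategy `"none"`, `"eba"`, `"lift"` or `"tsvm"`.
#' @param bank The initial trained `phase_bank`.
#' @param test_features List of per-trial feature data.frames, in collection
#'   order.
#' @param base_features The initial training-session features.
#' @param tau,m,vote_len,retrain_seed,max_augmented Strategy parameters; see
#'   [adaptation_state()] and [majority_vote()].
#' @param max_iter TSVM per-problem iteration cap.
#' @return List with `decisions` (list of voted per-trial decision frames,
#'   each with a `selected` column), `state` (final `adaptation_state`) and
#'   `bank` (final bank).
#' @export
run_adaptive_session <- function(strategy, bank, test_features, base_features,
                                 tau = 0.6, m = 5L, vote_len = 5L,
                                 retrain_seed = 1L, max_augmented = Inf,
                                 max_iter = 200L) {
  strategy <- match.arg(strategy, c("none", "eba", "lift", "tsvm"))
  state <- adaptation_state(base_features, strategy, tau = tau, m = m,
                            retrain_seed = retrain_seed,
                            max_augmented = max_augmented)
  decisions <- vector("list", length(test_features))
  for (k in seq_along(test_features)) {
    feats <- test_features[[k]]
    selected_label <- rep(NA_character_, nrow(feats))

    # Trial k is always classified with the bank as updated after trial
    # k - 1; the strategy's selection then runs on this trial's stream.
    dec <- classify_trial(bank, feats)
    if (strategy == "tsvm") {
      current <- if (is.null(state$augmented) || nrow(state$augmented) == 0)
        state$base else {
          b <- state$base; b$pseudo_label <- NA_character_
          rbind(b[, names(state$augmented)], state$augmented)
        }
      ts <- tsvm_multiclass(bank, current, feats, m = state$m,
                            max_iter = max_iter)
      # Only the selected transductive samples (those that moved into the
      # labeled set during the iterations) become training data; the
      # remainder are assigned a class but not retained.
      selected_label <- ifelse(ts$moved, ts$labels, NA_character_)
    } else {
      if (strategy == "eba") {
        picked <- eba_select(dec, feats, state$tau)
        selected_label[dec$entropy < state$tau] <-
          picked$pseudo_label
      } else if (strategy == "lift") {
        ls <- lift_select(lift_binary_decisions(dec, bank$modes), bank$modes)
        selected_label <- ls$label
      }
    }

    dec <- vote_decisions(dec, vote_len)
    dec$selected <- !is.na(selected_label)
    dec$trial <- k
    decisions[[k]] <- dec

    if (strategy != "none") {
      sel <- which(!is.na(selected_label))
      new_rows <- feats[sel, , drop = FALSE]
      if (length(sel)) new_rows$pseudo_label <- selected_label[sel]
      else new_rows$pseudo_label <- character(0)
      state <- append_augmented(state, new_rows)
      n_aug <- if (is.null(state$augmented)) 0L else nrow(state$augmented)
      state$history <- rbind(state$history,
                             data.frame(trial = k, n_selected = length(sel),
                                        n_augmented_total = n_aug))
      if (length(sel) > 0 || strategy == "tsvm")
        bank <- retrain(bank, state)
    } else {
      state$history <- rbind(state$history,
                             data.frame(trial = k, n_selected = 0L,
                                        n_augmented_total = 0L))
    }
  }
  list(decisions = decisions, state = state, bank = bank)
}
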
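fake_decisions <- function(entropies, labels = rep("W", length(entropies))) {
  data.frame(n = seq_along(entropies), entropy = entropies,
             raw_label = labels, stringsAsFactors = FALSE)
}

test_that("entropy-based selection is strictly below the threshold", {
  dec <- fake_decisions(c(0.3, 0.59, 0.6, 1.2),
                        c("W", "SA", "RD", "RA"))
  feats <- toy_features()[1:4, ]
  sel <- eba_select(dec, feats, tau = 0.6)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$pseudo_label, c("W", "SA"))

  expect_equal(nrow(eba_select(dec, feats, tau = 0)), 0)

  conf <- fake_decisions(rep(0, 4))
  expect_equal(nrow(eba_select(conf, feats, tau = 0.6)), 4)
})

test_that("LIFT selects exactly the unanimous windows", {
  B <- rbind(c(1, 0, 0, 0, 0),
             c(1, 1, 0, 0, 0),
             c(0, 0, 0, 0, 0),
             c(0, 0, 0, 1, 0))
  sel <- lift_select(B)
  expect_identical(sel$selected, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(sel$label, c("W", NA, NA, "SA"))
  expect_error(lift_select(B[, 1:3]), "n x 5")
  expect_error(lift_select(matrix(2, 1, 5)), "0/1")
})

test_that("transductive adaptation respects its batch and termination contract", {
  set.seed(20)
  Xl <- rbind(matrix(rnorm(40, 3), 20, 2), matrix(rnorm(40, -3), 20, 2))
  yl <- factor(rep(c("this", "rest"), each = 20), levels = c("this", "rest"))

  # no unlabeled data: identical to a plain fit
  plain <- e1071::svm(Xl, yl, kernel = "radial", cost = 1, gamma = 0.5,
                      scale = FALSE)
  res0 <- tsvm_adapt(Xl, yl, Xl[0, ], cost = 1, gamma = 0.5)
  probe <- matrix(rnorm(20), 10, 2)
  expect_equal(predict(res0$model, probe), predict(plain, probe))

  Xu <- matrix(rnorm(80, 0, 2), 40, 2)
  res <- tsvm_adapt(Xl, yl, Xu, cost = 1, gamma = 0.5, m = 5)
  expect_true(res$converged)
  expect_false(anyNA(res$labels))
  expect_length(res$labels, 40)
  expect_true(all(res$moved_per_iter <= 10))
  expect_lte(res$iterations, 40)

  expect_error(tsvm_adapt(Xl, factor(rep("this", 40),
                                     levels = c("this", "rest")), Xu),
               "both classes")
})

test_that("the transductive toy layout resolves to the geometric labels", {
  Xl <- rbind(cbind(rnorm(15, 3, 0.3), rnorm(15, 0, 0.3)),
              cbind(rnorm(15, -3, 0.3), rnorm(15, 0, 0.3)))
  yl <- factor(rep(c("this", "rest"), each = 15), levels = c("this", "rest"))
  Xu <- cbind(c(0.5, -0.5, 1.5, -1.5), c(0, 0, 0, 0))
  res <- tsvm_adapt(Xl, yl, Xu, cost = 4, gamma = 0.3, m = 5)
  expect_identical(as.character(res$labels),
                   ifelse(Xu[, 1] > 0, "this", "rest"))
})

test_that("multiclass transduction leaves an easy problem unchanged", {
  bank <- toy_bank()
  feats <- toy_features()
  empty <- feats[0, ]
  out <- tsvm_multiclass(bank, feats, empty, m = 5)
  expect_length(out$labels, 0)

  unl <- toy_features(n_per = 3, seed = 123)
  out2 <- tsvm_multiclass(bank, feats, unl, m = 5)
  expect_false(anyNA(out2$labels))
  expect_true(all(is.finite(out2$iterations)))
  # in the well-separated regime transduction agrees with plain labels
  plain <- classify_trial(bank, unl)$raw_label
  expect_gte(mean(out2$labels == plain), 0.95)
})

test_that("retraining is a no-op without augmentation and is deterministic", {
  bank <- toy_bank()
  feats <- toy_features()
  st <- adaptation_state(feats, "eba", retrain_seed = 5)
  probe <- toy_features(n_per = 4, seed = 321)

  bank_r <- retrain(bank, st)
  expect_identical(classify_trial(bank_r, probe)$raw_label,
                   classify_trial(bank, probe)$raw_label)

  aug <- feats[feats$phase == 1, ][1:10, ]
  aug$pseudo_label <- aug$true_mode
  st$augmented <- aug
  base_acc <- mean(classify_trial(bank, probe)$raw_label == probe$true_mode)
  bank_a <- retrain(bank, st)
  aug_acc <- mean(classify_trial(bank_a, probe)$raw_label == probe$true_mode)
  expect_gte(aug_acc, base_acc - 1 / nrow(probe))

  expect_identical(retrain(bank, st)$fingerprint,
                   retrain(bank, st)$fingerprint)

  bad <- aug; bad$phase <- 9L
  st$augmented <- bad
  expect_error(retrain(bank, st), "unknown phase")
})

test_that("the session loop honours the strategy contracts", {
  bank <- toy_bank()
  feats <- toy_features()
  trials <- list(toy_features(n_per = 3, seed = 7),
                 toy_features(n_per = 3, seed = 8))

  res_none <- run_adaptive_session("none", bank, trials, feats)
  for (k in 1:2)
    expect_identical(res_none$decisions[[k]]$raw_label,
                     vote_decisions(classify_trial(bank, trials[[k]]))$raw_label)
  expect_equal(sum(res_none$state$history$n_selected), 0)

  res_tau0 <- run_adaptive_session("eba", bank, trials, feats, tau = 0)
  for (k in 1:2)
    expect_identical(res_tau0$decisions[[k]]$voted_label,
                     res_none$decisions[[k]]$voted_label)

  res_eba <- run_adaptive_session("eba", bank, trials, feats, tau = 0.6)
  for (k in 1:2)
    expect_identical(res_eba$decisions[[k]]$selected,
                     res_eba$decisions[[k]]$entropy < 0.6)
  expect_error(run_adaptive_session("bogus", bank, trials, feats))
})

test_that("the augmented-set cap evicts oldest rows per phase", {
  feats <- toy_features()
  st <- adaptation_state(feats, "eba", max_augmented = 5)
  aug1 <- feats[feats$phase == 1, ][1:4, ]; aug1$pseudo_label <- "W"
  aug2 <- feats[feats$phase == 1, ][5:8, ]; aug2$pseudo_label <- "RA"
  st <- lmradapt:::append_augmented(st, aug1)
  st <- lmradapt:::append_augmented(st, aug2)
  expect_equal(nrow(st$augmented), 5)
  expect_equal(sum(st$augmented$pseudo_label == "RA"), 4)  # newest kept
})
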
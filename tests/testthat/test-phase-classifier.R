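test_that("standardizer computes population statistics and flags constants", {
  X <- rbind(c(1, 0), c(1, 2))
  std <- fit_standardizer(X)
  expect_equal(unname(std$center), c(1, 1))
  expect_equal(unname(std$scale), c(1, 1))  # constant col passes through
  expect_identical(unname(std$constant), c(TRUE, FALSE))

  X2 <- matrix(rnorm(200), 50, 4)
  std2 <- fit_standardizer(X2)
  Z <- apply_standardizer(std2, X2)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_error(fit_standardizer(X2[1, , drop = FALSE]), "2 rows")
})

test_that("direct decision values equal the fitted machine's predictions", {
  set.seed(10)
  for (i in 1:12) {
    n <- sample(30:120, 1)
    X <- matrix(rnorm(n * 8), n, 8)
    y <- factor(sample(c("this", "rest"), n, replace = TRUE),
                levels = c("this", "rest"))
    X[y == "this", 1] <- X[y == "this", 1] + runif(1, 0.5, 3)
    m <- e1071::svm(X, y, kernel = "radial", cost = runif(1, 0.5, 20),
                    gamma = runif(1, 0.01, 0.2), scale = FALSE)
    Xn <- matrix(rnorm(20 * 8), 20, 8)
    dv <- attr(predict(m, Xn, decision.values = TRUE), "decision.values")
    ref <- unname(if (colnames(dv) == "this/rest") dv[, 1] else -dv[, 1])
    expect_equal(lmradapt:::svm_decision_values(m, Xn), ref,
                 tolerance = 1e-9)
  }
})

test_that("a separable toy bank recalls its training data and is reproducible", {
  bank <- toy_bank()
  feats <- toy_features()
  dec <- classify_trial(bank, feats)
  expect_equal(mean(dec$raw_label == feats$true_mode), 1)

  bank2 <- train_phase_bank(toy_features(),
                            search_spec(cost = 4, gamma = 0.05, seed = 1))
  expect_identical(bank$fingerprint, bank2$fingerprint)
  dec2 <- classify_trial(bank2, feats)
  expect_identical(dec$raw_label, dec2$raw_label)
  expect_equal(dec$entropy, dec2$entropy)
})

test_that("training refuses a missing (phase, mode) cell by name", {
  feats <- toy_features()
  broken <- feats[!(feats$phase == 2 & feats$true_mode == "SD"), ]
  expect_error(train_phase_bank(broken, search_spec(cost = 4, gamma = 0.05)),
               "phase 2.*SD")
})

test_that("calibrated posteriors form a proper distribution", {
  bank <- toy_bank()
  feats <- toy_features()
  X <- lmradapt:::feature_matrix(feats[feats$phase == 1, ])
  cp <- calibrated_posteriors(bank, 1, X)
  expect_true(all(cp$posterior >= 0))
  expect_equal(unname(rowSums(cp$posterior)), rep(1, nrow(X)),
               tolerance = 1e-9)
  expect_identical(cp$posterior[1, ], cp$posterior[1, ])
  cp2 <- calibrated_posteriors(bank, 1, X[c(1, 1), , drop = FALSE])
  expect_equal(cp2$posterior[1, ], cp2$posterior[2, ])

  # a point deep on one mode's side has that mode as argmax
  deep <- X[which(feats$true_mode[feats$phase == 1] == "W")[1], ,
            drop = FALSE]
  cpd <- calibrated_posteriors(bank, 1, deep)
  expect_equal(names(which.max(cpd$posterior[1, ])), "W")
})

test_that("entropy matches closed forms and rejects bad input", {
  expect_equal(entropy(c(1, 0, 0, 0, 0)), 0)
  expect_equal(entropy(rep(0.2, 5)), log(5), tolerance = 1e-12)
  expect_equal(entropy(c(0.7, 0.1, 0.1, 0.05, 0.05)), 1.0098,
               tolerance = 1e-4)
  expect_error(entropy(c(-0.1, 1.1, 0, 0, 0)), "non-negative")
  expect_error(entropy(c(0.5, 0.1, 0.1, 0.1, 0.1)), "sum")
})

test_that("classification routes by phase and validates it", {
  bank <- toy_bank()
  feats <- toy_features()
  fv <- feats[3, , drop = FALSE]
  dec <- classify_window(bank, fv)
  expect_equal(nrow(dec), 1)
  expect_gte(dec$entropy, 0)
  expect_lte(dec$entropy, log(5))
  fv$phase <- 7
  expect_error(classify_window(bank, fv), "phase")
})

test_that("majority vote suppresses outliers with the stated tie-break", {
  v <- majority_vote(c("W", "W", "SA", "W", "W"), 5)
  expect_equal(v[5], "W")
  labs <- c("W", "SA", "RD", "W")
  expect_identical(majority_vote(labs, 1), labs)
  # shrunk window of 2 at n = 2 is a tie; most recent wins
  expect_equal(majority_vote(c("W", "SA"), 3)[2], "SA")
  expect_error(majority_vote(labs, 4), "odd")
  expect_error(majority_vote(labs, 0), "odd")

  set.seed(5)
  for (i in 1:20) {
    labs <- sample(lmr_modes, 30, replace = TRUE)
    voted <- majority_vote(labs, 5)
    for (n in seq_along(labs)) {
      win <- labs[max(1, n - 4):n]
      expect_true(voted[n] %in% win)  # vote never invents a label
    }
  }
})
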
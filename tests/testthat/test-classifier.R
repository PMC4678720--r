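test_that("the polynomial SVM separates well-separated classes deterministically", {
  sim <- generate_labeled_features(n_pos = 40, n_neg = 40, separation = 6,
                                   dims = 4, seed = 2)
  fit <- train_ires_svm(sim$x, sim$y)
  pred <- predict_ires(fit, sim$x)
  expect_equal(mean(pred$label == as.character(sim$y)), 1)

  fit2 <- train_ires_svm(sim$x, sim$y)
  expect_identical(predict_ires(fit2, sim$x)$decision, pred$decision)

  expect_error(train_ires_svm(sim$x, factor(rep("negative", 80),
                                            levels = c("negative", "positive"))),
               "single class")
})

test_that("raising the positive class cost does not reduce positive recall", {
  sim <- generate_labeled_features(n_pos = 60, n_neg = 200, separation = 1.2,
                                   dims = 4, seed = 9)
  # recall at the SVM decision boundary: the class weight scales the
  # misclassification cost of positives, so the boundary shifts toward the
  # negative class (Platt posteriors re-absorb class priors downstream, so
  # the mechanism is measured on the raw decision labels)
  recall <- function(w) {
    fit <- train_ires_svm(sim$x, sim$y,
                          class_weights = c(positive = w, negative = 1))
    raw <- predict(fit$svm, sim$x)
    mean(raw[sim$y == "positive"] == "positive")
  }
  expect_gte(recall(2), recall(1))
  expect_gte(recall(8), recall(1))
})

test_that("Platt calibration is symmetric, correctly oriented and recovers slopes", {
  # symmetric decision values, balanced classes -> B ~ 0, A < 0
  f <- c(rep(1, 200), rep(-1, 200))
  pos <- rep(c(TRUE, FALSE), each = 200)
  ab <- platt_calibrate(f, pos)
  expect_lt(ab[["A"]], 0)
  expect_lt(abs(ab[["B"]]), 0.05)
  # posterior is monotone increasing in f when A < 0
  post <- platt_posterior(seq(-3, 3, 0.5), ab)
  expect_true(all(diff(post) > 0))

  # parameter recovery on a logistic-generated fixture
  set.seed(31)
  fv <- rnorm(6000, sd = 2)
  a_true <- -1.5; b_true <- 0.3
  p <- 1 / (1 + exp(a_true * fv + b_true))
  lab <- runif(6000) < p
  ab2 <- platt_calibrate(fv, lab)
  expect_lt(abs(ab2[["A"]] - a_true) / abs(a_true), 0.10)
  expect_lt(abs(ab2[["B"]] - b_true) / max(abs(b_true), 1), 0.10)
})

test_that("posteriors complement to 1 and increase with the decision value", {
  sim <- generate_labeled_features(n_pos = 50, n_neg = 50, separation = 6,
                                   dims = 3, seed = 4)
  fit <- train_ires_svm(sim$x, sim$y)
  pred <- predict_ires(fit, sim$x)
  expect_true(all(pred$posterior > 0 & pred$posterior < 1))
  expect_true(all(pred$posterior[sim$y == "positive"] > 0.5))
  o <- order(pred$decision)
  expect_true(all(diff(pred$posterior[o]) >= 0) ||
                all(diff(pred$posterior[o]) <= 0))
  # labels agree with the 0.5 posterior threshold
  expect_identical(pred$label, ifelse(pred$posterior >= 0.5,
                                      "positive", "negative"))
})

test_that("confusion metrics match hand-computed values", {
  y <- rep(c("positive", "positive", "negative", "negative"),
           c(40, 10, 5, 45))
  p <- rep(c("positive", "negative", "positive", "negative"),
           c(40, 10, 5, 45))
  m <- confusion_metrics(y, p)
  expect_equal(unname(m), c(0.85, 0.70, 0.8, 0.9))

  m2 <- confusion_metrics(c("positive", "negative"), c("positive", "negative"))
  expect_equal(unname(m2[c("accuracy", "kappa")]), c(1, 1))

  # all-one-class predictions on balanced truth: chance agreement
  m3 <- confusion_metrics(rep(c("positive", "negative"), 10),
                          rep("positive", 20))
  expect_equal(m3[["kappa"]], 0)
  expect_error(confusion_metrics(character(0), character(0)), "empty")
})

test_that("grid search reports per-combination means and picks the best", {
  sim <- generate_labeled_features(n_pos = 30, n_neg = 60, separation = 6,
                                   dims = 3, seed = 6)
  cv <- grid_search_cv(sim$x, sim$y, grid = data.frame(gamma = 0.25, cost = 1),
                       folds = 5, repeats = 2, seed = 3)
  expect_identical(nrow(cv$report), 1L)
  expect_gte(cv$best$accuracy, 0.95)
  expect_gte(cv$best$kappa, 0.9)

  expect_error(grid_search_cv(sim$x, sim$y, folds = 40, repeats = 1),
               "fold count")
})

test_that("cross-validated kappa is near zero for pure-noise labels", {
  set.seed(17)
  x <- matrix(rnorm(240 * 4), 240, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(sample(rep(c("negative", "positive"), each = 120)),
              levels = c("negative", "positive"))
  cv <- grid_search_cv(x, y, grid = data.frame(gamma = 0.25, cost = 1),
                       folds = 10, repeats = 5, seed = 13)
  expect_lt(abs(cv$best$kappa), 0.1)
})

test_that("the empirical FDR is the control-call to utr-call percentage", {
  expect_equal(estimate_empirical_fdr(317, 6532), 100 * 317 / 6532)
  expect_equal(estimate_empirical_fdr(0, 100), 0)
  expect_equal(estimate_empirical_fdr(50, 50), 100)
  expect_error(estimate_empirical_fdr(5, 0), "denominator")
})

test_that("posterior calibration holds on held-out synthetic data", {
  # one draw split in half so train and holdout share the class geometry
  all <- generate_labeled_features(n_pos = 800, n_neg = 800, separation = 2,
                                   dims = 4, seed = 21)
  tr <- c(1:400, 801:1200)
  ho <- setdiff(seq_len(1600), tr)
  fit <- train_ires_svm(all$x[tr, ], all$y[tr])
  pred <- predict_ires(fit, all$x[ho, ])
  bins <- cut(pred$posterior, breaks = seq(0, 1, 0.1), include.lowest = TRUE)
  emp <- tapply(all$y[ho] == "positive", bins, mean)
  prd <- tapply(pred$posterior, bins, mean)
  ok <- !is.na(emp)
  expect_lt(mean(abs(emp[ok] - prd[ok])), 0.1)
})
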
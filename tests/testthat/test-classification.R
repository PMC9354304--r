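test_that("cosine KNN honours identity, scale invariance and zero-vector rejection", {
  cfg <- classifier_config("cosine_knn", neighbors = 1)
  train <- matrix(c(1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  y <- c("a", "b", "b")
  out <- fit_predict(cfg, train, y, train, positive_class = "b")
  expect_equal(out$labels, y)

  test <- matrix(c(7, 0, 0, 7), ncol = 2, byrow = TRUE)
  out7 <- fit_predict(cfg, train, y, test, positive_class = "b")
  out1 <- fit_predict(cfg, train, y, test / 7, positive_class = "b")
  expect_equal(out7$labels, out1$labels)
  expect_equal(out7$scores, out1$scores)

  expect_error(
    fit_predict(cfg, train, y, matrix(c(0, 0), 1), positive_class = "b"),
    "zero-vector"
  )
})

test_that("the quadratic SVM separates the XOR pattern", {
  set.seed(4)
  base <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  x <- base[rep(1:4, each = 10), ] + matrix(rnorm(80, 0, 0.05), ncol = 2)
  y <- rep(c("a", "b", "b", "a"), each = 10)
  cfg <- classifier_config("quadratic_svm")
  out <- fit_predict(cfg, x, y, x, positive_class = "b")
  expect_equal(mean(out$labels == y), 1.0)
})

test_that("logistic regression returns oriented probabilities", {
  set.seed(5)
  x <- matrix(c(rnorm(20, -2), rnorm(20, 2)), ncol = 1)
  y <- rep(c("neg", "pos"), each = 20)
  cfg <- classifier_config("logistic_regression")
  out <- fit_predict(cfg, x, y, matrix(c(-3, 3), ncol = 1), positive_class = "pos")
  expect_lt(out$scores[1], 0.05)
  expect_gt(out$scores[2], 0.95)
  expect_equal(out$labels, c("neg", "pos"))
})

test_that("cross-validation yields perfect metrics on separated clusters", {
  set.seed(10)
  x <- rbind(
    matrix(rnorm(60, 5), ncol = 3),
    matrix(rnorm(60, -5), ncol = 3)
  )
  y <- rep(c("pos", "neg"), each = 20)
  cfg <- classifier_config("cosine_knn", cv_folds = 5, seed = 2)
  cv <- cross_validate(cfg, x, y, positive_class = "pos")
  expect_equal(cv$accuracy, 1.0)
  expect_equal(cv$weighted_average_auc, 1.0)
  expect_equal(cv$sensitivity, 1.0)
  expect_equal(cv$specificity, 1.0)
})

test_that("pooled counts and the accuracy identity hold exactly", {
  set.seed(11)
  x <- matrix(rnorm(120, rep(c(0, 1.5), each = 30)), ncol = 2)
  y <- rep(c("a", "b"), each = 30)
  cfg <- classifier_config("cosine_knn", cv_folds = 5, seed = 3)
  cv <- cross_validate(cfg, x + 4, y, positive_class = "b")
  expect_equal(nrow(cv$predictions), cv$n)
  expect_equal(
    cv$n * cv$accuracy,
    cv$n_pos * cv$sensitivity + cv$n_neg * cv$specificity,
    tolerance = 1e-12
  )
  expect_true(all(c(cv$accuracy, cv$sensitivity, cv$specificity) >= 0 &
    c(cv$accuracy, cv$sensitivity, cv$specificity) <= 1))
})

test_that("AUC equals the all-pairs brute force and inverts with the scores", {
  set.seed(12)
  scores <- c(rnorm(40, 1), rnorm(60, 0))
  scores[5] <- scores[50] # force a tie across classes
  labels <- rep(c("pos", "neg"), c(40, 60))
  a <- auc_score(scores, labels, "pos")
  expect_equal(a, auc_bruteforce(scores, labels, "pos"), tolerance = 1e-12)
  expect_equal(auc_score(-scores, labels, "pos"), 1 - a, tolerance = 1e-12)
})

test_that("label-permuted data classifies at chance", {
  set.seed(13)
  x <- matrix(rnorm(40 * 3), ncol = 3) + 3
  accs <- vapply(seq_len(50), function(i) {
    y <- sample(rep(c("a", "b"), each = 20))
    cfg <- classifier_config("cosine_knn", cv_folds = 4, seed = i)
    cross_validate(cfg, x, y, positive_class = "b")$accuracy
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.05)
})

test_that("Wald half-widths reproduce the printed table conventions", {
  expect_equal(wald_ci_halfwidth(0.91, 65), 0.07)
  expect_equal(wald_ci_halfwidth(0.86, 50), 0.10)
  expect_equal(wald_ci_halfwidth(0.82, 33), 0.13)
  expect_equal(wald_ci_halfwidth(0.61, 38), 0.16)
  expect_equal(wald_ci_halfwidth(0.5, 100), 0.10)
  expect_equal(
    wald_ci_halfwidth(0.5, 100, digits = NULL),
    1.96 * sqrt(0.25 / 100)
  )
  expect_error(wald_ci_halfwidth(0.5, 0), "n must be")
  expect_error(wald_ci_halfwidth(1.2, 10), "p must")
})

test_that("two-step classification keeps predicted-healthy subjects out of step 2", {
  f <- make_separated_features(n_per_group = 12, gap = 8, seed = 20)
  cfg <- classifier_config("cosine_knn", cv_folds = 5)
  ts <- two_step_classify(cfg, f,
    columns = paste0("feat_", 1:6), seed = 3
  )
  expect_equal(ts$status, "ok")
  predicted_hc <- ts$step1$predictions$predicted == "HC"
  n_nonhealthy <- sum(!predicted_hc)
  for (cv in ts$step2) expect_equal(cv$n, n_nonhealthy)

  # widely separated groups classify nearly perfectly at step 2
  for (cv in ts$step2) expect_gte(cv$accuracy, 0.9)

  # determinism
  ts2 <- two_step_classify(cfg, f, columns = paste0("feat_", 1:6), seed = 3)
  expect_equal(tidy(ts), tidy(ts2))
})

test_that("feature-set comparison reuses identical folds", {
  f <- make_separated_features(n_per_group = 15, gap = 3, seed = 30, groups = c("HC", "AD"))
  cfg <- classifier_config("cosine_knn", cv_folds = 5, seed = 9)
  sets <- list(one = c("feat_1", "feat_2"), two = c("feat_1", "feat_2"))
  res <- compare_feature_sets(cfg, f, sets,
    labels = f$group, positive_class = "AD"
  )
  expect_identical(res$one$folds, res$two$folds)
  expect_equal(tidy(res$one)[-1], tidy(res$two)[-1])
  expect_error(
    compare_feature_sets(cfg, f, list(a = character()), f$group, "AD"),
    "non-empty"
  )
})

test_that("fold reduction warns when a class is smaller than the fold count", {
  set.seed(40)
  x <- matrix(rnorm(28), ncol = 2) + 4
  y <- rep(c("a", "b"), each = 7)
  cfg <- classifier_config("cosine_knn", cv_folds = 10, seed = 1)
  expect_warning(cross_validate(cfg, x, y, positive_class = "b"), "reducing folds")
})
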
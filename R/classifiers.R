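#' Classifier configuration
#'
#' @param kind `"cosine_knn"`, `"logistic_regression"` or `"quadratic_svm"`.
#' @param neighbors Neighbour count for cosine KNN.
#' @param cost SVM box constraint.
#' @param ridge Ridge penalty stabilizing logistic regression on separable
#'   data.
#' @param cv_folds Cross-validation folds (>= 2).
#' @param seed Seed used for fold assignment.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(kind = c(
                                "cosine_knn", "logistic_regression",
                                "quadratic_svm"
                              ),
                              neighbors = 10, cost = 1, ridge = 1e-6,
                              cv_folds = 10, seed = 1) {
  kind <- match.arg(kind)
  if (cv_folds < 2) abort("cv_folds must be >= 2")
  structure(
    list(
      kind = kind, neighbors = neighbors, cost = cost, ridge = ridge,
      cv_folds = cv_folds, seed = as.integer(seed)
    ),
    class = "classifier_config"
  )
}

# cosine distance KNN; distance ties broken by training order (stable sort),
# vote ties by the nearest neighbour's class
.knn_cosine <- function(train_x, train_y, test_x, k, positive_class) {
  tn <- sqrt(rowSums(train_x^2))
  sn <- sqrt(rowSums(test_x^2))
  if (any(tn == 0) || any(sn == 0)) {
    abort("zero-vector sample under cosine distance")
  }
  sim <- (test_x / sn) %*% t(train_x / tn)
  k <- min(k, nrow(train_x))
  labels <- character(nrow(test_x))
  scores <- numeric(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    ord <- order(1 - sim[i, ]) # stable: ties keep training order
    nb <- train_y[ord[seq_len(k)]]
    tab <- table(nb)
    top <- names(tab)[tab == max(tab)]
    labels[i] <- if (length(top) == 1) top else nb[1]
    scores[i] <- mean(nb == positive_class)
  }
  list(labels = labels, scores = scores)
}

#' Fit a classifier on training data and predict test samples
#'
#' Cosine KNN votes among the `neighbors` nearest training points by cosine
#' distance (1 - cosine similarity) and scores by the positive-class vote
#' fraction; it operates on the features as given (cosine distance is scale
#' invariant). Logistic regression (lightly ridge-penalized for stability on
#' separable data) and the degree-2 polynomial-kernel SVM z-score features
#' using training statistics and return class probabilities and signed
#' margins respectively. Scores are always oriented toward
#' `positive_class`.
#'
#' @param config A [classifier_config()].
#' @param train_x,train_y Training matrix (samples x features) and labels.
#' @param test_x Test matrix.
#' @param positive_class Label treated as positive for scoring.
#' @return List with `labels` (character) and `scores` (numeric).
#' @export
fit_predict <- function(config, train_x, train_y, test_x, positive_class) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- as.character(train_y)
  if (length(unique(train_y)) < 2) abort("training data must contain both classes")
  if (missing(positive_class)) positive_class <- sort(unique(train_y))[1]

  if (config$kind == "cosine_knn") {
    return(.knn_cosine(train_x, train_y, test_x, config$neighbors, positive_class))
  }

  mu <- colMeans(train_x)
  sig <- apply(train_x, 2, sd)
  sig[sig == 0] <- 1
  ztr <- sweep(sweep(train_x, 2, mu), 2, sig, "/")
  zte <- sweep(sweep(test_x, 2, mu), 2, sig, "/")

  if (config$kind == "logistic_regression") {
    ybin <- as.integer(train_y == positive_class)
    other <- setdiff(unique(train_y), positive_class)[1]
    if (ncol(ztr) == 1) ztr_g <- cbind(ztr, 0) else ztr_g <- ztr # glmnet needs >= 2 cols
    if (ncol(zte) == 1) zte_g <- cbind(zte, 0) else zte_g <- zte
    fit <- glmnet::glmnet(ztr_g, ybin,
      family = "binomial", alpha = 0,
      lambda = config$ridge, standardize = FALSE
    )
    prob <- as.numeric(predict(fit, zte_g, type = "response"))
    return(list(
      labels = ifelse(prob >= 0.5, positive_class, other),
      scores = prob
    ))
  }

  # quadratic SVM: polynomial kernel degree 2
  yf <- factor(train_y)
  fit <- e1071::svm(ztr, yf,
    kernel = "polynomial", degree = 2, gamma = 1,
    coef0 = 1, cost = config$cost, scale = FALSE
  )
  pred <- predict(fit, zte, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # orient the margin toward the positive class
  sgn <- if (grepl(paste0("^", positive_class, "/"), colnames(dv)[1])) 1 else -1
  list(labels = as.character(pred), scores = sgn * as.numeric(dv[, 1]))
}

#' Stratified fold assignment
#'
#' @param y Labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_stratified_folds <- function(y, k, seed = 1) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

#' Stratified train/test split
#'
#' @param y Labels.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` = training.
#' @export
stratified_split <- function(y, train_fraction = 0.7, seed = 1) {
  set.seed(seed)
  tr <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1), length(idx) - 1)
    tr[sample(idx, n_tr)] <- TRUE
  }
  tr
}

#' Area under the ROC curve from scores
#'
#' Trapezoidal AUC computed via the rank (Mann-Whitney) identity, with tied
#' scores counted one half.
#'
#' @param scores Numeric scores oriented toward `positive`.
#' @param labels Class labels.
#' @param positive Positive-class label.
#' @return AUC in \[0, 1\]; `NA` if a class is absent.
#' @export
auc_score <- function(scores, labels, positive) {
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' 95% Wald half-width for a proportion
#'
#' `1.96 * sqrt(p (1 - p) / n)`, the normal-approximation binomial
#' confidence half-width used for reporting accuracy, sensitivity and
#' specificity; rounded to 2 decimals by default to match tabular reporting.
#'
#' @param p Proportion in \[0, 1\].
#' @param n Count (>= 1): the task size for accuracy, the positive-class
#'   size for sensitivity, the negative-class size for specificity.
#' @param digits Rounding digits; `NULL` for the exact value.
#' @return Numeric half-width.
#' @export
wald_ci_halfwidth <- function(p, n, digits = 2) {
  if (any(n < 1)) abort("n must be >= 1")
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  hw <- 1.96 * sqrt(p * (1 - p) / n)
  if (is.null(digits)) hw else round(hw, digits)
}
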
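#' Neighbourhood component analysis feature weighting
#'
#' Learns nonnegative per-feature weights `w` maximizing the regularized
#' expected leave-one-out assignment objective
#' \deqn{\sum_i \sum_{j \ne i,\, y_j = y_i} p_{ij} \;-\; \lambda \sum_f w_f^2,}
#' where `p_ij` is the softmax over negative squared weighted distances
#' `d_ij = sum_f w_f^2 (x_if - x_jf)^2`. Optimization is plain gradient
#' ascent with a backtracking line search, so the recorded objective trace
#' is non-decreasing. Features should be standardized beforehand.
#'
#' @param x Numeric matrix, samples x features (standardized).
#' @param y Class labels (>= 2 classes, n >= 4).
#' @param lambda Ridge penalty on the weights, >= 0.
#' @param max_iter Maximum ascent iterations.
#' @param tol Stop when the objective improves by less than this.
#' @param init Initial weight value for every feature.
#' @return A `qeeg_nca` object with elements `weights` (nonnegative, named),
#'   `lambda`, `objective_trace`, `converged`.
#' @export
nca_fit <- function(x, y, lambda = 0, max_iter = 200, tol = 1e-6, init = 1) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) abort("non-finite values in feature matrix")
  y <- as.character(y)
  n <- nrow(x)
  if (n < 4) abort("need at least 4 samples")
  if (length(unique(y)) < 2) abort("need at least 2 classes")
  if (lambda < 0) abort("lambda must be >= 0")
  nf <- ncol(x)
  feature_names <- colnames(x) %||% paste0("f", seq_len(nf))

  # per-feature squared differences for all ordered pairs, n^2 x nf
  D2 <- matrix(0, n * n, nf)
  for (f in seq_len(nf)) {
    D2[, f] <- as.vector(outer(x[, f], x[, f], "-")^2)
  }
  same <- matrix(as.numeric(outer(y, y, "==")), n, n)

  w <- rep(init, nf)
  st <- .nca_eval_cpp(D2, same, w, lambda, TRUE)
  trace <- st$objective
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    grad <- st$gradient
    if (sqrt(sum(grad^2)) < 1e-12) {
      converged <- TRUE
      break
    }
    improved <- FALSE
    for (bt in 1:30) {
      w_new <- w + step * grad
      obj_new <- .nca_eval_cpp(D2, same, w_new, lambda, FALSE)$objective
      if (obj_new > st$objective) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {
      converged <- TRUE
      break
    }
    st_new <- .nca_eval_cpp(D2, same, w_new, lambda, TRUE)
    gain <- st_new$objective - st$objective
    w <- w_new
    st <- st_new
    trace <- c(trace, st$objective)
    step <- step * 1.2
    if (gain < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      weights = setNames(abs(w), feature_names),
      feature_names = feature_names,
      lambda = lambda,
      objective_trace = trace,
      converged = converged,
      n = n, n_features = nf
    ),
    class = "qeeg_nca"
  )
}

#' @export
print.qeeg_nca <- function(x, ...) {
  cat(sprintf(
    "<qeeg_nca> %d features, lambda = %.4g, objective %.4f after %d iterations%s\n",
    x$n_features, x$lambda, utils::tail(x$objective_trace, 1),
    length(x$objective_trace) - 1, if (x$converged) " (converged)" else ""
  ))
  top <- sort(x$weights, decreasing = TRUE)
  cat("  top weights:", paste(sprintf("%s=%.3f", names(head(top, 5)), head(top, 5)),
    collapse = ", "
  ), "\n")
  invisible(x)
}

#' Choose the NCA ridge penalty by inner cross-validation
#'
#' Evaluates each candidate lambda by 5-fold cross-validation: NCA is fitted
#' on the training part, features are scaled by the learned weights, and
#' held-out samples are classified with a weighted-space nearest-neighbour
#' vote; the lambda with the highest mean held-out accuracy wins (ties to
#' the smaller lambda).
#'
#' @param x Standardized feature matrix.
#' @param y Labels.
#' @param grid Candidate lambdas; default `c(0, 0.25, 0.5, 1) / n`.
#' @param folds Number of inner folds.
#' @param seed Integer seed for the fold assignment.
#' @return The selected lambda (numeric scalar).
#' @export
select_nca_lambda <- function(x, y, grid = NULL, folds = 5, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(grid)) grid <- c(0, 0.25, 0.5, 1) / n
  fold_id <- make_stratified_folds(y, folds, seed = seed)
  acc <- vapply(grid, function(lam) {
    correct <- 0
    for (k in sort(unique(fold_id))) {
      tr <- fold_id != k
      fit <- nca_fit(x[tr, , drop = FALSE], y[tr], lambda = lam)
      w <- fit$weights
      xt <- sweep(x[tr, , drop = FALSE], 2, w, "*")
      xv <- sweep(x[!tr, , drop = FALSE], 2, w, "*")
      d <- outer(rowSums(xv^2), rowSums(xt^2), "+") - 2 * xv %*% t(xt)
      pred <- y[tr][apply(d, 1, which.min)]
      correct <- correct + sum(pred == y[!tr])
    }
    correct / n
  }, numeric(1))
  grid[which.max(acc)]
}
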
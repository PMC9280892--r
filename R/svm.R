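#' Baseline SVM configuration
#'
#' Hyperparameters of the soft-margin SVM and of the three baseline
#' kernels. `gamma = "scale"` uses the common convention
#' `1 / (d * var(X))` with the total (population) variance of all entries
#' of the training matrix, computed at fit time.
#'
#' @param C soft-margin cost, positive.
#' @param gamma RBF/polynomial scale: positive number or `"scale"`.
#' @param degree polynomial degree, integer >= 1.
#' @param coef0 polynomial offset.
#' @param class_weight `"none"` or `"balanced"` (inverse class-frequency
#'   weights on the training split).
#' @param tolerance solver termination tolerance passed to the SVM
#'   optimizer.
#' @return A list of class `svm_control`.
#' @export
svm_control <- function(C = 1.0, gamma = "scale", degree = 3L, coef0 = 0,
                        class_weight = c("none", "balanced"),
                        tolerance = 0.001) {
  class_weight <- match.arg(class_weight)
  stopifnot(is.numeric(C), C > 0, degree >= 1)
  if (!identical(gamma, "scale")) stopifnot(is.numeric(gamma), gamma > 0)
  structure(list(C = C, gamma = gamma, degree = degree, coef0 = coef0,
                 class_weight = class_weight, tolerance = tolerance),
            class = "svm_control")
}

gamma_scale <- function(a) {
  v <- stats::var(as.numeric(a)) * (length(a) - 1) / length(a)
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(a) * v)
}

resolve_gamma <- function(svm, a) {
  if (identical(svm$gamma, "scale")) gamma_scale(a) else svm$gamma
}

#' Gram matrix of a baseline kernel
#'
#' The three stock kernels the evolved kernels are compared against:
#' linear `<a, b>`, polynomial `(gamma * <a, b> + coef0)^degree`, and
#' radial basis `exp(-gamma * ||a - b||^2)`.
#'
#' @param kind `"linear"`, `"rbf"` or `"poly"`.
#' @param a,b numeric matrices sharing the feature dimension.
#' @param svm an [svm_control()]; `gamma = "scale"` is resolved on `a`.
#' @return A `gf_gram` matrix of kernel values.
#' @export
baseline_gram <- function(kind = c("linear", "rbf", "poly"), a, b = a,
                          svm = svm_control()) {
  kind <- match.arg(kind)
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("a and b must share the feature dimension")
  lin <- tcrossprod(a, b)
  K <- switch(kind,
    linear = lin,
    poly = {
      g <- resolve_gamma(svm, a)
      (g * lin + svm$coef0)^svm$degree
    },
    rbf = {
      g <- resolve_gamma(svm, a)
      d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * lin
      exp(-g * pmax(d2, 0))
    })
  as_gf_gram(K, valid = all(is.finite(K)))
}

as_pm1 <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("labels must have exactly two classes")
    out <- ifelse(as.integer(y) == 2L, 1, -1)
    attr(out, "levels") <- levels(y)
    return(out)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("numeric labels must be coded -1/+1")
  y
}

# Fit libsvm on the empirical kernel map of a clip-repaired square Gram.
# Training a linear SVM on Z = V sqrt(lambda_+) is exactly the soft-margin
# SVM on the clipped precomputed Gram (Z %*% t(Z) reproduces it). For
# numerical conditioning the kernel is rescaled to unit mean self-similarity
# with the cost compensated exactly (kernel K/m at cost C*m has the same
# decision function as kernel K at cost C), which leaves the model
# unchanged while keeping the QP well-scaled for arbitrary evolved kernels.
fit_precomputed <- function(K, y, svm, weights = NULL, factor_tol = 1e-9) {
  fac <- clip_factor(K, tol = factor_tol)
  if (is.null(fac)) return(NULL)
  yf <- factor(y, levels = c(-1, 1))
  cw <- NULL
  if (!is.null(weights)) cw <- weights
  else if (svm$class_weight == "balanced") {
    tab <- table(yf)
    cw <- as.numeric(length(y) / (2 * tab))
    names(cw) <- names(tab)
  }
  m <- mean(rowSums(fac$Z^2))            # mean diagonal of the clipped Gram
  if (!is.finite(m) || m <= 0) m <- 1
  model <- e1071::svm(fac$Z / sqrt(m), yf, kernel = "linear",
                      cost = svm$C * m, scale = FALSE, fitted = FALSE,
                      tolerance = svm$tolerance, class.weights = cw)
  list(model = model, P = fac$P, m = m, levels = c("-1", "1"))
}

# Prediction from a fit_precomputed() handle given the rectangular
# cross-Gram K_new_train (rows: new points, columns: training points).
# Returns list(class = +/-1 vector, score = decision value oriented so
# that larger means the +1 class).
predict_precomputed <- function(fit, K_new_train) {
  Z_new <- (K_new_train %*% fit$P) / sqrt(fit$m)
  pr <- stats::predict(fit$model, Z_new, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- as.numeric(dv)
  # libsvm orients the decision value toward the first label of the
  # colname "a/b"; flip so positive score always means class +1
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first == "-1") score <- -score
  list(class = as.numeric(as.character(pr)), score = score)
}

#' Train and evaluate a precomputed-kernel SVM
#'
#' Trains a soft-margin SVM directly on a (repaired, symmetric) training
#' Gram matrix and evaluates it on a rectangular test Gram whose columns
#' are aligned to the training rows. Internally the Gram is factorized
#' into its exact empirical kernel map and the optimization is delegated
#' to libsvm; the fitted decision function is identical to the
#' precomputed-kernel SVM on the clipped Gram.
#'
#' @param K_train square training Gram (n x n), symmetric after repair.
#' @param y_train training labels: -1/+1 vector or two-level factor.
#' @param K_test optional m-by-n cross Gram `K(test_i, train_j)`.
#' @param y_test optional test labels, required for metrics on the test
#'   split.
#' @param svm an [svm_control()].
#' @return List with `model`, the training accuracy, and - when a test
#'   Gram is supplied - `predictions`, `scores` (decision values oriented
#'   toward the +1 class) and a `metrics` report from
#'   [classification_metrics()].
#' @export
train_eval_precomputed <- function(K_train, y_train, K_test = NULL,
                                   y_test = NULL, svm = svm_control()) {
  K_train <- as.matrix(K_train)
  if (nrow(K_train) != ncol(K_train)) stop("K_train must be square")
  if (nrow(K_train) != length(y_train))
    stop("K_train and y_train sizes disagree")
  y_train <- as_pm1(y_train)
  if (length(unique(y_train)) < 2L)
    stop("training labels contain a single class")
  if (max(abs(K_train - t(K_train))) > 1e-8)
    stop("K_train is not symmetric; repair it first (see repair_gram)")
  fit <- fit_precomputed(K_train, y_train, svm)
  if (is.null(fit)) stop("training Gram has no positive spectrum (degenerate kernel)")
  tr <- predict_precomputed(fit, K_train)
  out <- list(model = fit, train_accuracy = mean(tr$class == y_train))
  if (!is.null(K_test)) {
    K_test <- as.matrix(K_test)
    if (ncol(K_test) != nrow(K_train))
      stop("K_test columns must align to the training rows")
    te <- predict_precomputed(fit, K_test)
    out$predictions <- te$class
    out$scores <- te$score
    if (!is.null(y_test))
      out$metrics <- classification_metrics(as_pm1(y_test), te$class, te$score)
  }
  out
}
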
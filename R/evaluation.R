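#' Stratified k-fold assignments
#'
#' Partitions indices into k folds preserving class proportions: within
#' each class the (shuffled) members are dealt round-robin, so per-fold
#' class counts differ from balance by at most one.
#'
#' @param y labels, -1/+1 or two-level factor.
#' @param k number of folds; every class must have at least k members.
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @return List of k elements, each `list(train =, test =)` index vectors;
#'   the test sets partition `seq_along(y)`.
#' @export
stratified_kfold <- function(y, k = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as_pm1(y)
  k <- as.integer(k)
  stopifnot(k >= 2)
  fold_of <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop("class ", cls, " has fewer members (", length(idx), ") than folds (", k, ")")
    fold_of[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Binary classification metrics
#'
#' Accuracy, mean squared error of the 0/1-coded predictions (identical to
#' the misclassification rate, hence `mse = 1 - accuracy`), the 2x2
#' confusion matrix, and - when decision scores are supplied - the ROC AUC
#' computed as the Mann-Whitney probability that a random positive scores
#' above a random negative, ties counting one half.
#'
#' @param y_true true labels, -1/+1 or two-level factor.
#' @param y_pred predicted labels, same coding.
#' @param scores optional numeric decision scores (larger = more positive).
#' @return List of class `gf_metrics`: `accuracy`, `mse`, `auc` (`NA` when
#'   scores are missing or `y_true` has a single class), `confusion`
#'   (rows: truth, columns: prediction), `n`.
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- as_pm1(y_true); y_pred <- as_pm1(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (!is.null(scores)) stopifnot(length(scores) == length(y_true))
  acc <- mean(y_pred == y_true)
  t01 <- (y_true + 1) / 2; p01 <- (y_pred + 1) / 2
  mse <- mean((p01 - t01)^2)
  lv <- c("-1", "1")
  confusion <- table(truth = factor(y_true, lv), prediction = factor(y_pred, lv))
  auc <- NA_real_
  npos <- sum(y_true == 1); nneg <- sum(y_true == -1)
  if (!is.null(scores) && npos > 0 && nneg > 0) {
    r <- rank(scores)                       # midranks handle ties as 1/2
    auc <- (sum(r[y_true == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  structure(list(accuracy = acc, mse = mse, auc = auc,
                 confusion = confusion, n = length(y_true)),
            class = "gf_metrics")
}

#' @export
print.gf_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | mse %.4f | auc %s | n = %d\n",
              x$accuracy, x$mse,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc), x$n))
  print(x$confusion)
  invisible(x)
}

scale_fit <- function(x) {
  ctr <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(center = ctr, scale = sdv)
}

scale_apply <- function(x, sc) {
  scale(x, center = sc$center, scale = sc$scale)[, , drop = FALSE]
}

#' Compare the evolved kernel against the baseline kernels
#'
#' The nested evaluation protocol: data are split once by stratified
#' `outer_folds`-fold cross-validation; within every outer training split
#' a genetic folding run evolves a kernel (its fitness uses inner
#' cross-validation on that split only), and then the evolved kernel plus
#' the linear, RBF and polynomial baselines are all trained on the split
#' and scored on the identical held-out fold. Feature standardization is
#' re-fit on each outer training split to avoid information leakage.
#'
#' @param x feature matrix, or a `gf_dataset` from [preprocess_survey()]
#'   (in which case `y` is taken from it).
#' @param y labels, -1/+1 or two-level factor.
#' @param control a [gfs_control()] for the evolution runs. When
#'   `control$seed` is set, fold `f` uses seed `control$seed + f` so runs
#'   are reproducible yet independent across folds.
#' @param svm an [svm_control()] shared by all four models.
#' @param outer_folds number of outer folds.
#' @param seed optional seed for the outer fold assignment.
#' @param rescale re-standardize features per outer training split
#'   (default `TRUE`).
#' @return An object of class `gf_comparison`: per-model per-fold metric
#'   tables with mean and (n-1 denominator) SD, the shared fold
#'   assignment, the best evolved chromosome across folds (text and tree
#'   form) and the configuration echo.
#' @export
compare_kernels <- function(x, y = NULL, control = gfs_control(),
                            svm = svm_control(), outer_folds = 5L,
                            seed = NULL, rescale = TRUE) {
  if (inherits(x, "gf_dataset")) { y <- x$y; x <- x$X }
  x <- as.matrix(x); y <- as_pm1(y)
  if (length(unique(y)) < 2L)
    stop("comparison needs both outcome classes present")
  folds <- stratified_kfold(y, outer_folds, seed = seed)
  models <- c("gfs", "linear", "rbf", "poly")
  per_fold <- lapply(models, function(m)
    data.frame(fold = integer(0), accuracy = numeric(0), auc = numeric(0),
               mse = numeric(0)))
  names(per_fold) <- models
  confusions <- lapply(models, function(m) matrix(0, 2, 2))
  names(confusions) <- models
  best <- NULL
  evo_fitness <- numeric(length(folds))
  roc <- data.frame(fold = integer(0), model = character(0),
                    score = numeric(0), truth = numeric(0))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    Xtr <- x[tr, , drop = FALSE]; Xte <- x[te, , drop = FALSE]
    if (rescale) {
      sc <- scale_fit(Xtr)
      Xtr <- scale_apply(Xtr, sc); Xte <- scale_apply(Xte, sc)
    }
    ytr <- y[tr]; yte <- y[te]
    ctrl <- control
    if (!is.null(control$seed)) ctrl$seed <- control$seed + f
    evo <- evolve_kernel(Xtr, ytr, ctrl)
    evo_fitness[f] <- evo$best$fitness
    if (is.null(best) || evo$best$fitness > best$fitness ||
        (evo$best$fitness == best$fitness && evo$best$complexity < best$complexity))
      best <- evo$best
    grams <- list(
      gfs = list(tr = repair_gram(kernel_gram(evo$best$expression, Xtr), "clip"),
                 te = kernel_cross_gram(evo$best$expression, Xte, Xtr)),
      linear = list(tr = baseline_gram("linear", Xtr, svm = svm),
                    te = baseline_gram("linear", Xte, Xtr, svm = svm)),
      rbf = list(tr = baseline_gram("rbf", Xtr, svm = svm),
                 te = baseline_gram("rbf", Xte, Xtr, svm = svm)),
      poly = list(tr = baseline_gram("poly", Xtr, svm = svm),
                  te = baseline_gram("poly", Xte, Xtr, svm = svm)))
    for (m in models) {
      Ktr <- unclass(grams[[m]]$tr)
      Ktr <- (Ktr + t(Ktr)) / 2
      res <- train_eval_precomputed(Ktr, ytr, unclass(grams[[m]]$te), yte, svm)
      mt <- res$metrics
      per_fold[[m]] <- rbind(per_fold[[m]], data.frame(
        fold = f, accuracy = mt$accuracy, auc = mt$auc, mse = mt$mse))
      confusions[[m]] <- confusions[[m]] + unclass(mt$confusion)
      roc <- rbind(roc, data.frame(fold = f, model = m,
                                   score = res$scores, truth = yte))
    }
  }
  summarize <- function(df) {
    data.frame(metric = c("accuracy", "auc", "mse"),
               mean = c(mean(df$accuracy), mean(df$auc), mean(df$mse)),
               sd = c(stats::sd(df$accuracy), stats::sd(df$auc), stats::sd(df$mse)))
  }
  structure(list(
    models = stats::setNames(lapply(models, function(m) list(
      per_fold = per_fold[[m]], summary = summarize(per_fold[[m]]),
      confusion = confusions[[m]])), models),
    folds = folds, roc = roc,
    best = list(chromosome = best$chromosome, expression = best$expression,
                line = chromosome_line(best$chromosome),
                tree = tree_format(best$expression),
                fitness = best$fitness, complexity = best$complexity),
    evolution_fitness = evo_fitness,
    control = control, svm = svm, outer_folds = length(folds)),
    class = "gf_comparison")
}

#' @export
print.gf_comparison <- function(x, digits = 3, ...) {
  cat("Kernel comparison over", x$outer_folds, "stratified outer folds\n\n")
  tab <- t(vapply(x$models, function(m) {
    s <- m$summary
    c(accuracy = s$mean[1], acc_sd = s$sd[1], auc = s$mean[2], mse = s$mean[3])
  }, numeric(4)))
  print(round(tab, digits))
  cat("\nbest evolved kernel (fitness ", format(x$best$fitness, digits = 4),
      ", complexity ", x$best$complexity, "):\n", sep = "")
  cat(" ", x$best$line, "\n")
  cat(paste0("  ", x$best$tree, collapse = "\n"), "\n")
  invisible(x)
}
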
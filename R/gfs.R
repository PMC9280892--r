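#' Fit a genetic-folding evolved-kernel SVM
#'
#' The main modelling entry point. A genetic folding run evolves a kernel
#' expression on the training data (fitness = stratified cross-validated
#' accuracy of an SVM on the candidate's clip-repaired precomputed Gram
#' matrix), and the final soft-margin SVM is then refit with the best
#' kernel on all training rows.
#'
#' @param x feature matrix or data frame (numeric columns), or a model
#'   formula.
#' @param ... further arguments passed to methods.
#' @return An object of class `gfs`; see Details for components.
#'
#' @details The returned object carries the best chromosome and expression,
#' the full evolution history (per-generation best/mean fitness and best
#' complexity), the fitted SVM, the empirical kernel map needed for
#' prediction, and the training scaling parameters. Methods:
#' [predict.gfs()], `print`, `summary`, `plot` (fitness trajectory) and
#' `fitted`.
#'
#' @examples
#' \donttest{
#' tab <- synthesize_survey(survey_config(n = 120, seed = 1))
#' ds <- preprocess_survey(tab)
#' fit <- gfs(ds$X, ds$y, control = gfs_control(population_size = 10,
#'                                              generations = 3, seed = 1))
#' fit
#' }
#' @export
gfs <- function(x, ...) UseMethod("gfs")

#' @rdname gfs
#' @param y labels: -1/+1 numeric vector or two-level factor (second level
#'   is the positive class).
#' @param control a [gfs_control()] with the evolution settings.
#' @param svm an [svm_control()] for the final refit.
#' @param scale z-score standardize the feature columns before fitting
#'   (statistics are stored and re-applied in `predict`). Default `TRUE`;
#'   set `FALSE` when the input is already standardized.
#' @export
gfs.default <- function(x, y, control = gfs_control(), svm = svm_control(),
                        scale = TRUE, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  ylab <- if (is.factor(y)) levels(y) else c("-1", "1")
  y <- as_pm1(y)
  if (nrow(x) != length(y)) stop("x and y sizes disagree")
  scaling <- NULL
  if (scale) {
    scaling <- scale_fit(x)
    x <- scale_apply(x, scaling)
  }
  evo <- evolve_kernel(x, y, control)
  expr <- evo$best$expression
  K <- kernel_gram(expr, x)
  if (!isTRUE(attr(K, "valid")))
    stop("best evolved kernel produced non-finite Gram entries on refit")
  K <- unclass((K + t(K)) / 2)
  svm_refit <- svm
  svm_refit$C <- control$C
  if (control$balance == "weights") svm_refit$class_weight <- "balanced"
  fit <- fit_precomputed(K, y, svm_refit)
  if (is.null(fit)) stop("best evolved kernel is degenerate (no positive spectrum)")
  tr <- predict_precomputed(fit, K)
  obj <- structure(list(
    call = match.call(), levels = ylab,
    control = control, svm = svm_refit, scaling = scaling,
    evolution = evo,
    best_chromosome = evo$best$chromosome,
    best_expression = expr,
    fitness = evo$best$fitness,
    complexity = evo$best$complexity,
    model = fit, x_train = x, y = y,
    fitted = tr$class, decision = tr$score,
    training_accuracy = mean(tr$class == y)), class = "gfs")
  obj
}

#' @rdname gfs
#' @param formula model formula, outcome on the left.
#' @param data data frame holding the formula variables.
#' @export
gfs.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  tm <- attr(mf, "terms")
  attr(tm, "intercept") <- 0L
  x <- stats::model.matrix(tm, mf)
  obj <- gfs.default(x, y, ...)
  obj$terms <- tm
  obj$call <- match.call()
  obj
}

#' Predict from a fitted evolved-kernel SVM
#'
#' Builds the cross Gram between the new observations and the training
#' rows under the evolved kernel, maps it through the stored empirical
#' kernel map and applies the fitted SVM.
#'
#' @param object a fitted [gfs()] model.
#' @param newdata feature matrix or data frame with the training columns
#'   (or the formula variables when the model was formula-fitted); omitted
#'   = training data.
#' @param type `"class"` for labels (coded as the training labels were) or
#'   `"decision"` for the real-valued decision score oriented toward the
#'   positive class.
#' @param ... unused.
#' @return Vector of predictions.
#' @export
predict.gfs <- function(object, newdata = NULL, type = c("class", "decision"),
                        ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    out <- if (type == "class") object$fitted else object$decision
    return(relabel_gfs(object, out, type))
  }
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    mf <- stats::model.frame(stats::delete.response(object$terms), newdata)
    newdata <- stats::model.matrix(stats::delete.response(object$terms), mf)
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x_train))
    stop("newdata has ", ncol(newdata), " columns; training data had ",
         ncol(object$x_train))
  if (!is.null(object$scaling)) newdata <- scale_apply(newdata, object$scaling)
  K <- kernel_cross_gram(object$best_expression, newdata, object$x_train)
  if (!isTRUE(attr(K, "valid")))
    stop("evolved kernel produced non-finite values on newdata")
  pr <- predict_precomputed(object$model, unclass(K))
  relabel_gfs(object, if (type == "class") pr$class else pr$score, type)
}

relabel_gfs <- function(object, out, type) {
  if (type == "decision") return(out)
  if (identical(object$levels, c("-1", "1"))) return(out)
  factor(object$levels[ifelse(out == 1, 2L, 1L)], levels = object$levels)
}

#' @export
fitted.gfs <- function(object, ...) relabel_gfs(object, object$fitted, "class")

#' @export
print.gfs <- function(x, ...) {
  cat("Evolved-kernel SVM (genetic folding strategy)\n")
  cat("call:", deparse(x$call), "\n\n")
  cat("best kernel:", format(x$best_expression), "\n")
  cat("  ", chromosome_line(x$best_chromosome), "\n")
  cat(sprintf("CV fitness %.4f | complexity %d | training accuracy %.4f\n",
              x$fitness, x$complexity, x$training_accuracy))
  invisible(x)
}

#' @export
summary.gfs <- function(object, ...) {
  structure(list(object = object), class = "summary.gfs")
}

#' @export
print.summary.gfs <- function(x, ...) {
  o <- x$object
  print(o)
  cat("\nkernel tree:\n")
  cat(paste0("  ", tree_format(o$best_expression), collapse = "\n"), "\n")
  cat("\nevolution history (", o$evolution$generations_run, " generations ):\n")
  print(utils::tail(o$evolution$history, 5L), row.names = FALSE)
  cat("\nsupport vectors:", nrow(o$model$model$SV), "of", length(o$y),
      "training rows\n")
  cat("class balance: ", sum(o$y == 1), "positive vs", sum(o$y == -1),
      "negative\n")
  invisible(x)
}

#' Plot the fitness trajectory of a genetic folding run
#'
#' Best and mean population fitness per generation, with the best kernel's
#' complexity on a secondary axis.
#'
#' @param x a fitted `gfs` model (or a `gf_evolution` result).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gfs <- function(x, ...) {
  h <- if (inherits(x, "gfs")) x$evolution$history else x$history
  graphics::matplot(h$generation, cbind(h$best_fitness, h$mean_fitness),
                    type = "b", pch = c(19, 1), lty = c(1, 2),
                    col = c("black", "grey50"),
                    xlab = "generation", ylab = "fitness (CV accuracy)", ...)
  graphics::legend("bottomright", c("best", "population mean"),
                   pch = c(19, 1), lty = c(1, 2), col = c("black", "grey50"),
                   bty = "n")
  invisible(x)
}

#' @export
plot.gf_evolution <- plot.gfs
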
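test_that("baseline kernels match their closed forms", {
  set.seed(10)
  A <- matrix(rnorm(8 * 3), 8, 3)
  B <- matrix(rnorm(5 * 3), 5, 3)

  expect_equal(unclass(baseline_gram("linear", A, B)), tcrossprod(A, B),
               ignore_attr = TRUE)
  # rbf self-similarity is 1 for any gamma
  expect_equal(diag(unclass(baseline_gram("rbf", A, svm = svm_control(gamma = 0.7)))),
               rep(1, 8))
  # degree-1 polynomial with gamma 1 and coef0 0 is the linear kernel
  s1 <- svm_control(gamma = 1, degree = 1, coef0 = 0)
  expect_equal(unclass(baseline_gram("poly", A, B, s1)),
               unclass(baseline_gram("linear", A, B, s1)), ignore_attr = TRUE)
  # standard basis rows
  E <- diag(2)
  expect_equal(unclass(baseline_gram("linear", E)), diag(2), ignore_attr = TRUE)
  expect_error(svm_control(gamma = -1))
})

test_that("baseline Grams agree with kernlab's kernel matrices", {
  library(kernlab)
  set.seed(12)
  A <- matrix(rnorm(10 * 4), 10, 4)
  g <- 0.3
  expect_lt(max(abs(baseline_gram("rbf", A, svm = svm_control(gamma = g)) -
                    kernelMatrix(rbfdot(sigma = g), A))), 1e-12)
  expect_lt(max(abs(baseline_gram("poly", A, svm = svm_control(gamma = g, degree = 2, coef0 = 1)) -
                    kernelMatrix(polydot(degree = 2, scale = g, offset = 1), A))), 1e-12)
  expect_lt(max(abs(baseline_gram("linear", A) -
                    kernelMatrix(vanilladot(), A))), 1e-12)
})

test_that("the baseline linear Gram and the linear chromosome's Gram coincide", {
  set.seed(13)
  X <- matrix(rnorm(12 * 4), 12, 4)
  expect_lt(max(abs(baseline_gram("linear", X) -
                    kernel_gram(decode_chromosome(linear_chromosome()), X))), 1e-12)
})

test_that("precomputed-kernel SVM separates separable data and validates input", {
  sep <- make_separable(n = 50, seed = 3)
  tr <- c(1:20, 26:45); te <- setdiff(1:50, tr)
  K <- unclass(baseline_gram("linear", sep$X))
  res <- train_eval_precomputed(K[tr, tr], sep$y[tr], K[te, tr], sep$y[te])
  expect_equal(res$metrics$accuracy, 1.0)
  expect_equal(res$train_accuracy, 1.0)
  expect_equal(res$metrics$mse, 1 - res$metrics$accuracy)

  expect_error(train_eval_precomputed(K[tr, tr], rep(1, length(tr))), "single class")
  expect_error(train_eval_precomputed(K[tr, te], sep$y[tr]), "square")
  expect_error(train_eval_precomputed(K[tr, tr] + matrix(rnorm(1600), 40), sep$y[tr]),
               "symmetric")
  expect_error(train_eval_precomputed(K[tr, tr], sep$y[tr], K_test = K[te, te]),
               "align")
})

test_that("the empirical-map route reproduces a native linear SVM", {
  set.seed(14)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5)
  y <- sign(X[, 1] + 0.5 * rnorm(n)); y[y == 0] <- 1
  K <- tcrossprod(X)
  res <- train_eval_precomputed(K, y, K, y)
  direct <- e1071::svm(X, factor(y, levels = c(-1, 1)), kernel = "linear",
                       cost = 1, scale = FALSE)
  pd <- as.numeric(as.character(predict(direct, X)))
  expect_gt(mean(res$predictions == pd), 0.97)
})

test_that("decision scores are oriented toward the positive class", {
  sep <- make_separable(n = 40, seed = 5)
  K <- unclass(baseline_gram("linear", sep$X))
  res <- train_eval_precomputed(K, sep$y, K, sep$y)
  expect_true(all(res$scores[sep$y == 1] > res$scores[sep$y == -1]))
  expect_equal(res$metrics$auc, 1.0)
})

test_that("balanced class weights are accepted on imbalanced data", {
  set.seed(16)
  X <- rbind(matrix(rnorm(60 * 3, 1.5), 60, 3), matrix(rnorm(12 * 3, -1.5), 12, 3))
  y <- c(rep(1, 60), rep(-1, 12))
  K <- tcrossprod(X)
  res <- train_eval_precomputed(K, y, K, y, svm_control(class_weight = "balanced"))
  expect_gt(res$metrics$accuracy, 0.9)
})
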
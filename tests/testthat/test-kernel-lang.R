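test_that("evaluation semantics reproduce hand-computed kernel values", {
  lin <- gf_expr("*_s", gf_expr("x"), gf_expr("y"))
  expect_equal(eval_kernel(lin, c(1, 2), c(3, 4)), 11)

  # +_v(y,x) = (4,6); -_s -> (4+6) - (1+2) = 7; *_s -> 7 * (1+2) = 21
  ex <- decode_chromosome(example_chromosome())
  expect_equal(eval_kernel(ex, c(1, 2), c(3, 4)), 21)

  expect_equal(eval_kernel(gf_expr("+_s", gf_expr("x"), gf_expr("x")), c(0, 0), c(5, 5)), 0)

  # elementwise difference then implicit reduction: zero at x == y
  dv <- gf_expr("-_v", gf_expr("x"), gf_expr("y"))
  expect_equal(eval_kernel(dv, c(2, 3), c(2, 3)), 0)
  expect_equal(eval_kernel(dv, c(2, 3), c(1, 1)), 3)

  expect_error(eval_kernel(lin, c(1, 2), c(1, 2, 3)), "equal")
})

test_that("vectorized Gram equals entrywise brute force on random expressions", {
  set.seed(21)
  A <- matrix(rnorm(12 * 5), 12, 5)
  B <- matrix(rnorm(9 * 5), 9, 5)
  for (i in 1:10) {
    ex <- random_expression(4)
    expect_lt(max(abs(kernel_gram(ex, A, B) - brute_gram(ex, A, B))), 1e-10)
  }
})

test_that("the language contains the linear kernel up to floating error", {
  set.seed(2)
  X <- matrix(rnorm(15 * 6), 15, 6)
  lin <- decode_chromosome(linear_chromosome())
  expect_lt(max(abs(kernel_gram(lin, X) - tcrossprod(X))), 1e-12)
})

test_that("non-finite Gram entries flag the kernel invalid", {
  sq <- gf_expr("*_s", gf_expr("*_s", gf_expr("x"), gf_expr("x")),
                gf_expr("*_s", gf_expr("y"), gf_expr("y")))
  X <- matrix(1e200, 2, 2)
  K <- kernel_gram(sq, X)
  expect_false(attr(K, "valid"))
})

test_that("Gram repair symmetrizes and clips as specified", {
  G <- matrix(c(0, -1, 1, 0), 2, 2)
  expect_equal(unclass(repair_gram(G, "symmetrize")), matrix(0, 2, 2),
               ignore_attr = TRUE)

  expect_equal(unclass(repair_gram(diag(c(1, -1)), "clip")), diag(c(1, 0)),
               ignore_attr = TRUE)

  # PSD fixed point and idempotence
  set.seed(4)
  X <- matrix(rnorm(40), 10, 4)
  P <- tcrossprod(X)
  expect_lt(max(abs(repair_gram(P, "clip") - P)), 1e-10)
  R1 <- repair_gram(matrix(rnorm(64), 8, 8), "clip")
  R2 <- repair_gram(unclass(R1), "clip")
  expect_lt(max(abs(R1 - R2)), 1e-8)
  expect_gt(min(eigen(unclass(R1), symmetric = TRUE)$values), -1e-8)

  expect_error(repair_gram(matrix(0, 2, 3)), "square")
})

test_that("symmetrized cross Gram makes every evolved kernel symmetric", {
  set.seed(31)
  X <- matrix(rnorm(10 * 4), 10, 4)
  for (i in 1:10) {
    ex <- random_expression(4)
    S <- repair_gram(kernel_gram(ex, X), "symmetrize")
    expect_identical(unclass(S), t(unclass(S)))     # bit-equal after symmetrize
    # cross Gram of the same rows equals the symmetrized square Gram
    C <- kernel_cross_gram(ex, X, X)
    expect_lt(max(abs(C - S)), 1e-12)
  }
})

test_that("cosine normalization yields unit diagonal and refuses bad diagonals", {
  set.seed(6)
  X <- matrix(rnorm(30), 10, 3)
  K <- tcrossprod(X) + diag(10)
  N <- cosine_normalize(K)
  expect_equal(diag(unclass(N)), rep(1, 10))
  expect_error(cosine_normalize(diag(c(1, 0, 2))), "non-positive")
})

test_that("complexity counts operator nodes", {
  expect_identical(kernel_complexity(decode_chromosome(example_chromosome())), 3L)
  expect_identical(kernel_complexity(gf_expr("x")), 0L)
  set.seed(8)
  for (i in 1:30) {
    tr <- random_expression(5)
    ch <- encode_expression(tr)
    expect_identical(kernel_complexity(tr),
                     length(ch) - sum(is.na(ch$left)))
  }
})

test_that("random expressions respect depth bounds and seeding", {
  set.seed(9)
  expect_true(format(random_expression(0)) %in% gf_terminals())
  for (i in 1:50) {
    tr <- random_expression(3)
    ch <- encode_expression(tr)
    expect_s3_class(validate_chromosome(ch), "gf_chromosome")
    expect_lte(kernel_complexity(tr), 2^3 - 1)
  }
  set.seed(123); a <- random_expression(5)
  set.seed(123); b <- random_expression(5)
  expect_true(expr_identical(a, b))
  expect_error(random_expression(3, operators = character(0)), "nonempty")
})
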
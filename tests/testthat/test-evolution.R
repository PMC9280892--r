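test_that("roulette selection is fitness-proportionate with uniform fallback", {
  set.seed(20)
  expect_true(all(replicate(50, roulette_select(c(1, 0, 0))) == 1))

  draws <- replicate(4000, roulette_select(c(1, 1)))
  expect_gt(mean(draws == 1), 0.45)
  expect_lt(mean(draws == 1), 0.55)

  zero <- table(factor(replicate(3000, roulette_select(c(0, 0, 0))), 1:3))
  expect_gt(stats::chisq.test(zero)$p.value, 0.001)

  expect_error(roulette_select(numeric(0)), "empty")
  expect_error(roulette_select(c(-1, 2)), "negative")
})

test_that("fitness is perfect for the linear kernel on separable data", {
  sep <- make_separable(n = 60, d = 4, gap = 8, seed = 2)
  set.seed(1)
  f <- kernel_fitness(linear_chromosome(), sep$X, sep$y,
                      gfs_control(population_size = 2, generations = 1))
  expect_equal(f, 1.0)
})

test_that("degenerate kernels score zero fitness", {
  sep <- make_separable(n = 40, seed = 4)
  ctrl <- gfs_control(population_size = 2, generations = 1)
  set.seed(2)
  # -_s(x, x) is identically zero: constant Gram
  const <- encode_expression(gf_expr("-_s", gf_expr("x"), gf_expr("x")))
  expect_equal(kernel_fitness(const, sep$X, sep$y, ctrl), 0)
  # overflowing kernel: non-finite Gram
  deep <- gf_expr("*_s", gf_expr("x"), gf_expr("y"))
  for (i in 1:9) deep <- gf_expr("*_s", deep, deep)
  set.seed(2)
  expect_equal(kernel_fitness(encode_expression(deep), sep$X * 1e30, sep$y, ctrl), 0)
  expect_error(kernel_fitness(linear_chromosome(), sep$X, rep(1, 40), ctrl),
               "both classes")
})

test_that("evolution is reproducible and its best fitness never decreases", {
  sep <- make_separable(n = 50, d = 4, gap = 2.5, seed = 6)
  ctrl <- gfs_control(population_size = 8, generations = 6, max_depth = 3, seed = 99)
  e1 <- evolve_kernel(sep$X, sep$y, ctrl)
  e2 <- evolve_kernel(sep$X, sep$y, ctrl)
  expect_identical(e1$history, e2$history)
  expect_true(chrom_equal(e1$best$chromosome, e2$best$chromosome))
  expect_identical(e1$best$fitness, e2$best$fitness)

  expect_true(all(diff(e1$history$best_fitness) >= 0))
  expect_true(all(e1$history$best_fitness >= 0 & e1$history$best_fitness <= 1))
  expect_identical(nrow(e1$history), 6L)
  expect_equal(e1$best$fitness, max(e1$history$best_fitness))

  # every survivor is a structurally valid chromosome
  for (rec in e1$population)
    expect_s3_class(validate_chromosome(rec$chromosome), "gf_chromosome")
})

test_that("a one-individual, one-generation run returns that individual", {
  sep <- make_separable(n = 40, seed = 7)
  e <- evolve_kernel(sep$X, sep$y,
                     gfs_control(population_size = 1, generations = 1, seed = 3))
  expect_identical(nrow(e$history), 1L)
  expect_s3_class(validate_chromosome(e$best$chromosome), "gf_chromosome")
  expect_identical(e$generations_run, 1L)
})

test_that("early stopping halts after `patience` stale generations", {
  sep <- make_separable(n = 40, seed = 8)
  e <- evolve_kernel(sep$X, sep$y,
                     gfs_control(population_size = 6, generations = 15,
                                 patience = 2, seed = 5))
  expect_lt(e$generations_run, 15L)
})

test_that("restricted to the scalar product, evolution matches the linear baseline", {
  sep <- make_separable(n = 60, d = 4, gap = 8, seed = 9)
  ctrl <- gfs_control(population_size = 4, generations = 2, max_depth = 1,
                      operators = "*_s", seed = 11)
  e <- evolve_kernel(sep$X, sep$y, ctrl)
  set.seed(11)
  folds <- stratified_kfold(sep$y, 5)
  lin_acc <- cv_accuracy_gram(unclass(baseline_gram("linear", sep$X)), sep$y, folds)
  expect_equal(e$best$fitness, lin_acc)   # both 1.0 on separable data
})
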
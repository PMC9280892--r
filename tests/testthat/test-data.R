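test_that("the bundled sample survey CSV reads with shortcut headers", {
  path <- system.file("extdata", "survey_sample.csv", package = "genofold")
  tab <- read_survey_csv(path)
  expect_s3_class(tab, "survey_table")
  expect_identical(nrow(tab), 5L)
  expect_identical(sum(tab$LUNG_CANCER == "YES"), 2L)
  expect_identical(tab$GENDER, c("M", "M", "F", "M", "F"))
  expect_identical(tab$AGE, c(69, 74, 59, 63, 63))
  expect_setequal(names(tab), survey_columns())
})

test_that("missing columns and empty files are rejected by name", {
  tmp <- tempfile(fileext = ".csv")
  tab <- synthesize_survey(survey_config(n = 6, seed = 1))
  write.csv(tab[, setdiff(names(tab), "SMOKING")], tmp, row.names = FALSE)
  expect_error(read_survey_csv(tmp), "SMOKING")

  writeLines(paste(survey_columns(), collapse = ","), tmp)
  expect_error(read_survey_csv(tmp), "no data rows")
  expect_error(read_survey_csv(tempfile()), "cannot read")
})

test_that("preprocessing drops incomplete rows, encodes and standardizes", {
  tab <- synthesize_survey(survey_config(n = 40, seed = 2))
  tab$AGE[3] <- NA
  ds <- preprocess_survey(tab)
  expect_identical(ds$dropped, 1L)
  expect_identical(nrow(ds$X), 39L)
  expect_identical(ds$n_input, 40L)
  expect_true(all(abs(colMeans(ds$X)) < 1e-9))
  sds <- apply(ds$X, 2, sd)
  expect_true(all(abs(sds[!ds$scaling$zero_variance] - 1) < 1e-9))
  # label coding follows the YES/NO outcome
  expect_identical(unname(ds$y), ifelse(tab$LUNG_CANCER[-3] == "YES", 1, -1))
  # gender coded M = 2 / F = 1 before scaling
  expect_identical(ds$scaling$center[["GENDER"]],
                   mean(ifelse(tab$GENDER[-3] == "M", 2, 1)))
})

test_that("out-of-code values are rejected with the column named", {
  tab <- synthesize_survey(survey_config(n = 10, seed = 3))
  bad <- tab; bad$WHEEZING[2] <- 7
  expect_error(preprocess_survey(bad), "WHEEZING")
  bad <- tab; bad$GENDER[1] <- "Q"
  expect_error(preprocess_survey(bad), "GENDER")
  bad <- tab; bad$LUNG_CANCER[1] <- "MAYBE"
  expect_error(preprocess_survey(bad), "LUNG_CANCER")
})

test_that("scaling parameters are fit on the requested subset only", {
  tab <- synthesize_survey(survey_config(n = 60, seed = 4))
  fit_idx <- 1:40
  ds <- suppressWarnings(preprocess_survey(tab, fit_on = fit_idx))
  ok <- !ds$scaling$zero_variance
  expect_true(all(abs(colMeans(ds$X[fit_idx, ok])) < 1e-9))
  # applying the stored parameters reproduces the matrix bit-exactly
  raw <- cbind(GENDER = ifelse(tab$GENDER == "M", 2, 1), AGE = tab$AGE,
               as.matrix(tab[, setdiff(survey_columns(),
                                       c("GENDER", "AGE", "LUNG_CANCER"))]))
  redo <- scale(raw, center = ds$scaling$center, scale = ds$scaling$scale)
  expect_identical(unname(unclass(ds$X)), unname(redo[, , drop = FALSE]))
})

test_that("zero-variance columns are kept as constant zero with a warning", {
  tab <- synthesize_survey(survey_config(n = 20, seed = 5))
  tab$SMOKING <- 2
  expect_warning(ds <- preprocess_survey(tab), "SMOKING")
  expect_true(all(ds$X[, "SMOKING"] == 0))
})

test_that("synthetic tables are deterministic and round-trip through CSV", {
  cfg <- survey_config(n = 50, seed = 77)
  t1 <- synthesize_survey(cfg)
  t2 <- synthesize_survey(cfg)
  expect_identical(t1, t2)
  tmp <- tempfile(fileext = ".csv")
  write_survey_csv(t1, tmp)
  back <- read_survey_csv(tmp)
  expect_identical(back$GENDER, t1$GENDER)
  expect_identical(back$LUNG_CANCER, t1$LUNG_CANCER)
  expect_equal(as.matrix(back[, 2:15]), as.matrix(t1[, 2:15]), ignore_attr = TRUE)
})

test_that("generated data matches the configured class balance and age", {
  tab <- synthesize_survey(survey_config(n = 4000, seed = 6))
  expect_lt(abs(mean(tab$LUNG_CANCER == "NO") - 39 / 309), 0.02)
  expect_lt(abs(mean(tab$AGE) - 62.6), 0.5)
  expect_true(all(tab$AGE >= 21 & tab$AGE <= 90))
  # marginal symptom means track the configured targets
  expect_lt(abs(mean(tab$FATIGUE) - 1.8), 0.03)
  expect_lt(abs(mean(tab$COUGHING) - 1.6), 0.03)
  expect_lt(abs(mean(tab$ANXIETY) - 1.5), 0.03)
})

test_that("the XOR generator keeps the marginal outcome rate", {
  cfg <- survey_config(n = 4000, benign_fraction = 0.3, nonlinear_pair = c(1, 2),
                       effect_size = 4, seed = 7)
  tab <- synthesize_survey(cfg)
  expect_lt(abs(mean(tab$LUNG_CANCER == "NO") - 0.3), 0.03)
  # the interaction carries signal: outcome rate differs strongly across xor cells
  s <- xor(tab$SMOKING == 2, tab$YELLOW_FINGERS == 2)
  expect_gt(mean(tab$LUNG_CANCER[s] == "YES") -
            mean(tab$LUNG_CANCER[!s] == "YES"), 0.5)
})

test_that("a planted linear signal is recoverable by a linear SVM", {
  cfg <- survey_config(n = 300, linear_effect = 0.35, seed = 8)
  ds <- preprocess_survey(synthesize_survey(cfg))
  majority <- max(mean(ds$y == 1), mean(ds$y == -1))
  folds <- stratified_kfold(ds$y, 5, seed = 8)
  acc <- cv_accuracy_gram(unclass(baseline_gram("linear", ds$X)), ds$y, folds)
  expect_gt(acc, majority)
})
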
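# Canonical column set of the clinical survey dialect: gender, age,
# thirteen symptom indicators coded YES=2/NO=1, and a YES/NO outcome.
SURVEY_FEATURES <- c("GENDER", "AGE", "SMOKING", "YELLOW_FINGERS", "ANXIETY",
                     "PEER_PRESSURE", "CHRONIC_DISEASE", "FATIGUE", "ALLERGY",
                     "WHEEZING", "ALCOHOL_CONSUMING", "COUGHING",
                     "SHORTNESS_OF_BREATH", "SWALLOWING_DIFFICULTY",
                     "CHEST_PAIN")
SURVEY_OUTCOME <- "LUNG_CANCER"

#' Column names of the survey dialect
#' @return Character vector: fifteen feature columns followed by the
#'   outcome column.
#' @export
survey_columns <- function() c(SURVEY_FEATURES, SURVEY_OUTCOME)

normalize_colname <- function(x) {
  x <- toupper(trimws(x))
  x <- gsub("[^A-Z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

# Positional shortcut headers (F_1..F_15 + Out) are also accepted.
survey_aliases <- function() {
  stats::setNames(c(SURVEY_FEATURES, SURVEY_OUTCOME),
                  c(paste0("F_", 1:15), "OUT"))
}

#' Read a clinical survey CSV
#'
#' Accepts the survey dialect: a header with the fifteen feature columns
#' and the outcome (name matching is case- and punctuation-insensitive;
#' the positional shortcuts `F_1..F_15`/`Out` are also accepted), gender
#' coded `M`/`F`, age as an integer, symptoms coded `2` = yes / `1` = no,
#' outcome `YES`/`NO`. Unknown code values and missing cells are preserved
#' as read; [preprocess_survey()] rejects or drops them.
#'
#' @param path CSV file path.
#' @return A `survey_table` (a data.frame with the canonical columns).
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read survey CSV: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  names(df) <- normalize_colname(names(df))
  al <- survey_aliases()
  hit <- names(df) %in% names(al)
  names(df)[hit] <- al[names(df)[hit]]
  missing_cols <- setdiff(survey_columns(), names(df))
  if (length(missing_cols) > 0)
    stop("survey CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("survey CSV has no data rows")
  df <- df[, survey_columns()]
  df$GENDER <- toupper(trimws(as.character(df$GENDER)))
  df$GENDER[df$GENDER %in% c("NA", "")] <- NA
  df$LUNG_CANCER <- toupper(trimws(as.character(df$LUNG_CANCER)))
  df$LUNG_CANCER[df$LUNG_CANCER %in% c("NA", "")] <- NA
  for (col in setdiff(survey_columns(), c("GENDER", SURVEY_OUTCOME)))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  class(df) <- c("survey_table", "data.frame")
  df
}

#' Write a survey table as CSV
#'
#' Inverse of [read_survey_csv()]: tables written here round-trip through
#' the reader byte-identically in content.
#'
#' @param table a `survey_table` data.frame.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_survey_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Preprocess a survey table into a modelling dataset
#'
#' Applies the preprocessing pipeline: rows containing any missing value
#' are excluded (and counted), gender is encoded M = 2 / F = 1 to match the
#' 1/2 symptom coding, the YES/NO outcome maps to +1/-1, and every feature
#' column is z-score standardized with mean and standard deviation fitted
#' on the `fit_on` row subset only (the training split) and applied to all
#' retained rows. Out-of-code values (a symptom other than 1/2, a gender
#' other than M/F, an outcome other than YES/NO) are rejected with an
#' error naming the column.
#'
#' @param table a `survey_table`.
#' @param fit_on optional integer subset (indices into the *retained* rows)
#'   on which scaling parameters are fitted; defaults to all retained rows.
#' @return An object of class `gf_dataset`: `X` (n x 15 standardized
#'   matrix), `y` (+1 = YES / -1 = NO), `feature_names`, `scaling`
#'   (`center`, `scale`, `zero_variance`), `dropped` (excluded row count)
#'   and `n_input`.
#' @export
preprocess_survey <- function(table, fit_on = NULL) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(survey_columns(), names(table))
  if (length(missing_cols) > 0)
    stop("survey table is missing column(s): ", paste(missing_cols, collapse = ", "))
  n_input <- nrow(table)
  if (n_input == 0) stop("empty survey table")
  gender <- toupper(trimws(as.character(table$GENDER)))
  bad <- !is.na(gender) & !gender %in% c("M", "F")
  if (any(bad)) stop("column GENDER: unknown code '", gender[bad][1], "'")
  outc <- toupper(trimws(as.character(table$LUNG_CANCER)))
  bad <- !is.na(outc) & !outc %in% c("YES", "NO")
  if (any(bad)) stop("column LUNG_CANCER: unknown code '", outc[bad][1], "'")
  for (col in setdiff(SURVEY_FEATURES, c("GENDER", "AGE"))) {
    v <- table[[col]]
    bad <- !is.na(v) & !v %in% c(1, 2)
    if (any(bad)) stop("column ", col, ": unknown code '", v[bad][1], "' (expected 1/2)")
  }
  X <- cbind(GENDER = ifelse(gender == "M", 2, 1),
             AGE = as.numeric(table$AGE),
             as.matrix(table[, setdiff(SURVEY_FEATURES, c("GENDER", "AGE"))]))
  y <- ifelse(outc == "YES", 1, -1)
  keep <- stats::complete.cases(X) & !is.na(y)
  dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(X) == 0) stop("all rows dropped during null exclusion")
  if (is.null(fit_on)) fit_on <- seq_len(nrow(X))
  stopifnot(all(fit_on >= 1), all(fit_on <= nrow(X)))
  ctr <- colMeans(X[fit_on, , drop = FALSE])
  sdv <- apply(X[fit_on, , drop = FALSE], 2L, stats::sd)
  zero_var <- !is.finite(sdv) | sdv == 0
  if (any(zero_var))
    warning("zero-variance column(s) on the fit split, kept as constant 0: ",
            paste(colnames(X)[zero_var], collapse = ", "))
  sdv[zero_var] <- 1
  Xs <- scale(X, center = ctr, scale = sdv)
  attr(Xs, "scaled:center") <- NULL; attr(Xs, "scaled:scale") <- NULL
  structure(list(X = Xs, y = y, feature_names = colnames(X),
                 scaling = list(center = ctr, scale = sdv, zero_variance = zero_var),
                 dropped = dropped, n_input = n_input),
            class = "gf_dataset")
}

#' @export
print.gf_dataset <- function(x, ...) {
  cat("survey dataset:", nrow(x$X), "rows x", ncol(x$X), "features (",
      x$dropped, "of", x$n_input, "input rows dropped for missing values )\n")
  cat("outcome: ", sum(x$y == 1), " YES (+1) vs ", sum(x$y == -1), " NO (-1)\n")
  invisible(x)
}

#' Configuration of the synthetic survey generator
#'
#' Defaults emulate the published study data: 309 records with 39 benign
#' (NO) vs 270 malignant (YES) outcomes, mean age 62.6 years, and symptom
#' prevalences whose marginal means match the reported feature table
#' (fatigue 1.8, coughing and shortness of breath 1.6, all others 1.5).
#' A linear outcome signal is planted by shifting each symptom's
#' class-conditional prevalence (gap `linear_effect`) while preserving the
#' marginal mean. An optional nonlinear signal replaces the outcome model:
#' the two `nonlinear_pair` symptoms are drawn fair-coin and the outcome's
#' log-odds gain `effect_size * (2 * xor - 1)`, with the intercept solved
#' numerically so the marginal YES-rate still matches `1 - benign_fraction`.
#'
#' @param n number of records.
#' @param benign_fraction probability of a NO (benign) outcome.
#' @param age_mean,age_sd age distribution (normal, rounded, truncated to
#'   `age_range`).
#' @param age_range plausible-age truncation bounds.
#' @param symptom_means length-13 vector of target marginal symptom means
#'   on the 1/2 coding, ordered as in [survey_columns()].
#' @param linear_effect class-conditional prevalence gap
#'   `P(symptom = 2 | YES) - P(symptom = 2 | NO)` planted on every symptom.
#' @param nonlinear_pair optional pair of symptom indices (1-13) carrying
#'   an XOR interaction with the outcome.
#' @param effect_size log-odds scale of the XOR interaction.
#' @param gender_p probability of gender M.
#' @param seed optional integer seed.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(n = 309L, benign_fraction = 39 / 309,
                          age_mean = 62.6, age_sd = 8, age_range = c(21, 90),
                          symptom_means = c(1.5, 1.5, 1.5, 1.5, 1.5, 1.8, 1.5,
                                            1.5, 1.5, 1.6, 1.6, 1.5, 1.5),
                          linear_effect = 0.2, nonlinear_pair = NULL,
                          effect_size = 2, gender_p = 0.5, seed = NULL) {
  stopifnot(n >= 2, benign_fraction >= 0, benign_fraction <= 1,
            age_sd > 0, length(symptom_means) == 13L,
            all(symptom_means >= 1), all(symptom_means <= 2),
            gender_p >= 0, gender_p <= 1, linear_effect >= -1, linear_effect <= 1)
  if (!is.null(nonlinear_pair)) {
    stopifnot(length(nonlinear_pair) == 2L, all(nonlinear_pair %in% 1:13),
              nonlinear_pair[1] != nonlinear_pair[2])
    nonlinear_pair <- as.integer(nonlinear_pair)
  }
  structure(list(n = as.integer(n), benign_fraction = benign_fraction,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 symptom_means = symptom_means, linear_effect = linear_effect,
                 nonlinear_pair = nonlinear_pair, effect_size = effect_size,
                 gender_p = gender_p, seed = seed),
            class = "survey_config")
}

#' Generate a synthetic clinical survey table
#'
#' Draws a `survey_table` in the survey CSV dialect under a
#' [survey_config()]: outcome first (Bernoulli with the configured benign
#' fraction, or the XOR log-odds model when `nonlinear_pair` is set), then
#' age, gender and the class-conditional symptom indicators. Deterministic
#' for a fixed `config$seed`; generated tables round-trip through
#' [write_survey_csv()] / [read_survey_csv()].
#'
#' @param config a [survey_config()].
#' @return A `survey_table` with `config$n` rows.
#' @export
synthesize_survey <- function(config = survey_config()) {
  stopifnot(inherits(config, "survey_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  p_yes <- 1 - config$benign_fraction
  symptoms <- matrix(NA_real_, n, 13L)
  if (is.null(config$nonlinear_pair)) {
    out <- stats::rbinom(n, 1L, p_yes)
  } else {
    pair <- config$nonlinear_pair
    symptoms[, pair] <- stats::rbinom(2L * n, 1L, 0.5)
    s <- as.numeric(xor(symptoms[, pair[1]] == 1, symptoms[, pair[2]] == 1))
    e <- config$effect_size
    plogis2 <- function(a) 0.5 * (stats::plogis(a + e) + stats::plogis(a - e))
    alpha <- if (p_yes <= 0) -Inf else if (p_yes >= 1) Inf else
      stats::uniroot(function(a) plogis2(a) - p_yes, c(-40, 40))$root
    out <- stats::rbinom(n, 1L, stats::plogis(alpha + e * (2 * s - 1)))
    symptoms[, pair] <- symptoms[, pair] + 1   # back to 1/2 coding
  }
  # class-conditional prevalences preserving the marginal mean:
  # p = pi * p_yes_class + (1 - pi) * p_no_class, gap = linear_effect
  pi_yes <- p_yes
  for (j in seq_len(13L)) {
    if (!is.null(config$nonlinear_pair) && j %in% config$nonlinear_pair) next
    p_marg <- config$symptom_means[j] - 1
    pj_yes <- p_marg + (1 - pi_yes) * config$linear_effect
    pj_no <- p_marg - pi_yes * config$linear_effect
    pj <- ifelse(out == 1L, pj_yes, pj_no)
    pj <- pmin(pmax(pj, 0), 1)
    symptoms[, j] <- stats::rbinom(n, 1L, pj) + 1
  }
  age <- round(stats::rnorm(n, config$age_mean, config$age_sd))
  age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
  gender <- ifelse(stats::runif(n) < config$gender_p, "M", "F")
  df <- data.frame(GENDER = gender, AGE = as.integer(age),
                   stringsAsFactors = FALSE)
  sym_cols <- setdiff(SURVEY_FEATURES, c("GENDER", "AGE"))
  for (j in seq_along(sym_cols)) df[[sym_cols[j]]] <- as.integer(symptoms[, j])
  df[[SURVEY_OUTCOME]] <- ifelse(out == 1L, "YES", "NO")
  class(df) <- c("survey_table", "data.frame")
  df
}
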
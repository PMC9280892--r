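# Shared fixtures: all data is generated in code at test time.

# Two well-separated gaussian clusters; linearly separable by construction.
make_separable <- function(n = 60, d = 4, gap = 6, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  X <- rbind(matrix(rnorm(half * d, mean = gap / 2), half, d),
             matrix(rnorm((n - half) * d, mean = -gap / 2), n - half, d))
  list(X = scale(X), y = c(rep(1, half), rep(-1, n - half)))
}

# The canonical seven-gene worked example.
example_chromosome <- function() {
  parse_chromosome(c("2.3", "4.5", "3", "6.7", "5", "6", "7"),
                   c("*_s", "-_s", "x", "+_v", "x", "y", "x"))
}

linear_chromosome <- function() {
  encode_expression(gf_expr("*_s", gf_expr("x"), gf_expr("y")))
}

chrom_equal <- function(a, b) identical(chromosome_line(a), chromosome_line(b))

# Brute-force Gram: entrywise per-pair evaluation (the oracle kernel_gram
# is checked against).
brute_gram <- function(expr, A, B = A) {
  outer(seq_len(nrow(A)), seq_len(nrow(B)),
        Vectorize(function(i, j) eval_kernel(expr, A[i, ], B[j, ])))
}

# Brute-force Mann-Whitney AUC over all positive/negative score pairs.
brute_auc <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == -1]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# All kernel expressions with at most `max_size` nodes (node count is odd
# for binary trees). Used for the exhaustive round-trip check.
enumerate_expressions <- function(max_size = 7) {
  memo <- list()
  trees_of_size <- function(size) {
    key <- as.character(size)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (size == 1) {
      lapply(gf_terminals(), gf_expr)
    } else {
      acc <- list()
      for (lsize in seq(1, size - 2, by = 2)) {
        lefts <- trees_of_size(lsize)
        rights <- trees_of_size(size - 1 - lsize)
        for (op in gf_operators())
          for (L in lefts)
            for (R in rights)
              acc[[length(acc) + 1]] <- gf_expr(op, L, R)
      }
      acc
    }
    memo[[key]] <<- out
    out
  }
  unlist(lapply(seq(1, max_size, by = 2), trees_of_size), recursive = FALSE)
}

# XOR-signal synthetic survey data: the designed nonlinear-advantage
# condition (balanced classes, interaction-only signal).
xor_dataset <- function(n = 300, seed = 1) {
  cfg <- survey_config(n = n, benign_fraction = 0.5, nonlinear_pair = c(3, 4),
                       effect_size = 6, linear_effect = 0, seed = seed)
  preprocess_survey(synthesize_survey(cfg))
}

# Mean accuracy of a fixed (already repaired-as-needed) kernel under
# stratified k-fold CV, training a precomputed-kernel SVM per fold.
cv_accuracy_gram <- function(K, y, folds, svm = svm_control()) {
  accs <- vapply(folds, function(fold) {
    Ktr <- K[fold$train, fold$train, drop = FALSE]
    Ktr <- (Ktr + t(Ktr)) / 2
    res <- train_eval_precomputed(Ktr, y[fold$train],
                                  K[fold$test, fold$train, drop = FALSE],
                                  y[fold$test], svm)
    res$metrics$accuracy
  }, numeric(1))
  mean(accs)
}
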
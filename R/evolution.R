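#' Control parameters of the genetic folding search
#'
#' Defaults follow the published experimental settings: population 50,
#' 20 generations, mutation rate 0.5, roulette-wheel selection, fitness by
#' stratified 5-fold cross-validated SVM accuracy.
#'
#' @param population_size number of chromosomes per generation.
#' @param generations number of generations of selection and mutation.
#' @param mutation_rate per-gene symbol mutation probability.
#' @param max_depth maximum depth of the randomly initialized expression
#'   trees (mutation is symbol-only, so this also bounds all later trees).
#' @param operators,terminals symbol pools of the kernel language.
#' @param elitism number of best chromosomes copied unchanged into the
#'   next generation (>= 1 makes the best-fitness trajectory
#'   non-decreasing).
#' @param C soft-margin cost of the fitness SVM.
#' @param cv_folds folds of the stratified cross-validation inside the
#'   fitness function.
#' @param balance `"none"`, `"weights"` (balanced class weights) or
#'   `"oversample"` (random minority oversampling on each training fold).
#' @param patience optional early stop: halt after this many generations
#'   without best-fitness improvement (`NULL`, the default, never stops
#'   early).
#' @param tolerance termination tolerance of the fitness SVM solver. The
#'   fitness default (0.05) is looser than the reporting default of
#'   [svm_control()] (0.001): fitness is a selection signal evaluated
#'   thousands of times, and the looser KKT tolerance changes accuracies
#'   negligibly while avoiding pathological solver stalls on ill-scaled
#'   evolved kernels.
#' @param seed optional integer seed making the whole run reproducible.
#' @return A list of class `gfs_control`.
#' @export
gfs_control <- function(population_size = 50L, generations = 20L,
                        mutation_rate = 0.5, max_depth = 4L,
                        operators = gf_operators(), terminals = gf_terminals(),
                        elitism = 1L, C = 1.0, cv_folds = 5L,
                        balance = c("none", "weights", "oversample"),
                        patience = NULL, tolerance = 0.05, seed = NULL) {
  balance <- match.arg(balance)
  stopifnot(population_size >= 1, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            max_depth >= 0, elitism >= 0, elitism <= population_size,
            C > 0, cv_folds >= 2)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate, max_depth = as.integer(max_depth),
                 operators = operators, terminals = terminals,
                 elitism = as.integer(elitism), C = C,
                 cv_folds = as.integer(cv_folds), balance = balance,
                 patience = patience, tolerance = tolerance, seed = seed),
            class = "gfs_control")
}

#' Roulette-wheel (fitness-proportionate) selection
#'
#' Samples one index with probability proportional to fitness. When every
#' fitness is zero the draw is uniform, so selection never stalls on a
#' population of invalid kernels.
#'
#' @param fitness numeric vector of nonnegative fitness values.
#' @return The selected index.
#' @export
roulette_select <- function(fitness) {
  if (length(fitness) == 0) stop("empty population")
  if (any(fitness < 0)) stop("negative fitness")
  tot <- sum(fitness)
  if (tot <= 0) return(sample.int(length(fitness), 1L))
  sample.int(length(fitness), 1L, prob = fitness / tot)
}

#' Fitness of a chromosome: cross-validated precomputed-kernel SVM accuracy
#'
#' Decodes the chromosome, builds its Gram matrix on the supplied
#' (standardized) training data, clip-repairs it, and measures mean
#' accuracy over stratified k-fold cross-validation of a soft-margin SVM
#' trained on the repaired Gram. Kernels producing non-finite or constant
#' Gram matrices - and kernels on which the solver fails - score 0.
#'
#' @param chrom a `gf_chromosome`.
#' @param x standardized feature matrix (n x d).
#' @param y labels, -1/+1 or two-level factor; both classes required.
#' @param control a [gfs_control()].
#' @param folds optional precomputed fold list from [stratified_kfold()];
#'   generated (from the current RNG state) when missing.
#' @return Fitness in `[0, 1]`.
#' @export
kernel_fitness <- function(chrom, x, y, control = gfs_control(), folds = NULL) {
  expr <- decode_chromosome(chrom)
  expression_fitness(expr, as.matrix(x), as_pm1(y), control, folds)
}

expression_fitness <- function(expr, x, y, control, folds = NULL) {
  if (length(unique(y)) < 2L) stop("fitness needs both classes present")
  if (is.null(folds)) folds <- stratified_kfold(y, control$cv_folds)
  K <- kernel_gram(expr, x)
  if (!isTRUE(attr(K, "valid"))) return(0)
  fitness_from_gram(unclass(K), y, control, folds)
}

fitness_from_gram <- function(K, y, control, folds) {
  K <- (K + t(K)) / 2
  if (max(K) - min(K) < 1e-12) return(0)          # constant kernel: no information
  fac <- clip_factor(K)
  if (is.null(fac)) return(0)
  # unit mean self-similarity with exactly compensated cost: identical
  # model, well-scaled QP whatever the evolved kernel's magnitude
  m <- mean(rowSums(fac$Z^2))
  if (!is.finite(m) || m <= 0) return(0)
  Z <- fac$Z / sqrt(m)
  cost <- control$C * m
  balanced <- control$balance == "weights"
  acc <- vapply(folds, function(fold) {
    tr <- fold$train
    if (control$balance == "oversample") tr <- oversample_minority(tr, y)
    fit <- tryCatch({
      yf <- factor(y[tr], levels = c(-1, 1))
      cw <- if (balanced) {
        tab <- table(yf); w <- as.numeric(length(tr) / (2 * tab)); names(w) <- names(tab); w
      } else NULL
      suppressWarnings(
        e1071::svm(Z[tr, , drop = FALSE], yf, kernel = "linear", cost = cost,
                   scale = FALSE, fitted = FALSE,
                   tolerance = control$tolerance, class.weights = cw))
    }, error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pred <- stats::predict(fit, Z[fold$test, , drop = FALSE])
    mean(as.numeric(as.character(pred)) == y[fold$test])
  }, numeric(1))
  if (anyNA(acc)) return(0)
  mean(acc)
}

oversample_minority <- function(tr, y) {
  ytr <- y[tr]
  tab <- table(ytr)
  if (length(tab) < 2L || tab[1] == tab[2]) return(tr)
  minority <- as.numeric(names(tab)[which.min(tab)])
  extra <- max(tab) - min(tab)
  pool <- tr[ytr == minority]
  c(tr, sample(pool, extra, replace = TRUE))
}

new_fitness_record <- function(chrom, fitness) {
  list(chromosome = chrom, fitness = fitness,
       complexity = sum(is_gf_operator(chrom$symbols)))
}

#' Evolve a kernel by the genetic folding life cycle
#'
#' Initializes `population_size` random chromosomes, then for each
#' generation copies the `elitism` best unchanged and fills the rest with
#' symbol-mutated, roulette-selected parents; every chromosome is scored by
#' [kernel_fitness()] on one shared fold assignment. Ties in fitness are
#' broken toward lower complexity, then earlier index. Fully reproducible
#' for a fixed `control$seed`.
#'
#' @param x standardized feature matrix.
#' @param y labels, -1/+1 or two-level factor.
#' @param control a [gfs_control()].
#' @return An object of class `gf_evolution`: `best` (list with
#'   `chromosome`, `expression`, `fitness`, `complexity`), `history` (one
#'   row per generation: best/mean fitness, best complexity), `population`
#'   (final fitness records) and `generations_run`.
#' @export
evolve_kernel <- function(x, y, control = gfs_control()) {
  x <- as.matrix(x); y <- as_pm1(y)
  if (length(unique(y)) < 2L) stop("evolution needs both classes present")
  if (!is.null(control$seed)) set.seed(control$seed)
  folds <- stratified_kfold(y, control$cv_folds)
  cache <- new.env(parent = emptyenv())
  probe <- sample.int(length(y)^2, min(64L, length(y)^2))  # Gram fingerprint cells
  score <- function(chrom) {
    key <- paste(c(chrom$symbols, chromosome_links(chrom)), collapse = " ")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    K <- kernel_gram(decode_chromosome(chrom), x)
    f <- if (!isTRUE(attr(K, "valid"))) 0 else {
      K <- unclass(K)
      # semantically identical kernels (different genotypes, same Gram up
      # to transposition) share one fitness evaluation
      S <- (K + t(K)) / 2
      sig <- paste(signif(c(sum(S), S[probe]), 10), collapse = ",")
      sem <- cache[[sig]]
      if (!is.null(sem)) sem
      else cache[[sig]] <- fitness_from_gram(K, y, control, folds)
    }
    cache[[key]] <- f
    f
  }
  pop <- lapply(seq_len(control$population_size), function(i) {
    chrom <- encode_expression(random_expression(control$max_depth,
                                                 control$operators,
                                                 control$terminals))
    new_fitness_record(chrom, score(chrom))
  })
  rank_pop <- function(pop) {
    fit <- vapply(pop, `[[`, numeric(1), "fitness")
    cpx <- vapply(pop, `[[`, numeric(1), "complexity")
    order(-fit, cpx, seq_along(pop))
  }
  history <- data.frame(generation = integer(0), best_fitness = numeric(0),
                        mean_fitness = numeric(0), best_complexity = integer(0))
  stale <- 0L
  best_so_far <- -Inf
  gens <- 0L
  for (gen in seq_len(control$generations)) {
    ord <- rank_pop(pop)
    elite <- pop[ord[seq_len(control$elitism)]]
    n_off <- control$population_size - control$elitism
    offspring <- vector("list", n_off)
    fit <- vapply(pop, `[[`, numeric(1), "fitness")
    if (n_off > 0) {
      for (i in seq_len(n_off)) {
        parent <- pop[[roulette_select(fit)]]$chromosome
        child <- mutate_chromosome(parent, control$mutation_rate,
                                   control$operators, control$terminals)
        offspring[[i]] <- new_fitness_record(child, score(child))
      }
    }
    pop <- c(elite, offspring)
    gens <- gen
    fit <- vapply(pop, `[[`, numeric(1), "fitness")
    b <- rank_pop(pop)[1]
    history <- rbind(history, data.frame(
      generation = gen, best_fitness = pop[[b]]$fitness,
      mean_fitness = mean(fit), best_complexity = pop[[b]]$complexity))
    if (pop[[b]]$fitness > best_so_far + 1e-12) {
      best_so_far <- pop[[b]]$fitness; stale <- 0L
    } else stale <- stale + 1L
    if (!is.null(control$patience) && stale >= control$patience) break
  }
  b <- rank_pop(pop)[1]
  best <- pop[[b]]
  structure(list(
    best = list(chromosome = best$chromosome,
                expression = decode_chromosome(best$chromosome),
                fitness = best$fitness, complexity = best$complexity),
    history = history, population = pop, generations_run = gens,
    control = control), class = "gf_evolution")
}

#' @export
print.gf_evolution <- function(x, ...) {
  cat("genetic folding run:", x$generations_run, "generations, population",
      x$control$population_size, "\n")
  cat("best fitness (CV accuracy):", format(x$best$fitness, digits = 4),
      " complexity:", x$best$complexity, "\n")
  cat("best chromosome:\n  ", chromosome_line(x$best$chromosome), "\n")
  cat("best kernel:", format(x$best$expression), "\n")
  invisible(x)
}
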
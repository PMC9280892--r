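#' Gram matrix of a kernel expression over two sets of observations
#'
#' Computes `K[i, j] = eval_kernel(expr, a[i, ], b[j, ])` for all row pairs.
#' Rather than looping over pairs, the expression is evaluated symbolically:
#' every vector-valued subexpression in the language is of the form
#' `alpha * x + beta * y + gamma * 1` with pairwise scalar fields `alpha`,
#' `beta`, `gamma`, so each node reduces to elementwise arithmetic on a few
#' n-by-m matrices built from `a %*% t(b)`, the row norms and the row sums.
#' The result is identical (to floating-point error) to the per-pair
#' reference evaluation, which the test-suite asserts.
#'
#' @param expr a `gf_expr`.
#' @param a numeric matrix, n-by-d.
#' @param b numeric matrix, m-by-d (defaults to `a`).
#' @return An n-by-m matrix of class `gf_gram` with attributes `repaired`
#'   (`FALSE`), `repair_mode` (`"none"`) and `valid` (`FALSE` when any
#'   entry is non-finite, flagging an invalid kernel).
#' @examples
#' lin <- gf_expr("*_s", gf_expr("x"), gf_expr("y"))
#' X <- matrix(rnorm(20), 5, 4)
#' max(abs(kernel_gram(lin, X) - tcrossprod(X)))  # 0: linear kernel special case
#' @export
kernel_gram <- function(expr, a, b = a) {
  stopifnot(inherits(expr, "gf_expr"))
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("a and b must share the feature dimension")
  if (ncol(a) < 1L || nrow(a) < 1L || nrow(b) < 1L) stop("empty input matrix")
  n <- nrow(a); m <- nrow(b); d <- ncol(a)
  pre <- list(
    XY = tcrossprod(a, b),
    XX = matrix(rowSums(a * a), n, m),
    YY = matrix(rowSums(b * b), n, m, byrow = TRUE),
    SX = matrix(rowSums(a), n, m),
    SY = matrix(rowSums(b), n, m, byrow = TRUE),
    d = d)
  v <- gram_node(expr, pre)
  K <- gram_reduce(v, pre)
  if (!is.matrix(K)) K <- matrix(K, n, m)   # degenerate all-scalar coefficients
  as_gf_gram(K, valid = all(is.finite(K)))
}

as_gf_gram <- function(K, repaired = FALSE, repair_mode = "none", valid = TRUE) {
  structure(K, class = c("gf_gram", class(matrix())),
            repaired = repaired, repair_mode = repair_mode, valid = valid)
}

#' @export
print.gf_gram <- function(x, ...) {
  cat(nrow(x), "x", ncol(x), "Gram matrix",
      if (isTRUE(attr(x, "repaired"))) paste0("(repaired: ", attr(x, "repair_mode"), ")")
      else "(raw)",
      if (!isTRUE(attr(x, "valid"))) "[INVALID: non-finite entries]", "\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

# Node value in the pairwise-field algebra: either a scalar field
# list(kind = "s", v = n-by-m matrix) or a vector field
# list(kind = "v", ax =, by =, c =) with matrix-or-scalar coefficients of
# x, y and the broadcast constant 1.
gram_node <- function(node, pre) {
  sym <- node$symbol
  if (sym == "x") return(list(kind = "v", ax = 1, by = 0, c = 0))
  if (sym == "y") return(list(kind = "v", ax = 0, by = 1, c = 0))
  a <- gram_node(node$left, pre)
  b <- gram_node(node$right, pre)
  as_vec <- function(o) if (o$kind == "v") o else list(kind = "v", ax = 0, by = 0, c = o$v)
  switch(sym,
    "+_v" = { a <- as_vec(a); b <- as_vec(b)
              list(kind = "v", ax = a$ax + b$ax, by = a$by + b$by, c = a$c + b$c) },
    "-_v" = { a <- as_vec(a); b <- as_vec(b)
              list(kind = "v", ax = a$ax - b$ax, by = a$by - b$by, c = a$c - b$c) },
    "+_s" = list(kind = "s", v = gram_reduce(a, pre) + gram_reduce(b, pre)),
    "-_s" = list(kind = "s", v = gram_reduce(a, pre) - gram_reduce(b, pre)),
    "*_s" = if (a$kind == "v" && b$kind == "v")
              list(kind = "s", v =
                a$ax * b$ax * pre$XX + (a$ax * b$by + a$by * b$ax) * pre$XY +
                a$by * b$by * pre$YY + (a$ax * b$c + a$c * b$ax) * pre$SX +
                (a$by * b$c + a$c * b$by) * pre$SY + pre$d * a$c * b$c)
            else
              list(kind = "s", v = gram_reduce(a, pre) * gram_reduce(b, pre)),
    stop("unknown symbol: ", sym))
}

# Component-sum reduction of a node value to the n-by-m scalar field.
gram_reduce <- function(o, pre) {
  if (o$kind == "s") o$v
  else o$ax * pre$SX + o$by * pre$SY + pre$d * o$c
}

#' Symmetrized cross Gram between new and training observations
#'
#' An SVM is trained on the *symmetrized* Gram `(K + t(K)) / 2`, whose
#' kernel is `(k(u, v) + k(v, u)) / 2`. Evaluating that model on new
#' points must therefore use the same symmetrized kernel:
#' `kernel_cross_gram` returns
#' `(kernel_gram(expr, a, b) + t(kernel_gram(expr, b, a))) / 2`, the
#' rectangular Gram consistent with training on the repaired square Gram.
#' For symmetric expressions it coincides with [kernel_gram()].
#'
#' @param expr a `gf_expr`.
#' @param a new observations (m x d).
#' @param b training observations (n x d).
#' @return An m-by-n `gf_gram`.
#' @export
kernel_cross_gram <- function(expr, a, b) {
  K1 <- kernel_gram(expr, a, b)
  K2 <- kernel_gram(expr, b, a)
  as_gf_gram((unclass(K1) + t(unclass(K2))) / 2,
             valid = isTRUE(attr(K1, "valid")) && isTRUE(attr(K2, "valid")))
}

#' Repair a square Gram matrix for SVM training
#'
#' Evolved kernel expressions need not be symmetric or positive
#' semidefinite, but SVM solvers assume both. `symmetrize` replaces `G` by
#' `(G + t(G)) / 2`; `clip` additionally eigendecomposes the symmetrized
#' matrix and zeroes all negative eigenvalues (the standard spectrum-clip
#' repair for indefinite kernels). `clip` is idempotent and leaves any PSD
#' matrix unchanged up to floating-point error.
#'
#' @param G square numeric matrix (a `gf_gram` or plain matrix).
#' @param mode `"clip"` (default) or `"symmetrize"`.
#' @return The repaired matrix as a `gf_gram` with `repaired = TRUE` and
#'   `repair_mode` set.
#' @export
repair_gram <- function(G, mode = c("clip", "symmetrize")) {
  mode <- match.arg(mode)
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("repair requires a square Gram matrix")
  if (!all(is.finite(G))) stop("cannot repair a Gram matrix with non-finite entries")
  S <- (G + t(G)) / 2
  if (mode == "clip") {
    e <- eigen(S, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    S <- e$vectors %*% (lam * t(e$vectors))
    S <- (S + t(S)) / 2    # remove round-off asymmetry from the reconstruction
  }
  as_gf_gram(S, repaired = TRUE, repair_mode = mode)
}

# Positive-spectrum factorization of a square Gram matrix: returns the
# empirical kernel map Z (n x r, Z %*% t(Z) == clipped G) and the projector
# P (n x r) with which a cross-Gram maps to test features Zte = Kte %*% P.
# Eigenvalues below `tol * max(|lambda|)` are dropped; NULL when no
# positive spectrum remains (degenerate kernel).
clip_factor <- function(G, tol = 1e-9) {
  S <- (G + t(G)) / 2
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(NULL)
  V <- e$vectors[, keep, drop = FALSE]
  s <- sqrt(e$values[keep])
  list(Z = sweep(V, 2L, s, "*"), P = sweep(V, 2L, s, "/"), values = e$values)
}

#' Cosine-normalize a Gram matrix
#'
#' Rescales to unit self-similarity: `K'[i, j] = K[i, j] /
#' sqrt(K[i, i] * K[j, j])`. Off by default throughout the package; refused
#' (with an error) when any diagonal entry is non-positive, since the
#' normalization is then undefined and the kernel is treated as invalid.
#'
#' @param G square numeric matrix.
#' @return Normalized `gf_gram` with unit diagonal.
#' @export
cosine_normalize <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("cosine normalization requires a square Gram matrix")
  dg <- diag(G)
  if (any(!is.finite(dg)) || any(dg <= 0))
    stop("cosine normalization refused: non-positive diagonal entry (invalid kernel)")
  s <- 1 / sqrt(dg)
  as_gf_gram(G * tcrossprod(s))
}
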
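#' Operator and terminal sets of the genetic folding kernel language
#'
#' The kernel language builds expressions over two feature-vector terminals
#' `x` and `y` and five binary operators: elementwise (vector) addition and
#' subtraction `+_v`, `-_v`, scalar addition and subtraction `+_s`, `-_s`
#' (operands are reduced to scalars by component summation first), and the
#' scalar product `*_s` (inner product when both operands are vectors,
#' otherwise the product of the reduced operands).
#'
#' @return Character vector of symbol names.
#' @export
gf_operators <- function() c("+_v", "+_s", "-_v", "-_s", "*_s")

#' @rdname gf_operators
#' @export
gf_terminals <- function() c("x", "y")

is_gf_operator <- function(sym) sym %in% gf_operators()
is_gf_terminal <- function(sym) sym %in% gf_terminals()

assert_gf_symbol <- function(sym) {
  bad <- setdiff(sym, c(gf_operators(), gf_terminals()))
  if (length(bad) > 0)
    stop("unknown kernel-language symbol(s): ", paste(bad, collapse = ", "))
  invisible(sym)
}

#' Construct a kernel expression node
#'
#' Expressions are binary trees: terminal nodes carry a terminal symbol and
#' no children, internal nodes carry an operator symbol and exactly two
#' children.
#'
#' @param symbol symbol name, one of [gf_operators()] or [gf_terminals()].
#' @param left,right child expressions (both present for an operator,
#'   both absent for a terminal).
#' @return An object of class `gf_expr`.
#' @examples
#' gf_expr("*_s", gf_expr("x"), gf_expr("y"))   # the linear kernel
#' @export
gf_expr <- function(symbol, left = NULL, right = NULL) {
  assert_gf_symbol(symbol)
  if (is_gf_operator(symbol)) {
    if (is.null(left) || is.null(right))
      stop("operator '", symbol, "' needs two child expressions")
    stopifnot(inherits(left, "gf_expr"), inherits(right, "gf_expr"))
    node <- list(symbol = symbol, left = left, right = right)
  } else {
    if (!is.null(left) || !is.null(right))
      stop("terminal '", symbol, "' takes no children")
    node <- list(symbol = symbol, left = NULL, right = NULL)
  }
  class(node) <- "gf_expr"
  node
}

#' Number of operator nodes in a kernel expression
#'
#' The parsimony measure used when ranking evolved kernels: a single
#' terminal has complexity 0.
#'
#' @param expr a `gf_expr`.
#' @return Nonnegative integer count of internal (operator) nodes.
#' @export
kernel_complexity <- function(expr) {
  stopifnot(inherits(expr, "gf_expr"))
  if (is.null(expr$left)) return(0L)
  1L + kernel_complexity(expr$left) + kernel_complexity(expr$right)
}

expr_size <- function(expr) {
  if (is.null(expr$left)) return(1L)
  1L + expr_size(expr$left) + expr_size(expr$right)
}

expr_depth <- function(expr) {
  if (is.null(expr$left)) return(0L)
  1L + max(expr_depth(expr$left), expr_depth(expr$right))
}

#' Draw a random kernel expression
#'
#' Grows a random tree: at each node above `max_depth` remaining depth 0 a
#' branch is opened with probability `p_branch`, otherwise a terminal is
#' placed. With `max_depth = 0` the result is a single terminal. Uses the
#' current R random number generator state, so results are reproducible
#' under [set.seed()].
#'
#' @param max_depth maximum tree depth (root at depth 0).
#' @param operators,terminals symbol pools to draw from.
#' @param p_branch probability of placing an operator while depth remains.
#' @return A `gf_expr` of depth at most `max_depth`.
#' @export
random_expression <- function(max_depth = 4L,
                              operators = gf_operators(),
                              terminals = gf_terminals(),
                              p_branch = 0.6) {
  if (length(operators) == 0 || length(terminals) == 0)
    stop("operator and terminal sets must be nonempty")
  assert_gf_symbol(operators); assert_gf_symbol(terminals)
  if (!all(operators %in% gf_operators()) || !all(terminals %in% gf_terminals()))
    stop("operators/terminals swapped or malformed")
  stopifnot(max_depth >= 0)
  if (max_depth > 0 && stats::runif(1) < p_branch) {
    gf_expr(sample(operators, 1L),
            random_expression(max_depth - 1L, operators, terminals, p_branch),
            random_expression(max_depth - 1L, operators, terminals, p_branch))
  } else {
    gf_expr(sample(terminals, 1L))
  }
}

#' Evaluate a kernel expression on a pair of feature vectors
#'
#' Reference (per-pair) evaluation semantics of the kernel language:
#' terminals `x`, `y` stand for the two argument vectors; `+_v`/`-_v`
#' operate elementwise (a scalar operand broadcasts to all components);
#' `+_s`/`-_s` reduce each operand to a scalar by component summation and
#' then add/subtract; `*_s` is the inner product when both operands are
#' vectors and otherwise the product of the reduced operands. A vector
#' value at the root is reduced by component summation, so the kernel value
#' is always a single real number.
#'
#' [kernel_gram()] computes the same quantity for all row pairs of two
#' matrices through a closed-form vectorized path; this function is the
#' simple recursive definition.
#'
#' @param expr a `gf_expr`.
#' @param x,y numeric vectors of equal positive length.
#' @return A single numeric value; may be non-finite on overflow (callers
#'   building Gram matrices treat that as an invalid kernel).
#' @examples
#' lin <- gf_expr("*_s", gf_expr("x"), gf_expr("y"))
#' eval_kernel(lin, c(1, 2), c(3, 4))   # 11
#' @export
eval_kernel <- function(expr, x, y) {
  stopifnot(inherits(expr, "gf_expr"))
  x <- as.numeric(x); y <- as.numeric(y)
  d <- length(x)
  if (d < 1L || length(y) != d)
    stop("x and y must be numeric vectors of equal positive length")
  v <- eval_node(expr, x, y, d)
  if (v$scalar) v$val else sum(v$val)  # root reduction: sum over components
}

# Returns list(scalar = TRUE/FALSE, val = numeric scalar or length-d vector)
eval_node <- function(node, x, y, d) {
  sym <- node$symbol
  if (sym == "x") return(list(scalar = FALSE, val = x))
  if (sym == "y") return(list(scalar = FALSE, val = y))
  a <- eval_node(node$left, x, y, d)
  b <- eval_node(node$right, x, y, d)
  reduce <- function(o) if (o$scalar) o$val else sum(o$val)
  broadcast <- function(o) if (o$scalar) rep(o$val, d) else o$val
  switch(sym,
    "+_v" = list(scalar = FALSE, val = broadcast(a) + broadcast(b)),
    "-_v" = list(scalar = FALSE, val = broadcast(a) - broadcast(b)),
    "+_s" = list(scalar = TRUE, val = reduce(a) + reduce(b)),
    "-_s" = list(scalar = TRUE, val = reduce(a) - reduce(b)),
    "*_s" = if (!a$scalar && !b$scalar)
              list(scalar = TRUE, val = sum(a$val * b$val))
            else
              list(scalar = TRUE, val = reduce(a) * reduce(b)),
    stop("unknown symbol: ", sym))
}

#' @export
format.gf_expr <- function(x, ...) {
  if (is.null(x$left)) return(x$symbol)
  paste0(x$symbol, "(", format(x$left), ", ", format(x$right), ")")
}

#' @export
as.character.gf_expr <- function(x, ...) format(x)

#' @export
print.gf_expr <- function(x, ...) {
  cat("kernel expression:", format(x), "\n")
  invisible(x)
}

#' Pretty-print a kernel expression as an indented tree
#'
#' @param expr a `gf_expr`.
#' @return Character vector, one line per node, suitable for `cat(..., sep
#'   = "\n")`; mirrors the best-chromosome tree renderings in reports.
#' @export
tree_format <- function(expr) {
  stopifnot(inherits(expr, "gf_expr"))
  walk <- function(node, prefix, child_prefix) {
    line <- paste0(prefix, node$symbol)
    if (is.null(node$left)) return(line)
    c(line,
      walk(node$left, paste0(child_prefix, "|-- "), paste0(child_prefix, "|   ")),
      walk(node$right, paste0(child_prefix, "`-- "), paste0(child_prefix, "    ")))
  }
  walk(expr, "", "")
}

#' Test two expressions for structural equality
#' @param a,b `gf_expr` objects.
#' @return Logical.
#' @export
expr_identical <- function(a, b) {
  if (a$symbol != b$symbol) return(FALSE)
  if (is.null(a$left) != is.null(b$left)) return(FALSE)
  if (is.null(a$left)) return(TRUE)
  expr_identical(a$left, b$left) && expr_identical(a$right, b$right)
}
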
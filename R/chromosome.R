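#' Parse a genetic folding chromosome from link and symbol tokens
#'
#' A genetic folding chromosome is a linear array of genes. Gene `i` holds a
#' symbol and a link: an operator gene links to its two children as the pair
#' `"l.r"` (both strictly greater than `i`, so links only point forward),
#' while a terminal gene links to itself (the bare integer `i`). The
#' canonical seven-gene example is links `2.3, 4.5, 3, 6.7, 5, 6, 7` with
#' symbols `*_s, -_s, x, +_v, x, y, x`.
#'
#' @param links character or numeric vector of link tokens (`"l.r"` for
#'   operators, the gene's own position for terminals). Character tokens are
#'   preferred for positions above 9 (`"12.13"` is unambiguous; the numeric
#'   literal `12.130` is not).
#' @param symbols character vector of symbol names, same length as `links`.
#' @return A validated object of class `gf_chromosome` with components
#'   `symbols`, `left` and `right` (`NA` for terminal genes).
#' @examples
#' parse_chromosome(c("2.3", "4.5", "3", "6.7", "5", "6", "7"),
#'                  c("*_s", "-_s", "x", "+_v", "x", "y", "x"))
#' @export
parse_chromosome <- function(links, symbols) {
  if (length(links) != length(symbols))
    stop("links and symbols must have the same length (",
         length(links), " vs ", length(symbols), ")")
  L <- length(links)
  if (L < 1L) stop("a chromosome needs at least one gene")
  symbols <- as.character(symbols)
  assert_gf_symbol(symbols)
  links <- as.character(links)
  left <- rep(NA_integer_, L)
  right <- rep(NA_integer_, L)
  for (i in seq_len(L)) {
    tok <- links[i]
    if (!grepl("^[0-9]+(\\.[0-9]+)?$", tok))
      stop("malformed link token at position ", i, ": '", tok, "'")
    parts <- strsplit(tok, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      left[i] <- as.integer(parts[1]); right[i] <- as.integer(parts[2])
    } else {
      if (as.integer(parts[1]) != i)
        stop("terminal link at position ", i, " must equal its own position, got ", tok)
    }
  }
  chrom <- structure(list(symbols = symbols, left = left, right = right),
                     class = "gf_chromosome")
  validate_chromosome(chrom)
}

#' Validate the structural invariants of a chromosome
#'
#' Checks that operator/terminal genes have the matching link form, that
#' all links point strictly forward, that each position after the root is
#' referenced exactly once as a child, and that the root is never
#' referenced, which together make the link graph a single tree spanning
#' all genes.
#'
#' @param chrom a `gf_chromosome`.
#' @return The chromosome, invisibly usable, after passing all checks.
#' @export
validate_chromosome <- function(chrom) {
  stopifnot(inherits(chrom, "gf_chromosome"))
  L <- length(chrom$symbols)
  if (L < 1L) stop("empty chromosome")
  is_op <- is_gf_operator(chrom$symbols)
  has_pair <- !is.na(chrom$left)
  if (any(is_op != has_pair)) {
    i <- which(is_op != has_pair)[1]
    stop("gene ", i, " ('", chrom$symbols[i], "'): symbol arity and link form disagree")
  }
  kids <- c(chrom$left[has_pair], chrom$right[has_pair])
  pos <- which(has_pair)
  if (any(chrom$left[has_pair] <= pos) || any(chrom$right[has_pair] <= pos))
    stop("backward or self link: operator children must sit at later positions")
  if (any(kids > L))
    stop("link points past the end of the chromosome")
  if (any(kids == 1L))
    stop("the root gene (position 1) cannot be a child")
  ref_counts <- tabulate(kids, nbins = L)
  if (L > 1L) {
    dup <- which(ref_counts > 1L)
    if (length(dup) > 0)
      stop("position ", dup[1], " referenced more than once as a child")
    orphan <- which(ref_counts[-1] == 0L) + 1L
    if (length(orphan) > 0)
      stop("position ", orphan[1], " is never referenced as a child")
  }
  chrom
}

#' Decode a chromosome into its kernel expression tree
#'
#' @param chrom a valid `gf_chromosome`.
#' @return The corresponding `gf_expr`; one node per gene, left/right child
#'   order preserved.
#' @export
decode_chromosome <- function(chrom) {
  validate_chromosome(chrom)
  build <- function(i) {
    if (is.na(chrom$left[i])) gf_expr(chrom$symbols[i])
    else gf_expr(chrom$symbols[i], build(chrom$left[i]), build(chrom$right[i]))
  }
  build(1L)
}

#' Encode a kernel expression as a chromosome
#'
#' Genes are laid out in breadth-first order from the root, which is the
#' layout of the canonical printed example: encoding
#' `*_s(-_s(+_v(y, x), x), x)` yields links `2.3, 4.5, 3, 6.7, 5, 6, 7`.
#'
#' @param expr a `gf_expr`.
#' @return A `gf_chromosome`; `decode_chromosome(encode_expression(e))`
#'   reproduces `e`, and `encode_expression(decode_chromosome(c))`
#'   reproduces every BFS-laid-out chromosome `c`.
#' @export
encode_expression <- function(expr) {
  stopifnot(inherits(expr, "gf_expr"))
  n <- expr_size(expr)
  symbols <- character(n); left <- rep(NA_integer_, n); right <- rep(NA_integer_, n)
  queue <- list(expr)          # node at queue slot k occupies position k
  next_free <- 2L
  i <- 1L
  while (i < next_free) {
    node <- queue[[i]]
    symbols[i] <- node$symbol
    if (!is.null(node$left)) {
      left[i] <- next_free
      right[i] <- next_free + 1L
      queue[[next_free]] <- node$left
      queue[[next_free + 1L]] <- node$right
      next_free <- next_free + 2L
    }
    i <- i + 1L
  }
  validate_chromosome(structure(list(symbols = symbols, left = left, right = right),
                                class = "gf_chromosome"))
}

chromosome_links <- function(chrom) {
  ifelse(is.na(chrom$left),
         as.character(seq_along(chrom$symbols)),
         paste0(chrom$left, ".", chrom$right))
}

#' One-line text form of a chromosome
#'
#' Round-trippable single-line format:
#' `links: 2.3,4.5,3,6.7,5,6,7 | symbols: *_s,-_s,x,+_v,x,y,x`.
#'
#' @param chrom a `gf_chromosome`.
#' @return A single character string.
#' @seealso [parse_chromosome_line()]
#' @export
chromosome_line <- function(chrom) {
  validate_chromosome(chrom)
  paste0("links: ", paste(chromosome_links(chrom), collapse = ","),
         " | symbols: ", paste(chrom$symbols, collapse = ","))
}

#' Parse the one-line chromosome text form
#'
#' @param line a string as produced by [chromosome_line()].
#' @return A validated `gf_chromosome`.
#' @export
parse_chromosome_line <- function(line) {
  m <- regmatches(line, regexec(
    "^[ \t]*links:[ \t]*([0-9., \t]+)\\|[ \t]*symbols:[ \t]*(.+)$", line))[[1]]
  if (length(m) != 3L) stop("not a chromosome line: '", line, "'")
  links <- trimws(strsplit(m[2], ",")[[1]])
  symbols <- trimws(strsplit(m[3], ",")[[1]])
  parse_chromosome(links, symbols)
}

#' @export
format.gf_chromosome <- function(x, ...) chromosome_line(x)

#' @export
print.gf_chromosome <- function(x, ...) {
  cat("GF chromosome (", length(x$symbols), " genes)\n", sep = "")
  cat(" ", chromosome_line(x), "\n")
  invisible(x)
}

#' @export
length.gf_chromosome <- function(x) length(x$symbols)

chromosome_identical <- function(a, b) {
  length(a$symbols) == length(b$symbols) &&
    all(a$symbols == b$symbols) &&
    identical(is.na(a$left), is.na(b$left)) &&
    all(a$left == b$left, na.rm = TRUE) &&
    all(a$right == b$right, na.rm = TRUE)
}

#' Symbol-level point mutation of a chromosome
#'
#' Independently for every gene, with probability `rate`, the symbol is
#' replaced by a uniformly drawn *different* symbol of the same kind
#' (operators stay operators, terminals stay terminals). Links are never
#' touched, so structural validity is preserved by construction.
#'
#' @param chrom a valid `gf_chromosome`.
#' @param rate per-gene mutation probability in `[0, 1]`.
#' @param operators,terminals symbol pools to draw replacements from.
#' @return A valid `gf_chromosome`.
#' @export
mutate_chromosome <- function(chrom, rate = 0.5,
                              operators = gf_operators(),
                              terminals = gf_terminals()) {
  validate_chromosome(chrom)
  stopifnot(rate >= 0, rate <= 1)
  L <- length(chrom$symbols)
  hit <- stats::runif(L) < rate
  if (any(hit)) {
    syms <- chrom$symbols
    for (i in which(hit)) {
      pool <- if (is_gf_operator(syms[i])) operators else terminals
      pool <- setdiff(pool, syms[i])
      if (length(pool) > 0)
        syms[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    chrom$symbols <- syms
  }
  chrom
}
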
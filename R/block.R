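#' Block data container
#'
#' An ordered list of containers (or nested blocks) supporting joint
#' algebra.  It is the natural codomain of stacked operators: the Tikhonov
#' right-hand side \eqn{(b; 0)} and gradient images \eqn{(D_x u; D_y u)}
#' are block containers.  Arithmetic recurses blockwise and is defined only
#' between blocks of identical structure; the inner product is the sum of
#' blockwise inner products.
#'
#' @param ... containers (`tomo_data` or `block_data`), or a single list.
#' @return an object of class `block_data`.
#' @examples
#' ig <- image_geometry(4, 4)
#' b <- block_data(allocate(ig, 1), allocate(ig, 2))
#' l2norm(b)^2  # 16 + 64
#' @export
block_data <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.list(blocks[[1L]]) &&
      !inherits(blocks[[1L]], c("tomo_data", "block_data")))
    blocks <- blocks[[1L]]
  ok <- vapply(blocks, function(b)
    inherits(b, "tomo_data") || inherits(b, "block_data"), logical(1L))
  if (length(blocks) == 0L || !all(ok))
    stop("block_data takes one or more tomo_data/block_data blocks")
  structure(list(blocks = blocks), class = "block_data")
}

#' Number of blocks
#' @param x a `block_data`.
#' @export
n_blocks <- function(x) length(x$blocks)

#' Extract a block
#' @param x a `block_data`.
#' @param i block index.
#' @export
get_block <- function(x, i) x$blocks[[i]]

#' @export
print.block_data <- function(x, ...) {
  cat("<block_data> with", length(x$blocks), "blocks\n")
  invisible(x)
}

block_congruent <- function(a, b) {
  if (!inherits(a, "block_data") || !inherits(b, "block_data")) return(FALSE)
  if (length(a$blocks) != length(b$blocks)) return(FALSE)
  TRUE
}

#' @export
Ops.block_data <- function(e1, e2) {
  if (missing(e2)) {
    e1$blocks <- lapply(e1$blocks, function(b) get(.Generic)(b))
    return(e1)
  }
  b1 <- inherits(e1, "block_data"); b2 <- inherits(e2, "block_data")
  if (b1 && b2) {
    if (!block_congruent(e1, e2))
      stop("block algebra requires identical block structure")
    out <- e1
    out$blocks <- Map(function(a, b) get(.Generic)(a, b), e1$blocks, e2$blocks)
  } else if (b1) {
    stopifnot(is.numeric(e2), length(e2) == 1L)
    out <- e1
    out$blocks <- lapply(e1$blocks, function(b) get(.Generic)(b, e2))
  } else {
    stopifnot(is.numeric(e1), length(e1) == 1L)
    out <- e2
    out$blocks <- lapply(e2$blocks, function(b) get(.Generic)(e1, b))
  }
  out
}

#' @export
Math.block_data <- function(x, ...) {
  x$blocks <- lapply(x$blocks, function(b) get(.Generic)(b, ...))
  x
}

#' @export
mean.block_data <- function(x, ...)
  mean(unlist(lapply(x$blocks, mean, ...)))

#' @export
dot.block_data <- function(x, y) {
  if (!block_congruent(x, y))
    stop("inner product requires identical block structure")
  sum(unlist(Map(dot, x$blocks, y$blocks)))
}
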
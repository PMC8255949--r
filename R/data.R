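#' Labelled data containers
#'
#' A `tomo_data` object holds a dense numeric array together with ordered
#' axis labels and the geometry that implies its shape.  Two flavours exist:
#' `acquisition_data` (sinograms, attached to an [acquisition_geometry()])
#' and `image_data` (volumes, attached to an [image_geometry()]).  Standard
#' arithmetic (`+`, `-`, `*`, `/`, comparisons), `exp`, `log`, `abs`,
#' `sqrt` and `mean` work elementwise; [dot()] and [l2norm()] provide the
#' inner product and the Euclidean norm.  Algebra never touches geometry
#' metadata.
#'
#' @param values numeric array (or vector) whose dimensions match the
#'   geometry's implied shape in label order.
#' @param geometry an `acquisition_geometry` or `image_geometry`.
#' @param labels axis labels; defaults to the geometry's canonical order.
#' @return a `tomo_data` object (subclass `acquisition_data` or
#'   `image_data`).
#' @export
as_tomo_data <- function(values, geometry, labels = NULL) {
  shape <- geom_shape(geometry)
  if (is.null(labels)) labels <- geom_labels(geometry)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("axis labels must be unique")
  if (!setequal(labels, geom_labels(geometry)))
    stop("labels must match the geometry's axes")
  expected <- unname(shape[labels])
  values <- as.array(values)
  if (length(dim(values)) == 1L && length(expected) == 1L)
    dim(values) <- expected
  if (!identical(as.integer(dim(values)), as.integer(expected)))
    stop("array shape (", paste(dim(values), collapse = "x"),
         ") does not match geometry shape (",
         paste(expected, collapse = "x"), ") in label order")
  storage.mode(values) <- "double"
  cls <- if (inherits(geometry, "acquisition_geometry"))
    "acquisition_data" else "image_data"
  structure(list(values = values, labels = labels, geometry = geometry),
            class = c(cls, "tomo_data"))
}

#' Allocate a data container for a geometry
#'
#' @param geometry an acquisition or image geometry.
#' @param fill scalar fill value, or the string `"random"` for reproducible
#'   uniform noise in `[0, 1)`.
#' @param seed integer seed, required when `fill = "random"`.
#' @return a `tomo_data` of the geometry's canonical shape.
#' @examples
#' ig <- image_geometry(8, 8)
#' x <- allocate(ig, 0)
#' l2norm(allocate(ig, 1))  # sqrt(64)
#' @export
allocate <- function(geometry, fill = 0, seed = NULL) {
  if (inherits(geometry, "geometry_block"))
    return(allocate_any(geometry, fill, seed))
  shape <- unname(geom_shape(geometry))
  n <- prod(shape)
  if (identical(fill, "random")) {
    if (is.null(seed)) stop("random fill requires a 'seed'")
    old <- .Random.seed_exists()
    set.seed(as.integer(seed))
    v <- stats::runif(n)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    values <- array(v, dim = shape)
  } else {
    stopifnot(is.numeric(fill), length(fill) == 1L)
    values <- array(as.numeric(fill), dim = shape)
  }
  as_tomo_data(values, geometry)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

#' @export
print.tomo_data <- function(x, ...) {
  cat("<", class(x)[1L], "> ",
      paste(dim(x$values), collapse = " x "), " (",
      paste(x$labels, collapse = ", "), ")\n",
      "  range [", format(min(x$values)), ", ", format(max(x$values)),
      "], mean ", format(mean(x$values)), "\n", sep = "")
  invisible(x)
}

#' Raw array of a data container
#' @param x a `tomo_data`.
#' @return the underlying numeric array.
#' @export
as_array <- function(x) {
  stopifnot(inherits(x, "tomo_data"))
  x$values
}

#' Extract a slice along a labelled axis
#'
#' Removes one axis at a fixed (1-based) index.  The geometry is reduced
#' where a meaningful reduced geometry exists (e.g. extracting a vertical
#' slice of 3D parallel-beam data yields 2D parallel-beam data); otherwise
#' the slice keeps its labels with a `NULL` geometry.
#'
#' @param x a `tomo_data`.
#' @param label axis name to remove.
#' @param index 1-based index along that axis.
#' @return a `tomo_data` (or bare labelled array when no geometry remains).
#' @export
get_slice <- function(x, label, index) {
  stopifnot(inherits(x, "tomo_data"))
  ax <- match(label, x$labels)
  if (is.na(ax)) stop("unknown axis label: '", label, "'")
  d <- dim(x$values)
  if (index < 1L || index > d[ax])
    stop("index ", index, " out of range for axis '", label,
         "' (extent ", d[ax], ")")
  idx <- rep(list(quote(expr = )), length(d))
  idx[[ax]] <- index
  vals <- do.call(`[`, c(list(x$values), idx, list(drop = FALSE)))
  newdim <- d[-ax]
  vals <- array(vals, dim = newdim)
  g <- reduce_geometry(x$geometry, label)
  labs <- x$labels[-ax]
  if (!is.null(g) && setequal(labs, geom_labels(g))) {
    as_tomo_data(vals, g, labs)
  } else {
    structure(list(values = vals, labels = labs, geometry = NULL),
              class = c("tomo_slice", "tomo_data"))
  }
}

#' Permute the axes of a data container
#'
#' @param x a `tomo_data`.
#' @param order a permutation of `x$labels`.
#' @param ... unused.
#' @return `x` with values transposed and labels reordered; a round trip is
#'   bit-identical.
#' @export
reorder_dims <- function(x, order, ...) {
  stopifnot(inherits(x, "tomo_data"))
  order <- as.character(order)
  if (length(order) != length(x$labels) || anyDuplicated(order) ||
      !setequal(order, x$labels))
    stop("'order' must be a permutation of the axis labels: ",
         paste(x$labels, collapse = ", "))
  perm <- match(order, x$labels)
  x$values <- aperm(x$values, perm)
  x$labels <- order
  x
}

# internal: canonical order restore
to_canonical <- function(x) {
  canon <- geom_labels(x$geometry)
  if (identical(x$labels, canon)) x else reorder_dims(x, canon)
}

check_compatible <- function(e1, e2) {
  if (!identical(e1$labels, e2$labels) ||
      !identical(dim(e1$values), dim(e2$values)))
    stop("incompatible containers: labels/shapes must match ",
         "(got [", paste(e1$labels, collapse = ","), "] ",
         paste(dim(e1$values), collapse = "x"), " vs [",
         paste(e2$labels, collapse = ","), "] ",
         paste(dim(e2$values), collapse = "x"), ")")
}

#' @export
Ops.tomo_data <- function(e1, e2) {
  if (missing(e2)) {  # unary +/-
    e1$values <- get(.Generic)(e1$values)
    return(e1)
  }
  t1 <- inherits(e1, "tomo_data"); t2 <- inherits(e2, "tomo_data")
  if (t1 && t2) {
    check_compatible(e1, e2)
    out <- e1
    out$values <- get(.Generic)(e1$values, e2$values)
  } else if (t1) {
    stopifnot(is.numeric(e2), length(e2) == 1L)
    out <- e1
    out$values <- get(.Generic)(e1$values, e2)
  } else {
    stopifnot(is.numeric(e1), length(e1) == 1L)
    out <- e2
    out$values <- get(.Generic)(e1, e2$values)
  }
  out
}

#' @export
Math.tomo_data <- function(x, ...) {
  if (.Generic == "log" && any(x$values <= 0))
    stop("log of non-positive entry; use negative_log() for transmission data")
  x$values <- get(.Generic)(x$values, ...)
  x
}

#' @export
mean.tomo_data <- function(x, ...) mean(x$values, ...)

#' Inner product of two containers
#'
#' `dot(x, y)` is the sum of elementwise products, accumulated in double
#' precision; `l2norm(x)` is `sqrt(dot(x, x))`.
#'
#' @param x,y compatible `tomo_data` or `block_data` objects.
#' @return a scalar.
#' @export
dot <- function(x, y) UseMethod("dot")

#' @export
dot.tomo_data <- function(x, y) {
  stopifnot(inherits(y, "tomo_data"))
  check_compatible(x, y)
  sum(as.numeric(x$values) * as.numeric(y$values))
}

#' @export
dot.default <- function(x, y) sum(as.numeric(x) * as.numeric(y))

#' @rdname dot
#' @export
l2norm <- function(x) sqrt(dot(x, x))

# map over values preserving metadata (internal)
td_map <- function(x, f) { x$values <- f(x$values); x }
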
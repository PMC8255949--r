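#' Linear operators with direct/adjoint contracts
#'
#' A `linear_operator` maps domain-shaped containers to range-shaped
#' containers via `op_direct()` and implements the exact transpose of its
#' discretization via `op_adjoint()`, so that
#' \deqn{\langle A v, z\rangle = \langle v, A^* z\rangle}
#' holds to rounding on random pairs — the framework's load-bearing
#' invariant, verified for every operator kind in the test suite.
#'
#' @param kind short string tag.
#' @param domain,range geometry objects (or [geometry_block()]s).
#' @param direct,adjoint functions of one container argument.
#' @param norm_hint optional known operator norm (skips power iteration).
#' @return an object of class `linear_operator`.
#' @keywords internal
#' @export
linear_operator <- function(kind, domain, range, direct, adjoint,
                            norm_hint = NULL) {
  structure(list(kind = kind, domain = domain, range = range,
                 direct = direct, adjoint = adjoint,
                 norm_hint = norm_hint),
            class = "linear_operator")
}

#' @export
print.linear_operator <- function(x, ...) {
  cat("<linear_operator:", x$kind, ">\n")
  invisible(x)
}

#' Group several geometries into a block domain/range
#' @param ... geometry objects or a single list of them.
#' @return an object of class `geometry_block`.
#' @export
geometry_block <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1L]]) &&
      !inherits(gs[[1L]], c("acquisition_geometry", "image_geometry",
                            "geometry_block")))
    gs <- gs[[1L]]
  structure(list(geometries = gs), class = "geometry_block")
}

# allocate() support for block domains
allocate_any <- function(geometry, fill = 0, seed = NULL) {
  if (inherits(geometry, "geometry_block")) {
    blocks <- lapply(seq_along(geometry$geometries), function(i)
      allocate_any(geometry$geometries[[i]], fill,
                   if (is.null(seed)) NULL else seed + i))
    block_data(blocks)
  } else {
    allocate(geometry, fill, seed)
  }
}

domain_matches <- function(g, x) {
  if (inherits(g, "geometry_block")) {
    inherits(x, "block_data") &&
      length(g$geometries) == length(x$blocks) &&
      all(mapply(domain_matches, g$geometries, x$blocks))
  } else if (inherits(x, "tomo_data")) {
    sh <- geom_shape(g)
    setequal(names(sh), x$labels) &&
      identical(as.integer(unname(sh[x$labels])),
                as.integer(dim(x$values)))
  } else FALSE
}

#' Apply an operator (direct / adjoint)
#'
#' @param A a `linear_operator`.
#' @param x a container in `A`'s domain (`op_direct`) or range
#'   (`op_adjoint`).
#' @return the mapped container.
#' @export
op_direct <- function(A, x) {
  stopifnot(inherits(A, "linear_operator"))
  if (!domain_matches(A$domain, x))
    stop("geometry mismatch: input does not live in the operator's domain")
  A$direct(x)
}

#' @rdname op_direct
#' @export
op_adjoint <- function(A, x) {
  stopifnot(inherits(A, "linear_operator"))
  if (!domain_matches(A$range, x))
    stop("geometry mismatch: input does not live in the operator's range")
  A$adjoint(x)
}

#' Elementary operators
#'
#' Constructors for the building-block operators: identity, zero, diagonal
#' (elementwise multiplication by a container), binary mask, and a dense
#' matrix operator (mainly for small oracle problems).
#'
#' @param g,domain,range geometries.
#' @param d a `tomo_data` of diagonal entries.
#' @param mask logical/numeric array (1 keeps, 0 masks).
#' @param M a dense numeric matrix, `nrow = prod(range)`,
#'   `ncol = prod(domain)`.
#' @return a `linear_operator`.
#' @name elementary_operators
NULL

#' @rdname elementary_operators
#' @export
identity_operator <- function(g)
  linear_operator("identity", g, g, function(x) x, function(x) x,
                  norm_hint = 1)

#' @rdname elementary_operators
#' @export
zero_operator <- function(domain, range)
  linear_operator("zero", domain, range,
                  function(x) allocate_any(range, 0),
                  function(x) allocate_any(domain, 0),
                  norm_hint = 0)

#' @rdname elementary_operators
#' @export
diagonal_operator <- function(d) {
  stopifnot(inherits(d, "tomo_data"))
  g <- d$geometry
  linear_operator("diagonal", g, g,
                  function(x) x * d, function(x) x * d,
                  norm_hint = max(abs(d$values)))
}

#' @rdname elementary_operators
#' @export
mask_operator <- function(mask, g) {
  m <- array(as.numeric(mask), dim = dim(as.array(mask)))
  stopifnot(identical(as.integer(dim(m)), as.integer(unname(geom_shape(g)))))
  linear_operator("mask", g, g,
                  function(x) td_map(x, function(v) v * m),
                  function(x) td_map(x, function(v) v * m),
                  norm_hint = max(abs(m)))
}

#' @rdname elementary_operators
#' @export
dense_operator <- function(M, domain, range) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == prod(geom_shape(range)),
            ncol(M) == prod(geom_shape(domain)))
  linear_operator("dense", domain, range,
    function(x) as_tomo_data(array(as.numeric(M %*% as.numeric(x$values)),
                                   dim = unname(geom_shape(range))), range),
    function(z) as_tomo_data(array(as.numeric(crossprod(M, as.numeric(z$values))),
                                   dim = unname(geom_shape(domain))), domain))
}

# forward difference with Neumann boundary along axis ax of array arr
fd_forward_arr <- function(arr, ax) {
  d <- dim(arr); n <- d[ax]
  if (n < 2L) stop("finite differences need axis extent >= 2")
  idx_hi <- lapply(d, seq_len); idx_hi[[ax]] <- c(seq.int(2L, n), n)
  shifted <- do.call(`[`, c(list(arr), idx_hi, list(drop = FALSE)))
  out <- shifted - arr
  sel <- lapply(d, seq_len); sel[[ax]] <- n
  do.call(`[<-`, c(list(out), sel, list(value = 0)))
}

# exact transpose of fd_forward_arr
fd_adjoint_arr <- function(arr, ax) {
  d <- dim(arr); n <- d[ax]
  idx_lo <- lapply(d, seq_len); idx_lo[[ax]] <- c(1L, seq.int(1L, n - 1L))
  prev <- do.call(`[`, c(list(arr), idx_lo, list(drop = FALSE)))
  out <- prev - arr
  sel1 <- lapply(d, seq_len); sel1[[ax]] <- 1L
  a1 <- do.call(`[`, c(list(arr), sel1, list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), sel1, list(value = -a1)))
  seln <- lapply(d, seq_len); seln[[ax]] <- n
  selm <- lapply(d, seq_len); selm[[ax]] <- n - 1L
  am <- do.call(`[`, c(list(arr), selm, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), seln, list(value = am)))
}

#' Finite-difference operator
#'
#' Forward differences along one labelled axis with a Neumann (zero last
#' row) boundary: \eqn{(Du)_i = u_{i+1} - u_i} for \eqn{i < n}, last entry
#' 0.  The adjoint is the exact matrix transpose.
#'
#' @param g geometry of the containers the operator acts on.
#' @param axis axis label (e.g. `"horizontal_x"`).
#' @return a `linear_operator` with `norm_hint = 2` (upper bound).
#' @export
finite_difference_operator <- function(g, axis) {
  labs <- geom_labels(g)
  ax <- match(axis, labs)
  if (is.na(ax)) stop("unknown axis label: '", axis, "'")
  if (unname(geom_shape(g)[ax]) < 2L)
    stop("axis '", axis, "' has extent < 2")
  linear_operator(
    "finite_difference", g, g,
    function(x) td_map(to_canonical(x), function(v) fd_forward_arr(v, ax)),
    function(x) td_map(to_canonical(x), function(v) fd_adjoint_arr(v, ax)))
}

#' Gradient operator
#'
#' Stacks one finite-difference block per spatial axis of an image
#' geometry, in canonical axis order; the adjoint is the negative
#' divergence (sum of per-axis adjoints).  This is the \eqn{D} of the total
#' variation \eqn{\|Du\|_{2,1}}.
#'
#' @param ig an `image_geometry` with at least one axis of extent >= 2.
#' @return a `linear_operator` from `ig` to a [geometry_block()] of one
#'   copy of `ig` per axis; `norm_hint = sqrt(4d)` for `d` axes.
#' @export
gradient_operator <- function(ig) {
  stopifnot(inherits(ig, "image_geometry"))
  labs <- geom_labels(ig)
  labs <- labs[unname(geom_shape(ig)[labs]) >= 2L]
  if (length(labs) == 0L) stop("no axis with extent >= 2")
  axes <- match(labs, geom_labels(ig))
  rng <- geometry_block(rep(list(ig), length(labs)))
  linear_operator(
    "gradient", ig, rng,
    function(x) {
      x <- to_canonical(x)
      block_data(lapply(axes, function(ax)
        td_map(x, function(v) fd_forward_arr(v, ax))))
    },
    function(z) {
      out <- NULL
      for (i in seq_along(axes)) {
        term <- td_map(to_canonical(z$blocks[[i]]),
                       function(v) fd_adjoint_arr(v, axes[i]))
        out <- if (is.null(out)) term else out + term
      }
      out
    },
    norm_hint = sqrt(4 * length(labs)))
}

#' Blurring operator (2D convolution, reflect boundary)
#'
#' Convolves a 2D image with a user-supplied kernel using reflected-edge
#' padding.  The adjoint is the exact transpose (correlation composed with
#' the transpose of the reflection padding), so the adjoint contract holds
#' to rounding.
#'
#' @param ig a 2D `image_geometry`.
#' @param kernel numeric matrix with odd dimensions.
#' @return a `linear_operator`.
#' @export
blurring_operator <- function(ig, kernel) {
  stopifnot(inherits(ig, "image_geometry"), ig$voxel_num_z == 0L,
            ig$voxel_num_y > 0L)
  kernel <- as.matrix(kernel)
  if (any(dim(kernel) %% 2L == 0L)) stop("kernel dimensions must be odd")
  ry <- (nrow(kernel) - 1L) %/% 2L
  rx <- (ncol(kernel) - 1L) %/% 2L
  ny <- ig$voxel_num_y; nx <- ig$voxel_num_x
  if (2L * ry >= ny || 2L * rx >= nx) stop("kernel too large for image")
  ref_idx <- function(n, r) {           # reflected padding index map
    idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    idx
  }
  iy <- ref_idx(ny, ry); ix <- ref_idx(nx, rx)
  direct <- function(x) {
    u <- x$values
    up <- u[iy, ix, drop = FALSE]
    out <- matrix(0, ny, nx)
    for (a in seq_len(nrow(kernel))) for (b in seq_len(ncol(kernel))) {
      w <- kernel[a, b]
      if (w == 0) next
      out <- out + w * up[(a - 1L) + seq_len(ny), (b - 1L) + seq_len(nx),
                          drop = FALSE]
    }
    td_map(x, function(v) array(out, dim = dim(v)))
  }
  adjoint <- function(z) {
    zz <- z$values
    upadj <- matrix(0, ny + 2L * ry, nx + 2L * rx)
    for (a in seq_len(nrow(kernel))) for (b in seq_len(ncol(kernel))) {
      w <- kernel[a, b]
      if (w == 0) next
      rows <- (a - 1L) + seq_len(ny); cols <- (b - 1L) + seq_len(nx)
      upadj[rows, cols] <- upadj[rows, cols] + w * zz
    }
    out <- matrix(0, ny, nx)                 # transpose of reflect padding
    for (r in seq_len(ny + 2L * ry)) for (cc in seq_len(nx + 2L * rx)) {
      v <- upadj[r, cc]
      if (v != 0) out[iy[r], ix[cc]] <- out[iy[r], ix[cc]] + v
    }
    td_map(z, function(vv) array(out, dim = dim(vv)))
  }
  linear_operator("blurring", ig, ig, direct, adjoint,
                  norm_hint = sum(abs(kernel)))
}

#' Block operator
#'
#' A grid of operators acting jointly: entries in a column share a domain,
#' entries in a row share a range.  `op_direct` applies row-wise sums,
#' `op_adjoint` column-wise sums of entry adjoints.  The Tikhonov stack
#' \eqn{\tilde A = (A; \alpha D)} and the PDHG operator \eqn{K = (A; D)}
#' are block operators; nesting is supported (a block entry may itself map
#' to a block range, as the gradient operator does).
#'
#' @param ops list of `linear_operator`s (or `NULL` for a zero entry),
#'   row-major.
#' @param nrow,ncol grid shape.
#' @return a `linear_operator` whose domain/range are [geometry_block()]s
#'   (collapsed to a plain geometry when the grid has one column/row).
#' @export
block_operator <- function(ops, nrow = length(ops), ncol = 1L) {
  stopifnot(length(ops) == nrow * ncol, nrow >= 1L, ncol >= 1L)
  ent <- function(i, j) ops[[(i - 1L) * ncol + j]]
  col_dom <- vector("list", ncol)
  row_rng <- vector("list", nrow)
  for (j in seq_len(ncol)) for (i in seq_len(nrow)) {
    e <- ent(i, j)
    if (is.null(e)) next
    if (is.null(col_dom[[j]])) col_dom[[j]] <- e$domain
    else if (!geom_block_equal(col_dom[[j]], e$domain))
      stop("column ", j, " entries do not share a domain")
    if (is.null(row_rng[[i]])) row_rng[[i]] <- e$range
    else if (!geom_block_equal(row_rng[[i]], e$range))
      stop("row ", i, " entries do not share a range")
  }
  if (any(vapply(col_dom, is.null, logical(1L))) ||
      any(vapply(row_rng, is.null, logical(1L))))
    stop("every row and column needs at least one non-NULL entry")
  domain <- if (ncol == 1L) col_dom[[1L]] else geometry_block(col_dom)
  range <- if (nrow == 1L) row_rng[[1L]] else geometry_block(row_rng)
  direct <- function(x) {
    xs <- if (ncol == 1L) list(x) else x$blocks
    outs <- vector("list", nrow)
    for (i in seq_len(nrow)) {
      acc <- NULL
      for (j in seq_len(ncol)) {
        e <- ent(i, j)
        if (is.null(e)) next
        term <- e$direct(xs[[j]])
        acc <- if (is.null(acc)) term else acc + term
      }
      outs[[i]] <- acc
    }
    if (nrow == 1L) outs[[1L]] else block_data(outs)
  }
  adjoint <- function(z) {
    zs <- if (nrow == 1L) list(z) else z$blocks
    outs <- vector("list", ncol)
    for (j in seq_len(ncol)) {
      acc <- NULL
      for (i in seq_len(nrow)) {
        e <- ent(i, j)
        if (is.null(e)) next
        term <- e$adjoint(zs[[i]])
        acc <- if (is.null(acc)) term else acc + term
      }
      outs[[j]] <- acc
    }
    if (ncol == 1L) outs[[1L]] else block_data(outs)
  }
  op <- linear_operator("block", domain, range, direct, adjoint)
  op$grid <- list(ops = ops, nrow = nrow, ncol = ncol)
  op
}

geom_block_equal <- function(a, b, tol = 1e-9) {
  ab <- inherits(a, "geometry_block"); bb <- inherits(b, "geometry_block")
  if (ab != bb) return(FALSE)
  if (!ab) return(geom_equal(a, b, tol))
  length(a$geometries) == length(b$geometries) &&
    all(mapply(geom_block_equal, a$geometries, b$geometries))
}

#' Parallel-beam projection operator
#'
#' The native discretized Radon transform: `op_direct` is ray-driven
#' forward projection (Joseph-style bilinear interpolation along rays,
#' sampling step equal to the smaller in-plane voxel pitch, length-weighted),
#' `op_adjoint` is the exact transpose (matched back-projector).  3D
#' parallel-beam data is projected slice by slice; the geometry's
#' `rotation_axis_offset` is honoured.
#'
#' @param ig an `image_geometry` (2D, or 3D with `voxel_num_z` equal to the
#'   detector row count and matching pitches).
#' @param ag a parallel-beam `acquisition_geometry`.
#' @return a `linear_operator` from `ig` to `ag`.
#' @export
projection_operator <- function(ig, ag) {
  stopifnot(inherits(ig, "image_geometry"),
            inherits(ag, "acquisition_geometry"))
  if (!ag$beam_type %in% c("parallel2D", "parallel3D"))
    stop("only parallel-beam projection is supported (cone is represented ",
         "but not projected)")
  is3d <- ag$beam_type == "parallel3D"
  if (is3d) {
    if (ig$voxel_num_z != ag$pixel_num_v ||
        abs(ig$voxel_size_z - ag$pixel_size_v) > 1e-9)
      stop("3D projection requires voxel_num_z == pixel_num_v and equal ",
           "vertical pitches")
  } else if (ig$voxel_num_z != 0L) {
    stop("parallel2D projection requires a 2D image geometry")
  }
  angles <- geom_angles_rad(ag)
  nz <- max(ig$voxel_num_z, 1L); ny <- ig$voxel_num_y; nx <- ig$voxel_num_x
  nv <- if (is3d) ag$pixel_num_v else 1L
  na <- length(angles); nh <- ag$pixel_num_h
  direct <- function(x) {
    x <- to_canonical(x)
    v <- x$values
    dim(v) <- c(nz, ny, nx)
    s <- radon_forward_cpp(as.numeric(v), nz, ny, nx,
                           ig$voxel_size_x, ig$voxel_size_y,
                           ig$center_x, ig$center_y,
                           angles, nh, ag$pixel_size_h,
                           ag$rotation_axis_offset)
    dim(s) <- if (is3d) c(na, nv, nh) else c(na, nh)
    as_tomo_data(s, ag)
  }
  adjoint <- function(z) {
    z <- to_canonical(z)
    s <- z$values
    dim(s) <- c(na, nv, nh)
    v <- back_project_cpp(as.numeric(s), na, nv, nh,
                          ag$pixel_size_h, ag$rotation_axis_offset,
                          angles, nz, ny, nx,
                          ig$voxel_size_x, ig$voxel_size_y,
                          ig$center_x, ig$center_y)
    dim(v) <- if (is3d) c(nz, ny, nx) else c(ny, nx)
    as_tomo_data(v, ig)
  }
  linear_operator("projector", ig, ag, direct, adjoint)
}

#' Operator algebra
#'
#' Operators combine by scalar multiplication (`2 * A`), addition
#' (`A + B`, same domain and range) and composition
#' (`op_compose(A, B)` is \eqn{A \circ B}); adjoints follow
#' \eqn{(\alpha A)^* = \alpha A^*}, \eqn{(A+B)^* = A^* + B^*},
#' \eqn{(AB)^* = B^* A^*}.
#'
#' @param A,B `linear_operator`s.
#' @return a `linear_operator`.
#' @export
op_compose <- function(A, B) {
  stopifnot(inherits(A, "linear_operator"), inherits(B, "linear_operator"))
  if (!geom_block_equal(A$domain, B$range))
    stop("incompatible composition: range(B) must equal domain(A)")
  linear_operator("composition", B$domain, A$range,
                  function(x) A$direct(B$direct(x)),
                  function(z) B$adjoint(A$adjoint(z)))
}

#' @export
Ops.linear_operator <- function(e1, e2) {
  if (.Generic == "*") {
    if (inherits(e1, "linear_operator") && is.numeric(e2)) {
      A <- e1; a <- e2
    } else if (inherits(e2, "linear_operator") && is.numeric(e1)) {
      A <- e2; a <- e1
    } else stop("operator '*' requires one operator and one scalar")
    stopifnot(length(a) == 1L)
    return(linear_operator("scaled", A$domain, A$range,
                           function(x) a * A$direct(x),
                           function(z) a * A$adjoint(z),
                           norm_hint = if (is.null(A$norm_hint)) NULL
                                       else abs(a) * A$norm_hint))
  }
  if (.Generic == "+") {
    stopifnot(inherits(e1, "linear_operator"),
              inherits(e2, "linear_operator"))
    if (!geom_block_equal(e1$domain, e2$domain) ||
        !geom_block_equal(e1$range, e2$range))
      stop("operator sum requires matching domains and ranges")
    return(linear_operator("sum", e1$domain, e1$range,
                           function(x) e1$direct(x) + e2$direct(x),
                           function(z) e1$adjoint(z) + e2$adjoint(z)))
  }
  if (.Generic == "-") {
    if (missing(e2)) return((-1) * e1)
    return(e1 + (-1) * e2)
  }
  stop("unsupported operator generic: ", .Generic)
}

#' Operator norm by power iteration
#'
#' Estimates \eqn{\|A\|_2} by power iteration on \eqn{A^* A}, started from
#' a reproducible random element of the domain.
#'
#' @param A a `linear_operator`.
#' @param iters maximum iterations (default 20).
#' @param seed seed for the starting vector (default 1).
#' @param tol relative-change stopping tolerance (default `1e-8`).
#' @return a scalar norm estimate (0 for the zero operator).
#' @export
operator_norm <- function(A, iters = 20L, seed = 1L, tol = 1e-8) {
  stopifnot(inherits(A, "linear_operator"))
  v <- allocate_any(A$domain, "random", seed)
  nv <- l2norm(v)
  if (nv == 0) return(0)
  v <- v * (1 / nv)
  lam <- 0
  for (k in seq_len(iters)) {
    w <- A$adjoint(A$direct(v))
    nw <- l2norm(w)
    if (nw == 0) return(0)
    rel <- abs(nw - lam) / max(nw, .Machine$double.eps)
    lam <- nw
    v <- w * (1 / nw)
    if (k > 1L && rel < tol) break
  }
  sqrt(lam)
}
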
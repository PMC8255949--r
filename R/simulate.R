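#' Phantom specification
#'
#' Describes a synthetic test object.  Three kinds are provided:
#'
#' * `"disc"`: centred uniform disc (indicator), the analytic workhorse —
#'   its projection is the chord length \eqn{2\sqrt{r^2 - s^2}}.
#' * `"steel_wire_like"`: a low-attenuation cylinder with a high-value
#'   eccentric wire and a few zero-value bubbles, emulating a corroding
#'   aluminium cylinder with an embedded steel wire imaged in fast
#'   parallel-beam CT.
#' * `"rods"`: a host cylinder with 10 circular inserts of distinct
#'   attenuation values, emulating a metal-rod resolution phantom from
#'   golden-angle neutron tomography.
#'
#' All phantoms are deterministic given `seed`; values lie in
#' `[0, v_max]`.
#'
#' @param kind `"disc"`, `"steel_wire_like"` or `"rods"`.
#' @param n grid size (the phantom is `n` by `n`).
#' @param radius disc/cylinder radius as a fraction of the field of view
#'   (default 0.25 for `disc`, 0.4 for the cylinders).
#' @param value disc value / host cylinder attenuation.
#' @param v_max maximum attenuation value (default 1).
#' @param seed integer seed for randomized placements.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("disc", "steel_wire_like", "rods"),
                         n, radius = NULL, value = NULL, v_max = 1,
                         seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  stopifnot(n >= 8L, v_max > 0)
  if (is.null(radius)) radius <- if (kind == "disc") 0.25 else 0.4
  if (is.null(value)) value <- if (kind == "disc") v_max else 0.3 * v_max
  stopifnot(radius > 0, radius < 0.5)
  structure(list(kind = kind, n = n, radius = radius, value = value,
                 v_max = v_max, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build a phantom image
#'
#' @param spec a [phantom_spec()].
#' @param ig optional `image_geometry` (default: `n` by `n` unit-pitch grid
#'   centred at the origin).
#' @return an `image_data`; for `"rods"` the insert centres, radii and
#'   values are attached as attribute `"inserts"`.
#' @export
make_phantom <- function(spec, ig = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n
  if (is.null(ig)) ig <- image_geometry(n, n)
  stopifnot(ig$voxel_num_z == 0L)
  fov <- min(ig$voxel_num_x * ig$voxel_size_x,
             ig$voxel_num_y * ig$voxel_size_y)
  xs <- (seq_len(ig$voxel_num_x) - (ig$voxel_num_x + 1) / 2) * ig$voxel_size_x
  ys <- (seq_len(ig$voxel_num_y) - (ig$voxel_num_y + 1) / 2) * ig$voxel_size_y
  X <- matrix(xs, ig$voxel_num_y, ig$voxel_num_x, byrow = TRUE)
  Y <- matrix(ys, ig$voxel_num_y, ig$voxel_num_x)
  # partial-volume rendering: boundary pixels get their covered fraction
  # (4x4 supersampling), so discretized objects stay rotationally faithful
  sub <- (seq_len(4L) - 2.5) / 4
  shifts <- expand.grid(dx = sub * ig$voxel_size_x,
                        dy = sub * ig$voxel_size_y)
  coverage <- function(cx, cy, r) {
    acc <- 0
    for (k in seq_len(nrow(shifts)))
      acc <- acc + ((X + shifts$dx[k] - cx)^2 +
                      (Y + shifts$dy[k] - cy)^2 <= r^2)
    acc / nrow(shifts)
  }
  paint <- function(img, cx, cy, r, value) {
    cov <- coverage(cx, cy, r)
    img * (1 - cov) + value * cov
  }
  R <- spec$radius * fov
  img <- matrix(0, ig$voxel_num_y, ig$voxel_num_x)
  inserts <- NULL
  if (spec$kind == "disc") {
    img <- paint(img, 0, 0, R, spec$value)
  } else if (spec$kind == "steel_wire_like") {
    img <- paint(img, 0, 0, R, spec$value)
    set.seed(spec$seed)
    wa <- stats::runif(1, 0, 2 * pi)
    wr <- 0.4 * R
    img <- paint(img, wr * cos(wa), wr * sin(wa), 0.08 * R, spec$v_max)
    for (i in seq_len(3L)) {                     # corrosion bubbles
      ba <- stats::runif(1, 0, 2 * pi); br <- stats::runif(1, 0.2, 0.8) * R
      img <- paint(img, br * cos(ba), br * sin(ba), 0.06 * R, 0)
    }
  } else {  # rods: 10 circular inserts of distinct values
    img <- paint(img, 0, 0, R, spec$value)
    set.seed(spec$seed)
    vals <- seq(0.45, 1, length.out = 10L) * spec$v_max
    ring <- c(rep(0.62, 6L), rep(0.30, 4L)) * R   # two rings of holes
    angs <- c(seq(0, 2 * pi, length.out = 7L)[-7L],
              seq(0, 2 * pi, length.out = 5L)[-5L] + pi / 4)
    radii <- c(rep(0.14, 3L), rep(0.07, 3L), rep(0.14, 2L),
               rep(0.07, 2L)) * R
    inserts <- data.frame(cx = ring * cos(angs), cy = ring * sin(angs),
                          r = radii, value = vals)
    for (i in seq_len(nrow(inserts))) {
      if (sqrt(inserts$cx[i]^2 + inserts$cy[i]^2) + inserts$r[i] > R)
        stop("insert ", i, " exceeds the host cylinder")
      img <- paint(img, inserts$cx[i], inserts$cy[i], inserts$r[i],
                   inserts$value[i])
    }
  }
  out <- as_tomo_data(array(img, dim = c(ig$voxel_num_y, ig$voxel_num_x)),
                      ig)
  if (!is.null(inserts)) attr(out, "inserts") <- inserts
  out
}

#' Simulate a tomographic acquisition with optional noise
#'
#' Forward-projects a phantom and optionally corrupts the sinogram:
#' `gaussian` adds i.i.d. \eqn{N(0, \sigma^2)}; `poisson` converts the
#' sinogram to transmission, draws photon counts
#' \eqn{\mathrm{Pois}(I_0 e^{-y})} and maps back through
#' \eqn{-\log(\mathrm{counts}/I_0)}, flooring zero counts at 0.5 counts.
#'
#' @param phantom an `image_data`.
#' @param ag a parallel-beam `acquisition_geometry`.
#' @param noise `"none"` (default), or a list
#'   `list(type = "gaussian", sigma =, seed =)` /
#'   `list(type = "poisson", I0 =, seed =, floor_counts = 0.5)`.
#' @return an `acquisition_data` sinogram.
#' @export
simulate_acquisition <- function(phantom, ag, noise = "none") {
  stopifnot(inherits(phantom, "image_data"),
            inherits(ag, "acquisition_geometry"))
  A <- projection_operator(phantom$geometry, ag)
  sino <- op_direct(A, phantom)
  if (identical(noise, "none")) return(sino)
  stopifnot(is.list(noise), !is.null(noise$type))
  if (is.null(noise$seed)) stop("noise simulation requires a 'seed'")
  set.seed(as.integer(noise$seed))
  if (noise$type == "gaussian") {
    stopifnot(is.numeric(noise$sigma), noise$sigma >= 0)
    td_map(sino, function(v)
      v + array(stats::rnorm(length(v), sd = noise$sigma), dim = dim(v)))
  } else if (noise$type == "poisson") {
    I0 <- noise$I0
    if (is.null(I0) || I0 <= 0) stop("poisson noise requires I0 > 0")
    floor_counts <- noise$floor_counts %||% 0.5
    td_map(sino, function(v) {
      counts <- stats::rpois(length(v), I0 * exp(-as.numeric(v)))
      counts <- pmax(counts, floor_counts)
      array(-log(counts / I0), dim = dim(v))
    })
  } else stop("unknown noise type: ", noise$type)
}

#' Golden-angle acquisition angles
#'
#' Successive increments of \eqn{(\sqrt5 - 1)/2 \cdot 180^\circ =
#' 111.246\ldots^\circ}: near-uniform angular coverage for any prefix of
#' the sequence.
#'
#' @param n number of angles (>= 1).
#' @param start starting angle in degrees (default 0).
#' @return numeric vector of `n` angles in degrees, reduced mod 360.
#' @export
generate_golden_angles <- function(n, start = 0) {
  stopifnot(n >= 1L)
  g <- (sqrt(5) - 1) / 2 * 180
  (start + (seq_len(n) - 1) * g) %% 360
}

#' Image quality metrics
#'
#' Mean-square error and peak signal-to-noise ratio against a ground
#' truth: `psnr = 20 log10(data_range) - 10 log10(mse)`; identical inputs
#' report `psnr = Inf`.
#'
#' @param a,b containers (or arrays) of equal shape; by convention `b` is
#'   the ground truth.
#' @param data_range peak value (default: max of `b`).
#' @return `mse`/`psnr`: scalar; `quality_report`: list with both.
#' @export
mse <- function(a, b) {
  av <- if (inherits(a, "tomo_data")) a$values else as.array(a)
  bv <- if (inherits(b, "tomo_data")) b$values else as.array(b)
  if (!identical(dim(av), dim(bv))) stop("shape mismatch")
  mean((as.numeric(av) - as.numeric(bv))^2)
}

#' @rdname mse
#' @export
psnr <- function(a, b, data_range = NULL) {
  m <- mse(a, b)
  if (is.null(data_range)) {
    bv <- if (inherits(b, "tomo_data")) b$values else as.array(b)
    data_range <- max(bv)
  }
  stopifnot(data_range > 0)
  if (m == 0) return(Inf)
  20 * log10(data_range) - 10 * log10(m)
}

#' @rdname mse
#' @export
quality_report <- function(a, b, data_range = NULL) {
  list(mse = mse(a, b), psnr = psnr(a, b, data_range))
}
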
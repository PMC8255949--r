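#' Ramp-filter a sinogram
#'
#' Applies the 1D frequency-domain reconstruction filter along the detector
#' (horizontal) axis of every projection, with zero-padding to the next
#' power of two at least `padding` times the detector width.  The `ramp`
#' filter is \eqn{|\nu|} (physical frequency units); `shepp-logan`
#' multiplies the ramp by a sinc apodization.  The operation is linear and
#' removes the DC component.
#'
#' @param b parallel-beam `acquisition_data`.
#' @param filter `"ramp"` (default) or `"shepp-logan"`.
#' @param padding padding factor (default 2; the padded length is the next
#'   power of two >= `padding * nh`).
#' @return filtered sinogram with unchanged geometry.
#' @export
filter_sinogram <- function(b, filter = c("ramp", "shepp-logan"),
                            padding = 2L) {
  filter <- match.arg(filter)
  stopifnot(inherits(b, "acquisition_data"))
  if (!b$geometry$beam_type %in% c("parallel2D", "parallel3D"))
    stop("filtering is defined for parallel-beam data")
  stopifnot(padding >= 2L)
  b <- to_canonical(b)
  ds <- b$geometry$pixel_size_h
  d <- dim(b$values)
  nh <- d[length(d)]
  np <- 2^ceiling(log2(padding * nh))
  # physical frequencies of the padded DFT grid
  k <- c(seq.int(0L, np %/% 2L), seq.int(-(np %/% 2L - 1L), -1L))
  nu <- abs(k) / (np * ds)
  H <- nu
  if (filter == "shepp-logan") {
    arg <- pi * nu * ds
    H <- H * ifelse(arg == 0, 1, sin(arg) / arg)
  }
  m <- matrix(b$values, ncol = nh)        # rows: (angle [, vertical])
  mp <- matrix(0, nrow(m), np)
  mp[, seq_len(nh)] <- m
  ft <- t(stats::mvfft(t(mp)))            # FFT along detector axis
  ft <- sweep(ft, 2L, H, `*`)
  back <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / np
  out <- back[, seq_len(nh), drop = FALSE]
  td_map(b, function(v) array(out, dim = dim(v)))
}

# per-angle weights in radians: half-gap to each angular neighbour mod 180
# degrees; reduces to pi/n for equispaced coverage of [0, 180) and handles
# golden-angle sets
angle_weights <- function(ag) {
  th <- geom_angles_rad(ag) %% pi
  n <- length(th)
  if (n == 1L) return(pi)
  o <- order(th)
  s <- th[o]
  gaps <- diff(c(s, s[1L] + pi))         # circular gaps over [0, pi)
  w_sorted <- (gaps + c(gaps[n], gaps[-n])) / 2
  w <- numeric(n)
  w[o] <- w_sorted
  w
}

#' Filtered back-projection reconstruction
#'
#' The analytic parallel-beam baseline: ramp filtering
#' ([filter_sinogram()]) followed by the matched back-projector, with
#' per-angle angular weights \eqn{\Delta\theta} (half-gap rule, so
#' golden-angle acquisitions are handled) and a \eqn{1/\Delta x} factor
#' converting the discretized adjoint into true backprojection.  The
#' geometry's `rotation_axis_offset` is honoured.
#'
#' @param b parallel-beam `acquisition_data`.
#' @param ig target `image_geometry` (default [default_image_geometry()]).
#' @param filter,padding passed to [filter_sinogram()].
#' @return reconstructed `image_data`.
#' @examples
#' ig <- image_geometry(64, 64)
#' ag <- acquisition_geometry("parallel2D", angles = seq(0, 179, by = 1),
#'                            pixel_num_h = 64)
#' u <- make_phantom(phantom_spec("disc", 64))
#' rec <- fbp_reconstruct(simulate_acquisition(u, ag), ig)
#' @export
fbp_reconstruct <- function(b, ig = NULL, filter = "ramp", padding = 2L) {
  stopifnot(inherits(b, "acquisition_data"))
  ag <- b$geometry
  if (!ag$beam_type %in% c("parallel2D", "parallel3D"))
    stop("FBP supports parallel-beam data only")
  if (is.null(ig)) ig <- default_image_geometry(ag)
  q <- filter_sinogram(b, filter, padding)
  w <- angle_weights(ag)
  q <- to_canonical(q)
  q$values <- sweep(q$values, 1L, w, `*`)  # angle axis first
  Aop <- projection_operator(ig, ag)
  rec <- op_adjoint(Aop, q)
  rec * (1 / min(ig$voxel_size_x, ig$voxel_size_y))
}
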
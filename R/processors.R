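#' Flat- and dark-field normalisation
#'
#' Converts raw detector counts to transmission: `(raw - dark) / (flat -
#' dark)` elementwise.  Where `|flat - dark| < eps` the output is set to 1
#' and a warning reports the count of guarded pixels.
#'
#' @param raw an `acquisition_data` (or plain array).
#' @param flat,dark flat-field and dark-field detector images, broadcastable
#'   to the detector shape (scalars allowed).
#' @param eps degeneracy guard on the denominator (default `1e-8`).
#' @return container of the same shape, transmission-scaled.
#' @export
normalise <- function(raw, flat, dark = 0, eps = 1e-8) {
  vals <- if (inherits(raw, "tomo_data")) raw$values else as.array(raw)
  fl <- broadcast_field(flat, vals, raw)
  dk <- broadcast_field(dark, vals, raw)
  den <- fl - dk
  bad <- abs(den) < eps
  out <- (vals - dk) / den
  if (any(bad)) {
    out[bad] <- 1.0
    warning(sum(bad), " pixel(s) with |flat - dark| < ", eps,
            " replaced by 1.0")
  }
  replace_values(raw, out)
}

# expand a flat/dark field (scalar, detector image, or full-shape array) to
# the data shape; detector fields are replicated across the angle axis
broadcast_field <- function(f, vals, x) {
  if (is.numeric(f) && length(f) == 1L)
    return(array(f, dim = dim(vals)))
  f <- as.array(f)
  if (identical(dim(f), dim(vals))) return(f)
  if (inherits(x, "tomo_data")) {
    ax <- match("angle", x$labels)
    if (!is.na(ax) && identical(as.integer(dim(f)),
                                as.integer(dim(vals)[-ax]))) {
      na <- dim(vals)[ax]
      out <- array(rep(as.numeric(f), each = if (ax == 1L) na else 1L),
                   dim = dim(vals))
      if (ax != 1L) stop("detector-field broadcast expects the angle axis first")
      return(out)
    }
  }
  stop("flat/dark field shape does not match the data")
}

replace_values <- function(x, vals) {
  if (inherits(x, "tomo_data")) { x$values <- vals; x } else vals
}

#' Lambert-Beer negative-logarithm conversion
#'
#' Maps transmission data in (0, 1] to line integrals of attenuation:
#' `-log(pmax(x, clip_floor))`.  Non-positive entries are floored and
#' counted in a warning.
#'
#' @param x transmission-scaled container.
#' @param clip_floor positive floor applied before the log (default `1e-6`).
#' @return container of absorption line integrals.
#' @export
negative_log <- function(x, clip_floor = 1e-6) {
  stopifnot(clip_floor > 0)
  vals <- if (inherits(x, "tomo_data")) x$values else as.array(x)
  nbad <- sum(vals < clip_floor)
  if (nbad > 0)
    warning(nbad, " entry(ies) below clip floor ", clip_floor, " were floored")
  replace_values(x, -log(pmax(vals, clip_floor)))
}

roi_normalize <- function(r, extent, what) {
  if (length(r) == 2L) r <- c(r, 1L)
  if (length(r) != 3L) stop("ROI for '", what,
                            "' must be (start, stop[, step])")
  start <- as.integer(r[1L]); stop_ <- as.integer(r[2L])
  step <- as.integer(r[3L])
  if (is.na(start)) start <- 1L
  if (is.na(stop_)) stop_ <- extent
  if (step < 1L) stop("ROI step must be >= 1")
  if (start < 1L || stop_ > extent || start > stop_)
    stop("empty or out-of-range ROI for axis '", what, "'")
  seq.int(start, stop_, by = step)
}

#' Slice (crop / subsample) labelled axes
#'
#' Keeps a 1-based inclusive `(start, stop, step)` range per named axis and
#' updates the geometry (angle subset, detector/voxel counts).  E.g. on a
#' 91-angle scan, `roi = list(angle = c(1, 90))` drops the final mirror
#' projection and `list(angle = c(1, 90, 6))` keeps every sixth of those.
#'
#' @param x a `tomo_data`.
#' @param roi named list; each element `c(start, stop)` or
#'   `c(start, stop, step)` with `NA` meaning "from the first" / "to the
#'   last".
#' @return cropped/subsampled container with consistent geometry.
#' @export
slice_axes <- function(x, roi) {
  stopifnot(inherits(x, "tomo_data"), is.list(roi), !is.null(names(roi)))
  x <- to_canonical(x)
  d <- dim(x$values)
  keep <- lapply(seq_along(d), function(i) seq_len(d[i]))
  for (lab in names(roi)) {
    ax <- match(lab, x$labels)
    if (is.na(ax)) stop("unknown axis label: '", lab, "'")
    keep[[ax]] <- roi_normalize(roi[[lab]], d[ax], lab)
  }
  vals <- do.call(`[`, c(list(x$values), keep, list(drop = FALSE)))
  g <- update_geometry_extents(x$geometry, x$labels, keep)
  as_tomo_data(vals, g, x$labels)
}

# rebuild geometry after per-axis index selections (slicer) or resizes
update_geometry_extents <- function(g, labels, keep) {
  if (inherits(g, "acquisition_geometry")) {
    ai <- match("angle", labels); hi <- match("horizontal", labels)
    vi <- match("vertical", labels)
    g$angles <- g$angles[keep[[ai]]]
    g$pixel_num_h <- length(keep[[hi]])
    if (!is.na(vi)) g$pixel_num_v <- length(keep[[vi]])
    g
  } else {
    xi <- match("horizontal_x", labels); yi <- match("horizontal_y", labels)
    zi <- match("vertical", labels)
    g$voxel_num_x <- length(keep[[xi]])
    if (!is.na(yi)) g$voxel_num_y <- length(keep[[yi]])
    if (!is.na(zi)) g$voxel_num_z <- length(keep[[zi]])
    g
  }
}

#' Bin (downsample by block mean) labelled axes
#'
#' Non-overlapping means over blocks of the given factor per axis; trailing
#' remainder elements are dropped.  Geometry pixel/voxel sizes are
#' multiplied by the factor and counts divided (floor).  The mean (not the
#' sum) keeps transmission data in \[0, 1\].
#'
#' @param x a `tomo_data`.
#' @param factors named list/vector of integer factors (>= 1) per axis label.
#' @return binned container.
#' @export
bin_axes <- function(x, factors) {
  stopifnot(inherits(x, "tomo_data"))
  x <- to_canonical(x)
  for (lab in names(factors)) {
    f <- as.integer(factors[[lab]])
    if (f < 1L) stop("bin factor must be >= 1")
    if (f == 1L) next
    ax <- match(lab, x$labels)
    if (is.na(ax)) stop("unknown axis label: '", lab, "'")
    d <- dim(x$values)
    if (f > d[ax]) stop("bin factor ", f, " exceeds extent of axis '",
                        lab, "' (", d[ax], ")")
    nkeep <- (d[ax] %/% f) * f
    keep <- lapply(seq_along(d), function(i) seq_len(d[i]))
    keep[[ax]] <- seq_len(nkeep)
    vals <- do.call(`[`, c(list(x$values), keep, list(drop = FALSE)))
    # average consecutive groups of f along axis ax
    perm <- c(ax, seq_along(d)[-ax])
    v <- aperm(vals, perm)
    dim(v) <- c(f, nkeep %/% f, prod(dim(vals)[-ax]))
    v <- colMeans(v)                      # (nkeep/f) x rest
    dim(v) <- c(nkeep %/% f, dim(vals)[-ax])
    v <- aperm(v, order(perm))
    g <- bin_geometry(x$geometry, lab, f, nkeep %/% f)
    x <- as_tomo_data(v, g, x$labels)
  }
  x
}

bin_geometry <- function(g, lab, f, newn) {
  if (inherits(g, "acquisition_geometry")) {
    switch(lab,
      angle = { g$angles <- g$angles[seq_len(newn * f)]
                g$angles <- colMeans(matrix(g$angles, nrow = f)); g },
      horizontal = { g$pixel_num_h <- newn
                     g$pixel_size_h <- g$pixel_size_h * f; g },
      vertical = { g$pixel_num_v <- newn
                   g$pixel_size_v <- g$pixel_size_v * f; g })
  } else {
    switch(lab,
      horizontal_x = { g$voxel_num_x <- newn
                       g$voxel_size_x <- g$voxel_size_x * f; g },
      horizontal_y = { g$voxel_num_y <- newn
                       g$voxel_size_y <- g$voxel_size_y * f; g },
      vertical = { g$voxel_num_z <- newn
                   g$voxel_size_z <- g$voxel_size_z * f; g })
  }
}

#' Pad labelled axes
#'
#' Extends axes by `(before, after)` elements, either with a constant value
#' or by replicating the edge element.  Geometry counts are updated;
#' padded angles are extrapolated with the mean angular step.
#'
#' @param x a `tomo_data`.
#' @param widths named list of `c(before, after)` pairs (>= 0) per axis.
#' @param mode `"constant"` (default) or `"edge"`.
#' @param value fill value for constant mode (default 0).
#' @return padded container.
#' @export
pad_axes <- function(x, widths, mode = c("constant", "edge"), value = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "tomo_data"))
  x <- to_canonical(x)
  for (lab in names(widths)) {
    w <- as.integer(widths[[lab]])
    if (length(w) == 1L) w <- c(w, w)
    if (any(w < 0L)) stop("pad widths must be >= 0")
    if (all(w == 0L)) next
    ax <- match(lab, x$labels)
    if (is.na(ax)) stop("unknown axis label: '", lab, "'")
    d <- dim(x$values)
    newd <- d; newd[ax] <- d[ax] + sum(w)
    idxmap <- c(rep(1L, w[1L]), seq_len(d[ax]), rep(d[ax], w[2L]))
    keep <- lapply(seq_along(d), function(i) seq_len(d[i]))
    keep[[ax]] <- idxmap
    vals <- do.call(`[`, c(list(x$values), keep, list(drop = FALSE)))
    if (mode == "constant") {
      sel <- lapply(seq_along(d), function(i) seq_len(newd[i]))
      pre <- seq_len(w[1L]); post <- w[1L] + d[ax] + seq_len(w[2L])
      for (rng in list(pre, post)) {
        if (length(rng) == 0L) next
        s <- sel; s[[ax]] <- rng
        vals <- do.call(`[<-`, c(list(vals), s, list(value = value)))
      }
    }
    g <- pad_geometry(x$geometry, lab, w)
    x <- as_tomo_data(vals, g, x$labels)
  }
  x
}

pad_geometry <- function(g, lab, w) {
  if (inherits(g, "acquisition_geometry")) {
    switch(lab,
      angle = {
        step <- if (length(g$angles) > 1L) mean(diff(g$angles)) else 1
        g$angles <- c(g$angles[1L] - rev(seq_len(w[1L])) * step, g$angles,
                      g$angles[length(g$angles)] + seq_len(w[2L]) * step)
        g },
      horizontal = { g$pixel_num_h <- g$pixel_num_h + sum(w); g },
      vertical = { g$pixel_num_v <- g$pixel_num_v + sum(w); g })
  } else {
    switch(lab,
      horizontal_x = { g$voxel_num_x <- g$voxel_num_x + sum(w); g },
      horizontal_y = { g$voxel_num_y <- g$voxel_num_y + sum(w); g },
      vertical = { g$voxel_num_z <- g$voxel_num_z + sum(w); g })
  }
}

#' Centre-of-rotation estimation by cross-correlation
#'
#' Estimates the signed offset (in detector pixels) of the rotation-axis
#' image from the detector midline on parallel-beam data, using normalized
#' cross-correlation between the central-row profile at an angle
#' \eqn{\theta} and the horizontally flipped profile at \eqn{\theta + 180^\circ}
#' (pair matched within 0.1 degrees), refined by 3-point parabolic
#' interpolation; the offset is half the argmax lag.
#'
#' @param x parallel-beam `acquisition_data` containing an opposing angle
#'   pair.
#' @param ang_tol pairing tolerance in degrees (default 0.1).
#' @return signed sub-pixel offset, in detector pixels.
#' @seealso [correct_centre_of_rotation()] which writes the estimate into
#'   the geometry (data untouched).
#' @export
find_centre_of_rotation <- function(x, ang_tol = 0.1) {
  stopifnot(inherits(x, "acquisition_data"))
  ag <- x$geometry
  if (!ag$beam_type %in% c("parallel2D", "parallel3D"))
    stop("centre-of-rotation estimation requires parallel-beam data")
  if (length(ag$angles) < 2L)
    stop("need at least two projections with an opposing (theta, theta+180) pair")
  x <- to_canonical(x)
  ang_deg <- if (ag$angle_unit == "degree") ag$angles else ag$angles * 180 / pi
  # find a pair (i, j) with angle_j - angle_i ~ 180 (mod 360)
  pair <- NULL
  gap <- outer(ang_deg, ang_deg, function(a, b) abs(((b - a) - 180) %% 360))
  gap <- pmin(gap, 360 - gap)
  hit <- which(gap <= ang_tol, arr.ind = TRUE)
  if (nrow(hit) > 0L) pair <- hit[1L, ]
  if (is.null(pair))
    stop("no opposing projection pair (theta, theta+180) found within ",
         ang_tol, " degrees")
  prof <- function(i) {
    if (ag$beam_type == "parallel3D") {
      v <- dim(x$values)[2L]
      x$values[i, max(1L, (v + 1L) %/% 2L), ]
    } else x$values[i, ]
  }
  p0 <- prof(pair[1L]); p1 <- rev(prof(pair[2L]))
  if (stats::sd(p0) == 0 || stats::sd(p1) == 0)
    stop("flat (zero-variance) profiles; cannot estimate centre of rotation")
  n <- length(p0)
  p0 <- p0 - mean(p0); p1 <- p1 - mean(p1)
  maxlag <- n %/% 2L
  lags <- seq.int(-maxlag, maxlag)
  cc <- vapply(lags, function(l) {
    i0 <- max(1L, 1L + l); i1 <- min(n, n + l)
    a <- p0[i0:i1]; b <- p1[(i0 - l):(i1 - l)]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) -Inf else sum(a * b) / den
  }, numeric(1L))
  k <- which.max(cc)
  lag <- lags[k]
  # parabolic sub-pixel refinement
  if (k > 1L && k < length(cc) && is.finite(cc[k - 1L]) &&
      is.finite(cc[k + 1L])) {
    den <- cc[k - 1L] - 2 * cc[k] + cc[k + 1L]
    if (den < 0) lag <- lag + 0.5 * (cc[k - 1L] - cc[k + 1L]) / den
  }
  # p0(s) ~ f(s - off), p1rev(s) ~ f(s + off)  =>  argmax lag = 2 * off
  lag / 2
}

#' Write the centre-of-rotation estimate into the geometry
#'
#' Runs [find_centre_of_rotation()] and records the estimate (converted to
#' physical units) in `geometry$rotation_axis_offset`, leaving the data
#' untouched; the offset is consumed by the projector and FBP.
#'
#' @inheritParams find_centre_of_rotation
#' @return the input container with updated geometry.
#' @export
correct_centre_of_rotation <- function(x, ang_tol = 0.1) {
  off_px <- find_centre_of_rotation(x, ang_tol)
  x$geometry$rotation_axis_offset <- off_px * x$geometry$pixel_size_h
  x
}

#' Binary mask generation and application
#'
#' `make_mask` flags entries to KEEP: inside `[lo, hi]` for the threshold
#' method, or inside the central quantile range for the quantile method.
#' `apply_mask` replaces masked-out entries by a constant or by the mean of
#' their kept neighbours (along the last axis).
#'
#' @param x a `tomo_data`.
#' @param method `"threshold"` or `"quantile"`.
#' @param lo,hi threshold bounds (defaults `-Inf`, `Inf`).
#' @param probs central quantile mass to keep (default 0.98 keeps the
#'   \[1%, 99%\] range).
#' @return `make_mask`: a logical array (TRUE = keep); `apply_mask`: a
#'   container with masked-out entries filled.
#' @export
make_mask <- function(x, method = c("threshold", "quantile"),
                      lo = -Inf, hi = Inf, probs = 0.98) {
  method <- match.arg(method)
  vals <- if (inherits(x, "tomo_data")) x$values else as.array(x)
  if (method == "quantile") {
    a <- (1 - probs) / 2
    q <- stats::quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
    lo <- q[1L]; hi <- q[2L]
  }
  vals >= lo & vals <= hi
}

#' @rdname make_mask
#' @param mask logical array of the data's shape (TRUE = keep).
#' @param fill `"value"` or `"neighbour-mean"`.
#' @param value constant used when `fill = "value"` (default 0).
#' @export
apply_mask <- function(x, mask, fill = c("value", "neighbour-mean"),
                       value = 0) {
  fill <- match.arg(fill)
  vals <- if (inherits(x, "tomo_data")) x$values else as.array(x)
  if (!identical(dim(mask), dim(vals)))
    stop("mask shape must equal data shape")
  if (fill == "value") {
    vals[!mask] <- value
  } else {
    if (!any(mask)) stop("all-false mask with neighbour-mean fill")
    d <- dim(vals)
    lastn <- d[length(d)]
    m2 <- matrix(vals, ncol = lastn)
    k2 <- matrix(mask, ncol = lastn)
    for (r in which(rowSums(!k2) > 0L)) {
      rowv <- m2[r, ]; rowk <- k2[r, ]
      for (j in which(!rowk)) {
        left <- which(rowk & seq_len(lastn) < j)
        right <- which(rowk & seq_len(lastn) > j)
        nb <- c(if (length(left)) rowv[max(left)],
                if (length(right)) rowv[min(right)])
        m2[r, j] <- if (length(nb)) mean(nb) else mean(rowv[rowk])
      }
    }
    vals <- array(m2, dim = d)
  }
  replace_values(x, vals)
}

#' Validated processor specification
#'
#' A serializable description of one preprocessing step, as used by the CLI
#' YAML configuration.  Parameters are validated at construction, before
#' any data is seen.
#'
#' @param name one of `"normaliser"`, `"negative_log"`, `"slicer"`,
#'   `"binner"`, `"padder"`, `"cor_corrector"`, `"mask_generator"`,
#'   `"masker"`.
#' @param parameters named list of name-specific parameters.
#' @return an object of class `processor_spec`.
#' @export
processor_spec <- function(name, parameters = list()) {
  name <- match.arg(name, c("normaliser", "negative_log", "slicer", "binner",
                            "padder", "cor_corrector", "mask_generator",
                            "masker"))
  stopifnot(is.list(parameters))
  switch(name,
    negative_log = {
      cf <- parameters$clip_floor %||% 1e-6
      if (!is.numeric(cf) || cf <= 0) stop("clip_floor must be > 0")
    },
    slicer = if (is.null(parameters$roi)) stop("slicer requires 'roi'"),
    binner = if (is.null(parameters$factors)) stop("binner requires 'factors'"),
    padder = if (is.null(parameters$widths)) stop("padder requires 'widths'"),
    normaliser = if (is.null(parameters$flat)) stop("normaliser requires 'flat'"),
    invisible(NULL))
  structure(list(name = name, parameters = parameters),
            class = "processor_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a processor specification to a container
#' @param spec a [processor_spec()].
#' @param x a `tomo_data`.
#' @return the processed container.
#' @export
apply_processor <- function(spec, x) {
  stopifnot(inherits(spec, "processor_spec"))
  p <- spec$parameters
  switch(spec$name,
    normaliser = normalise(x, p$flat, p$dark %||% 0, p$eps %||% 1e-8),
    negative_log = negative_log(x, p$clip_floor %||% 1e-6),
    slicer = slice_axes(x, p$roi),
    binner = bin_axes(x, p$factors),
    padder = pad_axes(x, p$widths, p$mode %||% "constant", p$value %||% 0),
    cor_corrector = correct_centre_of_rotation(x, p$ang_tol %||% 0.1),
    mask_generator = make_mask(x, p$method %||% "threshold",
                               p$lo %||% -Inf, p$hi %||% Inf,
                               p$probs %||% 0.98),
    masker = apply_mask(x, p$mask, p$fill %||% "value", p$value %||% 0))
}
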
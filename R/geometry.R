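#' Acquisition geometry
#'
#' Describes a tomographic scan configuration: beam type, rotation angles,
#' detector layout and rotation-axis placement.  An acquisition geometry is
#' attached to every sinogram ([acquisition data][allocate]) and consumed by
#' the projector and the FBP reconstructor.
#'
#' The canonical axis order for acquisition data is
#' `(angle, vertical, horizontal)`; 2D geometries drop `vertical`.
#' Angles are stored with an explicit unit flag (`"degree"` default) and are
#' measured counterclockwise from the +x axis.  `rotation_axis_offset` is the
#' signed horizontal displacement (physical units) of the rotation-axis image
#' from the detector midline; it is honoured by the projector and FBP.
#'
#' Cone-beam geometries are represented (fields validated and stored) but not
#' projected; `source_position` and `detector_position` are required for them.
#'
#' @param beam_type one of `"parallel2D"`, `"parallel3D"`, `"cone2D"`,
#'   `"cone3D"`.
#' @param angles numeric vector of rotation angles (at least one).
#' @param pixel_num_h,pixel_num_v detector pixel counts (horizontal,
#'   vertical); `pixel_num_v` is ignored for 2D beam types.
#' @param pixel_size_h,pixel_size_v physical pixel pitches (> 0).
#' @param angle_unit `"degree"` (default) or `"radian"`.
#' @param rotation_axis_offset signed offset of the axis image on the
#'   detector, in physical units (default 0).
#' @param rotation_axis_direction length-3 unit-ish vector, default `(0,0,1)`;
#'   a tilted axis is stored for cone3D (laminography) but not projected.
#' @param source_position,detector_position length-3 vectors, cone beam only.
#' @param dimension_labels optional permutation of the labels implied by
#'   `beam_type`; the default is the canonical order.
#' @return an object of class `acquisition_geometry`.
#' @examples
#' ag <- acquisition_geometry("parallel3D", angles = seq(0, 180, length.out = 91),
#'                            pixel_num_h = 160, pixel_num_v = 135)
#' geom_shape(ag)
#' @export
acquisition_geometry <- function(beam_type = c("parallel2D", "parallel3D",
                                               "cone2D", "cone3D"),
                                 angles,
                                 pixel_num_h,
                                 pixel_num_v = 1L,
                                 pixel_size_h = 1,
                                 pixel_size_v = pixel_size_h,
                                 angle_unit = c("degree", "radian"),
                                 rotation_axis_offset = 0,
                                 rotation_axis_direction = c(0, 0, 1),
                                 source_position = NULL,
                                 detector_position = NULL,
                                 dimension_labels = NULL) {
  beam_type <- match.arg(beam_type)
  angle_unit <- match.arg(angle_unit)
  if (length(angles) < 1L || !is.numeric(angles))
    stop("'angles' must contain at least one rotation angle")
  is3d <- beam_type %in% c("parallel3D", "cone3D")
  is_cone <- beam_type %in% c("cone2D", "cone3D")
  pixel_num_h <- as.integer(pixel_num_h)
  pixel_num_v <- if (is3d) as.integer(pixel_num_v) else 1L
  if (pixel_num_h < 1L || pixel_num_v < 1L)
    stop("detector pixel counts must be >= 1")
  if (pixel_size_h <= 0 || pixel_size_v <= 0)
    stop("detector pixel sizes must be > 0")
  if (is_cone && (is.null(source_position) || is.null(detector_position)))
    stop("cone-beam geometry requires 'source_position' and 'detector_position'")
  if (!is_cone) {
    source_position <- NULL
    detector_position <- NULL
  } else {
    stopifnot(length(source_position) == 3L, length(detector_position) == 3L)
    source_position <- as.numeric(source_position)
    detector_position <- as.numeric(detector_position)
  }
  if (length(rotation_axis_direction) != 3L)
    stop("'rotation_axis_direction' must be a length-3 vector")
  canonical <- if (is3d) c("angle", "vertical", "horizontal")
               else c("angle", "horizontal")
  if (is.null(dimension_labels)) {
    dimension_labels <- canonical
  } else if (!setequal(dimension_labels, canonical) ||
             length(dimension_labels) != length(canonical)) {
    stop("'dimension_labels' must be a permutation of: ",
         paste(canonical, collapse = ", "))
  }
  structure(list(
    beam_type = beam_type,
    angles = as.numeric(angles),
    angle_unit = angle_unit,
    pixel_num_h = pixel_num_h,
    pixel_num_v = pixel_num_v,
    pixel_size_h = as.numeric(pixel_size_h),
    pixel_size_v = as.numeric(pixel_size_v),
    rotation_axis_offset = as.numeric(rotation_axis_offset),
    rotation_axis_direction = as.numeric(rotation_axis_direction),
    source_position = source_position,
    detector_position = detector_position,
    dimension_labels = as.character(dimension_labels)
  ), class = "acquisition_geometry")
}

#' Create an acquisition geometry from a flat configuration list
#'
#' Thin wrapper over [acquisition_geometry()] for configuration-driven use
#' (YAML/HDF5 round trips, CLI).
#'
#' @param config named list with at least `beam_type`, `angles` and
#'   `pixel_num_h`; remaining entries as in [acquisition_geometry()].
#' @return an `acquisition_geometry`.
#' @export
create_acquisition_geometry <- function(config) {
  stopifnot(is.list(config))
  do.call(acquisition_geometry, config)
}

#' Image geometry
#'
#' Voxel-grid specification for a reconstruction volume.  Canonical axis
#' order is `(vertical, horizontal_y, horizontal_x)`; 2D grids drop
#' `vertical` (set `voxel_num_z = 0`), 1D grids keep only `horizontal_x`.
#'
#' @param voxel_num_x,voxel_num_y,voxel_num_z voxel counts; `voxel_num_y = 0`
#'   gives a 1D grid, `voxel_num_z = 0` a 2D grid.
#' @param voxel_size_x,voxel_size_y,voxel_size_z physical voxel pitches (> 0).
#' @param center_x,center_y,center_z offsets of the volume centre from the
#'   rotation axis / origin, in physical units.
#' @param dimension_labels optional permutation of the implied labels.
#' @return an object of class `image_geometry`.
#' @examples
#' ig <- image_geometry(64, 64)
#' geom_shape(ig)
#' @export
image_geometry <- function(voxel_num_x,
                           voxel_num_y = voxel_num_x,
                           voxel_num_z = 0L,
                           voxel_size_x = 1,
                           voxel_size_y = voxel_size_x,
                           voxel_size_z = voxel_size_x,
                           center_x = 0, center_y = 0, center_z = 0,
                           dimension_labels = NULL) {
  voxel_num_x <- as.integer(voxel_num_x)
  voxel_num_y <- as.integer(voxel_num_y)
  voxel_num_z <- as.integer(voxel_num_z)
  if (voxel_num_x < 1L) stop("'voxel_num_x' must be >= 1")
  if (voxel_num_y < 0L || voxel_num_z < 0L)
    stop("voxel counts must be non-negative")
  if (voxel_num_z > 0L && voxel_num_y < 1L)
    stop("3D grid requires voxel_num_y >= 1")
  if (voxel_size_x <= 0 || voxel_size_y <= 0 || voxel_size_z <= 0)
    stop("voxel sizes must be > 0")
  canonical <- c(if (voxel_num_z > 0L) "vertical",
                 if (voxel_num_y > 0L) "horizontal_y",
                 "horizontal_x")
  if (is.null(dimension_labels)) {
    dimension_labels <- canonical
  } else if (!setequal(dimension_labels, canonical) ||
             length(dimension_labels) != length(canonical)) {
    stop("'dimension_labels' must be a permutation of: ",
         paste(canonical, collapse = ", "))
  }
  structure(list(
    voxel_num_x = voxel_num_x, voxel_num_y = voxel_num_y,
    voxel_num_z = voxel_num_z,
    voxel_size_x = as.numeric(voxel_size_x),
    voxel_size_y = as.numeric(voxel_size_y),
    voxel_size_z = as.numeric(voxel_size_z),
    center_x = as.numeric(center_x), center_y = as.numeric(center_y),
    center_z = as.numeric(center_z),
    dimension_labels = as.character(dimension_labels)
  ), class = "image_geometry")
}

#' Default reconstruction grid for a parallel-beam scan
#'
#' Derives the conventional reconstruction volume from a parallel-beam
#' acquisition geometry: `voxel_num_x = voxel_num_y = pixel_num_h`,
#' `voxel_num_z = pixel_num_v` (3D only), voxel sizes equal to the detector
#' pixel sizes, volume centred on the rotation axis.
#'
#' @param ag a parallel-beam `acquisition_geometry`.
#' @return an `image_geometry`.
#' @export
default_image_geometry <- function(ag) {
  stopifnot(inherits(ag, "acquisition_geometry"))
  if (!ag$beam_type %in% c("parallel2D", "parallel3D"))
    stop("default image geometry is only defined for parallel-beam data ",
         "(cone-beam magnification rules are out of scope)")
  image_geometry(
    voxel_num_x = ag$pixel_num_h,
    voxel_num_y = ag$pixel_num_h,
    voxel_num_z = if (ag$beam_type == "parallel3D") ag$pixel_num_v else 0L,
    voxel_size_x = ag$pixel_size_h,
    voxel_size_y = ag$pixel_size_h,
    voxel_size_z = ag$pixel_size_v
  )
}

#' Canonical axis labels of a geometry
#' @param g an `acquisition_geometry` or `image_geometry`.
#' @return character vector of axis labels in canonical storage order.
#' @export
geom_labels <- function(g) {
  if (inherits(g, "acquisition_geometry")) {
    if (g$beam_type %in% c("parallel3D", "cone3D"))
      c("angle", "vertical", "horizontal")
    else c("angle", "horizontal")
  } else if (inherits(g, "image_geometry")) {
    c(if (g$voxel_num_z > 0L) "vertical",
      if (g$voxel_num_y > 0L) "horizontal_y",
      "horizontal_x")
  } else stop("not a geometry object")
}

#' Implied array shape of a geometry
#' @param g an `acquisition_geometry` or `image_geometry`.
#' @return named integer vector, one entry per canonical axis.
#' @export
geom_shape <- function(g) {
  labs <- geom_labels(g)
  if (inherits(g, "acquisition_geometry")) {
    dims <- c(angle = length(g$angles), vertical = g$pixel_num_v,
              horizontal = g$pixel_num_h)
  } else {
    dims <- c(vertical = g$voxel_num_z, horizontal_y = g$voxel_num_y,
              horizontal_x = g$voxel_num_x)
  }
  dims[labs]
}

#' Geometry equality with tolerance
#'
#' Field-by-field comparison; numeric fields compared with absolute
#' tolerance `tol`.  Used to gate operator/data compatibility.
#'
#' @param a,b geometry objects.
#' @param tol numeric tolerance on float fields (default `1e-9`).
#' @return logical scalar.
#' @export
geom_equal <- function(a, b, tol = 1e-9) {
  if (!identical(class(a), class(b))) return(FALSE)
  fields <- union(names(a), names(b))
  for (f in fields) {
    va <- a[[f]]; vb <- b[[f]]
    if (is.null(va) != is.null(vb)) return(FALSE)
    if (is.null(va)) next
    if (is.character(va)) {
      if (!identical(va, vb)) return(FALSE)
    } else {
      if (length(va) != length(vb)) return(FALSE)
      if (any(abs(as.numeric(va) - as.numeric(vb)) > tol)) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("<acquisition_geometry> ", x$beam_type, "\n",
      "  angles: ", length(x$angles), " (", x$angle_unit, "), range [",
      format(min(x$angles)), ", ", format(max(x$angles)), "]\n",
      "  detector: ", x$pixel_num_h, " x ", x$pixel_num_v,
      " (pitch ", x$pixel_size_h, " x ", x$pixel_size_v, ")\n",
      "  rotation axis offset: ", x$rotation_axis_offset, "\n", sep = "")
  invisible(x)
}

#' @export
print.image_geometry <- function(x, ...) {
  cat("<image_geometry> ",
      paste(geom_shape(x), collapse = " x "), " voxels (",
      paste(geom_labels(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# angles in radians regardless of stored unit
geom_angles_rad <- function(ag) {
  if (ag$angle_unit == "degree") ag$angles * pi / 180 else ag$angles
}

# reduce a geometry after removing one axis (get_slice); returns NULL when no
# meaningful geometry remains (e.g. a single projection extracted by angle)
reduce_geometry <- function(g, label) {
  if (inherits(g, "acquisition_geometry")) {
    switch(label,
      vertical = acquisition_geometry(
        "parallel2D", angles = g$angles, pixel_num_h = g$pixel_num_h,
        pixel_size_h = g$pixel_size_h, angle_unit = g$angle_unit,
        rotation_axis_offset = g$rotation_axis_offset),
      NULL)
  } else {
    switch(label,
      vertical = image_geometry(
        g$voxel_num_x, g$voxel_num_y, 0L,
        g$voxel_size_x, g$voxel_size_y, g$voxel_size_z,
        g$center_x, g$center_y, 0),
      horizontal_y = image_geometry(
        g$voxel_num_x, 0L, 0L, g$voxel_size_x,
        center_x = g$center_x),
      NULL)
  }
}
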
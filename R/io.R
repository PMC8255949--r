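# Minimal uncompressed 32-bit-float little-endian TIFF codec (single strip,
# SampleFormat = IEEE float).  No TIFF package exists in this R stack; the
# subset below is sufficient for lossless self-roundtrip of float imagery and
# is readable by the common scientific TIFF readers.

write_float_tiff <- function(m, path) {
  m <- as.matrix(m)
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  data_offset <- 8L
  nbytes <- w * h * 4L
  ifd_offset <- data_offset + nbytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  # pixel data, row-major (TIFF scanlines)
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  entries <- list(
    c(256L, 4L, 1L, w),            # ImageWidth
    c(257L, 4L, 1L, h),            # ImageLength
    c(258L, 3L, 1L, 32L),          # BitsPerSample
    c(259L, 3L, 1L, 1L),           # Compression: none
    c(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
    c(273L, 4L, 1L, data_offset),  # StripOffsets
    c(277L, 3L, 1L, 1L),           # SamplesPerPixel
    c(278L, 4L, 1L, h),            # RowsPerStrip
    c(279L, 4L, 1L, nbytes),       # StripByteCounts
    c(339L, 3L, 1L, 3L))           # SampleFormat: IEEE float
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(e[1L], con, size = 2, endian = "little")
    writeBin(e[2L], con, size = 2, endian = "little")
    writeBin(e[3L], con, size = 4, endian = "little")
    if (e[2L] == 3L) {             # SHORT packed into 4-byte value slot
      writeBin(e[4L], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(e[4L], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

read_float_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "II"))
    stop("unsupported TIFF byte order (need little-endian) in ", path)
  fortytwo <- readBin(con, "integer", 1, size = 2, endian = "little")
  if (fortytwo != 42L) stop("not a TIFF file: ", path)
  ifd_offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, ifd_offset)
  nent <- readBin(con, "integer", 1, size = 2, endian = "little")
  tags <- list()
  for (i in seq_len(nent)) {
    tag <- readBin(con, "integer", 1, size = 2, endian = "little")
    typ <- readBin(con, "integer", 1, size = 2, endian = "little")
    cnt <- readBin(con, "integer", 1, size = 4, endian = "little")
    val <- if (typ == 3L) {
      v <- readBin(con, "integer", 1, size = 2, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      v
    } else readBin(con, "integer", 1, size = 4, endian = "little")
    tags[[as.character(tag)]] <- val
  }
  need <- c("256", "257", "273", "279")
  if (!all(need %in% names(tags)))
    stop("TIFF file missing required tags: ", path)
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
    stop("compressed TIFF not supported: ", path)
  if (!is.null(tags[["339"]]) && tags[["339"]] != 3L)
    stop("only IEEE-float sample format supported: ", path)
  w <- tags[["256"]]; h <- tags[["257"]]
  if (tags[["279"]] != w * h * 4L)
    stop("odd-sized TIFF strip in ", path)
  seek(con, tags[["273"]])
  px <- readBin(con, "numeric", w * h, size = 4, endian = "little")
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

# ---- geometry <-> plain list (YAML / HDF5 serialization) -------------------

#' Serialize a geometry to a plain list (and back)
#'
#' Used by the YAML sidecars, the HDF5 container and the CLI configuration.
#'
#' @param g a geometry object (or, for `geometry_from_list`, a list as
#'   produced by `geometry_to_list`).
#' @return a named list / a geometry object.
#' @export
geometry_to_list <- function(g) {
  out <- unclass(g)
  out$geometry_class <- class(g)[1L]
  out[!vapply(out, is.null, logical(1L))]
}

#' @rdname geometry_to_list
#' @export
geometry_from_list <- function(g) {
  cls <- g$geometry_class
  if (is.null(cls))
    cls <- if (!is.null(g$beam_type)) "acquisition_geometry"
           else "image_geometry"
  g$geometry_class <- NULL
  if (cls == "acquisition_geometry") {
    do.call(acquisition_geometry, g[intersect(names(g),
      names(formals(acquisition_geometry)))])
  } else {
    do.call(image_geometry, g[intersect(names(g),
      names(formals(image_geometry)))])
  }
}

#' Write / read a TIFF stack
#'
#' Writes one 32-bit float TIFF per leading-axis index (angles for
#' acquisition data, vertical slices for volumes) with zero-padded 5-digit
#' suffixes, plus a YAML sidecar `<prefix>_geometry.yaml` recording the
#' geometry and axis labels.  2D data writes a single file.  The roundtrip
#' is bit-exact at 32-bit precision.
#'
#' @param x a `tomo_data` (2D or 3D).
#' @param directory output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `write_tiff_stack`: the directory, invisibly;
#'   `read_tiff_stack`: a `tomo_data`.
#' @export
write_tiff_stack <- function(x, directory, prefix = "slice") {
  stopifnot(inherits(x, "tomo_data"))
  x <- to_canonical(x)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  d <- dim(x$values)
  if (length(d) == 2L) {
    write_float_tiff(x$values, file.path(directory,
                                         sprintf("%s_%05d.tif", prefix, 0L)))
  } else if (length(d) == 3L) {
    for (i in seq_len(d[1L]))
      write_float_tiff(array(x$values[i, , ], dim = d[-1L]),
                       file.path(directory,
                                 sprintf("%s_%05d.tif", prefix, i - 1L)))
  } else stop("TIFF stacks support 2D/3D data only")
  side <- list(geometry = geometry_to_list(x$geometry), labels = x$labels)
  yaml::write_yaml(side, file.path(directory,
                                   paste0(prefix, "_geometry.yaml")))
  invisible(directory)
}

#' @rdname write_tiff_stack
#' @param geometry optional geometry; when `NULL` the YAML sidecar written
#'   by `write_tiff_stack` is required.
#' @export
read_tiff_stack <- function(directory, prefix = "slice", geometry = NULL) {
  files <- sort(list.files(directory,
                           pattern = paste0("^", prefix, "_\\d{5}\\.tif$"),
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no TIFF files with prefix '", prefix, "' in ", directory)
  labels <- NULL
  if (is.null(geometry)) {
    side_path <- file.path(directory, paste0(prefix, "_geometry.yaml"))
    if (!file.exists(side_path))
      stop("no geometry given and no sidecar found at ", side_path)
    side <- yaml::read_yaml(side_path)
    geometry <- geometry_from_list(side$geometry)
    labels <- unlist(side$labels)
  }
  shape <- unname(geom_shape(geometry))
  slices <- lapply(files, read_float_tiff)
  dims <- unique(lapply(slices, dim))
  if (length(dims) > 1L) stop("inconsistent slice sizes in TIFF stack")
  if (length(shape) == 2L) {
    if (length(files) != 1L) stop("2D geometry but ", length(files), " files")
    vals <- array(slices[[1L]], dim = shape)
    if (!identical(as.integer(dim(slices[[1L]])), as.integer(shape)))
      stop("TIFF slice shape does not match the geometry")
  } else {
    if (length(files) != shape[1L])
      stop("geometry expects ", shape[1L], " slices, found ", length(files))
    if (!identical(as.integer(dims[[1L]]), as.integer(shape[-1L])))
      stop("TIFF slice shape does not match the geometry")
    vals <- array(0, dim = shape)
    for (i in seq_along(slices)) vals[i, , ] <- slices[[i]]
  }
  as_tomo_data(vals, geometry, labels)
}

#' Write / read the HDF5 container
#'
#' A minimal NeXus-style fixed tree: values under
#' `/entry1/tomo_entry/data/data`, geometry fields and axis labels under
#' `/entry1/tomo_entry/config/*`.  The roundtrip reproduces values
#' bit-exactly and the geometry to tolerance.
#'
#' @param x a `tomo_data`.
#' @param path file path (overwritten).
#' @return `write_hdf5`: the path, invisibly; `read_hdf5`: a `tomo_data`.
#' @export
write_hdf5 <- function(x, path) {
  stopifnot(inherits(x, "tomo_data"))
  x <- to_canonical(x)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "entry1")
  rhdf5::h5createGroup(path, "entry1/tomo_entry")
  rhdf5::h5createGroup(path, "entry1/tomo_entry/data")
  rhdf5::h5createGroup(path, "entry1/tomo_entry/config")
  rhdf5::h5write(x$values, path, "entry1/tomo_entry/data/data")
  rhdf5::h5write(x$labels, path, "entry1/tomo_entry/config/dimension_labels")
  gl <- geometry_to_list(x$geometry)
  gl$dimension_labels <- NULL   # the data labels above are authoritative
  for (f in names(gl))
    rhdf5::h5write(gl[[f]], path,
                   paste0("entry1/tomo_entry/config/", f))
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_hdf5
#' @export
read_hdf5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- rhdf5::h5ls(path)
  paths <- file.path(ls$group, ls$name)
  if (!"/entry1/tomo_entry/data/data" %in% paths)
    stop("malformed container: missing node /entry1/tomo_entry/data/data")
  vals <- rhdf5::h5read(path, "entry1/tomo_entry/data/data")
  cfg_rows <- ls$group == "/entry1/tomo_entry/config"
  cfg <- list()
  for (nm in ls$name[cfg_rows])
    cfg[[nm]] <- drop_h5(rhdf5::h5read(path,
                                       paste0("entry1/tomo_entry/config/", nm)))
  rhdf5::h5closeAll()
  labels <- as.character(cfg$dimension_labels)
  cfg$dimension_labels <- NULL
  g <- geometry_from_list(cfg)
  as_tomo_data(vals, g, labels)
}

drop_h5 <- function(v) {
  v <- drop(v)
  if (length(v) == 1L && is.numeric(v)) as.numeric(v) else v
}
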
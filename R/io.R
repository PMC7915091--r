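## Self-describing array container: a single binary file holding one labeled
## numeric array (a frame, a shift matrix, or an image cube) plus named
## dimensions and metadata attributes. Layout: 4-byte magic "HSC1", a uint32
## header length, a UTF-8 JSON header (dim names, dim sizes, attributes),
## then the array payload as little-endian float64 in R (column-major)
## order. The round trip is bit-exact.

CONTAINER_MAGIC <- "HSC1"

write_container <- function(values, dim_names, attrs, path) {
  dims <- dim(values)
  if (is.null(dims)) dims <- length(values)
  if (length(dims) != length(dim_names))
    stop_shape("`dim_names` must name every array dimension")
  header <- jsonlite::toJSON(
    list(dims = as.list(stats::setNames(as.integer(dims), dim_names)),
         dim_order = dim_names, dtype = "float64", byte_order = "little",
         attrs = attrs),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  raw_header <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(CONTAINER_MAGIC), con)
  writeBin(length(raw_header), con, size = 4, endian = "little")
  writeBin(raw_header, con)
  writeBin(as.numeric(values), con, size = 8, endian = "little")
  invisible(path)
}

read_container <- function(path, required_attrs = character(0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, CONTAINER_MAGIC))
    stop_format(sprintf("'%s' is not a desmile array container", path))
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  for (field in c("dims", "dim_order")) {
    if (is.null(header[[field]]))
      stop_format(sprintf("container header lacks required field \"%s\"", field))
  }
  attrs <- as.list(header$attrs)
  for (field in required_attrs) {
    if (is.null(attrs[[field]]))
      stop_format(sprintf("container header lacks required attribute \"%s\"", field))
  }
  dims <- unname(unlist(header$dims[header$dim_order]))
  values <- readBin(con, "numeric", prod(dims), size = 8, endian = "little")
  if (length(values) != prod(dims))
    stop_format("container payload is shorter than the declared dimensions")
  dim(values) <- dims
  list(values = values, dim_order = header$dim_order, attrs = attrs)
}

#' Write an image cube to a container file
#'
#' Stores the cube values with named dims `(scan_index, y, x)` and all
#' metadata (exposure, scan geometry, crop window, the corrected flag and
#' any extras) in the self-describing header. [read_cube()] restores it
#' losslessly.
#'
#' @param cube An [hsi_cube()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  if (!inherits(cube, "hsi_cube")) stop_validation("`cube` must be an hsi_cube")
  attrs <- list(
    exposure_ms = cube$meta$exposure_ms, scan_length = cube$meta$scan_length,
    scan_velocity = cube$meta$scan_velocity, corrected = cube$meta$corrected,
    crop = cube$meta$crop, units = cube$meta$units
  )
  if (length(cube$meta$extra) > 0) attrs$extra <- cube$meta$extra
  write_container(cube$values, c("scan_index", "y", "x"), attrs, path)
}

#' Read an image cube from a container file
#'
#' @param path File written by [write_cube()].
#' @return An [hsi_cube()]. A file lacking the `corrected` attribute (or the
#'   dimension declarations) raises a format error naming the missing field.
#' @export
read_cube <- function(path) {
  rc <- read_container(path, required_attrs = "corrected")
  if (!identical(rc$dim_order, c("scan_index", "y", "x")))
    stop_format("container does not hold (scan_index, y, x) cube data")
  a <- rc$attrs
  hsi_cube(rc$values,
           exposure_ms = a$exposure_ms %||% NA_real_,
           scan_length = a$scan_length %||% NA_real_,
           scan_velocity = a$scan_velocity %||% NA_real_,
           corrected = isTRUE(a$corrected),
           crop = a$crop, units = a$units %||% "counts",
           extra = a$extra %||% list())
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a single frame (or shift matrix) to a container file
#'
#' @param frame Numeric matrix with dims `(y, x)`.
#' @param path Output file path.
#' @param attrs Named list of metadata to store (e.g. frame and distortion
#'   parameters, or shift-matrix provenance).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, attrs = list()) {
  if (!is.matrix(frame)) stop_shape("`frame` must be a matrix")
  if (inherits(frame, "shift_matrix") && is.null(attrs$provenance)) {
    prov <- attr(frame, "provenance")
    attrs$provenance <- prov[, setdiff(names(prov), "mode"), drop = FALSE]
    attrs$kind <- "shift_matrix"
  }
  write_container(unclass(frame)[, , drop = FALSE], c("y", "x"), attrs, path)
}

#' Read a single frame (or shift matrix) from a container file
#'
#' @param path File written by [write_frame()].
#' @return List with `frame` (matrix) and `attrs` (metadata list).
#' @export
read_frame <- function(path) {
  rc <- read_container(path)
  if (!identical(rc$dim_order, c("y", "x")))
    stop_format("container does not hold (y, x) frame data")
  list(frame = rc$values, attrs = rc$attrs)
}

#' Export a frame as 16-bit grayscale TIFF for visual inspection
#'
#' Values are scaled by `max_value` (default: the frame maximum) into
#' `[0, 1]` and quantized to 16 bits, so the export is lossy; use
#' [write_frame()] for exact persistence.
#'
#' @param frame Numeric matrix.
#' @param path Output `.tif` path.
#' @param max_value Intensity mapped to full scale.
#' @return `path`, invisibly.
#' @export
export_frame_tiff <- function(frame, path, max_value = NULL) {
  if (is.null(max_value)) max_value <- max(frame)
  if (max_value <= 0) max_value <- 1
  img <- pmin(pmax(frame / max_value, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}

#' Import a 16-bit TIFF frame
#'
#' @param path TIFF file.
#' @param max_value Scale restoring the original intensity range.
#' @return Numeric matrix.
#' @export
import_frame_tiff <- function(path, max_value = 1) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * max_value
}

#' Write a false-color image to PNG
#'
#' @param rgb Array `(scan_index, y, 3)` from [false_color()].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_false_color_png <- function(rgb, path) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop_shape("`rgb` must be a (scan_index, y, 3) array")
  png::writePNG(aperm(rgb, c(2, 1, 3)), path) # y as image height, scan as width
  invisible(path)
}
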
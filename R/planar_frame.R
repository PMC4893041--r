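#' Static planar scintigraphy frame
#'
#' A `planar_frame` holds one static planar gamma-camera view: a grid of
#' detected counts per pixel plus acquisition metadata.  Pixel values are raw
#' detected events (non-negative integers); no rescaling or decay correction
#' is applied at this level.  Pixel coordinates throughout the package are
#' 0-based `(row, col)` with pixel centers at integer coordinates.
#'
#' @param counts numeric matrix of detected counts; all entries must be
#'   non-negative and integral.
#' @param pixel_spacing_mm positive length-2 numeric, physical pixel size
#'   (row, col) in millimetres.
#' @param acquisition_start_s acquisition start, seconds from injection.
#' @param duration_s positive acquisition duration in seconds.
#' @param view_label free-text view label, e.g. `"hands-anterior"` or
#'   `"salivary-anterior"`.
#'
#' @return An object of class `planar_frame`: a list with elements `counts`,
#'   `matrix_size`, `pixel_spacing_mm`, `acquisition_start_s`, `duration_s`
#'   and `view_label`.
#' @examples
#' f <- planar_frame(matrix(1, 4, 4))
#' total_counts(f)
#' @export
planar_frame <- function(counts, pixel_spacing_mm = c(1, 1),
                         acquisition_start_s = 0, duration_s = 600,
                         view_label = "static") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_quant("counts: must be a numeric matrix")
  }
  if (any(!is.finite(counts))) stop_quant("counts: non-finite pixel values")
  if (any(counts < 0)) stop_quant("counts: negative pixel values")
  counts <- check_integral(counts, "counts")
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 2L ||
      any(!is.finite(pixel_spacing_mm)) || any(pixel_spacing_mm <= 0)) {
    stop_quant("pixel_spacing_mm: must be two positive numbers")
  }
  if (!is_number(acquisition_start_s)) {
    stop_quant("acquisition_start_s: must be a finite number")
  }
  if (!is_number(duration_s) || duration_s <= 0) {
    stop_quant("duration_s: must be a positive number")
  }
  structure(
    list(
      counts = counts,
      matrix_size = dim(counts),
      pixel_spacing_mm = as.numeric(pixel_spacing_mm),
      acquisition_start_s = as.numeric(acquisition_start_s),
      duration_s = as.numeric(duration_s),
      view_label = as.character(view_label)
    ),
    class = "planar_frame"
  )
}

#' @export
print.planar_frame <- function(x, ...) {
  cat(sprintf(
    "<planar_frame> %dx%d '%s'\n  pixel %g x %g mm, t0 = %g s, duration = %g s, total counts = %.0f\n",
    x$matrix_size[1], x$matrix_size[2], x$view_label,
    x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
    x$acquisition_start_s, x$duration_s, total_counts(x)
  ))
  invisible(x)
}

#' Total detected counts in a frame
#' @param frame a [planar_frame()].
#' @return Scalar sum of all pixel counts.
#' @export
total_counts <- function(frame) {
  stopifnot(inherits(frame, "planar_frame"))
  sum(frame$counts)
}

#' Write a planar frame in the fixture dialect
#'
#' The fixture dialect is a single JSON document (format tag
#' `"srsquant-planar"`, version 1) holding the acquisition metadata and the
#' integer counts grid as a nested array.  Integer counts round-trip
#' bit-exactly.
#'
#' @param frame a [planar_frame()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_planar()]
#' @export
write_planar <- function(frame, path) {
  stopifnot(inherits(frame, "planar_frame"))
  doc <- list(
    format = "srsquant-planar",
    version = 1L,
    matrix_size = frame$matrix_size,
    pixel_spacing_mm = frame$pixel_spacing_mm,
    acquisition_start_s = frame$acquisition_start_s,
    duration_s = frame$duration_s,
    view_label = frame$view_label,
    counts = frame$counts
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

fixture_field <- function(doc, field, path) {
  if (is.null(doc[[field]])) {
    stop_quant("parse error in '", path, "': missing field '", field, "'")
  }
  doc[[field]]
}

read_planar_fixture <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop_quant("parse error in '", path, "': ", conditionMessage(e))
  )
  if (!identical(doc$format, "srsquant-planar")) {
    stop_quant("parse error in '", path, "': field 'format' is not 'srsquant-planar'")
  }
  counts <- fixture_field(doc, "counts", path)
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1)
  msize <- fixture_field(doc, "matrix_size", path)
  if (!all(dim(counts) == msize)) {
    stop_quant("parse error in '", path, "': field 'matrix_size' does not match counts grid")
  }
  planar_frame(
    counts = counts,
    pixel_spacing_mm = fixture_field(doc, "pixel_spacing_mm", path),
    acquisition_start_s = fixture_field(doc, "acquisition_start_s", path),
    duration_s = fixture_field(doc, "duration_s", path),
    view_label = fixture_field(doc, "view_label", path)
  )
}

#' Read a static planar image
#'
#' Reads one static planar view either from the package's plain-text fixture
#' dialect (see [write_planar()]) or from a planar nuclear-medicine DICOM
#' object (read-only; explicit or implicit VR little endian).
#'
#' @param path file path.
#' @param dialect `"fixture"` or `"dicom"`.
#' @param view_label optional view label override (DICOM input only).
#' @return A validated [planar_frame()]; pixel values are raw counts.
#' @export
read_planar <- function(path, dialect = c("fixture", "dicom"), view_label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_quant("file not found: ", path)
  if (dialect == "fixture") {
    frame <- read_planar_fixture(path)
    if (!is.null(view_label)) frame$view_label <- view_label
    frame
  } else {
    read_dicom_planar(path, view_label = view_label)
  }
}
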
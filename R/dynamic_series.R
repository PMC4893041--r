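#' Dynamic scintigraphy series
#'
#' A `dynamic_series` is an ordered set of [planar_frame()]s sharing one
#' matrix size, with strictly increasing frame-edge times (seconds from
#' injection) and a stimulus timestamp (sialoscintigraphy: lemon-juice
#' administration).  Frame edges can be given explicitly or derived from each
#' frame's `acquisition_start_s` and `duration_s`, in which case frames must
#' tile time contiguously without overlap.
#'
#' @param frames list of [planar_frame()] objects, ordered in time.
#' @param frame_edges_s optional numeric vector of length `length(frames)+1`,
#'   strictly increasing frame boundary times.
#' @param stimulus_time_s stimulus time in seconds from injection; must lie
#'   within `[first edge, last edge]`.
#' @return An object of class `dynamic_series` with elements `frames`,
#'   `frame_edges_s`, `stimulus_time_s`, `matrix_size`.
#' @examples
#' f <- lapply(0:7, function(k) {
#'   planar_frame(matrix(5, 8, 8), acquisition_start_s = k * 240, duration_s = 240)
#' })
#' s <- dynamic_series(f, stimulus_time_s = 960)
#' s$frame_edges_s
#' @export
dynamic_series <- function(frames, frame_edges_s = NULL, stimulus_time_s) {
  if (!is.list(frames) || length(frames) < 1L ||
      !all(vapply(frames, inherits, logical(1), "planar_frame"))) {
    stop_quant("frames: must be a non-empty list of planar_frame objects")
  }
  sizes <- vapply(frames, function(f) f$matrix_size, numeric(2))
  if (any(sizes[1, ] != sizes[1, 1]) || any(sizes[2, ] != sizes[2, 1])) {
    stop_quant("frames: all frames must share one matrix size")
  }
  if (is.null(frame_edges_s)) {
    starts <- vapply(frames, function(f) f$acquisition_start_s, numeric(1))
    durs <- vapply(frames, function(f) f$duration_s, numeric(1))
    ord <- order(starts)
    frames <- frames[ord]
    starts <- starts[ord]
    durs <- durs[ord]
    ends <- starts + durs
    if (length(frames) > 1L &&
        any(abs(starts[-1] - ends[-length(ends)]) > 1e-6)) {
      stop_quant("frames: overlapping or non-contiguous frame times")
    }
    frame_edges_s <- c(starts, ends[length(ends)])
  }
  if (!is.numeric(frame_edges_s) ||
      length(frame_edges_s) != length(frames) + 1L) {
    stop_quant("frame_edges_s: needs length(frames) + 1 values")
  }
  if (any(diff(frame_edges_s) <= 0)) {
    stop_quant("frame_edges_s: must be strictly increasing")
  }
  if (!is_number(stimulus_time_s) ||
      stimulus_time_s < frame_edges_s[1] ||
      stimulus_time_s > frame_edges_s[length(frame_edges_s)]) {
    stop_quant("stimulus_time_s: must lie within the acquisition window")
  }
  structure(
    list(
      frames = frames,
      frame_edges_s = as.numeric(frame_edges_s),
      stimulus_time_s = as.numeric(stimulus_time_s),
      matrix_size = frames[[1]]$matrix_size
    ),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  e <- x$frame_edges_s
  cat(sprintf(
    "<dynamic_series> %d frames %dx%d, t = [%g, %g] s, stimulus at %g s\n",
    length(x$frames), x$matrix_size[1], x$matrix_size[2],
    e[1], e[length(e)], x$stimulus_time_s
  ))
  invisible(x)
}

#' Number of frames
#' @param series a [dynamic_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  length(series$frames)
}

#' Write a dynamic series in the fixture dialect
#'
#' Single JSON document (format tag `"srsquant-dynamic"`, version 1) with
#' frame edges, stimulus time and the per-frame integer count grids.
#'
#' @param series a [dynamic_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dynamic <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  doc <- list(
    format = "srsquant-dynamic",
    version = 1L,
    matrix_size = series$matrix_size,
    frame_edges_s = series$frame_edges_s,
    stimulus_time_s = series$stimulus_time_s,
    pixel_spacing_mm = series$frames[[1]]$pixel_spacing_mm,
    frames = lapply(series$frames, function(f) f$counts)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a dynamic scintigraphy series
#'
#' @param path file path (fixture JSON or multi-frame planar DICOM object).
#' @param dialect `"fixture"` or `"dicom"`.
#' @param stimulus_time_s stimulus time override, seconds from injection.
#'   Required when the file carries no stimulus annotation (always the case
#'   for DICOM input).
#' @return A validated [dynamic_series()] with frames sorted by time.
#' @export
read_dynamic <- function(path, dialect = c("fixture", "dicom"),
                         stimulus_time_s = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_quant("file not found: ", path)
  if (dialect == "dicom") {
    return(read_dicom_dynamic(path, stimulus_time_s = stimulus_time_s))
  }
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop_quant("parse error in '", path, "': ", conditionMessage(e))
  )
  if (!identical(doc$format, "srsquant-dynamic")) {
    stop_quant("parse error in '", path, "': field 'format' is not 'srsquant-dynamic'")
  }
  edges <- fixture_field(doc, "frame_edges_s", path)
  spacing <- fixture_field(doc, "pixel_spacing_mm", path)
  mats <- fixture_field(doc, "frames", path)
  if (is.array(mats) && length(dim(mats)) == 3L) {
    mats <- lapply(seq_len(dim(mats)[1]), function(k) mats[k, , ])
  }
  frames <- lapply(seq_along(mats), function(k) {
    planar_frame(as.matrix(mats[[k]]), pixel_spacing_mm = spacing,
                 acquisition_start_s = edges[k],
                 duration_s = edges[k + 1] - edges[k],
                 view_label = sprintf("frame-%03d", k))
  })
  stim <- doc$stimulus_time_s %||% stimulus_time_s
  if (is.null(stim)) {
    stop_quant("stimulus time absent from '", path,
               "' and no stimulus_time_s argument given")
  }
  dynamic_series(frames, frame_edges_s = edges, stimulus_time_s = stim)
}
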
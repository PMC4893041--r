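# Minimal read-only parser for planar nuclear-medicine DICOM objects.
# Supports Part-10 files (preamble + DICM + file meta) in explicit or
# implicit VR little endian; sequences are skipped.  Scope is deliberately
# narrow: single- or multi-frame planar images with integer pixel data.

dcm_uint16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE, endian = "little")
}

dcm_uint32 <- function(bytes, pos) {
  lo <- dcm_uint16(bytes, pos)
  hi <- dcm_uint16(bytes, pos + 2L)
  hi * 65536 + lo
}

DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

# advance past an undefined-length sequence/item payload, returning the
# position just after its delimitation item
dcm_skip_undefined <- function(bytes, pos) {
  repeat {
    if (pos + 7L > length(bytes)) stop_quant("DICOM parse error: unterminated sequence")
    group <- dcm_uint16(bytes, pos)
    elem <- dcm_uint16(bytes, pos + 2L)
    len <- dcm_uint32(bytes, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && elem == 0xE0DD) return(pos) # sequence delimiter
    if (group == 0xFFFE && elem == 0xE000) {           # item
      pos <- if (len == 4294967295) dcm_skip_item_undefined(bytes, pos) else pos + len
    } else {
      stop_quant("DICOM parse error: unexpected tag inside sequence")
    }
  }
}

dcm_skip_item_undefined <- function(bytes, pos) {
  # item with undefined length: scan nested elements until item delimiter
  repeat {
    if (pos + 7L > length(bytes)) stop_quant("DICOM parse error: unterminated item")
    group <- dcm_uint16(bytes, pos)
    elem <- dcm_uint16(bytes, pos + 2L)
    if (group == 0xFFFE && elem == 0xE00D) return(pos + 8L)
    parsed <- dcm_read_element(bytes, pos, explicit = TRUE, collect = FALSE)
    pos <- parsed$pos
  }
}

# read one data element starting at pos; returns list(tag, vr, value_raw, pos)
dcm_read_element <- function(bytes, pos, explicit, collect = TRUE) {
  group <- dcm_uint16(bytes, pos)
  elem <- dcm_uint16(bytes, pos + 2L)
  pos <- pos + 4L
  vr <- NA_character_
  if (explicit && group != 0xFFFE) {
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    pos <- pos + 2L
    if (vr %in% DCM_LONG_VRS) {
      len <- dcm_uint32(bytes, pos + 2L)
      pos <- pos + 6L
    } else {
      len <- dcm_uint16(bytes, pos)
      pos <- pos + 2L
    }
  } else {
    len <- dcm_uint32(bytes, pos)
    pos <- pos + 4L
  }
  tag <- sprintf("%04X%04X", group, elem)
  if (len == 4294967295) { # undefined length: sequence (or encapsulated data)
    end <- dcm_skip_undefined(bytes, pos)
    return(list(tag = tag, vr = vr, value = NULL, pos = end))
  }
  value <- NULL
  if (collect && len > 0) {
    if (pos + len - 1L > length(bytes)) {
      stop_quant("DICOM parse error: element ", tag, " overruns file")
    }
    value <- bytes[pos:(pos + len - 1L)]
  }
  list(tag = tag, vr = vr, value = value, pos = pos + len)
}

dcm_string <- function(raw) {
  if (is.null(raw)) return(NULL)
  trimws(rawToChar(raw[raw != as.raw(0)]))
}

dcm_numbers <- function(raw) {
  s <- dcm_string(raw)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

# parse a whole DICOM stream into a tag -> list(vr, value) map
read_dicom_elements <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  explicit <- TRUE
  if (length(bytes) >= 132L && rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
    # file meta group (0002) is always explicit little endian
    meta <- list()
    while (pos + 7L <= length(bytes) && dcm_uint16(bytes, pos) == 0x0002) {
      el <- dcm_read_element(bytes, pos, explicit = TRUE)
      meta[[el$tag]] <- el
      pos <- el$pos
    }
    ts <- dcm_string(meta[["00020010"]]$value)
    if (!is.null(ts)) {
      if (ts == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (ts != "1.2.840.10008.1.2.1") {
        stop_quant("DICOM parse error: unsupported transfer syntax '", ts,
                   "' (only little-endian uncompressed is supported)")
      }
    }
  }
  out <- list()
  while (pos + 7L <= length(bytes)) {
    el <- dcm_read_element(bytes, pos, explicit = explicit)
    out[[el$tag]] <- el
    pos <- el$pos
  }
  out
}

dcm_required <- function(elements, tag, name) {
  el <- elements[[tag]]
  if (is.null(el) || is.null(el$value)) {
    stop_quant("DICOM parse error: missing required field '", name, "' (", tag, ")")
  }
  el
}

# decode the pixel grid(s); returns a list of count matrices (one per frame)
dcm_pixel_frames <- function(elements) {
  rows <- dcm_uint16(dcm_required(elements, "00280010", "Rows")$value, 1L)
  cols <- dcm_uint16(dcm_required(elements, "00280011", "Columns")$value, 1L)
  bits <- dcm_uint16(dcm_required(elements, "00280100", "BitsAllocated")$value, 1L)
  rep_el <- elements[["00280103"]]
  signed <- !is.null(rep_el$value) && dcm_uint16(rep_el$value, 1L) == 1L
  nf_el <- elements[["00280008"]]
  n_frames <- if (is.null(nf_el$value)) 1L else as.integer(dcm_numbers(nf_el$value)[1])
  px <- dcm_required(elements, "7FE00010", "PixelData")$value
  vals <- switch(as.character(bits),
    "16" = readBin(px, "integer", n = length(px) / 2L, size = 2L,
                   signed = signed, endian = "little"),
    "8" = as.integer(px),
    "32" = readBin(px, "integer", n = length(px) / 4L, size = 4L,
                   signed = TRUE, endian = "little"),
    stop_quant("DICOM parse error: unsupported BitsAllocated = ", bits)
  )
  if (bits == 16 && !signed) vals <- ifelse(vals < 0, vals + 65536, vals)
  need <- as.numeric(rows) * cols * n_frames
  if (length(vals) < need) stop_quant("DICOM parse error: PixelData shorter than Rows*Columns*NumberOfFrames")
  lapply(seq_len(n_frames), function(k) {
    frame_vals <- vals[((k - 1L) * rows * cols + 1L):(k * rows * cols)]
    # DICOM pixel order is row-major
    matrix(frame_vals, nrow = rows, ncol = cols, byrow = TRUE)
  })
}

dcm_pixel_spacing <- function(elements) {
  sp <- dcm_numbers(elements[["00280030"]]$value)
  if (is.null(sp) || length(sp) != 2L) c(1, 1) else sp
}

read_dicom_planar <- function(path, view_label = NULL) {
  elements <- read_dicom_elements(path)
  frames <- dcm_pixel_frames(elements)
  if (length(frames) != 1L) {
    stop_quant("DICOM object has ", length(frames),
               " frames; use read_dynamic() for dynamic series")
  }
  dur <- dcm_numbers(elements[["00181242"]]$value) # ActualFrameDuration, ms
  label <- view_label %||% dcm_string(elements[["0008103E"]]$value) %||% "dicom"
  planar_frame(
    counts = frames[[1]],
    pixel_spacing_mm = dcm_pixel_spacing(elements),
    acquisition_start_s = 0,
    duration_s = if (is.null(dur)) 600 else dur[1] / 1000,
    view_label = label
  )
}

read_dicom_dynamic <- function(path, stimulus_time_s = NULL, start_s = 0) {
  elements <- read_dicom_elements(path)
  mats <- dcm_pixel_frames(elements)
  dur <- dcm_numbers(elements[["00181242"]]$value) # ms
  if (is.null(dur)) dur <- dcm_numbers(elements[["00181063"]]$value) # FrameTime
  if (is.null(dur)) stop_quant("DICOM parse error: no frame duration (0018,1242 or 0018,1063)")
  dur_s <- dur[1] / 1000
  spacing <- dcm_pixel_spacing(elements)
  frames <- lapply(seq_along(mats), function(k) {
    planar_frame(mats[[k]], pixel_spacing_mm = spacing,
                 acquisition_start_s = start_s + (k - 1) * dur_s,
                 duration_s = dur_s, view_label = sprintf("frame-%03d", k))
  })
  if (is.null(stimulus_time_s)) {
    stop_quant("stimulus_time_s must be given: DICOM input carries no stimulus annotation")
  }
  dynamic_series(frames, stimulus_time_s = stimulus_time_s)
}
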
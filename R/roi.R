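#' Named polygonal regions of interest
#'
#' An `roi_set` holds named polygon regions in 0-based pixel coordinates
#' (`row`, `col`; pixel centers at integer coordinates), each tagged with a
#' role.  Roles distinguish targets (`joint`, `gland`) from the background
#' references the scoring scale is anchored to: calf muscle for joints
#' (`background_calf`) and the temporal region for sialoscintigraphy
#' (`background_temporal`).
#'
#' @param regions named list; each element a list with `vertices` (an n-by-2
#'   numeric matrix of `(row, col)` vertices, n >= 3, describing a simple
#'   polygon), `role` (one of the four roles above) and optionally
#'   `anatomical_label`.
#' @return An object of class `roi_set`.
#' @examples
#' rs <- roi_set(list(
#'   wrist = list(vertices = rbind(c(2, 2), c(2, 8), c(8, 8), c(8, 2)),
#'                role = "joint"),
#'   calf = list(vertices = rbind(c(20, 2), c(20, 8), c(28, 5)),
#'               role = "background_calf")
#' ))
#' @export
roi_set <- function(regions) {
  if (!is.list(regions) || length(regions) == 0L) {
    stop_quant("regions: must be a non-empty named list")
  }
  ids <- names(regions)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop_quant("regions: region ids must be unique non-empty names")
  }
  regions <- lapply(ids, function(id) validate_region(regions[[id]], id))
  names(regions) <- ids
  roles <- vapply(regions, `[[`, character(1), "role")
  if (any(roles %in% c("joint", "gland")) && !any(startsWith(roles, "background"))) {
    stop_quant("roi_set: target regions present but no background region")
  }
  structure(list(regions = regions), class = "roi_set")
}

ROI_ROLES <- c("joint", "gland", "background_calf", "background_temporal")

validate_region <- function(region, id) {
  v <- region$vertices
  if (is.null(v)) stop_quant("region '", id, "': missing vertices")
  v <- as.matrix(v)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L || nrow(v) < 3L || any(!is.finite(v))) {
    stop_quant("region '", id, "': polygon needs >= 3 finite (row, col) vertices")
  }
  if (!is_simple_polygon(v)) {
    stop_quant("region '", id, "': polygon is degenerate or self-intersecting")
  }
  role <- region$role
  if (is.null(role) || !role %in% ROI_ROLES) {
    stop_quant("region '", id, "': unknown role '", role %||% "<missing>",
               "'; allowed roles: ", paste(ROI_ROLES, collapse = ", "))
  }
  list(
    vertices = v,
    role = role,
    anatomical_label = as.character(region$anatomical_label %||% id)
  )
}

# orientation of ordered point triple; 0 = collinear
orient3 <- function(p, q, r) {
  v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  if (abs(v) < 1e-12) 0 else sign(v)
}

on_segment <- function(p, q, r) {
  min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
    min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
}

segments_cross <- function(a1, a2, b1, b2) {
  o1 <- orient3(a1, a2, b1); o2 <- orient3(a1, a2, b2)
  o3 <- orient3(b1, b2, a1); o4 <- orient3(b1, b2, a2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_segment(a1, a2, b1)) || (o2 == 0 && on_segment(a1, a2, b2)) ||
    (o3 == 0 && on_segment(b1, b2, a1)) || (o4 == 0 && on_segment(b1, b2, a2))
}

# simple-polygon test: non-adjacent edges must not intersect, adjacent edges
# only at their shared vertex, and the polygon must have nonzero area
is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (abs(shoelace_area(v)) < 1e-12) return(FALSE)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(edges[i, ], edges[j, ])) > 0L
      a1 <- v[edges[i, 1], ]; a2 <- v[edges[i, 2], ]
      b1 <- v[edges[j, 1], ]; b2 <- v[edges[j, 2], ]
      if (!shared) {
        if (segments_cross(a1, a2, b1, b2)) return(FALSE)
      } else {
        # adjacent edges: reject overlap beyond the shared vertex
        pts <- rbind(a1, a2, b1, b2)
        shared_pt <- pts[duplicated(pts), , drop = FALSE]
        others <- pts[!duplicated(pts) & !duplicated(pts, fromLast = TRUE), , drop = FALSE]
        if (nrow(shared_pt) >= 1L && nrow(others) == 2L &&
            orient3(shared_pt[1, ], others[1, ], others[2, ]) == 0 &&
            on_segment(shared_pt[1, ], others[1, ], others[2, ])) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

# signed polygon area (shoelace formula), in pixel^2
shoelace_area <- function(v) {
  x <- v[, 2]; y <- v[, 1]
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d regions\n", length(x$regions)))
  for (id in names(x$regions)) {
    r <- x$regions[[id]]
    cat(sprintf("  %-16s %-20s %d vertices (%s)\n", id, r$role, nrow(r$vertices),
                r$anatomical_label))
  }
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$regions)

#' Read a region-of-interest polygon file
#'
#' JSON schema (format tag `"srsquant-roi"`, version 1):
#' ```json
#' {"format": "srsquant-roi", "version": 1,
#'  "regions": {"<id>": {"vertices": [[row, col], ...],
#'                       "role": "joint|gland|background_calf|background_temporal",
#'                       "anatomical_label": "text"}}}
#' ```
#' Vertices are 0-based pixel coordinates.  Polygons must be simple; unknown
#' roles are rejected with the list of allowed roles.
#'
#' @param path JSON file path.
#' @return A validated [roi_set()].
#' @export
read_roiset <- function(path) {
  if (!file.exists(path)) stop_quant("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop_quant("parse error in '", path, "': ", conditionMessage(e))
  )
  if (!identical(doc$format, "srsquant-roi")) {
    stop_quant("parse error in '", path, "': field 'format' is not 'srsquant-roi'")
  }
  if (is.null(doc$regions)) stop_quant("parse error in '", path, "': missing field 'regions'")
  regions <- lapply(doc$regions, function(r) {
    r$vertices <- do.call(rbind, lapply(r$vertices, unlist))
    r
  })
  roi_set(regions)
}

#' Write a region-of-interest set
#' @param rois an [roi_set()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_roiset <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  doc <- list(
    format = "srsquant-roi", version = 1L,
    regions = lapply(rois$regions, function(r) {
      list(vertices = unname(lapply(seq_len(nrow(r$vertices)),
                                    function(i) r$vertices[i, ])),
           role = r$role, anatomical_label = r$anatomical_label)
    })
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
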
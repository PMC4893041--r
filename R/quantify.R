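#' Rasterize a polygon region onto a frame grid
#'
#' A pixel belongs to the mask when its center (0-based integer `(row, col)`
#' coordinate) lies inside or on the boundary of the polygon.  The mask is
#' deterministic and invariant under reversal of the vertex order.
#'
#' @param vertices n-by-2 matrix of `(row, col)` polygon vertices, or a
#'   single region entry from an [roi_set()].
#' @param frame a [planar_frame()] supplying the grid.
#' @param region_id label used in error messages.
#' @return A logical matrix with the frame's dimensions.
#' @export
rasterize <- function(vertices, frame, region_id = "region") {
  stopifnot(inherits(frame, "planar_frame"))
  if (is.list(vertices) && !is.null(vertices$vertices)) {
    vertices <- vertices$vertices
  }
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2L, nrow(v) >= 3L)
  nr <- frame$matrix_size[1]; nc <- frame$matrix_size[2]
  rows <- as.vector(outer(seq_len(nr) - 1, rep(1, nc)))
  cols <- as.vector(outer(rep(1, nr), seq_len(nc) - 1))
  inside <- pracma::inpolygon(cols, rows, v[, 2], v[, 1], boundary = TRUE)
  mask <- matrix(inside, nr, nc)
  if (!any(mask)) {
    stop_quant("region '", region_id, "' rasterizes to an empty mask")
  }
  mask
}

#' Target-to-background uptake per region
#'
#' Computes mean counts per pixel in every target region (roles `joint` and
#' `gland`) and divides by the pooled background mean: background regions of
#' `background_role` are pooled as total counts over total pixels before the
#' ratio is formed.
#'
#' @param frame a [planar_frame()].
#' @param roi_set an [roi_set()] containing at least one region with
#'   `background_role`.
#' @param background_role background role to normalise against.
#' @return A `data.frame` (class `region_uptake`) with columns `region_id`,
#'   `anatomical_label`, `role`, `n_pixels`, `mean_counts_per_px`,
#'   `background_mean` and `tb_ratio`.
#' @examples
#' f <- planar_frame(matrix(10, 32, 32))
#' rs <- roi_set(list(
#'   joint = list(vertices = rbind(c(4, 4), c(4, 10), c(10, 10), c(10, 4)),
#'                role = "joint"),
#'   calf = list(vertices = rbind(c(20, 4), c(20, 12), c(28, 12), c(28, 4)),
#'               role = "background_calf")
#' ))
#' region_uptake(f, rs)$tb_ratio  # uniform frame: exactly 1
#' @export
region_uptake <- function(frame, roi_set, background_role = "background_calf") {
  stopifnot(inherits(frame, "planar_frame"), inherits(roi_set, "roi_set"))
  roles <- vapply(roi_set$regions, `[[`, character(1), "role")
  bg_ids <- names(roles)[roles == background_role]
  if (length(bg_ids) == 0L) {
    stop_quant("no region with role '", background_role, "' in the ROI set")
  }
  bg_counts <- 0; bg_px <- 0L
  for (id in bg_ids) {
    m <- rasterize(roi_set$regions[[id]], frame, id)
    bg_counts <- bg_counts + sum(frame$counts[m])
    bg_px <- bg_px + sum(m)
  }
  bg_mean <- bg_counts / bg_px
  if (bg_mean == 0) {
    stop_quant("background mean is zero; target-to-background ratio undefined")
  }
  target_ids <- names(roles)[roles %in% c("joint", "gland")]
  out <- do.call(rbind, lapply(target_ids, function(id) {
    r <- roi_set$regions[[id]]
    m <- rasterize(r, frame, id)
    mu <- mean(frame$counts[m])
    data.frame(region_id = id, anatomical_label = r$anatomical_label,
               role = r$role, n_pixels = sum(m), mean_counts_per_px = mu,
               background_mean = bg_mean, tb_ratio = mu / bg_mean,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("region_uptake", "data.frame")
  out
}

#' Time-activity curve of a region
#'
#' One sample per frame at the frame midpoint: target mean counts per pixel,
#' background mean counts per pixel, and their ratio.  Counts are not decay
#' corrected.  Frames whose background mean is zero are flagged and their
#' ratio set to `NA` with a warning; flagged frames are excluded from window
#' sums downstream.
#'
#' @param series a [dynamic_series()].
#' @param roi target region (vertices matrix or [roi_set()] region entry).
#' @param background background region.
#' @return A `data.frame` of class `srs_tac` with columns `frame`, `t_mid`,
#'   `target_mean`, `background_mean`, `tb`, `flagged`.
#' @export
time_activity_curve <- function(series, roi, background) {
  stopifnot(inherits(series, "dynamic_series"))
  f1 <- series$frames[[1]]
  tmask <- rasterize(roi, f1, "target")
  bmask <- rasterize(background, f1, "background")
  e <- series$frame_edges_s
  k <- length(series$frames)
  tm <- bm <- numeric(k)
  for (i in seq_len(k)) {
    cnt <- series$frames[[i]]$counts
    tm[i] <- mean(cnt[tmask])
    bm[i] <- mean(cnt[bmask])
  }
  flagged <- bm == 0
  if (any(flagged)) {
    warning(sum(flagged), " frame(s) with zero background counts flagged",
            call. = FALSE)
  }
  out <- data.frame(
    frame = seq_len(k), t_mid = (e[-1] + e[-(k + 1)]) / 2,
    target_mean = tm, background_mean = bm,
    tb = ifelse(flagged, NA_real_, tm / bm), flagged = flagged
  )
  attr(out, "stimulus_time_s") <- series$stimulus_time_s
  class(out) <- c("srs_tac", "data.frame")
  out
}

#' @export
plot.srs_tac <- function(x, ...) {
  graphics::plot(x$t_mid / 60, x$tb, type = "b", xlab = "time (min)",
                 ylab = "target / background", ...)
  stim <- attr(x, "stimulus_time_s")
  if (!is.null(stim)) graphics::abline(v = stim / 60, lty = 2)
  invisible(x)
}

# frames fully inside a half-open window [start, end); edges must tile it
window_frames <- function(series, window) {
  e <- series$frame_edges_s
  tol <- 1e-6
  if (min(abs(e - window[1])) > tol || min(abs(e - window[2])) > tol ||
      window[1] < e[1] - tol || window[2] > e[length(e)] + tol) {
    stop_quant("window [", window[1], ", ", window[2],
               ") s is not tiled exactly by the frame edges")
  }
  which(e[-length(e)] >= window[1] - tol & e[-1] <= window[2] + tol)
}

#' Sialoscintigraphy uptake and functional scores
#'
#' The uptake score of a time window is the target-to-background ratio of
#' summed activity: counts summed over the gland masks and the window's
#' frames, divided by the background counts in the same window scaled to the
#' gland pixel count (i.e. a per-pixel T/B of window sums).  Windows are
#' half-open `[start, end)` in seconds from injection and must be tiled
#' exactly by frame edges.  The functional score is the pre-stimulus uptake
#' score over the post-stimulus one; values above 1 indicate stimulated
#' secretion.
#'
#' Returns one result per gland region plus a combined result summing
#' activity over all gland regions (both parotid glands in the clinical
#' protocol).
#'
#' @param series a [dynamic_series()].
#' @param roi_set an [roi_set()] with regions of `gland_role` and at least
#'   one region of `background_role`.
#' @param pre_window,post_window `(start, end)` windows in seconds; defaults
#'   are minutes 12-16 (pre-stimulus) and 28-32 (post-stimulus).
#' @param background_role,gland_role role tags selecting the regions.
#' @return A `data.frame` of class `sgs_result` with columns `gland_id`,
#'   `uptake_score_pre`, `uptake_score_post`, `functional_score`, `flagged`;
#'   the last row has `gland_id = "combined"`.
#' @export
sgs_scores <- function(series, roi_set, pre_window = c(720, 960),
                       post_window = c(1680, 1920),
                       background_role = "background_temporal",
                       gland_role = "gland") {
  stopifnot(inherits(series, "dynamic_series"), inherits(roi_set, "roi_set"))
  if (pre_window[1] >= pre_window[2] || post_window[1] >= post_window[2]) {
    stop_quant("windows must satisfy start < end")
  }
  if (pre_window[2] > series$stimulus_time_s + 1e-6) {
    stop_quant("pre_window must end at or before the stimulus")
  }
  roles <- vapply(roi_set$regions, `[[`, character(1), "role")
  gland_ids <- names(roles)[roles == gland_role]
  bg_ids <- names(roles)[roles == background_role]
  if (length(gland_ids) == 0L) stop_quant("no region with role '", gland_role, "'")
  if (length(bg_ids) == 0L) stop_quant("no region with role '", background_role, "'")
  f1 <- series$frames[[1]]
  gmasks <- lapply(gland_ids, function(id) rasterize(roi_set$regions[[id]], f1, id))
  names(gmasks) <- gland_ids
  bmask <- Reduce(`|`, lapply(bg_ids, function(id) {
    rasterize(roi_set$regions[[id]], f1, id)
  }))
  idx_pre <- window_frames(series, pre_window)
  idx_post <- window_frames(series, post_window)
  window_sum <- function(mask, idx) {
    tot <- 0
    for (i in idx) tot <- tot + sum(series$frames[[i]]$counts[mask])
    tot
  }
  uptake <- function(mask, idx) {
    bg <- window_sum(bmask, idx)
    if (bg == 0) return(NA_real_)
    # background counts scaled per pixel, then to the gland pixel count
    window_sum(mask, idx) / (bg / sum(bmask) * sum(mask))
  }
  one <- function(id, mask) {
    pre <- uptake(mask, idx_pre)
    post <- uptake(mask, idx_post)
    flagged <- is.na(pre) || is.na(post) || post <= 0
    data.frame(gland_id = id, uptake_score_pre = pre, uptake_score_post = post,
               functional_score = if (flagged) NA_real_ else pre / post,
               flagged = flagged, stringsAsFactors = FALSE)
  }
  combined_mask <- Reduce(`|`, gmasks)
  out <- rbind(
    do.call(rbind, Map(one, gland_ids, gmasks)),
    one("combined", combined_mask)
  )
  if (any(out$flagged)) {
    warning("functional score undefined for: ",
            paste(out$gland_id[out$flagged], collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("sgs_result", "data.frame")
  out
}
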
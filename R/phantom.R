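#' Static phantom specification
#'
#' Describes a synthetic planar acquisition with analytic ground truth:
#' spatially uniform background activity plus circular hotspots at known true
#' target-to-background (T/B) ratios, an isotropic Gaussian point-spread
#' function, and Poisson counting noise.  The expected pixel value is
#' `background_rate * true_tb` inside a hotspot and `background_rate`
#' elsewhere, convolved with the PSF before Poisson sampling (shot noise is
#' detection noise, so it acts after blurring).
#'
#' @param matrix_size integer pair `(rows, cols)`.
#' @param pixel_spacing_mm positive pair, mm per pixel.
#' @param background_rate expected counts per pixel in background tissue over
#'   the acquisition (> 0).
#' @param hotspots list of [hotspot()] descriptions.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels (>= 0).
#' @param seed integer seed; all randomness in [simulate_static()] flows from
#'   it.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(hotspots = list(hotspot(c(32, 32), 10, 1.5, "wrist")))
#' sim <- simulate_static(spec)
#' sim$truth
#' @export
phantom_spec <- function(matrix_size = c(64, 64), pixel_spacing_mm = c(4, 4),
                         background_rate = 1e4, hotspots = list(),
                         psf_sigma_px = 1, seed = 1L) {
  stopifnot(length(matrix_size) == 2L, all(matrix_size >= 4))
  if (!is_number(background_rate) || background_rate <= 0) {
    stop_quant("background_rate: must be > 0")
  }
  if (!is_number(psf_sigma_px) || psf_sigma_px < 0) {
    stop_quant("psf_sigma_px: must be >= 0")
  }
  hotspots <- lapply(hotspots, function(h) {
    stopifnot(inherits(h, "phantom_hotspot"))
    h
  })
  ids <- vapply(hotspots, `[[`, character(1), "anatomical_label")
  if (anyDuplicated(ids)) stop_quant("hotspots: anatomical labels must be unique")
  names(hotspots) <- ids
  structure(
    list(matrix_size = as.integer(matrix_size),
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         background_rate = background_rate, hotspots = hotspots,
         psf_sigma_px = psf_sigma_px, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Circular hotspot description
#'
#' @param center `(row, col)` center in 0-based pixel coordinates.
#' @param radius_px radius in pixels (>= 1).
#' @param true_tb true target-to-background ratio (>= 0).
#' @param anatomical_label unique label, e.g. `"wrist-left"`.
#' @param role `"joint"` or `"gland"`.
#' @return An object of class `phantom_hotspot`.
#' @export
hotspot <- function(center, radius_px, true_tb, anatomical_label,
                    role = c("joint", "gland")) {
  role <- match.arg(role)
  stopifnot(length(center) == 2L, is.finite(center))
  if (!is_number(radius_px) || radius_px < 1) stop_quant("radius_px: must be >= 1")
  if (!is_number(true_tb) || true_tb < 0) stop_quant("true_tb: must be >= 0")
  structure(
    list(center = as.numeric(center), radius_px = radius_px, true_tb = true_tb,
         anatomical_label = as.character(anatomical_label), role = role),
    class = "phantom_hotspot"
  )
}

# pixel-center distance mask of a circular hotspot
hotspot_mask <- function(h, matrix_size) {
  r <- outer(seq_len(matrix_size[1]) - 1, rep(1, matrix_size[2]))
  c_ <- outer(rep(1, matrix_size[1]), seq_len(matrix_size[2]) - 1)
  (r - h$center[1])^2 + (c_ - h$center[2])^2 <= h$radius_px^2
}

# Separable Gaussian blur as a column-normalised linear operator: every source
# pixel redistributes its expected counts with weights that are renormalised
# where the kernel is truncated by the detector edge, so the total expected
# count is conserved exactly.
blur_operator <- function(n, sigma) {
  idx <- seq_len(n)
  m <- outer(idx, idx, function(i, j) stats::dnorm(i - j, sd = sigma))
  sweep(m, 2L, colSums(m), "/")
}

blur_gaussian <- function(mat, sigma) {
  if (sigma == 0) return(mat)
  blur_operator(nrow(mat), sigma) %*% mat %*% t(blur_operator(ncol(mat), sigma))
}

# expected (pre-PSF) rate map of a static phantom, counts/pixel
static_rate_map <- function(spec) {
  rate <- matrix(spec$background_rate, spec$matrix_size[1], spec$matrix_size[2])
  for (h in spec$hotspots) {
    m <- hotspot_mask(h, spec$matrix_size)
    if (!any(m)) {
      stop_quant("hotspot '", h$anatomical_label, "' lies fully outside the image")
    }
    rate[m] <- spec$background_rate * h$true_tb
  }
  rate
}

#' Simulate a static planar acquisition
#'
#' Builds the expected rate map (`background_rate` times `true_tb` inside
#' hotspots, times 1 elsewhere), applies the Gaussian PSF, and draws
#' independent Poisson counts per pixel under the spec's seed.  Repeated calls
#' with the same spec give identical frames.
#'
#' @param spec a [phantom_spec()].
#' @param view_label view label stored on the frame.
#' @return A list with `frame` (a [planar_frame()]), `truth` (named vector of
#'   true T/B per hotspot) and `rate_map` (expected counts/pixel after PSF).
#' @export
simulate_static <- function(spec, view_label = "phantom-static") {
  stopifnot(inherits(spec, "phantom_spec"))
  rate <- blur_gaussian(static_rate_map(spec), spec$psf_sigma_px)
  set.seed(spec$seed)
  counts <- matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
  truth <- vapply(spec$hotspots, `[[`, numeric(1), "true_tb")
  list(
    frame = planar_frame(counts, pixel_spacing_mm = spec$pixel_spacing_mm,
                         acquisition_start_s = 10800, duration_s = 600,
                         view_label = view_label),
    truth = truth,
    rate_map = rate
  )
}

#' Regions of interest matching a phantom
#'
#' Builds a polygon [roi_set()] from a phantom spec: one regular polygon
#' approximating each hotspot circle, plus one rectangular background region
#' placed in an image corner clear of every hotspot (clearance
#' `radius + 4 * psf_sigma` pixels).
#'
#' @param spec a [phantom_spec()].
#' @param background_role role tag for the background region.
#' @param n_vertices vertices of the polygon approximating each circle.
#' @param radius_frac hotspot polygon radius as a fraction of the true radius
#'   (1 = full hotspot).
#' @return An [roi_set()] with one region per hotspot plus `"background"`.
#' @export
phantom_roiset <- function(spec, background_role = "background_calf",
                           n_vertices = 64L, radius_frac = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  regions <- lapply(spec$hotspots, function(h) {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    list(vertices = cbind(h$center[1] + h$radius_px * radius_frac * sin(th),
                          h$center[2] + h$radius_px * radius_frac * cos(th)),
         role = h$role, anatomical_label = h$anatomical_label)
  })
  names(regions) <- vapply(spec$hotspots, `[[`, character(1), "anatomical_label")
  regions$background <- list(vertices = phantom_background_rect(spec),
                             role = background_role,
                             anatomical_label = "background")
  roi_set(regions)
}

phantom_background_rect <- function(spec) {
  nr <- spec$matrix_size[1]; nc <- spec$matrix_size[2]
  h <- max(4, floor(nr * 0.3)); w <- max(4, floor(nc * 0.3))
  corners <- list(c(1, 1), c(1, nc - 2 - w), c(nr - 2 - h, 1),
                  c(nr - 2 - h, nc - 2 - w))
  for (tl in corners) {
    rect <- rbind(tl, tl + c(0, w), tl + c(h, w), tl + c(h, 0))
    clear <- all(vapply(spec$hotspots, function(hs) {
      margin <- hs$radius_px + 4 * spec$psf_sigma_px
      hs$center[1] + margin < tl[1] || hs$center[1] - margin > tl[1] + h ||
        hs$center[2] + margin < tl[2] || hs$center[2] - margin > tl[2] + w
    }, logical(1)))
    if (clear || length(spec$hotspots) == 0L) return(rect)
  }
  stop_quant("no hotspot-free corner available for a background region")
}

# ---------------------------------------------------------------------------
# Dynamic salivary-gland kinetics

#' Salivary-gland kinetic model
#'
#' Piecewise tracer kinetics for a stimulated salivary gland, expressed as an
#' additive excess over a constant background rate.  Before the stimulus the
#' gland excess rises toward a plateau, `g(t) = plateau * (1 - exp(-k_u t))`;
#' after the stimulus at `t_s` it decays exponentially toward a residual
#' level, `g(t) = r * plateau + (g(t_s) - r * plateau) * exp(-k_w (t - t_s))`
#' with residual fraction `r`.  All rates are expected counts per pixel per
#' second.
#'
#' @param plateau_rate gland excess rate at plateau (counts/px/s, >= 0).
#' @param uptake_k_per_s uptake rise constant (1/s, >= 0; `Inf` means
#'   instantaneous rise).
#' @param washout_k_per_s washout decay constant after stimulus (1/s, >= 0;
#'   `Inf` means instantaneous washout).
#' @param residual_fraction fraction of plateau retained after complete
#'   washout, in `[0, 1]`.
#' @param background_rate constant temporal-region background rate
#'   (counts/px/s, > 0).
#' @return An object of class `gland_kinetics`.
#' @export
gland_kinetics <- function(plateau_rate = 2, uptake_k_per_s = 1 / 240,
                           washout_k_per_s = 1 / 120,
                           residual_fraction = 0.3, background_rate = 0.5) {
  stopifnot(plateau_rate >= 0, uptake_k_per_s >= 0, washout_k_per_s >= 0)
  if (!is_number(residual_fraction) || residual_fraction < 0 || residual_fraction > 1) {
    stop_quant("residual_fraction: must lie in [0, 1]")
  }
  if (!is_number(background_rate) || background_rate <= 0) {
    stop_quant("background_rate: must be > 0")
  }
  structure(
    list(plateau_rate = plateau_rate, uptake_k_per_s = uptake_k_per_s,
         washout_k_per_s = washout_k_per_s,
         residual_fraction = residual_fraction,
         background_rate = background_rate),
    class = "gland_kinetics"
  )
}

# gland excess rate g(t), vectorised over t; stimulus at t_s seconds
kinetics_rate <- function(kin, t, t_s) {
  P <- kin$plateau_rate; ku <- kin$uptake_k_per_s
  kw <- kin$washout_k_per_s; R <- kin$residual_fraction * P
  g_ts <- if (is.infinite(ku)) P else P * (1 - exp(-ku * pmax(t_s, 0)))
  pre <- if (is.infinite(ku)) rep(P, length(t)) else P * (1 - exp(-ku * pmax(t, 0)))
  post <- if (is.infinite(kw)) rep(R, length(t)) else {
    R + (g_ts - R) * exp(-kw * pmax(t - t_s, 0))
  }
  ifelse(t < t_s, pre, post)
}

# exact integral of the gland excess rate over [a, b]
kinetics_integral <- function(kin, a, b, t_s) {
  stopifnot(b >= a)
  P <- kin$plateau_rate; ku <- kin$uptake_k_per_s
  kw <- kin$washout_k_per_s; R <- kin$residual_fraction * P
  int_pre <- function(a, b) {
    if (b <= a) return(0)
    if (is.infinite(ku)) return(P * (b - a))
    if (ku == 0) return(0)
    P * ((b - a) + (exp(-ku * b) - exp(-ku * a)) / ku)
  }
  g_ts <- if (is.infinite(ku)) P else if (ku == 0) 0 else P * (1 - exp(-ku * t_s))
  int_post <- function(a, b) {
    if (b <= a) return(0)
    if (is.infinite(kw)) return(R * (b - a))
    if (kw == 0) return(g_ts * (b - a))
    R * (b - a) + (g_ts - R) * (exp(-kw * (a - t_s)) - exp(-kw * (b - t_s))) / kw
  }
  int_pre(a, min(b, t_s)) + int_post(max(a, t_s), b)
}

#' Simulate a dynamic sialoscintigraphy acquisition
#'
#' Gland hotspot pixels follow `background + gland excess` kinetics from
#' `kinetics`; all other pixels carry the constant background rate.  Expected
#' per-frame counts are the exact time integral of the rate over each frame,
#' blurred by the spec's PSF, then Poisson-sampled.  Hotspot `true_tb` values
#' in the spec are ignored in dynamic mode (the kinetics define the gland
#' signal).
#'
#' @param spec a [phantom_spec()] providing geometry (matrix, hotspots with
#'   role `"gland"`, PSF, seed).
#' @param kinetics a [gland_kinetics()].
#' @param total_s acquisition length in seconds (default 32 min).
#' @param frame_s frame duration in seconds; must divide `total_s`.
#' @param stimulus_s stimulus time in seconds (default 16 min).
#' @return A list with `series` (a [dynamic_series()]), `truth` (list with
#'   the kinetics, the per-frame expected gland/background rates and frame
#'   midpoints) — see [analytic_sgs_scores()] for closed-form window scores.
#' @export
simulate_dynamic <- function(spec, kinetics, total_s = 1920, frame_s = 60,
                             stimulus_s = 960) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(kinetics, "gland_kinetics"))
  if (!is_number(frame_s) || frame_s <= 0) stop_quant("frame_s: must be > 0")
  k <- total_s / frame_s
  if (abs(k - round(k)) > 1e-9) stop_quant("total_s must be divisible by frame_s")
  k <- as.integer(round(k))
  if (stimulus_s < 0 || stimulus_s > total_s) {
    stop_quant("stimulus_s: must lie within the acquisition")
  }
  glands <- Filter(function(h) h$role == "gland", spec$hotspots)
  if (length(glands) == 0L) stop_quant("spec has no hotspots with role 'gland'")
  gmask <- Reduce(`|`, lapply(glands, hotspot_mask, matrix_size = spec$matrix_size))
  if (!any(gmask)) stop_quant("gland hotspots lie fully outside the image")
  edges <- seq(0, total_s, by = frame_s)
  set.seed(spec$seed)
  frames <- vector("list", k)
  gland_frame_counts <- numeric(k)
  for (i in seq_len(k)) {
    bg_counts <- kinetics$background_rate * frame_s
    g_counts <- kinetics_integral(kinetics, edges[i], edges[i + 1], stimulus_s)
    gland_frame_counts[i] <- g_counts
    rate <- matrix(bg_counts, spec$matrix_size[1], spec$matrix_size[2])
    rate[gmask] <- rate[gmask] + g_counts
    rate <- blur_gaussian(rate, spec$psf_sigma_px)
    frames[[i]] <- planar_frame(
      matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate)),
      pixel_spacing_mm = spec$pixel_spacing_mm,
      acquisition_start_s = edges[i], duration_s = frame_s,
      view_label = sprintf("frame-%03d", i)
    )
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  list(
    series = dynamic_series(frames, frame_edges_s = edges,
                            stimulus_time_s = stimulus_s),
    truth = list(
      kinetics = kinetics, stimulus_s = stimulus_s, frame_s = frame_s,
      t_mid = mids,
      gland_rate = kinetics$background_rate + kinetics_rate(kinetics, mids, stimulus_s),
      background_rate = rep(kinetics$background_rate, k),
      gland_frame_counts = gland_frame_counts
    )
  )
}

#' Closed-form sialoscintigraphy scores for known kinetics
#'
#' Analytic counterpart of [sgs_scores()]: window uptake score
#' `U(W) = (B |W| + integral of gland excess over W) / (B |W|)` and
#' functional score `U(pre) / U(post)`, computed from the exact rate-function
#' integrals.
#'
#' @param kinetics a [gland_kinetics()].
#' @param stimulus_s stimulus time (s).
#' @param pre_window,post_window numeric `(start, end)` windows in seconds.
#' @return A list with `uptake_score_pre`, `uptake_score_post` and
#'   `functional_score`.
#' @export
analytic_sgs_scores <- function(kinetics, stimulus_s = 960,
                                pre_window = c(720, 960),
                                post_window = c(1680, 1920)) {
  stopifnot(inherits(kinetics, "gland_kinetics"))
  u <- function(w) {
    bg <- kinetics$background_rate * (w[2] - w[1])
    (bg + kinetics_integral(kinetics, w[1], w[2], stimulus_s)) / bg
  }
  pre <- u(pre_window); post <- u(post_window)
  list(uptake_score_pre = pre, uptake_score_post = post,
       functional_score = pre / post)
}

# ---------------------------------------------------------------------------
# Synthetic cohort generator

#' Synthetic cohort specification
#'
#' Parameters for simulating a paired pre/post-therapy cohort of per-joint
#' ordinal scores.  Each joint carries a latent true T/B ratio drawn from
#' `N(tb_mean, tb_sd)` (truncated at 0); the post-therapy latent value adds a
#' treatment effect drawn from `N(effect_mean, effect_sd)` per joint.  Each
#' of two readers scores a T/B perturbed by `N(0, reader_sd)` on the 0-5
#' scale via [score_from_tb()], so generated scores are bounded in `[0, 5]`
#' by construction.  Defaults reflect a treated rheumatoid-arthritis cohort:
#' 11 paired patients, 16 scored joints each, latent T/B around 1.05 with
#' spread 0.25, reader perturbation 0.05, and a mean post-therapy T/B drop of
#' 0.25.
#'
#' @param n_patients number of patients (>= 2).
#' @param n_joints_per_patient scored joints per patient.
#' @param tb_mean,tb_sd latent pre-therapy T/B distribution.
#' @param reader_sd per-reader T/B perturbation SD.
#' @param effect_mean,effect_sd additive treatment-effect distribution on the
#'   latent T/B (negative mean = improvement).
#' @param positivity_threshold positivity threshold passed to
#'   [aggregate_patient()].
#' @param seed integer seed; all randomness in [simulate_cohort()] flows from
#'   it.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 11L, n_joints_per_patient = 16L,
                            tb_mean = 1.05, tb_sd = 0.25, reader_sd = 0.05,
                            effect_mean = -0.25, effect_sd = 0.1,
                            positivity_threshold = 1, seed = 1L) {
  if (!is_count_scalar(n_patients, min = 2)) stop_quant("n_patients: must be >= 2")
  if (!is_count_scalar(n_joints_per_patient, min = 1)) {
    stop_quant("n_joints_per_patient: must be >= 1")
  }
  stopifnot(tb_sd >= 0, reader_sd >= 0, effect_sd >= 0)
  structure(
    list(n_patients = as.integer(n_patients),
         n_joints_per_patient = as.integer(n_joints_per_patient),
         tb_mean = tb_mean, tb_sd = tb_sd, reader_sd = reader_sd,
         effect_mean = effect_mean, effect_sd = effect_sd,
         positivity_threshold = positivity_threshold, seed = as.integer(seed)),
    class = "cohort_sim_spec"
  )
}

#' Simulate a paired pre/post-therapy score cohort
#'
#' @param spec a [cohort_sim_spec()].
#' @return A [score_record_table()] with one `pre` and one `post` row per
#'   patient (`joints_n`, `joints_global`, `joints_severity`), plus an
#'   attribute `"latent"` carrying the per-patient latent T/B matrices.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  nj <- spec$n_joints_per_patient
  rows <- vector("list", 2L * spec$n_patients)
  latent <- vector("list", spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    tb_pre <- pmax(stats::rnorm(nj, spec$tb_mean, spec$tb_sd), 0)
    tb_post <- pmax(tb_pre + stats::rnorm(nj, spec$effect_mean, spec$effect_sd), 0)
    latent[[p]] <- cbind(pre = tb_pre, post = tb_post)
    for (phase in c("pre", "post")) {
      tb <- if (phase == "pre") tb_pre else tb_post
      reader_scores <- vapply(1:2, function(r) {
        score_from_tb(pmax(tb + stats::rnorm(nj, 0, spec$reader_sd), 0))
      }, numeric(nj))
      avg <- rowMeans(matrix(reader_scores, nrow = nj))
      card <- aggregate_patient(joint_scores = avg,
                                positivity_threshold = spec$positivity_threshold,
                                patient_id = p, phase = phase)
      rows[[(p - 1L) * 2L + (phase == "post") + 1L]] <- data.frame(
        patient_id = p, phase = phase,
        joints_n = card$joints$n_positive,
        joints_global = card$joints$global_score,
        joints_severity = card$joints$severity_index
      )
    }
  }
  out <- score_record_table(do.call(rbind, rows))
  attr(out, "latent") <- latent
  out
}
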
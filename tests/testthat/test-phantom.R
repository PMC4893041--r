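test_that("static phantom simulation is deterministic under its seed", {
  spec <- phantom_spec(hotspots = list(hotspot(c(20, 20), 6, 1.4, "wrist")),
                       seed = 31L)
  a <- simulate_static(spec)
  b <- simulate_static(spec)
  expect_identical(a$frame$counts, b$frame$counts)
  expect_equal(a$truth, c(wrist = 1.4))
})

test_that("a unit-ratio hotspot is statistically indistinguishable from background", {
  spec <- phantom_spec(background_rate = 500,
                       hotspots = list(hotspot(c(20, 20), 8, 1.0, "null-spot")),
                       psf_sigma_px = 0, seed = 5L)
  sim <- simulate_static(spec)
  mask <- sim$rate_map * 0
  mask[sqrt(outer((0:63 - 20)^2, rep(1, 64)) +
              outer(rep(1, 64), (0:63 - 20)^2)) <= 8] <- 1
  inside <- sim$frame$counts[mask == 1]
  outside <- sim$frame$counts[mask == 0]
  z <- (mean(inside) - mean(outside)) /
    sqrt(var(inside) / length(inside) + var(outside) / length(outside))
  expect_lt(abs(z), 3)
})

test_that("measured T/B at high counts recovers the truth within Poisson error", {
  # relative half-width sqrt(1/N_t + 1/N_b) is well under 1% at these counts
  for (seed in c(1L, 17L, 303L)) {
    spec <- phantom_spec(matrix_size = c(48, 48), background_rate = 1e4,
                         hotspots = list(hotspot(c(14, 24), 10, 1.5, "wrist")),
                         psf_sigma_px = 0, seed = seed)
    sim <- simulate_static(spec)
    u <- region_uptake(sim$frame, phantom_roiset(spec))
    expect_gte(u$tb_ratio, 1.485)
    expect_lte(u$tb_ratio, 1.515)
  }
})

test_that("the PSF operator conserves expected counts and Poisson totals track the rate map", {
  set.seed(88)
  m <- matrix(rpois(400, 50) + 1, 20, 20)
  blurred <- srsquant:::blur_gaussian(m, 2.5)
  expect_equal(sum(blurred), sum(m), tolerance = 1e-12)
  spec <- phantom_spec(matrix_size = c(48, 48), background_rate = 200,
                       hotspots = list(hotspot(c(20, 20), 8, 1.5, "w")),
                       psf_sigma_px = 1.5, seed = 1L)
  expected <- sum(simulate_static(spec)$rate_map)
  totals <- vapply(1:8, function(s) {
    spec$seed <- s
    total_counts(simulate_static(spec)$frame)
  }, numeric(1))
  # mean of 8 replicates within 4 sigma of the expected total
  expect_lt(abs(mean(totals) - expected), 4 * sqrt(expected / 8))
})

test_that("raising true T/B strictly raises the expected measured ratio", {
  tbs <- c(0.6, 0.9, 1.1, 1.3, 1.5, 1.8)
  measured <- vapply(tbs, function(tb) {
    spec <- phantom_spec(matrix_size = c(48, 48),
                         hotspots = list(hotspot(c(16, 24), 8, tb, "w")),
                         psf_sigma_px = 1, seed = 1L)
    rate <- simulate_static(spec)$rate_map
    mask <- rasterize(phantom_roiset(spec)$regions$w,
                      planar_frame(matrix(0, 48, 48)))
    bgmask <- rasterize(phantom_roiset(spec)$regions$background,
                        planar_frame(matrix(0, 48, 48)))
    mean(rate[mask]) / mean(rate[bgmask])
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("hotspots fully outside the image are rejected", {
  spec <- phantom_spec(hotspots = list(hotspot(c(500, 500), 5, 1.2, "far")))
  expect_error(simulate_static(spec), "outside")
})

test_that("gland kinetics limiting cases give exact functional scores", {
  # time-invariant gland: instantaneous uptake, no washout -> score 1
  flat <- gland_kinetics(plateau_rate = 2, uptake_k_per_s = Inf,
                         washout_k_per_s = 0, residual_fraction = 1,
                         background_rate = 0.5)
  expect_equal(analytic_sgs_scores(flat)$functional_score, 1.0)
  # instantaneous complete washout: post-stimulus T/B is exactly 1 and the
  # functional score equals the pre-stimulus uptake score
  washed <- gland_kinetics(plateau_rate = 2, uptake_k_per_s = Inf,
                           washout_k_per_s = Inf, residual_fraction = 0,
                           background_rate = 0.5)
  a <- analytic_sgs_scores(washed)
  expect_equal(a$uptake_score_post, 1.0)
  expect_equal(a$functional_score, a$uptake_score_pre)
  expect_equal(a$uptake_score_pre, 1 + 2 / 0.5)
})

test_that("kinetics integrals agree with numeric quadrature", {
  kin <- gland_kinetics(plateau_rate = 3, uptake_k_per_s = 1 / 300,
                        washout_k_per_s = 1 / 100, residual_fraction = 0.25,
                        background_rate = 0.4)
  for (w in list(c(0, 500), c(720, 960), c(900, 1100), c(1680, 1920))) {
    num <- stats::integrate(function(t) {
      srsquant:::kinetics_rate(kin, t, t_s = 960)
    }, w[1], w[2], rel.tol = 1e-10)$value
    expect_equal(srsquant:::kinetics_integral(kin, w[1], w[2], t_s = 960),
                 num, tolerance = 1e-8)
  }
})

test_that("simulated dynamic series carry analytic expected curves", {
  spec <- phantom_spec(matrix_size = c(24, 24), psf_sigma_px = 0, seed = 2L,
                       hotspots = list(hotspot(c(8, 8), 4, 1, "parotid-left",
                                               role = "gland")))
  kin <- gland_kinetics(plateau_rate = 4, background_rate = 1)
  sim <- simulate_dynamic(spec, kin, total_s = 1920, frame_s = 120,
                          stimulus_s = 960)
  expect_equal(n_frames(sim$series), 16L)
  expect_equal(sim$series$stimulus_time_s, 960)
  # expected gland curve is monotone rising before the stimulus
  pre <- sim$truth$gland_rate[sim$truth$t_mid < 960]
  expect_true(all(diff(pre) > 0))
  expect_error(simulate_dynamic(spec, kin, total_s = 1900, frame_s = 240),
               "divisible")
  expect_error(simulate_dynamic(spec, kin, frame_s = -1), "> 0")
})

test_that("cohort simulation is reproducible and bounded", {
  spec <- cohort_sim_spec(seed = 9L)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 22L)
  expect_true(all(a$joints_global <= 5 * spec$n_joints_per_patient))
  expect_true(all(is.na(a$joints_severity) |
                    (a$joints_severity >= 0 & a$joints_severity <= 5)))
  expect_error(cohort_sim_spec(n_patients = 1), ">= 2")
})

test_that("a strong simulated treatment effect is detected with high power", {
  rejected <- vapply(1:40, function(r) {
    co <- simulate_cohort(cohort_sim_spec(effect_mean = -0.3, seed = 1000L + r))
    pre <- co[co$phase == "pre", ]
    post <- co[co$phase == "post", ]
    cmp <- paired_t(pre$joints_global, post$joints_global)
    !is.na(cmp$p_value) && cmp$p_value < 0.05 && cmp$mean_post < cmp$mean_pre
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})
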
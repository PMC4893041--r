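test_that("planar frames validate their invariants", {
  expect_error(planar_frame(matrix(-1, 2, 2)), "negative")
  expect_error(planar_frame(matrix(1.5, 2, 2)), "integral")
  expect_error(planar_frame(matrix(1, 2, 2), duration_s = 0), "positive")
  expect_error(planar_frame(matrix(1, 2, 2), pixel_spacing_mm = c(1, -1)),
               "positive")
  f <- planar_frame(matrix(1, 4, 4), pixel_spacing_mm = c(1, 1))
  expect_equal(total_counts(f), 16)
  expect_equal(f$matrix_size, c(4L, 4L))
})

test_that("planar fixture write/read round-trips counts and metadata exactly", {
  set.seed(11)
  counts <- matrix(rpois(64, 40), 8, 8)
  f <- planar_frame(counts, pixel_spacing_mm = c(4.664, 4.664),
                    acquisition_start_s = 10800, duration_s = 600,
                    view_label = "hands-anterior")
  path <- withr::local_tempfile(fileext = ".json")
  write_planar(f, path)
  g <- read_planar(path)
  expect_equal(g$counts, f$counts)
  expect_identical(total_counts(g), total_counts(f))
  expect_equal(g$pixel_spacing_mm, f$pixel_spacing_mm)
  expect_equal(g$duration_s, f$duration_s)
  expect_identical(g$view_label, f$view_label)
})

test_that("malformed planar fixtures fail naming the offending field", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- jsonlite::read_json(write_planar(uniform_frame(4), path))
  doc$duration_s <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_planar(path), "duration_s")
  expect_error(read_planar(tempfile()), "not found")
})

test_that("dynamic series derive edges and enforce frame ordering", {
  frames <- lapply(0:7, function(k) {
    planar_frame(matrix(5, 8, 8), acquisition_start_s = k * 240,
                 duration_s = 240)
  })
  s <- dynamic_series(frames, stimulus_time_s = 960)
  expect_equal(s$frame_edges_s, seq(0, 1920, by = 240))
  # overlapping frames rejected
  bad <- frames
  bad[[3]]$acquisition_start_s <- 300
  expect_error(dynamic_series(bad, stimulus_time_s = 960), "overlapping")
  expect_error(dynamic_series(frames, stimulus_time_s = 5000),
               "within the acquisition")
})

test_that("dynamic fixture round-trips a 32-min series bit-exactly", {
  set.seed(12)
  frames <- lapply(0:31, function(k) {
    planar_frame(matrix(rpois(256, 30), 16, 16),
                 acquisition_start_s = k * 60, duration_s = 60)
  })
  s <- dynamic_series(frames, stimulus_time_s = 960)
  path <- withr::local_tempfile(fileext = ".json")
  write_dynamic(s, path)
  g <- read_dynamic(path)
  expect_equal(g$frame_edges_s, s$frame_edges_s)
  expect_equal(g$stimulus_time_s, 960)
  for (k in seq_along(frames)) {
    expect_equal(g$frames[[k]]$counts, s$frames[[k]]$counts)
  }
})

test_that("a series without stimulus annotation needs the explicit argument", {
  path <- withr::local_tempfile(fileext = ".json")
  s <- noiseless_series(rep(100, 8))
  write_dynamic(s, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$stimulus_time_s <- NULL
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  expect_error(read_dynamic(path), "stimulus")
  g <- read_dynamic(path, stimulus_time_s = 960)
  expect_equal(g$stimulus_time_s, 960)
})

test_that("roiset files validate polygons and roles", {
  path <- withr::local_tempfile(fileext = ".json")
  rs <- roi_set(list(
    tri = list(vertices = rbind(c(1, 1), c(1, 6), c(6, 3)), role = "joint"),
    calf = list(vertices = rect_roi(10, 10, 4, 4), role = "background_calf")
  ))
  write_roiset(rs, path)
  g <- read_roiset(path)
  expect_length(g, 2L)
  expect_equal(g$regions$tri$vertices, rs$regions$tri$vertices)
  # degenerate 2-vertex polygon
  expect_error(roi_set(list(bad = list(vertices = rbind(c(0, 0), c(1, 1)),
                                       role = "joint"))), ">= 3")
  # self-intersecting bow-tie
  expect_error(roi_set(list(bow = list(
    vertices = rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0)), role = "joint"
  ))), "self-intersecting")
  # unknown role lists the allowed roles
  expect_error(roi_set(list(x = list(vertices = rect_roi(0, 0, 2, 2),
                                     role = "lesion"))),
               "background_temporal")
  # targets require a background region
  expect_error(roi_set(list(j = list(vertices = rect_roi(0, 0, 2, 2),
                                     role = "joint"))), "background")
})

test_that("an out-of-bounds polygon fails at rasterization, not at read", {
  rs <- roi_set(list(
    far = list(vertices = rect_roi(100, 100, 5, 5), role = "joint"),
    calf = list(vertices = rect_roi(10, 10, 4, 4), role = "background_calf")
  ))
  expect_error(rasterize(rs$regions$far, uniform_frame(16), "far"),
               "empty mask")
})

test_that("score tables read, validate and round-trip", {
  cohort <- srs_cohort()
  expect_s3_class(cohort, "score_record_table")
  expect_equal(sum(cohort$phase == "pre"), 18L)
  both <- intersect(cohort$patient_id[cohort$phase == "pre"],
                    cohort$patient_id[cohort$phase == "post"])
  expect_length(both, 11L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(cohort, path)
  again <- read_scores(path)
  expect_equal(again$joints_global, cohort$joints_global)
  # empty file is an empty table, not an error
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_equal(nrow(read_scores(empty)), 0L)
  # bounded score columns carry the row index in the error
  bad <- data.frame(patient_id = 1:2, phase = "pre",
                    joints_severity = c(2, 7))
  expect_error(score_record_table(bad), "row 2")
  expect_error(score_record_table(data.frame(patient_id = 1, phase = "mid")),
               "phase")
})

test_that("DICOM planar objects read back the oracle's pixel array", {
  oracle <- write_dicom_oracle(rows = 128, cols = 128, seed = 42)
  expect_true(oracle$ok)
  f <- read_planar(oracle$dcm, dialect = "dicom")
  expect_equal(f$matrix_size, c(128L, 128L))
  ref <- as.matrix(utils::read.table(oracle$tsv))
  dimnames(ref) <- NULL
  expect_true(all(f$counts == ref))
  expect_equal(f$pixel_spacing_mm, c(4.664, 4.664))
  expect_equal(f$duration_s, 600)
})

test_that("multi-frame DICOM objects become dynamic series", {
  oracle <- write_dicom_oracle(rows = 32, cols = 32, n_frames = 4,
                               frame_ms = 240000, seed = 7)
  expect_true(oracle$ok)
  expect_error(read_dynamic(oracle$dcm, dialect = "dicom"), "stimulus")
  s <- read_dynamic(oracle$dcm, dialect = "dicom", stimulus_time_s = 480)
  expect_equal(n_frames(s), 4L)
  expect_equal(s$frame_edges_s, seq(0, 960, by = 240))
  ref <- as.matrix(utils::read.table(oracle$tsv))
  dimnames(ref) <- NULL
  expect_true(all(s$frames[[2]]$counts == ref[33:64, ]))
})
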
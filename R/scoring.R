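#' Ordinal uptake score from a target-to-background ratio
#'
#' The 0-5 visual/semi-quantitative scale used for joints and salivary
#' glands, anchored to the background (calf muscle for joints):
#'
#' | score | T/B            | reading                            |
#' |-------|----------------|------------------------------------|
#' | 0     | `< 0.8`        | no uptake, less than background    |
#' | 1     | `[0.8, 1.0]`   | detectable but below background    |
#' | 2     | `(1.0, 1.2]`   | similar to background              |
#' | 3     | `(1.2, 1.4]`   | slightly higher than background    |
#' | 4     | `(1.4, 1.6]`   | much higher than background        |
#' | 5     | `> 1.6`        | clearly high                       |
#'
#' Interior bin boundaries are upper-inclusive (1.2 scores 2, not 3); 0.8 and
#' 1.6 belong to scores 1 and 4 respectively, consistent with the strict
#' inequalities defining scores 0 and 5.
#'
#' @param tb numeric vector of finite, non-negative T/B ratios.
#' @return Integer scores in `0:5`, same length as `tb`.
#' @examples
#' score_from_tb(c(0.5, 0.8, 1.2, 1.3, 1.7))
#' @export
score_from_tb <- function(tb) {
  if (!is.numeric(tb) || length(tb) == 0L) stop_quant("tb: must be numeric")
  if (any(!is.finite(tb))) stop_quant("tb: non-finite values")
  if (any(tb < 0)) stop_quant("tb: negative values")
  # bins (-Inf, .8) [.8, 1] (1, 1.2] (1.2, 1.4] (1.4, 1.6] (1.6, Inf)
  s <- findInterval(tb, c(0.8, 1.0, 1.2, 1.4, 1.6), left.open = TRUE,
                    rightmost.closed = FALSE)
  # findInterval with left.open makes bins (lo, hi]; 0.8 itself must score 1
  s[tb == 0.8] <- 1L
  as.integer(s)
}

#' Average per-region scores across readers
#'
#' Reader scores for one region (or a regions-by-readers matrix) are averaged
#' arithmetically; half-integer averages are legitimate downstream.  Regions
#' where readers disagree by more than one score point are flagged.
#'
#' @param scores integer scores in `[0, 5]`: a vector (one region, one score
#'   per reader) or a matrix (rows = regions, columns = readers).
#' @return A `data.frame` with columns `avg_score` and `discrepancy` (logical
#'   inter-reader disagreement flag), one row per region.
#' @examples
#' average_readers(c(2, 3))
#' average_readers(rbind(c(0, 5), c(4, 4)))
#' @export
average_readers <- function(scores) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1)
  if (!is.numeric(scores) || ncol(scores) < 1L || nrow(scores) < 1L) {
    stop_quant("scores: need at least one reader score")
  }
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 5)) {
    stop_quant("scores: reader scores must lie in [0, 5]")
  }
  data.frame(
    avg_score = rowMeans(scores),
    discrepancy = apply(scores, 1L, function(r) diff(range(r)) > 1)
  )
}

#' Aggregate region scores into a patient scorecard
#'
#' Per-patient aggregates of reader-averaged region scores:
#' * `n_positive` — regions with average score strictly greater than the
#'   positivity threshold (default 1);
#' * `global_score` — sum of the positive regions' average scores;
#' * `severity_index` — `global_score / n_positive`, undefined (`NA`) when no
#'   region is positive (joints only).
#'
#' Glands are aggregated with the same positivity rule, without a severity
#' index.  Full precision is kept; rounding to one decimal is presentation
#' only (see [format()] methods and the report builders).
#'
#' @param joint_scores numeric vector of reader-averaged joint scores in
#'   `[0, 5]`.
#' @param gland_scores optional numeric vector of gland scores.
#' @param positivity_threshold positivity cut (score strictly greater than
#'   this counts as positive).
#' @param patient_id,phase identifiers carried into the scorecard.
#' @return An object of class `patient_scorecard`: a list with `patient_id`,
#'   `phase`, `joints` (`n_positive`, `global_score`, `severity_index`) and,
#'   when gland scores are given, `glands` (`n_positive`, `global_score`).
#' @examples
#' aggregate_patient(c(4, 2, 0))  # n = 2, global = 6, severity = 3
#' @export
aggregate_patient <- function(joint_scores, gland_scores = NULL,
                              positivity_threshold = 1,
                              patient_id = NA, phase = NA) {
  agg <- function(scores) {
    if (length(scores) == 0L) {
      return(list(n_positive = 0L, global_score = 0, severity_index = NA_real_))
    }
    if (any(!is.finite(scores)) || any(scores < 0 | scores > 5)) {
      stop_quant("scores must lie in [0, 5]")
    }
    pos <- scores[scores > positivity_threshold]
    n <- length(pos)
    g <- sum(pos)
    list(n_positive = n, global_score = g,
         severity_index = if (n > 0) g / n else NA_real_)
  }
  joints <- agg(joint_scores)
  out <- list(patient_id = patient_id, phase = phase, joints = joints)
  if (!is.null(gland_scores)) {
    glands <- agg(gland_scores)
    glands$severity_index <- NULL
    out$glands <- glands
  }
  structure(out, class = "patient_scorecard")
}

#' @export
print.patient_scorecard <- function(x, ...) {
  cat(sprintf("<patient_scorecard> patient %s, phase %s\n",
              as.character(x$patient_id), as.character(x$phase)))
  j <- x$joints
  cat(sprintf("  joints: n = %d, global score = %.1f, severity index = %s\n",
              j$n_positive, j$global_score,
              if (is.na(j$severity_index)) "undefined"
              else sprintf("%.1f", j$severity_index)))
  if (!is.null(x$glands)) {
    cat(sprintf("  glands: n = %d, global score = %.1f\n",
                x$glands$n_positive, x$glands$global_score))
  }
  invisible(x)
}

#' Image-to-scorecard scoring pipeline
#'
#' Deterministic composition of the scoring stages for one patient and one
#' static frame: [region_uptake()] to measure T/B per region, one
#' [score_from_tb()] pass per reader (optionally on a reader-perturbed T/B),
#' [average_readers()] per region, and [aggregate_patient()] split by region
#' role (joints vs glands).  Per-stage intermediates are retained for audit.
#'
#' @param frame a [planar_frame()].
#' @param roi_set an [roi_set()] with target and background regions.
#' @param n_readers number of scoring passes.
#' @param reader_sd SD of the per-reader Gaussian perturbation applied to the
#'   measured T/B before binning (0 = identical deterministic readers).
#' @param background_role background role for T/B normalisation.
#' @param positivity_threshold passed to [aggregate_patient()].
#' @param patient_id,phase identifiers for the scorecard.
#' @param seed seed for reader perturbation (ignored when `reader_sd = 0`).
#' @return A list of class `score_pipeline_result`: `scorecard` (a
#'   [aggregate_patient()] scorecard) and `stages` (`uptake`, `reader_scores`,
#'   `averaged`).
#' @export
score_pipeline <- function(frame, roi_set, n_readers = 2L, reader_sd = 0,
                           background_role = "background_calf",
                           positivity_threshold = 1,
                           patient_id = NA, phase = NA, seed = NULL) {
  uptake <- region_uptake(frame, roi_set, background_role = background_role)
  if (reader_sd > 0 && !is.null(seed)) set.seed(seed)
  reader_scores <- vapply(seq_len(n_readers), function(r) {
    tb <- uptake$tb_ratio
    if (reader_sd > 0) tb <- pmax(tb + stats::rnorm(length(tb), 0, reader_sd), 0)
    score_from_tb(tb)
  }, numeric(nrow(uptake)))
  reader_scores <- matrix(reader_scores, nrow = nrow(uptake),
                          dimnames = list(uptake$region_id,
                                          paste0("reader", seq_len(n_readers))))
  averaged <- average_readers(reader_scores)
  averaged$region_id <- uptake$region_id
  averaged$role <- uptake$role
  scorecard <- aggregate_patient(
    joint_scores = averaged$avg_score[averaged$role == "joint"],
    gland_scores = if (any(averaged$role == "gland")) {
      averaged$avg_score[averaged$role == "gland"]
    },
    positivity_threshold = positivity_threshold,
    patient_id = patient_id, phase = phase
  )
  structure(
    list(scorecard = scorecard,
         stages = list(uptake = uptake, reader_scores = reader_scores,
                       averaged = averaged)),
    class = "score_pipeline_result"
  )
}

#' @export
print.score_pipeline_result <- function(x, ...) {
  print(x$scorecard)
  invisible(x)
}
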
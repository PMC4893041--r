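#' Packaged clinical score tables
#'
#' Per-patient semi-quantitative scintigraphy results of an 18-patient
#' rheumatoid-arthritis / secondary Sjögren's cohort imaged with a
#' radiolabelled somatostatin analogue before and (for 11 patients) after
#' anti-TNF-alpha therapy, shipped as plain CSV under `inst/extdata`:
#'
#' * `pre_therapy` — all 18 patients at baseline: `patient_id`, `age`, `sex`,
#'   joints `joints_n` (positive joints) and `joints_global` (global score),
#'   salivary `glands_n` and `glands_global`.
#' * `joints_pre_post` — the 11 treated patients: joints `n`, global score
#'   and severity index per phase (`pre_*`, `post_*` columns).
#' * `salivary_pre_post` — the same 11 patients: salivary-gland `n`, global
#'   score and the sialoscintigraphy functional score per phase.
#'
#' @return A list of three data frames: `pre_therapy`, `joints_pre_post`,
#'   `salivary_pre_post`.
#' @seealso [srs_cohort()] for the same data reshaped to the
#'   [score_record_table()] contract.
#' @examples
#' tabs <- srs_tables()
#' colMeans(tabs$pre_therapy[c("joints_n", "joints_global")])
#' @export
srs_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "srsquant", mustWork = TRUE)
  list(
    pre_therapy = utils::read.csv(path("srs_table1_pre_therapy.csv"),
                                  stringsAsFactors = FALSE),
    joints_pre_post = utils::read.csv(path("srs_table2_joints_pre_post.csv"),
                                      stringsAsFactors = FALSE),
    salivary_pre_post = utils::read.csv(path("srs_table3_salivary_pre_post.csv"),
                                        stringsAsFactors = FALSE)
  )
}

#' Packaged cohort as a long score table
#'
#' Reshapes the packaged tables (see [srs_tables()]) into one
#' [score_record_table()]: a `pre` row for each of the 18 patients and a
#' `post` row for each of the 11 treated patients, with columns `joints_n`,
#' `joints_global`, `joints_severity`, `glands_n`, `glands_global`,
#' `sgs_functional`.  Severity indices are the table values where printed
#' (one decimal); baseline severity for untreated patients is derived as
#' global score over positive-joint count.
#'
#' @return A [score_record_table()] with 29 rows.
#' @examples
#' rep <- build_report(srs_cohort())
#' rep$n_salivary_positive
#' @export
srs_cohort <- function() {
  tabs <- srs_tables()
  t1 <- tabs$pre_therapy; t2 <- tabs$joints_pre_post; t3 <- tabs$salivary_pre_post
  pre <- data.frame(
    patient_id = t1$patient_id, phase = "pre", age = t1$age, sex = t1$sex,
    joints_n = t1$joints_n, joints_global = t1$joints_global,
    joints_severity = ifelse(t1$joints_n > 0,
                             t1$joints_global / t1$joints_n, NA_real_),
    glands_n = t1$glands_n, glands_global = t1$glands_global,
    sgs_functional = NA_real_, stringsAsFactors = FALSE
  )
  # treated subset: use the published per-phase values (printed precision)
  i <- match(t2$patient_id, pre$patient_id)
  pre$joints_n[i] <- t2$pre_n
  pre$joints_global[i] <- t2$pre_global
  pre$joints_severity[i] <- t2$pre_severity
  j <- match(t3$patient_id, pre$patient_id)
  pre$glands_n[j] <- t3$pre_n
  pre$glands_global[j] <- t3$pre_global
  pre$sgs_functional[j] <- t3$pre_functional
  post <- data.frame(
    patient_id = t2$patient_id, phase = "post",
    age = pre$age[i], sex = pre$sex[i],
    joints_n = t2$post_n, joints_global = t2$post_global,
    joints_severity = t2$post_severity,
    glands_n = t3$post_n[match(t2$patient_id, t3$patient_id)],
    glands_global = t3$post_global[match(t2$patient_id, t3$patient_id)],
    sgs_functional = t3$post_functional[match(t2$patient_id, t3$patient_id)],
    stringsAsFactors = FALSE
  )
  score_record_table(rbind(pre, post))
}
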
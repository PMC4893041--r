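#' Read a per-patient score table
#'
#' Reads a delimited (CSV) table of per-patient semi-quantitative scintigraphy
#' aggregates, one row per patient per phase.  Header contract — required
#' columns: `patient_id`, `phase` (`pre` or `post`); recognised optional
#' columns: `age`, `sex`, `joints_n`, `joints_global`, `joints_severity`,
#' `glands_n`, `glands_global`, `sgs_functional`, plus any number of
#' per-region reader score columns named `score_*` (each in `[0, 5]`).
#'
#' Validation: patient ids unique within a phase, ages positive, counts and
#' global scores non-negative, severity and `score_*` columns within
#' `[0, 5]`.  An empty file yields an empty table, not an error.
#'
#' @param path CSV file path.
#' @return A `score_record_table`: a `data.frame` with the columns above.
#' @seealso [write_scores()], [srs_cohort()]
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_quant("file not found: ", path)
  if (file.size(path) == 0L) {
    return(score_record_table(data.frame(patient_id = character(),
                                         phase = character())))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  score_record_table(df)
}

#' Construct/validate a score record table
#' @param df data frame following the [read_scores()] header contract.
#' @return A validated `score_record_table`.
#' @export
score_record_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("patient_id", "phase")) {
    if (!col %in% names(df)) stop_quant("score table: missing required column '", col, "'")
  }
  if (nrow(df) > 0L) {
    bad <- which(!df$phase %in% c("pre", "post"))
    if (length(bad)) {
      stop_quant("score table row ", bad[1], ": phase must be 'pre' or 'post'")
    }
    dup <- which(duplicated(df[, c("patient_id", "phase")]))
    if (length(dup)) {
      stop_quant("score table row ", dup[1], ": duplicate patient_id within phase")
    }
    if ("age" %in% names(df)) {
      bad <- which(!is.na(df$age) & df$age <= 0)
      if (length(bad)) stop_quant("score table row ", bad[1], ": age must be positive")
    }
    bounded <- c("joints_severity", grep("^score_", names(df), value = TRUE))
    for (col in intersect(bounded, names(df))) {
      bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 5))
      if (length(bad)) {
        stop_quant("score table row ", bad[1], ": column '", col,
                   "' outside [0, 5]")
      }
    }
    nonneg <- c("joints_n", "joints_global", "glands_n", "glands_global",
                "sgs_functional")
    for (col in intersect(nonneg, names(df))) {
      bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
      if (length(bad)) {
        stop_quant("score table row ", bad[1], ": column '", col, "' negative")
      }
    }
  }
  class(df) <- c("score_record_table", "data.frame")
  df
}

#' Write a score record table as CSV
#' @param scores a `score_record_table` (or compatible data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}
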
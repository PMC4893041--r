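#' Column means and SDs of a cohort table
#'
#' Builds the mean / SD summary row of a per-patient table.  SDs use the
#' sample (n - 1) denominator.  `NA` cells are excluded column-wise with a
#' count; non-numeric cells in a requested column are an error naming the
#' location.
#'
#' @param rows data frame of per-patient values.
#' @param columns character vector of columns to summarise; default all
#'   numeric columns except identifiers.
#' @return An object of class `cohort_table`: list with `rows` and `summary`
#'   (data frame with `column`, `n`, `mean`, `sd`).
#' @examples
#' tabs <- srs_tables()
#' summarize_cohort(tabs$pre_therapy,
#'                  columns = c("joints_n", "joints_global"))
#' @export
summarize_cohort <- function(rows, columns = NULL) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 2L)
  if (is.null(columns)) {
    columns <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                       c("patient_id", "age"))
  }
  summ <- do.call(rbind, lapply(columns, function(col) {
    if (!col %in% names(rows)) stop_quant("summarize: no column '", col, "'")
    x <- rows[[col]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(x))))[1]
      stop_quant("summarize: non-numeric cell at column '", col, "', row ",
                 bad %||% 1)
    }
    x <- x[!is.na(x)]
    data.frame(column = col, n = length(x), mean = mean(x), sd = stats::sd(x),
               stringsAsFactors = FALSE)
  }))
  structure(list(rows = rows, summary = summ), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, digits = 1, ...) {
  cat(sprintf("<cohort_table> %d rows\n", nrow(x$rows)))
  s <- x$summary
  s$mean <- round(s$mean, digits)
  s$sd <- round(s$sd, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Paired Student's t test on pre/post values
#'
#' Classical paired t on the per-patient differences with a two-sided p-value
#' from the t distribution on `n_pairs - 1` degrees of freedom.  Pairs with an
#' undefined value on either side are dropped and counted.  Zero variance of
#' the differences yields a degenerate result flagged with `p_value = NA`
#' (except in the exactly-equal case `pre == post`, where `t = 0`, `p = 1`).
#'
#' @param pre,post equal-length numeric vectors, paired by patient.
#' @param metric label carried into the result.
#' @return An object of class `paired_comparison`: list with `metric`,
#'   `n_pairs`, `n_dropped`, `mean_pre`, `mean_post`, `t_statistic`,
#'   `degrees_freedom`, `p_value`, `degenerate`.
#' @examples
#' paired_t(c(5, 7, 9, 4), c(3, 6, 5, 4))
#' @export
paired_t <- function(pre, post, metric = "metric") {
  if (length(pre) != length(post)) stop_quant("pre and post must have equal length")
  keep <- is.finite(pre) & is.finite(post)
  n_dropped <- sum(!keep)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 2L) stop_quant("paired_t: need at least 2 complete pairs")
  d <- pre - post
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    degenerate <- TRUE
    if (all(d == 0)) {
      t_stat <- 0; p <- 1; degenerate <- FALSE
    } else {
      t_stat <- NA_real_; p <- NA_real_
    }
  } else {
    degenerate <- FALSE
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(
    list(metric = metric, n_pairs = n, n_dropped = n_dropped,
         mean_pre = mean(pre), mean_post = mean(post), t_statistic = t_stat,
         degrees_freedom = n - 1L, p_value = p, degenerate = degenerate),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> %s: n = %d%s, mean %.2f -> %.2f, t(%d) = %s, p = %s%s\n",
    x$metric, x$n_pairs,
    if (x$n_dropped > 0) sprintf(" (%d pair(s) dropped)", x$n_dropped) else "",
    x$mean_pre, x$mean_post, x$degrees_freedom,
    if (is.na(x$t_statistic)) "NA" else sprintf("%.3f", x$t_statistic),
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
    if (x$degenerate) " [degenerate: zero variance]" else ""
  ))
  invisible(x)
}

#' Unpaired Student's t test between two groups
#'
#' Pooled-variance Student's t by default; Welch's unequal-variance variant
#' optional.  Zero pooled variance yields a degenerate flagged result
#' (`t = 0`, `p = 1` when the group means are also equal).
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param variant `"pooled"` (classical) or `"welch"`.
#' @return A list of class `unpaired_comparison` with `t_statistic`,
#'   `degrees_freedom`, `p_value`, `mean_a`, `mean_b`, `variant`,
#'   `degenerate`.
#' @export
unpaired_t <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_quant("unpaired_t: each group needs at least 2 values")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    equal <- mean(group_a) == mean(group_b)
    return(structure(
      list(t_statistic = if (equal) 0 else NA_real_,
           degrees_freedom = length(group_a) + length(group_b) - 2L,
           p_value = if (equal) 1 else NA_real_,
           mean_a = mean(group_a), mean_b = mean(group_b),
           variant = variant, degenerate = TRUE),
      class = "unpaired_comparison"
    ))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = (variant == "pooled"))
  structure(
    list(t_statistic = unname(ht$statistic),
         degrees_freedom = unname(ht$parameter),
         p_value = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
         variant = variant, degenerate = FALSE),
    class = "unpaired_comparison"
  )
}

#' @export
print.unpaired_comparison <- function(x, ...) {
  cat(sprintf("<unpaired_comparison> (%s) mean %.2f vs %.2f, t(%.1f) = %.3f, p = %s%s\n",
              x$variant, x$mean_a, x$mean_b, x$degrees_freedom,
              x$t_statistic, format.pval(x$p_value, digits = 3),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Ordinary least-squares regression between two parameters
#'
#' Simple linear regression `y = intercept + slope * x` with Pearson
#' correlation and the two-sided p-value for the slope.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return A list of class `srs_regression`: `slope`, `intercept`, `r`,
#'   `r_squared`, `p_value`, `n`.
#' @export
regress <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 3L) {
    stop_quant("regress: need >= 3 complete (x, y) pairs")
  }
  if (stats::sd(x) == 0) stop_quant("regress: zero variance in x")
  fit <- stats::lm(y ~ x)
  # summary() warns on exact fits; the estimates are still what we report
  co <- suppressWarnings(summary(fit))$coefficients
  r <- stats::cor(x, y)
  structure(
    list(slope = unname(co["x", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         r = r, r_squared = r^2,
         p_value = if (nrow(co) > 1) unname(co["x", "Pr(>|t|)"]) else NA_real_,
         n = length(x)),
    class = "srs_regression"
  )
}

#' @export
print.srs_regression <- function(x, ...) {
  cat(sprintf("<regression> y = %.4g + %.4g x, r^2 = %.3f, p(slope) = %s, n = %d\n",
              x$intercept, x$slope, x$r_squared,
              format.pval(x$p_value, digits = 3), x$n))
  invisible(x)
}

#' Build the cohort report
#'
#' Reconstructs the three clinical summary tables and the pre/post paired
#' comparisons from a per-patient score table (see [read_scores()] for the
#' column contract and [srs_cohort()] for the packaged cohort):
#'
#' * pre-therapy table — joints and salivary-gland aggregates of every
#'   patient with a `pre` row, with mean/SD summary;
#' * joints pre/post table — patients with both phases, joints `n`, global
#'   score, severity index;
#' * salivary pre/post table — same patients, gland `n`, global score and
#'   sialoscintigraphy functional score;
#' * paired comparisons (joints n / global / severity; glands global; SGS
#'   functional).  Patients with an undefined severity index are dropped
#'   pairwise from the severity comparison; the dropped count is reported.
#'
#' When some patients lack a `post` row, the paired tables are restricted to
#' the paired subset with a notice.
#'
#' @param cohort a [score_record_table()] (or compatible data frame) with
#'   `pre` and `post` rows.
#' @return An object of class `srs_report`: list with `pre_therapy` (a
#'   [summarize_cohort()] table), `joints_pre_post`, `salivary_pre_post`,
#'   `comparisons` (named list of [paired_t()] results),
#'   `n_salivary_positive`, `n_patients_pre`, `n_paired`.
#' @seealso [write_report()]
#' @export
build_report <- function(cohort) {
  cohort <- score_record_table(as.data.frame(cohort))
  pre <- cohort[cohort$phase == "pre", , drop = FALSE]
  post <- cohort[cohort$phase == "post", , drop = FALSE]
  if (nrow(pre) < 2L) stop_quant("build_report: need >= 2 pre-therapy rows")
  paired_ids <- intersect(pre$patient_id, post$patient_id)
  if (length(paired_ids) < nrow(pre)) {
    message("paired tables restricted to ", length(paired_ids), " of ",
            nrow(pre), " patients with both phases")
  }
  has <- function(col) col %in% names(cohort)
  joint_cols <- intersect(c("joints_n", "joints_global", "joints_severity"),
                          names(cohort))
  gland_cols <- intersect(c("glands_n", "glands_global", "sgs_functional"),
                          names(cohort))
  pre_tab <- summarize_cohort(pre, columns = c(joint_cols, gland_cols))
  prep <- pre[match(paired_ids, pre$patient_id), , drop = FALSE]
  postp <- post[match(paired_ids, post$patient_id), , drop = FALSE]
  pair_tab <- function(cols) {
    if (length(paired_ids) < 2L || length(cols) == 0L) return(NULL)
    wide <- data.frame(patient_id = paired_ids)
    for (col in cols) {
      wide[[paste0("pre_", col)]] <- prep[[col]]
      wide[[paste0("post_", col)]] <- postp[[col]]
    }
    summarize_cohort(wide, columns = setdiff(names(wide), "patient_id"))
  }
  comparisons <- list()
  if (length(paired_ids) >= 2L) {
    for (col in c(joint_cols, gland_cols)) {
      comparisons[[col]] <- paired_t(prep[[col]], postp[[col]], metric = col)
    }
  }
  structure(
    list(
      pre_therapy = pre_tab,
      joints_pre_post = pair_tab(joint_cols),
      salivary_pre_post = pair_tab(gland_cols),
      comparisons = comparisons,
      n_salivary_positive = if (has("glands_n")) {
        sum(pre$glands_n > 0, na.rm = TRUE)
      } else NA_integer_,
      n_patients_pre = nrow(pre),
      n_paired = length(paired_ids)
    ),
    class = "srs_report"
  )
}

#' @export
print.srs_report <- function(x, ...) {
  cat(sprintf("<srs_report> %d patients pre-therapy, %d paired\n",
              x$n_patients_pre, x$n_paired))
  if (!is.na(x$n_salivary_positive)) {
    cat(sprintf("  patients with >= 1 positive salivary gland: %d of %d\n",
                x$n_salivary_positive, x$n_patients_pre))
  }
  cat("\nPre-therapy summary:\n")
  print(x$pre_therapy)
  cat("\nPaired comparisons:\n")
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits the report tables as CSV (per-patient rows with a mean/SD summary
#' row appended, values rounded to one decimal for presentation) plus a
#' human-readable Markdown summary.
#'
#' @param report an [build_report()] result.
#' @param dir output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "srs_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(tab, name) {
    if (is.null(tab)) return()
    rows <- tab$rows
    num <- vapply(rows, is.numeric, logical(1))
    rows[num] <- lapply(rows[num], round1)
    summary_row <- rows[1, , drop = FALSE]
    summary_row[] <- NA
    sd_row <- summary_row
    summary_row[[1]] <- "Mean"; sd_row[[1]] <- "SD"
    for (i in seq_len(nrow(tab$summary))) {
      col <- tab$summary$column[i]
      summary_row[[col]] <- round1(tab$summary$mean[i])
      sd_row[[col]] <- round1(tab$summary$sd[i])
    }
    out <- rbind(rows, summary_row, sd_row)
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(out, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  emit(report$pre_therapy, "pre_therapy")
  emit(report$joints_pre_post, "joints_pre_post")
  emit(report$salivary_pre_post, "salivary_pre_post")
  md <- file.path(dir, "report.md")
  lines <- c(
    "# Scintigraphy cohort report", "",
    sprintf("- patients with pre-therapy data: %d", report$n_patients_pre),
    sprintf("- paired pre/post patients: %d", report$n_paired),
    if (!is.na(report$n_salivary_positive)) {
      sprintf("- patients with >= 1 positive salivary gland: %d of %d",
              report$n_salivary_positive, report$n_patients_pre)
    },
    "", "## Paired comparisons (pre vs post therapy)", "",
    "| metric | n | mean pre | mean post | t | df | p (two-sided) |",
    "|---|---|---|---|---|---|---|",
    vapply(report$comparisons, function(cmp) {
      sprintf("| %s | %d | %.2f | %.2f | %s | %d | %s |",
              cmp$metric, cmp$n_pairs, cmp$mean_pre, cmp$mean_post,
              if (is.na(cmp$t_statistic)) "NA" else sprintf("%.3f", cmp$t_statistic),
              cmp$degrees_freedom,
              if (is.na(cmp$p_value)) "NA" else format.pval(cmp$p_value, digits = 3))
    }, character(1))
  )
  writeLines(lines, md)
  invisible(c(paths, md))
}
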
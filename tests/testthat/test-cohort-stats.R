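test_that("cohort summaries reproduce the packaged baseline table", {
  tabs <- srs_tables()
  s <- summarize_cohort(tabs$pre_therapy,
                        columns = c("joints_n", "joints_global",
                                    "glands_n", "glands_global"))
  get <- function(col, what) s$summary[[what]][s$summary$column == col]
  expect_equal(get("joints_n", "mean"), 8.5)
  expect_equal(round(get("joints_global", "mean"), 1), 17.0)
  expect_equal(round(get("glands_n", "mean"), 1), 1.2)
  expect_equal(round(get("glands_global", "mean"), 1), 1.9)
  expect_equal(get("joints_n", "n"), 18L)
  # sample SD (n-1): check one column against the direct formula
  x <- tabs$pre_therapy$joints_n
  expect_equal(get("joints_n", "sd"),
               sqrt(sum((x - mean(x))^2) / (length(x) - 1)), tolerance = 1e-12)
  # invariant to row order
  s2 <- summarize_cohort(tabs$pre_therapy[sample(18), ],
                         columns = c("joints_n", "joints_global"))
  expect_equal(s2$summary$mean[1], 8.5)
  # degenerate and malformed inputs
  expect_equal(summarize_cohort(data.frame(x = rep(3, 4)))$summary$sd, 0)
  expect_error(summarize_cohort(data.frame(x = c("a", "b", "c")), columns = "x"),
               "non-numeric")
})

test_that("paired t matches the closed-form oracle and its symmetries", {
  pre <- c(13, 5, 2, 1, 7, 10, 4, 4, 10, 12, 8)
  post <- c(6, 4, 2, 1, 3, 6, 3, 2, 7, 5, 2)
  cmp <- paired_t(pre, post, metric = "joints_n")
  d <- pre - post
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(t_oracle), df = length(d) - 1)
  expect_equal(cmp$t_statistic, t_oracle, tolerance = 1e-10)
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(cmp$degrees_freedom, 10L)
  # antisymmetry: swapping pre/post negates t, keeps p
  rev <- paired_t(post, pre)
  expect_equal(rev$t_statistic, -cmp$t_statistic, tolerance = 1e-12)
  expect_equal(rev$p_value, cmp$p_value, tolerance = 1e-12)
  # pre == post: t = 0, p = 1
  eq <- paired_t(pre, pre)
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_false(eq$degenerate)
  # constant nonzero difference: degenerate, no p
  deg <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  # undefined pairs dropped with a count
  na <- paired_t(c(pre, NA), c(post, 3))
  expect_equal(na$n_pairs, 11L)
  expect_equal(na$n_dropped, 1L)
})

test_that("paired-t p-values are uniform under the null", {
  set.seed(2024)
  pvals <- replicate(1000, {
    x <- rnorm(11); y <- x + rnorm(11)
    paired_t(x, y)$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("unpaired t covers pooled and Welch variants against oracles", {
  a <- c(5.1, 4.8, 6.0, 5.5, 4.9)
  b <- c(4.0, 4.4, 3.8, 4.9)
  cmp <- unpaired_t(a, b)
  # pooled-variance closed form
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(cmp$t_statistic, t_oracle, tolerance = 1e-10)
  expect_equal(cmp$p_value,
               2 * pt(-abs(t_oracle), df = length(a) + length(b) - 2),
               tolerance = 1e-10)
  # swapped groups negate t, keep p
  sw <- unpaired_t(b, a)
  expect_equal(sw$t_statistic, -cmp$t_statistic, tolerance = 1e-12)
  expect_equal(sw$p_value, cmp$p_value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  idn <- unpaired_t(a, a)
  expect_equal(idn$t_statistic, 0, tolerance = 1e-12)
  expect_equal(idn$p_value, 1, tolerance = 1e-12)
  # Welch differs from pooled when variances differ
  w <- unpaired_t(a, c(b, 12), variant = "welch")
  expect_lt(w$degrees_freedom, length(a) + length(b) + 1 - 2)
  # constant groups flag degeneracy
  expect_true(unpaired_t(c(2, 2), c(2, 2))$degenerate)
})

test_that("regression recovers exact and noisy relationships", {
  x <- c(1, 2, 3, 4, 5)
  fit <- regress(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(regress(x, x)$r, 1, tolerance = 1e-12)
  # normal-equations oracle on noisy data
  set.seed(3)
  xn <- rnorm(20); yn <- 0.7 * xn - 0.2 + rnorm(20, 0, 0.5)
  fitn <- regress(xn, yn)
  beta <- solve(crossprod(cbind(1, xn)), crossprod(cbind(1, xn), yn))
  expect_equal(fitn$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fitn$slope, beta[2], tolerance = 1e-10)
  expect_error(regress(rep(2, 5), rnorm(5)), "zero variance")
  expect_error(regress(1:2, 1:2), ">= 3")
})

test_that("the cohort report reproduces the published summary values", {
  expect_message(rep <- build_report(srs_cohort()), "11 of 18")
  expect_equal(rep$n_patients_pre, 18L)
  expect_equal(rep$n_paired, 11L)
  expect_equal(rep$n_salivary_positive, 12L)
  jt <- rep$joints_pre_post$summary
  val <- function(tab, col) round(tab$mean[tab$column == col], 1)
  expect_equal(val(jt, "pre_joints_n"), 6.9)
  expect_equal(val(jt, "post_joints_n"), 3.7)
  expect_equal(val(jt, "pre_joints_global"), 12.6)
  expect_equal(val(jt, "post_joints_global"), 5.2)
  expect_equal(val(jt, "pre_joints_severity"), 1.9)
  expect_equal(val(jt, "post_joints_severity"), 1.4)
  sal <- rep$salivary_pre_post$summary
  expect_equal(round(sal$mean[sal$column == "pre_glands_global"], 2), 1.73)
  expect_equal(round(sal$mean[sal$column == "post_glands_global"], 2), 1.18)
  expect_equal(round(sal$mean[sal$column == "pre_sgs_functional"], 2), 5.96)
  expect_equal(round(sal$mean[sal$column == "post_sgs_functional"], 2), 6.23)
  # joints improve significantly; salivary metrics do not
  expect_lt(rep$comparisons$joints_global$p_value, 0.05)
  expect_gt(rep$comparisons$glands_global$p_value, 0.05)
  expect_gt(rep$comparisons$sgs_functional$p_value, 0.05)
})

test_that("undefined severity pairs are dropped pairwise with a count", {
  co <- rbind(
    data.frame(patient_id = 1:4, phase = "pre",
               joints_n = c(3, 0, 5, 2), joints_global = c(6, 0, 9, 4),
               joints_severity = c(2, NA, 1.8, 2)),
    data.frame(patient_id = 1:4, phase = "post",
               joints_n = c(1, 0, 2, 1), joints_global = c(2, 0, 3, 1.5),
               joints_severity = c(2, NA, 1.5, 1.5))
  )
  rep <- build_report(score_record_table(co))
  expect_equal(rep$comparisons$joints_severity$n_pairs, 3L)
  expect_equal(rep$comparisons$joints_severity$n_dropped, 1L)
  expect_equal(rep$comparisons$joints_n$n_pairs, 4L)
})

test_that("report files are written with summary rows", {
  dir <- withr::local_tempdir()
  rep <- suppressMessages(build_report(srs_cohort()))
  paths <- write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "pre_therapy.csv")))
  expect_true(file.exists(file.path(dir, "report.md")))
  tab <- read.csv(file.path(dir, "pre_therapy.csv"))
  expect_equal(tail(tab$patient_id, 2), c("Mean", "SD"))
  expect_equal(as.numeric(tail(tab$joints_n, 2)[1]), 8.5)
})
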
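#' Wilcoxon rank-sum comparison of per-patient utilisation counts
#'
#' Two-sided rank-sum test between arms. Small untied samples (both n <= 20)
#' use exact enumeration; otherwise the tie-corrected normal approximation
#' with continuity correction is used (utilisation counts are heavily tied).
#'
#' @param x,y per-patient counts in the two arms (nonempty numeric).
#' @return object of class `comparison_result` with `statistic` (the
#'   rank-sum W), `p_value`, `test_name` and per-group summaries.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  exact <- length(x) <= 20 && length(y) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  comparison_result(
    statistic = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    test_name = if (exact) "wilcoxon_rank_sum_exact"
                else "wilcoxon_rank_sum_normal_approx",
    x = x, y = y
  )
}

#' Two-sample test of the diagnosis-rate difference
#'
#' Two-sample t-test on the binary diagnosis indicator (Welch), with the
#' pooled two-proportion z statistic reported as a cross-check. Degenerate
#' zero-variance inputs are handled explicitly: identical proportions give
#' statistic 0 / p = 1, complete separation gives an infinite statistic and
#' p = 0.
#'
#' @param dx_a,n_a diagnoses and patients in arm A (0 <= dx <= n, n > 0).
#' @param dx_b,n_b diagnoses and patients in arm B.
#' @return `comparison_result` with fields `statistic` (t), `p_value`,
#'   `z_statistic` and `z_p_value`.
#' @examples
#' diagnosis_rate_test(230, 403, 193, 399)
#' @export
diagnosis_rate_test <- function(dx_a, n_a, dx_b, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("group sizes must be positive",
                                 call. = FALSE)
  if (dx_a < 0 || dx_a > n_a || dx_b < 0 || dx_b > n_b) {
    stop("diagnosis counts must lie in [0, n]", call. = FALSE)
  }
  p_a <- dx_a / n_a
  p_b <- dx_b / n_b
  # Welch t on the 0/1 indicator (sample variances with n-1 denominators)
  v_a <- if (n_a > 1) p_a * (1 - p_a) * n_a / (n_a - 1) else 0
  v_b <- if (n_b > 1) p_b * (1 - p_b) * n_b / (n_b - 1) else 0
  se <- sqrt(v_a / n_a + v_b / n_b)
  if (se > 0) {
    t_stat <- (p_a - p_b) / se
    df <- (v_a / n_a + v_b / n_b)^2 /
      ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1))
    p_t <- 2 * stats::pt(-abs(t_stat), df)
  } else if (p_a == p_b) {
    t_stat <- 0; p_t <- 1
  } else {
    t_stat <- sign(p_a - p_b) * Inf; p_t <- 0
  }
  # pooled two-proportion z cross-check
  pp <- (dx_a + dx_b) / (n_a + n_b)
  se_z <- sqrt(pp * (1 - pp) * (1 / n_a + 1 / n_b))
  if (se_z > 0) {
    z <- (p_a - p_b) / se_z
    p_z <- 2 * stats::pnorm(-abs(z))
  } else {
    z <- 0; p_z <- 1
  }
  res <- comparison_result(
    statistic = t_stat, p_value = p_t,
    test_name = "two_sample_t_binary_indicator",
    x = c(rep(1, dx_a), rep(0, n_a - dx_a)),
    y = c(rep(1, dx_b), rep(0, n_b - dx_b))
  )
  res$z_statistic <- z
  res$z_p_value <- p_z
  res
}

comparison_result <- function(statistic, p_value, test_name, x, y) {
  structure(
    list(
      statistic = statistic,
      p_value = p_value,
      test_name = test_name,
      group_summaries = data.frame(
        group = c("a", "b"),
        n = c(length(x), length(y)),
        mean = c(mean(x), mean(y)),
        median = c(stats::median(x), stats::median(y))
      )
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  print(x$group_summaries, row.names = FALSE)
  invisible(x)
}

#' Per-category between-arm utilisation comparisons
#'
#' Builds per-patient annual event counts per category (zero for patients
#' with no events in that category) and rank-sum tests imaging vs standard
#' of care. Categories with zero events in both arms are skipped.
#'
#' @param events event table.
#' @param cohort cohort table (supplies each patient's arm).
#' @return data.frame: one row per category with group sizes, means and the
#'   rank-sum statistic and p-value.
#' @export
compare_utilisation <- function(events, cohort) {
  out <- list()
  for (cat_i in hcru_categories) {
    ev <- events[events$category == cat_i, ]
    counts <- stats::setNames(rep(0, nrow(cohort)), cohort$patient_id)
    if (nrow(ev)) {
      tot <- tapply(ev$count, ev$patient_id, sum)
      counts[names(tot)] <- tot
    }
    x <- counts[cohort$arm == "imaging"]
    y <- counts[cohort$arm == "soc"]
    if (sum(x) + sum(y) == 0) next
    res <- rank_sum_test(x, y)
    out[[cat_i]] <- data.frame(
      category = cat_i,
      n_imaging = length(x), n_soc = length(y),
      total_imaging = sum(x), total_soc = sum(y),
      mean_imaging = mean(x), mean_soc = mean(y),
      statistic = res$statistic, p_value = res$p_value
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
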
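#' Aggregate per-sample association scores into a cohort summary
#'
#' Computes the quantities reported per cohort: mean normalized association
#' score, sample standard deviation (divisor `n - 1`; the error bars), and
#' the t-based symmetric 95% confidence interval for the mean,
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)` — the standard interval for the
#' small per-group sample counts (4–9) typical of imaging cohorts. The
#' cohort-level call is `association` if the CI lies entirely above 0,
#' `repulsion` if entirely below, otherwise `none`.
#'
#' @param scores numeric vector of per-sample association scores (each from
#'   [analyze_sample()]); must be finite and computed in a single analysis
#'   mode (never pool point, region and self scores).
#' @param group_label cohort name (e.g. `"FASST"`, `"aged 63-73"`).
#' @return An object of class `group_summary`.
#' @export
summarize_group <- function(scores, group_label = NA_character_) {
  scores <- as.numeric(scores)
  if (!length(scores))
    stop_nncoloc("nncoloc_schema", "summarize_group() needs >= 1 score")
  if (!all(is.finite(scores)))
    stop_nncoloc("nncoloc_schema", "non-finite score present")
  n <- length(scores)
  m <- mean(scores)
  s <- if (n >= 2L) stats::sd(scores) else NA_real_
  ci <- if (n >= 2L) {
    half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
    c(m - half, m + half)
  } else c(NA_real_, NA_real_)
  call <- if (n >= 2L && !anyNA(ci)) {
    if (ci[1] > 0) "association" else if (ci[2] < 0) "repulsion" else "none"
  } else "none"
  structure(list(group_label = group_label, scores = scores, n_samples = n,
                 mean_score = m, sd_score = s, ci95 = ci,
                 association_call = call),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Cohort '%s': n = %d samples\n", x$group_label, x$n_samples))
  cat(sprintf("  mean association score %.3f, sd %.3f\n",
              x$mean_score, x$sd_score))
  if (!anyNA(x$ci95))
    cat(sprintf("  95%% CI (%.3f, %.3f) -> %s\n",
                x$ci95[1], x$ci95[2], x$association_call))
  invisible(x)
}

#' Compare two cohorts' association scores
#'
#' Welch two-sample t-test on the per-sample score vectors. Reported
#' alongside — never instead of — the per-group confidence intervals.
#'
#' @param a,b `group_summary` objects with at least 2 samples each.
#' @return `list(mean_difference, t_statistic, df, p_value)` where
#'   `mean_difference = mean(a) - mean(b)`.
#' @export
compare_groups <- function(a, b) {
  if (!inherits(a, "group_summary") || !inherits(b, "group_summary"))
    stop_nncoloc("nncoloc_schema", "compare_groups() needs group_summary objects")
  if (a$n_samples < 2L || b$n_samples < 2L)
    stop_nncoloc("nncoloc_schema", "each group needs >= 2 samples")
  if (stats::sd(a$scores) == 0 && stats::sd(b$scores) == 0 &&
      a$mean_score == b$mean_score)
    return(list(mean_difference = 0, t_statistic = 0,
                df = a$n_samples + b$n_samples - 2, p_value = 1))
  tt <- stats::t.test(a$scores, b$scores, var.equal = FALSE)
  list(mean_difference = a$mean_score - b$mean_score,
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
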
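#' One-tailed Wilcoxon rank-sum test
#'
#' Tests whether `x` tends to be larger than `y` (alternative
#' `"x_greater"`). With a combined sample size of at most 20 and no ties the
#' one-tailed p-value is exact: every one of the `choose(nx+ny, nx)` rank
#' assignments is enumerated and the proportion with a rank sum at least the
#' observed one is reported. Otherwise midranks with a tie-corrected,
#' continuity-corrected normal approximation are used; the `method` field
#' records which path was taken.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative Only `"x_greater"` is offered (the directional
#'   hypothesis of the group comparison).
#' @param exact_max Largest combined n for the exact path (default 20).
#' @return List of class `rank_sum_result`: `rank_sum_W` (sum of x ranks),
#'   `p_one_tailed`, `method` (`"exact"` or `"normal_approx"`), `n_x`, `n_y`.
#' @export
wilcoxon_rank_sum_one_tailed <- function(x, y, alternative = "x_greater",
                                         exact_max = 20L) {
  alternative <- match.arg(alternative, "x_greater")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  comb <- c(x, y)
  has_ties <- anyDuplicated(comb) > 0L
  rk <- rank(comb)                               # midranks under ties
  W <- sum(rk[seq_len(nx)])
  if (!has_ties && n <= exact_max) {
    sets <- utils::combn(n, nx)
    sums <- colSums(matrix(seq_len(n)[sets], nrow = nx))
    p <- mean(sums >= W - 1e-9)
    method <- "exact"
  } else {
    mu <- nx * (n + 1) / 2
    tie_tab <- table(comb)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1                                     # all values identical
    } else {
      z <- (W - mu - 0.5) / sqrt(v)              # continuity correction
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal_approx"
  }
  structure(list(rank_sum_W = W, p_one_tailed = min(max(p, 0), 1),
                 method = method, n_x = nx, n_y = ny),
            class = "rank_sum_result")
}

#' Dependent-sample t-test on paired differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#' Two-tailed by default; the directional footwear hypotheses can use
#' `tail = "one"` (upper tail of t).
#'
#' @param diffs Paired differences (n >= 2, nonzero variance).
#' @param tail `"two"` (default) or `"one"`.
#' @return List of class `paired_t_result`: `t_statistic`, `df`, `p_value`,
#'   `tail`.
#' @export
paired_t <- function(diffs, tail = c("two", "one")) {
  tail <- match.arg(tail)
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 2L) stop("need >= 2 paired differences", call. = FALSE)
  s <- stats::sd(diffs)
  if (s == 0) stop("zero variance in paired differences", call. = FALSE)
  t_stat <- mean(diffs) / (s / sqrt(n))
  df <- n - 1L
  p <- if (tail == "two") {
    2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  } else {
    stats::pt(t_stat, df, lower.tail = FALSE)
  }
  structure(list(t_statistic = t_stat, df = df, p_value = p, tail = tail),
            class = "paired_t_result")
}

#' Simple linear regression (ordinary least squares)
#'
#' Closed-form OLS of `y` on `x` with the slope t-test and a confidence
#' interval for the slope.
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` not constant.
#' @param conf_level Confidence level of the slope interval (default 0.95).
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_slope`, `slope_se`, `slope_ci` (length 2), `n`.
#' @export
linear_regression <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3L || length(y) != n) {
    stop("need matched x and y with n >= 3", call. = FALSE)
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant: slope undefined", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst
  df <- n - 2L
  sigma2 <- sse / df
  se <- sqrt(sigma2 / sxx)
  if (se == 0) {
    p <- if (slope == 0) 1 else 0
    ci <- c(slope, slope)
  } else {
    t_stat <- slope / se
    p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- slope + c(-1, 1) * tcrit * se
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = max(0, min(1, r2)), p_slope = p,
                 slope_se = se, slope_ci = ci, n = n),
            class = "regression_result")
}

#' Cohen's d with unweighted variance pooling
#'
#' `d = (mean_j - mean_i) / sqrt((var_j + var_i) / 2)` — the denominator is
#' the square root of the plain average of the two sample variances, NOT the
#' sample-size-weighted pooled variance. Magnitude labels: |d| >= 0.2 small,
#' >= 0.5 medium, >= 0.8 large, else negligible.
#'
#' @param mean_j,var_j Mean and sample variance of group j.
#' @param mean_i,var_i Mean and sample variance of group i.
#' @return List of class `effect_size`: `d`, the four inputs and `magnitude`.
#' @export
cohens_d <- function(mean_j, var_j, mean_i, var_i) {
  if (var_j < 0 || var_i < 0) stop("variances must be >= 0", call. = FALSE)
  if (var_j + var_i == 0) {
    stop("both variances are zero: d undefined", call. = FALSE)
  }
  d <- (mean_j - mean_i) / sqrt((var_j + var_i) / 2)
  magnitude <- if (abs(d) >= 0.8) "large"
               else if (abs(d) >= 0.5) "medium"
               else if (abs(d) >= 0.2) "small"
               else "negligible"
  structure(list(d = d, mean_j = mean_j, mean_i = mean_i,
                 var_j = var_j, var_i = var_i, magnitude = magnitude),
            class = "effect_size")
}

#' Cohen's d from two samples
#'
#' Convenience wrapper computing means and sample variances first.
#'
#' @param xj,xi Numeric samples (group j and group i).
#' @return An `effect_size` (see [cohens_d()]).
#' @export
cohens_d_samples <- function(xj, xi) {
  cohens_d(mean(xj), stats::var(xj), mean(xi), stats::var(xi))
}

#' Run the full statistical battery of the study
#'
#' Orchestrates, per knee sub-region: (1) the one-tailed exact Wilcoxon
#' rank-sum comparing shoe-averaged reductions of the high-deviation half of
#' the cohort against the low half; (2) the dependent-sample t-test between
#' each subject's maximum- and minimum-deviation shoe; (3) the simple linear
#' regression of shoe-averaged reduction on overall deviation; plus Cohen's
#' d (unweighted variance pooling) for both comparisons. P-values are
#' uncorrected across regions by default; set
#' `config$holm_correction` for Holm-adjusted columns.
#'
#' @param summaries List of `subject_summary` objects (one per subject).
#' @param reductions Reduction table (subject, condition, region,
#'   pct_reduction), covering the same subjects.
#' @param config An `analysis_config`.
#' @return List of class `study_result` with data frames `group_tests`,
#'   `footwear_tests`, `regressions`, the `groups` split, and `alpha`.
#' @export
run_study_analysis <- function(summaries, reductions,
                               config = analysis_config()) {
  subj_s <- sort(unname(vapply(summaries, function(s) s$subject_id, "")))
  subj_r <- sort(unique(as.character(reductions$subject)))
  if (!identical(subj_s, subj_r)) {
    stop("subject mismatch between deviations and reductions; ",
         "missing from reductions: ",
         paste(setdiff(subj_s, subj_r), collapse = ", "),
         "; missing from deviations: ",
         paste(setdiff(subj_r, subj_s), collapse = ", "), call. = FALSE)
  }
  names(summaries) <- vapply(summaries, function(s) s$subject_id, "")
  groups <- split_groups(summaries)
  avg <- subject_region_average(reductions)
  overall <- vapply(summaries, function(s) s$overall_deg, 0)

  regions <- knee_regions()
  group_rows <- list(); shoe_rows <- list(); reg_rows <- list()
  for (rg in regions) {
    a <- avg[avg$region == rg, ]
    hi <- a$mean_pct_reduction[a$subject %in% groups$high]
    lo <- a$mean_pct_reduction[a$subject %in% groups$low]

    rs <- wilcoxon_rank_sum_one_tailed(hi, lo)
    es <- tryCatch(cohens_d_samples(hi, lo), error = function(e) NULL)
    group_rows[[rg]] <- data.frame(
      region = rg, test = "rank_sum_high_gt_low",
      statistic = rs$rank_sum_W, p_value = rs$p_one_tailed,
      method = rs$method,
      d = if (is.null(es)) NA_real_ else es$d,
      magnitude = if (is.null(es)) NA_character_ else es$magnitude,
      n = rs$n_x + rs$n_y,
      significant = rs$p_one_tailed <= config$alpha,
      stringsAsFactors = FALSE)

    # per-subject reduction in the max- vs min-deviation shoe
    max_v <- min_v <- rep(NA_real_, length(summaries))
    for (k in seq_along(summaries)) {
      s <- summaries[[k]]
      pick <- function(shoe) {
        v <- reductions$pct_reduction[reductions$subject == s$subject_id &
                                        reductions$condition == shoe &
                                        reductions$region == rg]
        if (length(v) == 1L) v else NA_real_
      }
      max_v[k] <- pick(s$max_shoe)
      min_v[k] <- pick(s$min_shoe)
    }
    diffs <- max_v - min_v
    tt <- tryCatch(paired_t(diffs[!is.na(diffs)]), error = function(e) e)
    es_f <- tryCatch(cohens_d_samples(max_v[!is.na(max_v)],
                                      min_v[!is.na(min_v)]),
                     error = function(e) NULL)
    not_comp <- inherits(tt, "error")
    shoe_rows[[rg]] <- data.frame(
      region = rg, test = "paired_t_max_vs_min_shoe",
      statistic = if (not_comp) NA_real_ else tt$t_statistic,
      df = if (not_comp) NA_integer_ else tt$df,
      p_value = if (not_comp) NA_real_ else tt$p_value,
      d = if (is.null(es_f)) NA_real_ else es_f$d,
      magnitude = if (is.null(es_f)) NA_character_ else es_f$magnitude,
      n = sum(!is.na(diffs)),
      significant = if (not_comp) NA else tt$p_value <= config$alpha,
      note = if (not_comp) conditionMessage(tt) else "",
      stringsAsFactors = FALSE)

    lr <- tryCatch(
      linear_regression(overall[a$subject], a$mean_pct_reduction),
      error = function(e) e)
    bad_lr <- inherits(lr, "error")
    reg_rows[[rg]] <- data.frame(
      region = rg, test = "regression_reduction_on_deviation",
      slope = if (bad_lr) NA_real_ else lr$slope,
      intercept = if (bad_lr) NA_real_ else lr$intercept,
      r_squared = if (bad_lr) NA_real_ else lr$r_squared,
      p_value = if (bad_lr) NA_real_ else lr$p_slope,
      n = if (bad_lr) NA_integer_ else lr$n,
      significant = if (bad_lr) NA else lr$p_slope <= config$alpha,
      stringsAsFactors = FALSE)
  }
  group_tests <- do.call(rbind, group_rows)
  footwear_tests <- do.call(rbind, shoe_rows)
  regressions <- do.call(rbind, reg_rows)
  if (isTRUE(config$holm_correction)) {
    group_tests$p_holm <- stats::p.adjust(group_tests$p_value, "holm")
    footwear_tests$p_holm <- stats::p.adjust(footwear_tests$p_value, "holm")
    regressions$p_holm <- stats::p.adjust(regressions$p_value, "holm")
  }
  rownames(group_tests) <- rownames(footwear_tests) <-
    rownames(regressions) <- NULL
  structure(list(group_tests = group_tests,
                 footwear_tests = footwear_tests,
                 regressions = regressions,
                 groups = groups[c("high", "low")],
                 alpha = config$alpha),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  cat("High group:", paste(x$groups$high, collapse = ", "), "\n")
  cat("Low group: ", paste(x$groups$low, collapse = ", "), "\n\n")
  cat("Group comparison (one-tailed rank-sum, high > low):\n")
  print(x$group_tests[, c("region", "statistic", "p_value", "d",
                          "magnitude", "significant")], row.names = FALSE)
  cat("\nFootwear comparison (paired t, max vs min deviation shoe):\n")
  print(x$footwear_tests[, c("region", "statistic", "p_value", "d",
                             "significant")], row.names = FALSE)
  cat("\nRegressions (reduction ~ overall deviation):\n")
  print(x$regressions[, c("region", "slope", "r_squared", "p_value",
                          "significant")], row.names = FALSE)
  invisible(x)
}
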
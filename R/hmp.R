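#' Habitual motion path baseline from half-squat crossings
#'
#' The baseline is the component-wise mean of the frontal and transverse
#' knee angles read at the critical flexion angle across a subject's valid
#' half-squats. One baseline per subject; it is the reference against which
#' every running condition is compared.
#'
#' @param squat_crossings List (or 2-column matrix) of per-squat
#'   `(frontal_deg, transverse_deg)` pairs.
#' @param subject_id Subject identifier.
#' @param n_excluded Count of squats that produced no valid crossing
#'   (recorded, not used numerically).
#' @return A list of class `hmp_baseline` with `frontal_deg`,
#'   `transverse_deg`, `n_squats_used`, `n_excluded` and `per_squat_values`.
#' @export
compute_baseline <- function(squat_crossings, subject_id = "S01",
                             n_excluded = 0L) {
  if (is.matrix(squat_crossings) || is.data.frame(squat_crossings)) {
    squat_crossings <- lapply(seq_len(nrow(squat_crossings)),
                              function(i) as.numeric(squat_crossings[i, 1:2]))
  }
  if (length(squat_crossings) < 1L) {
    stop("zero valid squat crossings for subject ", subject_id,
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(squat_crossings, function(x) as.numeric(x[1:2])))
  structure(list(subject_id = as.character(subject_id),
                 frontal_deg = mean(m[, 1]),
                 transverse_deg = mean(m[, 2]),
                 n_squats_used = nrow(m),
                 n_excluded = as.integer(n_excluded),
                 per_squat_values = m),
            class = "hmp_baseline")
}

#' @export
print.hmp_baseline <- function(x, ...) {
  cat(sprintf(
    "<hmp_baseline> %s: frontal %.2f deg, transverse %.2f deg (%d squats)\n",
    x$subject_id, x$frontal_deg, x$transverse_deg, x$n_squats_used))
  invisible(x)
}

#' Total deviation score from per-plane deviations
#'
#' The overall habitual-motion-path deviation weights the transverse plane at
#' half the frontal plane, reflecting the smaller transverse range of motion
#' of the knee in running:
#' `dev_total = dev_front + 0.5 * dev_trans`.
#'
#' @param dev_front,dev_trans Per-plane deviations in degrees.
#' @param transverse_weight Transverse weight (default 0.5).
#' @return Total deviation in degrees.
#' @export
total_deviation <- function(dev_front, dev_trans, transverse_weight = 0.5) {
  dev_front + transverse_weight * dev_trans
}

#' Deviation of one running crossing from the baseline
#'
#' Per-plane deviations are absolute differences between the running angles
#' and the squat baseline at the critical flexion angle (set
#' `signed = TRUE` to keep signs); the total combines them via
#' [total_deviation()].
#'
#' @param run_crossing Numeric `(frontal_deg, transverse_deg)` from a running
#'   stride.
#' @param baseline An `hmp_baseline`.
#' @param transverse_weight Weight of the transverse deviation in the total.
#' @param signed Keep the sign of per-plane differences (default `FALSE`).
#' @return Named numeric `(dev_front, dev_trans, dev_total)` in degrees.
#' @export
compute_deviation <- function(run_crossing, baseline,
                              transverse_weight = 0.5, signed = FALSE) {
  stopifnot(inherits(baseline, "hmp_baseline"))
  df <- as.numeric(run_crossing[1]) - baseline$frontal_deg
  dt <- as.numeric(run_crossing[2]) - baseline$transverse_deg
  if (!signed) {
    df <- abs(df)
    dt <- abs(dt)
  }
  c(dev_front = df, dev_trans = dt,
    dev_total = total_deviation(df, dt, transverse_weight))
}

#' Aggregate per-stride deviations into one condition-level deviation
#'
#' Component-wise mean over strides; the total is recomputed from the
#' averaged components (identical to the mean of per-stride totals because
#' the weighting is linear).
#'
#' @param stride_deviations List (or 3-column matrix) of per-stride
#'   `(dev_front, dev_trans, dev_total)` values.
#' @param subject_id,condition Identifiers attached to the result.
#' @param transverse_weight Transverse weight for the recomputed total.
#' @return A list of class `hmp_deviation` with `dev_front_deg`,
#'   `dev_trans_deg`, `dev_total_deg` and `n_strides`.
#' @export
aggregate_condition <- function(stride_deviations, subject_id = "S01",
                                condition = "neutral",
                                transverse_weight = 0.5) {
  if (is.matrix(stride_deviations) || is.data.frame(stride_deviations)) {
    stride_deviations <- lapply(seq_len(nrow(stride_deviations)),
                                function(i) as.numeric(stride_deviations[i, ]))
  }
  if (length(stride_deviations) < 1L) {
    stop("no strides to aggregate for ", subject_id, "/", condition,
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(stride_deviations,
                             function(x) as.numeric(x[1:2])))
  hmp_deviation(subject_id, condition,
                dev_front_deg = mean(m[, 1]), dev_trans_deg = mean(m[, 2]),
                n_strides = nrow(m), transverse_weight = transverse_weight)
}

#' Construct a condition-level deviation record
#'
#' @param subject_id,condition Identifiers.
#' @param dev_front_deg,dev_trans_deg Per-plane deviations (degrees).
#' @param n_strides Number of strides averaged.
#' @param transverse_weight Transverse weight of the total score.
#' @return A list of class `hmp_deviation`; `dev_total_deg` is derived.
#' @export
hmp_deviation <- function(subject_id, condition, dev_front_deg,
                          dev_trans_deg, n_strides = 1L,
                          transverse_weight = 0.5) {
  structure(list(subject_id = as.character(subject_id),
                 condition = as.character(condition),
                 dev_front_deg = dev_front_deg,
                 dev_trans_deg = dev_trans_deg,
                 dev_total_deg = total_deviation(dev_front_deg, dev_trans_deg,
                                                 transverse_weight),
                 n_strides = as.integer(n_strides)),
            class = "hmp_deviation")
}

#' Summarise a subject's deviations across footwear conditions
#'
#' Overall deviation is the unweighted mean of the condition totals; the
#' minimum- and maximum-deviation shoes are identified, breaking exact ties
#' by a fixed condition order (with a warning).
#'
#' @param per_shoe Named list, condition -> `hmp_deviation`.
#' @param tie_order Condition order used for tie-breaking; conditions absent
#'   from it follow in their input order.
#' @return A list of class `subject_summary` with `subject_id`, `per_shoe`,
#'   `overall_deg`, `min_shoe`, `max_shoe`.
#' @export
summarize_subject <- function(per_shoe,
                              tie_order = c("neutral", "lateral_post",
                                            "medial_post")) {
  if (length(per_shoe) < 2L) {
    stop("need >= 2 conditions to summarise a subject", call. = FALSE)
  }
  if (is.null(names(per_shoe))) {
    names(per_shoe) <- vapply(per_shoe, function(d) d$condition, "")
  }
  ord <- c(intersect(tie_order, names(per_shoe)),
           setdiff(names(per_shoe), tie_order))
  per_shoe <- per_shoe[ord]
  totals <- vapply(per_shoe, function(d) d$dev_total_deg, 0)
  if (anyDuplicated(totals[totals == min(totals)]) ||
      anyDuplicated(totals[totals == max(totals)])) {
    warning("tie among condition totals; broken by fixed condition order")
  }
  structure(list(subject_id = per_shoe[[1L]]$subject_id,
                 per_shoe = per_shoe,
                 overall_deg = mean(totals),
                 min_shoe = names(totals)[which.min(totals)],
                 max_shoe = names(totals)[which.max(totals)]),
            class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf(
    "<subject_summary> %s: overall %.2f deg | min %s, max %s\n",
    x$subject_id, x$overall_deg, x$min_shoe, x$max_shoe))
  invisible(x)
}

#' Split subjects into high- and low-deviation halves
#'
#' Subjects are sorted by overall deviation; the top half forms the high
#' group, the bottom half the low group (the design of the group analysis
#' requires an even count). Exact ties at the boundary are broken by subject
#' id order with a warning.
#'
#' @param summaries List of `subject_summary` objects, or a named numeric
#'   vector of overall deviations.
#' @return List with `high` and `low`, each a character vector of subject
#'   ids, plus `high_values` / `low_values`.
#' @export
split_groups <- function(summaries) {
  if (is.numeric(summaries)) {
    vals <- summaries
    if (is.null(names(vals))) {
      names(vals) <- sprintf("S%02d", seq_along(vals))
    }
  } else {
    vals <- vapply(summaries, function(s) s$overall_deg, 0)
    names(vals) <- vapply(summaries, function(s) s$subject_id, "")
  }
  n <- length(vals)
  if (n %% 2L != 0L) {
    stop("odd subject count (", n, "): assign groups explicitly",
         call. = FALSE)
  }
  ord <- order(vals, names(vals), decreasing = TRUE)
  half <- n %/% 2L
  boundary <- vals[ord][half]
  if (sum(vals == boundary) > 1L &&
      any(vals[ord][(half + 1L):n] == boundary)) {
    warning("exact tie at the group boundary; broken by subject id order")
  }
  list(high = sort(names(vals)[ord[seq_len(half)]]),
       low = sort(names(vals)[ord[(half + 1L):n]]),
       high_values = vals[ord[seq_len(half)]],
       low_values = vals[ord[(half + 1L):n]])
}

#' Critical-angle crossing for one trial
#'
#' Convenience wrapper running the kinematics chain on a single trial:
#' optional zero-phase filtering, stance detection (running trials),
#' eccentric-phase detection, then angle extraction at the critical flexion
#' angle. Running trials use the first detected stance.
#'
#' @param tr An `hmp_trial`.
#' @param config An `analysis_config`.
#' @param filter Apply the low-pass filter first (default `TRUE`).
#' @return Named numeric `(frontal_deg, transverse_deg)` with attribute
#'   `crossing_time_s`.
#' @export
critical_angles <- function(tr, config = analysis_config(), filter = TRUE) {
  stopifnot(inherits(tr, "hmp_trial"))
  rate <- trial_rate_hz(tr)
  work <- tr
  if (filter) {
    work$flexion_deg <- lowpass(tr$flexion_deg,
                                config$filter_cutoff_angles_Hz, rate,
                                config$filter_order)
    work$adduction_deg <- lowpass(tr$adduction_deg,
                                  config$filter_cutoff_angles_Hz, rate,
                                  config$filter_order)
    work$int_rot_deg <- lowpass(tr$int_rot_deg,
                                config$filter_cutoff_angles_Hz, rate,
                                config$filter_order)
    if (!is.null(tr$grf_vertical_N)) {
      work$grf_vertical_N <- lowpass(tr$grf_vertical_N,
                                     min(config$filter_cutoff_force_Hz,
                                         rate / 2 * 0.99), rate,
                                     config$filter_order)
    }
  }
  within <- NULL
  if (tr$movement_kind == "run") {
    if (is.null(work$grf_vertical_N)) {
      stop("running trial without a vertical force series: ",
           tr$subject_id, "/", tr$condition, call. = FALSE)
    }
    stances <- detect_stance(work$grf_vertical_N, config$stance_threshold_N,
                             rate, config$min_stance_s)
    if (length(stances) == 0L) {
      stop("no stance detected in running trial ", tr$subject_id, "/",
           tr$condition, call. = FALSE)
    }
    within <- stances[[1L]]
  }
  ecc <- detect_eccentric_phase(work$flexion_deg, within)
  angles_at_critical_flexion(work, ecc, config$critical_flexion_deg)
}
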
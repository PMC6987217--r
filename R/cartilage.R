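#' Normalise a cartilage volume to body mass and height
#'
#' `vc / (mass * height)`, in mm^3 per (kg m). Because percent reductions
#' are ratios of pre and post volumes of the same subject, this
#' normalisation cancels in every downstream statistic; it only affects
#' reported normalised volumes.
#'
#' @param vc_mm3 Cartilage volume in mm^3.
#' @param mass_kg Body mass (> 0).
#' @param height_m Body height (> 0).
#' @return Normalised volume in mm^3/(kg m).
#' @export
normalize_volume <- function(vc_mm3, mass_kg, height_m) {
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0)) {
    stop("body mass must be positive", call. = FALSE)
  }
  if (any(!is.finite(height_m)) || any(height_m <= 0)) {
    stop("body height must be positive", call. = FALSE)
  }
  vc_mm3 / (mass_kg * height_m)
}

#' Percent cartilage volume reduction
#'
#' `100 * (pre - post) / pre`, relative to the pre-run volume. Negative
#' values (volume increases) are legitimate measurements and retained.
#'
#' @param pre_mm3 Pre-run volume (> 0).
#' @param post_mm3 Post-run volume.
#' @return Percent reduction (vectorised).
#' @export
percent_reduction <- function(pre_mm3, post_mm3) {
  if (any(!is.finite(pre_mm3)) || any(pre_mm3 <= 0)) {
    stop("pre-run volume must be positive", call. = FALSE)
  }
  100 * (pre_mm3 - post_mm3) / pre_mm3
}

#' Validate a cartilage volume table
#'
#' Checks the schema and that every subject/condition pair carries exactly
#' the seven knee sub-regions; a missing or duplicated region is an explicit
#' error, never a silent drop.
#'
#' @param cart Data frame with columns subject, condition, region, pre_mm3,
#'   post_mm3, mass_kg, height_m.
#' @return The validated data frame, invisibly.
#' @export
validate_cartilage <- function(cart) {
  need <- c("subject", "condition", "region", "pre_mm3", "post_mm3",
            "mass_kg", "height_m")
  missing_cols <- setdiff(need, names(cart))
  if (length(missing_cols) > 0L) {
    stop("cartilage table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_region <- setdiff(unique(cart$region), knee_regions())
  if (length(bad_region) > 0L) {
    stop("unknown region label(s): ", paste(bad_region, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(cart$subject, cart$condition)
  for (k in unique(key)) {
    regs <- cart$region[key == k]
    miss <- setdiff(knee_regions(), regs)
    if (length(miss) > 0L) {
      stop("subject/condition ", k, " missing region(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(regs)) {
      stop("subject/condition ", k, " has duplicated region rows",
           call. = FALSE)
    }
  }
  if (any(cart$pre_mm3 <= 0) || any(cart$post_mm3 <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  invisible(cart)
}

#' Reduction table from a cartilage volume table
#'
#' Adds percent reductions and mass/height-normalised pre and post volumes.
#'
#' @param cart Validated cartilage table (see [validate_cartilage()]).
#' @return Data frame: subject, condition, region, pct_reduction,
#'   normalized_pre, normalized_post.
#' @export
reduction_table <- function(cart) {
  validate_cartilage(cart)
  data.frame(subject = cart$subject, condition = cart$condition,
             region = cart$region,
             pct_reduction = percent_reduction(cart$pre_mm3, cart$post_mm3),
             normalized_pre = normalize_volume(cart$pre_mm3, cart$mass_kg,
                                               cart$height_m),
             normalized_post = normalize_volume(cart$post_mm3, cart$mass_kg,
                                                cart$height_m),
             stringsAsFactors = FALSE)
}

#' Per-subject, per-region reduction averaged over footwear conditions
#'
#' The group comparison averages each subject's reductions over all shoes to
#' improve robustness; this computes that unweighted mean.
#'
#' @param reductions Data frame with subject, condition, region,
#'   pct_reduction (from [reduction_table()]), or a numeric vector of
#'   reductions for one subject/region.
#' @return If given a vector, its mean. Otherwise a data frame
#'   subject x region with column `mean_pct_reduction`.
#' @export
subject_region_average <- function(reductions) {
  if (is.numeric(reductions)) {
    if (length(reductions) < 1L) {
      stop("no reductions to average", call. = FALSE)
    }
    return(mean(reductions))
  }
  if (nrow(reductions) < 1L) stop("empty reduction table", call. = FALSE)
  agg <- stats::aggregate(pct_reduction ~ subject + region, reductions, mean)
  names(agg)[names(agg) == "pct_reduction"] <- "mean_pct_reduction"
  agg[order(agg$subject, match(agg$region, knee_regions())), ,
      drop = FALSE]
}
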
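#' Seven knee cartilage sub-region labels
#'
#' Patella (P), medial/lateral tibial compartments (MT, LT), medial/lateral
#' femoral condyles (MF, LF) and the central weight-bearing medial/lateral
#' femoral condyles (CMF, CLF).
#'
#' @return Character vector of the seven labels, in canonical order.
#' @export
knee_regions <- function() c("P", "MT", "LT", "MF", "LF", "CMF", "CLF")

#' Construct a ground-truth subject for the synthetic cohort
#'
#' Holds everything the generator needs to produce one subject's trials and
#' cartilage records, and everything a recovery test needs to check the
#' pipeline against: the habitual-path baseline angles, per-shoe deviation
#' offsets, region pre-run volumes and the linear coupling of percent volume
#' reduction to deviation.
#'
#' @param subject_id Identifier, e.g. `"S01"`.
#' @param index Integer subject index (used for seed derivation).
#' @param body_mass_kg,body_height_m Anthropometry (> 0).
#' @param baseline_frontal,baseline_transverse Habitual-path angles (deg) at
#'   the critical flexion angle.
#' @param shoe_offsets Named list, condition -> `c(frontal, transverse)`
#'   offsets in degrees (>= 0) added to the baseline during running.
#' @param region_pre_volumes Named numeric, region -> pre-run volume in mm^3
#'   (> 0), all seven regions.
#' @param coupling_alpha Named numeric, region -> intercept of percent
#'   reduction (%).
#' @param coupling_beta Named numeric, region -> slope of percent reduction
#'   per degree of total deviation (%/deg).
#' @param noise_sd_angle_deg SD of additive Gaussian angle noise (deg).
#' @param noise_sd_reduction_pct SD of additive Gaussian noise on percent
#'   reductions.
#' @param frontal_slope,transverse_slope Linear dependence (deg/deg) of the
#'   non-sagittal angles on flexion around the critical angle.
#' @return A list of class `subject_truth`.
#' @export
subject_truth <- function(subject_id, index,
                          body_mass_kg, body_height_m,
                          baseline_frontal, baseline_transverse,
                          shoe_offsets,
                          region_pre_volumes,
                          coupling_alpha, coupling_beta,
                          noise_sd_angle_deg = 0.5,
                          noise_sd_reduction_pct = 1.0,
                          frontal_slope = 0.05, transverse_slope = 0.08) {
  stopifnot(body_mass_kg > 0, body_height_m > 0,
            all(region_pre_volumes > 0),
            setequal(names(region_pre_volumes), knee_regions()),
            setequal(names(coupling_alpha), knee_regions()),
            setequal(names(coupling_beta), knee_regions()),
            length(shoe_offsets) >= 1)
  structure(list(subject_id = as.character(subject_id),
                 index = as.integer(index),
                 body_mass_kg = body_mass_kg,
                 body_height_m = body_height_m,
                 baseline_frontal = baseline_frontal,
                 baseline_transverse = baseline_transverse,
                 shoe_offsets = shoe_offsets,
                 region_pre_volumes = region_pre_volumes[knee_regions()],
                 coupling_alpha = coupling_alpha[knee_regions()],
                 coupling_beta = coupling_beta[knee_regions()],
                 noise_sd_angle_deg = noise_sd_angle_deg,
                 noise_sd_reduction_pct = noise_sd_reduction_pct,
                 frontal_slope = frontal_slope,
                 transverse_slope = transverse_slope),
            class = "subject_truth")
}

#' Default distribution parameters for drawing a synthetic cohort
#'
#' Anthropometry matches the study sample (mass 70.9 +/- 9.9 kg, height
#' 1.77 +/- 0.08 m). Baseline angles, per-shoe deviation offsets, pre-run
#' volumes and coupling parameters are package choices documented in the
#' methods vignette; the coupling slope default is 0.4 %/deg.
#'
#' @return Named list of distribution parameters, all overridable through
#'   the `truth_params` argument of [generate_cohort()].
#' @export
default_truth_params <- function() {
  list(
    mass_mean = 70.9, mass_sd = 9.9,
    height_mean = 1.77, height_sd = 0.08,
    baseline_frontal_mean = 2, baseline_frontal_sd = 2,
    baseline_transverse_mean = -3, baseline_transverse_sd = 3,
    # per-shoe mean frontal/transverse offsets (deg); subject_effect_sd
    # creates consistent high/low deviators across shoes
    offset_frontal_mean = c(neutral = 5.5, lateral_post = 7.0,
                            medial_post = 6.5),
    offset_transverse_mean = c(neutral = 6.0, lateral_post = 8.0,
                               medial_post = 7.0),
    offset_sd = 1.0,
    subject_effect_sd = 2.5,
    # pre-run volumes (mm^3): order P, MT, LT, MF, LF, CMF, CLF
    volume_mean = c(P = 3500, MT = 2200, LT = 2600, MF = 2400, LF = 2600,
                    CMF = 1200, CLF = 1400),
    volume_cv = 0.15,
    alpha_mean = 2.5, alpha_sd = 0.5,
    beta = 0.4,
    noise_sd_angle_deg = 0.5,
    noise_sd_reduction_pct = 1.0
  )
}

#' Draw one subject's ground truth from the cohort distributions
#'
#' Uses the current RNG stream; [generate_cohort()] wraps this in a seeded
#' stream derived from the cohort seed.
#'
#' @param index Subject index (1-based).
#' @param shoes Condition labels.
#' @param p Distribution parameters (see [default_truth_params()]).
#' @return A `subject_truth`.
#' @export
draw_subject_truth <- function(index, shoes, p = default_truth_params()) {
  regions <- knee_regions()
  subj_eff <- stats::rnorm(1, 0, p$subject_effect_sd)
  offs <- lapply(shoes, function(sh) {
    mf <- if (sh %in% names(p$offset_frontal_mean)) {
      p$offset_frontal_mean[[sh]]
    } else mean(p$offset_frontal_mean)
    mt <- if (sh %in% names(p$offset_transverse_mean)) {
      p$offset_transverse_mean[[sh]]
    } else mean(p$offset_transverse_mean)
    c(frontal = max(0, mf + subj_eff + stats::rnorm(1, 0, p$offset_sd)),
      transverse = max(0, mt + subj_eff + stats::rnorm(1, 0, p$offset_sd)))
  })
  names(offs) <- shoes
  vols <- stats::rnorm(length(regions), p$volume_mean,
                       p$volume_mean * p$volume_cv)
  vols <- pmax(vols, p$volume_mean * 0.5)
  names(vols) <- regions
  alpha <- stats::rnorm(length(regions), p$alpha_mean, p$alpha_sd)
  names(alpha) <- regions
  beta <- rep(p$beta, length(regions))
  names(beta) <- regions
  subject_truth(
    subject_id = sprintf("S%02d", index), index = index,
    body_mass_kg = max(45, stats::rnorm(1, p$mass_mean, p$mass_sd)),
    body_height_m = max(1.45, stats::rnorm(1, p$height_mean, p$height_sd)),
    baseline_frontal = stats::rnorm(1, p$baseline_frontal_mean,
                                    p$baseline_frontal_sd),
    baseline_transverse = stats::rnorm(1, p$baseline_transverse_mean,
                                       p$baseline_transverse_sd),
    shoe_offsets = offs,
    region_pre_volumes = vols,
    coupling_alpha = alpha, coupling_beta = beta,
    noise_sd_angle_deg = p$noise_sd_angle_deg,
    noise_sd_reduction_pct = p$noise_sd_reduction_pct)
}

# Non-sagittal angles as affine functions of flexion: equal to the target
# value at the critical angle (40 deg) by construction, so a noiseless trial
# round-trips through the pipeline exactly (linear interpolation and linear
# filtering both preserve affine relations between series).
nonsagittal_from_flexion <- function(flex, value_at_40, slope, noise_sd) {
  value_at_40 + slope * (flex - 40) +
    if (noise_sd > 0) stats::rnorm(length(flex), 0, noise_sd) else 0
}

#' Generate one half-squat trial
#'
#' Flexion follows a raised cosine from ~5 degrees up to a peak drawn in
#' [82, 98] degrees and back, guaranteeing exactly one rising and one falling
#' crossing of the 40-degree critical angle. Frontal and transverse angles
#' are affine functions of flexion equal to the subject's baseline at 40
#' degrees, plus additive Gaussian noise.
#'
#' @param subject A `subject_truth`.
#' @param rep_index Repetition number (1-based); part of the trial's seed.
#' @param cfg A `cohort_config`.
#' @return An `hmp_trial` of kind `"squat"`, with attribute `truth` holding
#'   the generated peak index and peak flexion.
#' @export
generate_squat_trial <- function(subject, rep_index, cfg) {
  seed <- mix_seed(cfg$seed, 1L, subject$index, rep_index)
  withr_seed(seed, {
    dur <- 3.0
    n <- round(dur * cfg$sampling_rate_mocap) + 1L
    t <- (seq_len(n) - 1L) / cfg$sampling_rate_mocap
    peak <- stats::runif(1, 82, 98)
    start <- stats::runif(1, 4, 8)
    flex <- start + (peak - start) * 0.5 * (1 - cos(2 * pi * t / dur))
    fr <- nonsagittal_from_flexion(flex, subject$baseline_frontal,
                                   subject$frontal_slope,
                                   subject$noise_sd_angle_deg)
    tv <- nonsagittal_from_flexion(flex, subject$baseline_transverse,
                                   subject$transverse_slope,
                                   subject$noise_sd_angle_deg)
    tr <- trial(t, flex, fr, tv, movement_kind = "squat",
                subject_id = subject$subject_id, condition = "squat")
    attr(tr, "truth") <- list(peak_index = which.max(flex),
                              peak_flexion_deg = peak)
    tr
  })
}

#' Generate one running stride
#'
#' One stance phase (smooth force bump peaking near 2.5 body weights,
#' exactly zero during the flight padding on both sides) with flexion rising
#' from ~15-20 degrees at contact to a 50-degree peak at 40% of stance
#' (asymmetric beta-shaped bump) and falling back, guaranteeing a rising
#' 40-degree crossing in the eccentric part of stance. Non-sagittal angles
#' equal baseline + shoe offset at the crossing, plus noise.
#'
#' @param subject A `subject_truth`.
#' @param shoe Condition label; must be one of `names(subject$shoe_offsets)`.
#' @param stride_index Stride number (1-based); part of the trial's seed.
#' @param cfg A `cohort_config`.
#' @return An `hmp_trial` of kind `"run"` with a `grf_vertical_N` series and
#'   attribute `truth` (stance bounds, stance duration, true crossing
#'   angles).
#' @export
generate_running_trial <- function(subject, shoe, stride_index, cfg) {
  if (!shoe %in% names(subject$shoe_offsets)) {
    stop(sprintf("unknown shoe label '%s' for subject %s (have: %s)",
                 shoe, subject$subject_id,
                 paste(names(subject$shoe_offsets), collapse = ", ")),
         call. = FALSE)
  }
  shoe_idx <- match(shoe, names(subject$shoe_offsets))
  seed <- mix_seed(cfg$seed, 2L, subject$index, shoe_idx, stride_index)
  withr_seed(seed, {
    rate <- cfg$sampling_rate_mocap
    stance_dur <- stats::runif(1, 0.24, 0.32)
    lead <- 0.10
    n_lead <- round(lead * rate)
    n_st <- round(stance_dur * rate) + 1L
    n <- n_lead + n_st + n_lead
    t <- (seq_len(n) - 1L) / rate
    stance_idx <- (n_lead + 1L):(n_lead + n_st)
    s <- (seq_len(n_st) - 1L) / (n_st - 1L)            # stance fraction [0,1]

    bw <- subject$body_mass_kg * 9.81
    force <- numeric(n)
    force[stance_idx] <- 2.5 * bw * sin(pi * s)^2

    contact_flex <- stats::runif(1, 15, 20)
    peak_flex <- 50
    bump <- s^2 * (1 - s)^3
    bump <- bump / max(bump)                           # peak 1 at s = 0.4
    flex <- rep(contact_flex, n)
    flex[stance_idx] <- contact_flex + (peak_flex - contact_flex) * bump

    off <- subject$shoe_offsets[[shoe]]
    fr <- nonsagittal_from_flexion(flex,
                                   subject$baseline_frontal + off[["frontal"]],
                                   subject$frontal_slope,
                                   subject$noise_sd_angle_deg)
    tv <- nonsagittal_from_flexion(
      flex, subject$baseline_transverse + off[["transverse"]],
      subject$transverse_slope, subject$noise_sd_angle_deg)

    tr <- trial(t, flex, fr, tv, grf_vertical_N = force,
                movement_kind = "run",
                subject_id = subject$subject_id, condition = shoe)
    attr(tr, "truth") <- list(
      stance_start_index = stance_idx[1L],
      stance_end_index = stance_idx[n_st],
      stance_duration_s = stance_dur,
      peak_index = stance_idx[which.max(bump)],
      crossing_frontal = subject$baseline_frontal + off[["frontal"]],
      crossing_transverse = subject$baseline_transverse + off[["transverse"]])
    tr
  })
}

#' Generate marker trajectories from a pose sequence
#'
#' Applies each frame's rigid pose to a marker template and adds isotropic
#' Gaussian noise: the fixture for testing rigid-body pose recovery.
#'
#' @param pose_sequence List of poses, each a list with `rotation` (3x3) and
#'   `translation` (length 3).
#' @param template n x 3 marker template (n >= 3, non-collinear), metres.
#' @param noise_sd_m Isotropic noise SD in metres (default 0).
#' @return List of n x 3 observed marker matrices, one per frame.
#' @export
generate_marker_trial <- function(pose_sequence, template, noise_sd_m = 0) {
  template <- as.matrix(template)
  if (nrow(template) < 3L) {
    stop("marker template needs >= 3 points", call. = FALSE)
  }
  A <- sweep(template, 2, colMeans(template))
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[2] <= max(sv) * 1e-10) {
    stop("marker template points are collinear", call. = FALSE)
  }
  lapply(pose_sequence, function(p) {
    obs <- template %*% t(p$rotation) +
      matrix(p$translation, nrow(template), 3, byrow = TRUE)
    if (noise_sd_m > 0) {
      obs <- obs + matrix(stats::rnorm(length(obs), 0, noise_sd_m),
                          nrow(obs), 3)
    }
    obs
  })
}

#' Generate a cartilage record for one subject and shoe
#'
#' Per region, the percent volume reduction is `alpha + beta * deviation`
#' plus Gaussian noise, truncated at zero (cartilage volume cannot grow from
#' loading in this model); the post-run volume is
#' `pre * (1 - reduction / 100)`.
#'
#' @param subject A `subject_truth`.
#' @param shoe Condition label.
#' @param realized_deviation Total deviation (deg, >= 0) that drove the
#'   loading in this condition.
#' @param seed Optional integer seed for the noise draw; `NULL` uses the
#'   current RNG stream.
#' @return Data frame: subject, condition, region, pre_mm3, post_mm3,
#'   mass_kg, height_m, plus `true_reduction_pct`.
#' @export
generate_cartilage_volumes <- function(subject, shoe, realized_deviation,
                                       seed = NULL) {
  stopifnot(realized_deviation >= 0)
  gen <- function() {
    regions <- knee_regions()
    red <- subject$coupling_alpha + subject$coupling_beta * realized_deviation
    if (subject$noise_sd_reduction_pct > 0) {
      red <- red + stats::rnorm(length(regions), 0,
                                subject$noise_sd_reduction_pct)
    }
    red <- pmax(red, 0)
    pre <- subject$region_pre_volumes
    data.frame(subject = subject$subject_id, condition = shoe,
               region = regions,
               pre_mm3 = as.numeric(pre),
               post_mm3 = as.numeric(pre * (1 - red / 100)),
               mass_kg = subject$body_mass_kg,
               height_m = subject$body_height_m,
               true_reduction_pct = as.numeric(red),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

#' Generate a complete synthetic cohort
#'
#' Draws subject ground truth, then all half-squat trials, running strides
#' and cartilage records. The cartilage coupling uses each subject's true
#' per-shoe total deviation (frontal offset + 0.5 x transverse offset), so a
#' zero-noise cohort round-trips through the whole pipeline exactly.
#'
#' @param cfg A `cohort_config`; `cfg$seed` makes the dataset deterministic.
#' @param truth_params Named list overriding entries of
#'   [default_truth_params()].
#' @param subjects Optional list of `subject_truth` objects to use instead of
#'   drawing them (length must equal `cfg$n_subjects`).
#' @param eq1_transverse_weight Transverse weight used to compute the true
#'   deviations driving cartilage coupling (default 0.5).
#' @return A list of class `hmp_cohort`: `trials` (list of `hmp_trial`),
#'   `cartilage` (data frame), `truth` (list of `subject_truth`),
#'   `truth_table` (data frame of per-subject per-shoe true deviations and
#'   reductions) and `cfg`.
#' @export
generate_cohort <- function(cfg, truth_params = list(), subjects = NULL,
                            eq1_transverse_weight = 0.5) {
  validate_cohort_config(cfg)
  p <- utils::modifyList(default_truth_params(), truth_params)
  if (is.null(subjects)) {
    subjects <- withr_seed(mix_seed(cfg$seed, 0L), {
      lapply(seq_len(cfg$n_subjects), draw_subject_truth,
             shoes = cfg$shoes, p = p)
    })
  } else if (length(subjects) != cfg$n_subjects) {
    stop("length(subjects) must equal cfg$n_subjects", call. = FALSE)
  }

  trials <- list()
  cart <- list()
  truth_rows <- list()
  for (su in subjects) {
    for (r in seq_len(cfg$n_squats_per_subject)) {
      trials[[length(trials) + 1L]] <- generate_squat_trial(su, r, cfg)
    }
    for (sh in cfg$shoes) {
      for (k in seq_len(cfg$n_strides_per_condition)) {
        trials[[length(trials) + 1L]] <- generate_running_trial(su, sh, k, cfg)
      }
      off <- su$shoe_offsets[[sh]]
      dev_tot <- off[["frontal"]] + eq1_transverse_weight * off[["transverse"]]
      rec <- generate_cartilage_volumes(
        su, sh, dev_tot, seed = mix_seed(cfg$seed, 3L, su$index,
                                         match(sh, cfg$shoes)))
      cart[[length(cart) + 1L]] <- rec
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subject = su$subject_id, condition = sh,
        true_dev_front = off[["frontal"]], true_dev_trans = off[["transverse"]],
        true_dev_total = dev_tot, stringsAsFactors = FALSE)
    }
  }
  structure(list(trials = trials,
                 cartilage = do.call(rbind, cart),
                 truth = subjects,
                 truth_table = do.call(rbind, truth_rows),
                 cfg = cfg),
            class = "hmp_cohort")
}

#' @export
print.hmp_cohort <- function(x, ...) {
  cat(sprintf("<hmp_cohort> %d subjects x %d shoes | %d trials | seed %d\n",
              x$cfg$n_subjects, length(x$cfg$shoes), length(x$trials),
              x$cfg$seed))
  invisible(x)
}

# Evaluate expr with a temporary RNG state; restores (or clears) the
# caller's state afterwards so generators never perturb user code.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
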
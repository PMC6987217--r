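#' Cohort configuration for the synthetic-data generator
#'
#' Describes the study layout the generator emulates: a cohort of runners,
#' each measured in several footwear conditions, performing half-squats (to
#' establish the habitual motion path baseline) and treadmill running strides.
#' Defaults mirror the study design: 12 subjects, three shoes (neutral,
#' laterally posted, medially posted), ten half-squats per subject.
#'
#' @param n_subjects Number of subjects; must be even (the group analysis
#'   splits the cohort into high/low deviation halves) and at least 2.
#' @param shoes Character vector of footwear condition labels.
#' @param sampling_rate_mocap Motion-capture sampling rate in Hz.
#' @param sampling_rate_force Force-plate sampling rate in Hz (kept for
#'   interface fidelity; generated trials share the mocap time base).
#' @param n_squats_per_subject Half-squat repetitions per subject.
#' @param n_strides_per_condition Running strides analysed per shoe.
#'   Protocols for this measurement do not fix a stride count; 20 is the
#'   package default and is freely configurable.
#' @param seed Integer master seed; every generated trial derives its own
#'   sub-stream from it, so the full cohort is reproducible bytewise.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12L,
                          shoes = c("neutral", "lateral_post", "medial_post"),
                          sampling_rate_mocap = 200,
                          sampling_rate_force = 1000,
                          n_squats_per_subject = 10L,
                          n_strides_per_condition = 20L,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    shoes = as.character(shoes),
    sampling_rate_mocap = sampling_rate_mocap,
    sampling_rate_force = sampling_rate_force,
    n_squats_per_subject = as.integer(n_squats_per_subject),
    n_strides_per_condition = as.integer(n_strides_per_condition),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  bad <- character(0)
  if (!is.finite(cfg$n_subjects) || cfg$n_subjects < 2L ||
      cfg$n_subjects %% 2L != 0L) {
    bad <- c(bad, "n_subjects (must be even and >= 2)")
  }
  if (length(cfg$shoes) < 1L || anyDuplicated(cfg$shoes)) {
    bad <- c(bad, "shoes (non-empty, unique labels)")
  }
  if (!is.finite(cfg$sampling_rate_mocap) || cfg$sampling_rate_mocap <= 0) {
    bad <- c(bad, "sampling_rate_mocap (> 0)")
  }
  if (!is.finite(cfg$sampling_rate_force) || cfg$sampling_rate_force <= 0) {
    bad <- c(bad, "sampling_rate_force (> 0)")
  }
  if (cfg$n_squats_per_subject < 1L) bad <- c(bad, "n_squats_per_subject (>= 1)")
  if (cfg$n_strides_per_condition < 1L) {
    bad <- c(bad, "n_strides_per_condition (>= 1)")
  }
  if (!is.finite(cfg$seed)) bad <- c(bad, "seed (finite integer)")
  if (length(bad) > 0L) {
    stop("invalid cohort_config field(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Analysis configuration
#'
#' Central home for the constants of the deviation protocol and the
#' statistical battery: the critical knee flexion angle at which non-sagittal
#' angles are sampled (40 degrees), the transverse-plane weight of the total
#' deviation score (0.5), stance detection and filtering defaults, and the
#' significance level (0.05).
#'
#' @param critical_flexion_deg Knee flexion angle (degrees, in (0, 90)) at
#'   which frontal and transverse angles are read off during the eccentric
#'   phase.
#' @param eq1_transverse_weight Weight applied to the transverse-plane
#'   deviation in the total deviation score (frontal weight is 1).
#' @param stance_threshold_N Vertical force threshold for stance detection.
#' @param min_stance_s Minimum stance duration; shorter intervals discarded.
#' @param filter_cutoff_angles_Hz,filter_cutoff_force_Hz,filter_order
#'   Zero-phase low-pass settings for angles and force.
#' @param alpha Significance level for all tests.
#' @param signed_deviation If `TRUE`, per-plane deviations keep their sign
#'   instead of the default absolute value (exploratory option; the total
#'   score is then a signed sum).
#' @param holm_correction If `TRUE`, Holm-adjusted p-values are added across
#'   the seven regions per test family (off by default: uncorrected
#'   region-wise p-values are the convention this battery mirrors).
#' @param tie_shoe_order Condition order used to break exact ties when
#'   identifying a subject's extreme shoes.
#' @param seed Seed recorded alongside results for provenance.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(critical_flexion_deg = 40,
                            eq1_transverse_weight = 0.5,
                            stance_threshold_N = 20,
                            min_stance_s = 0.1,
                            filter_cutoff_angles_Hz = 12,
                            filter_cutoff_force_Hz = 50,
                            filter_order = 4L,
                            alpha = 0.05,
                            signed_deviation = FALSE,
                            holm_correction = FALSE,
                            tie_shoe_order = c("neutral", "lateral_post",
                                               "medial_post"),
                            seed = 1L) {
  stopifnot(critical_flexion_deg > 0, critical_flexion_deg < 90,
            eq1_transverse_weight > 0,
            alpha > 0, alpha < 1,
            stance_threshold_N >= 0, min_stance_s >= 0, filter_order >= 1)
  cfg <- list(
    critical_flexion_deg = critical_flexion_deg,
    eq1_transverse_weight = eq1_transverse_weight,
    stance_threshold_N = stance_threshold_N,
    min_stance_s = min_stance_s,
    filter_cutoff_angles_Hz = filter_cutoff_angles_Hz,
    filter_cutoff_force_Hz = filter_cutoff_force_Hz,
    filter_order = as.integer(filter_order),
    alpha = alpha,
    signed_deviation = isTRUE(signed_deviation),
    holm_correction = isTRUE(holm_correction),
    tie_shoe_order = as.character(tie_shoe_order),
    seed = as.integer(seed)
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from a JSON file
#'
#' Unknown keys are rejected so that typos in config files fail loudly.
#'
#' @param path Path to a JSON file whose keys are `analysis_config()`
#'   argument names.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, raw)
}

# Deterministic per-trial sub-seed: mixes integer components into [1, 2^31-2].
# Doubles hold the intermediate products exactly (all < 2^53).
mix_seed <- function(base, ...) {
  s <- as.double(base) %% 2147483647
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s + 1)
}
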
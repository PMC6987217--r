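# Shared fixtures: compact ground-truth subjects and small cohorts built in
# code at test time.

regions <- knee_regions()

make_subject <- function(index = 1L,
                         baseline_frontal = 3, baseline_transverse = -2,
                         offsets = list(neutral = c(frontal = 5,
                                                    transverse = 4),
                                        lateral_post = c(frontal = 8,
                                                         transverse = 6),
                                        medial_post = c(frontal = 3,
                                                        transverse = 2)),
                         alpha = 2.5, beta = 0.4,
                         noise_angle = 0, noise_reduction = 0,
                         mass = 70, height = 1.77) {
  subject_truth(
    subject_id = sprintf("S%02d", index), index = index,
    body_mass_kg = mass, body_height_m = height,
    baseline_frontal = baseline_frontal,
    baseline_transverse = baseline_transverse,
    shoe_offsets = offsets,
    region_pre_volumes = stats::setNames(rep(2000, 7), regions),
    coupling_alpha = stats::setNames(rep(alpha, 7), regions),
    coupling_beta = stats::setNames(rep(beta, 7), regions),
    noise_sd_angle_deg = noise_angle,
    noise_sd_reduction_pct = noise_reduction)
}

small_noiseless_cohort <- function(n_subjects = 4L, seed = 7L,
                                   n_squats = 3L, n_strides = 2L) {
  cfg <- cohort_config(n_subjects = n_subjects,
                       n_squats_per_subject = n_squats,
                       n_strides_per_condition = n_strides, seed = seed)
  generate_cohort(cfg, truth_params = list(noise_sd_angle_deg = 0,
                                           noise_sd_reduction_pct = 0))
}

# isotropic 8-marker cube cluster (half-edge 0.15 m): well-conditioned
# geometry for pose recovery fixtures
cube_template <- function(half = 0.15) {
  as.matrix(expand.grid(x = c(-half, half), y = c(-half, half),
                        z = c(-half, half)))
}

rot_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rotation_angle_deg <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
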
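#' Construct a motion trial
#'
#' A trial is one movement repetition: a uniformly sampled time vector with
#' knee joint angle components (flexion, adduction = frontal plane, internal
#' rotation = transverse plane) in degrees, and, for running trials, the
#' vertical ground-reaction force in newtons on the same time base.
#'
#' @param time Time in seconds, strictly increasing, uniform to 1e-6 s.
#' @param flexion_deg,adduction_deg,int_rot_deg Angle series in degrees.
#' @param grf_vertical_N Optional vertical force series in newtons.
#' @param movement_kind `"squat"` or `"run"`.
#' @param subject_id Subject identifier.
#' @param condition Condition label (footwear for runs, `"squat"` otherwise).
#' @return A list of class `hmp_trial`.
#' @export
trial <- function(time, flexion_deg, adduction_deg, int_rot_deg,
                  grf_vertical_N = NULL,
                  movement_kind = c("squat", "run"),
                  subject_id = "S01", condition = "squat") {
  movement_kind <- match.arg(movement_kind)
  n <- length(time)
  if (n < 2L) stop("trial needs at least 2 samples", call. = FALSE)
  if (length(flexion_deg) != n || length(adduction_deg) != n ||
      length(int_rot_deg) != n) {
    stop("angle series must match time length (", n, ")", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  gap <- max(abs(dt - dt[1]))
  if (gap > 1e-6) {
    stop(sprintf("time not uniform: max gap deviation %.3g s", gap),
         call. = FALSE)
  }
  if (!is.null(grf_vertical_N) && length(grf_vertical_N) != n) {
    stop("grf_vertical_N must match time length", call. = FALSE)
  }
  structure(list(time = as.double(time),
                 flexion_deg = as.double(flexion_deg),
                 adduction_deg = as.double(adduction_deg),
                 int_rot_deg = as.double(int_rot_deg),
                 grf_vertical_N = if (is.null(grf_vertical_N)) NULL
                                  else as.double(grf_vertical_N),
                 movement_kind = movement_kind,
                 subject_id = as.character(subject_id),
                 condition = as.character(condition)),
            class = "hmp_trial")
}

#' @export
print.hmp_trial <- function(x, ...) {
  cat(sprintf("<hmp_trial> %s | %s | %s | %d samples @ %.6g Hz%s\n",
              x$subject_id, x$movement_kind, x$condition, length(x$time),
              1 / (x$time[2] - x$time[1]),
              if (is.null(x$grf_vertical_N)) "" else " + GRF"))
  invisible(x)
}

trial_rate_hz <- function(tr) 1 / (tr$time[2] - tr$time[1])

#' Construct a phase interval
#'
#' Half-open sample-index interval `[start, end)` (1-based) marking a stance
#' or eccentric phase inside a trial.
#'
#' @param start_index,end_index Integer sample indices, `1 <= start < end`.
#' @param kind `"stance"` or `"eccentric"`.
#' @param n_samples Optional series length to validate `end_index` against.
#' @return A list of class `phase_interval`.
#' @export
phase_interval <- function(start_index, end_index,
                           kind = c("stance", "eccentric"),
                           n_samples = NULL) {
  kind <- match.arg(kind)
  start_index <- as.integer(start_index)
  end_index <- as.integer(end_index)
  if (start_index < 1L || end_index <= start_index) {
    stop("phase_interval requires 1 <= start < end", call. = FALSE)
  }
  if (!is.null(n_samples) && end_index > n_samples + 1L) {
    stop("phase_interval end exceeds series length", call. = FALSE)
  }
  structure(list(start_index = start_index, end_index = end_index,
                 kind = kind),
            class = "phase_interval")
}

#' Least-squares rigid-body fit of matched 3-D point sets
#'
#' Finds the proper rotation and translation minimising the sum of squared
#' distances between `rotation %*% template + translation` and `observed`
#' (Kabsch/Umeyama solution via SVD). Reflections are rejected: if the raw
#' SVD solution has determinant -1, the smallest singular direction is
#' flipped, yielding the optimal proper rotation. This is the marker-cloud
#' optimisation that makes skin-marker coordinates comply with the rigid-body
#' assumption before joint angles are computed.
#'
#' @param template n x 3 matrix of reference marker positions (n >= 3,
#'   non-collinear), metres.
#' @param observed n x 3 matrix of observed positions, matched row-to-row.
#' @return A `segment_pose`: list with `rotation` (3x3, det +1), `translation`
#'   (length 3) and `residual_rms` (metres).
#' @export
fit_rigid_transform <- function(template, observed) {
  template <- as.matrix(template)
  observed <- as.matrix(observed)
  if (ncol(template) != 3L || ncol(observed) != 3L) {
    stop("point sets must be n x 3 matrices", call. = FALSE)
  }
  if (nrow(template) != nrow(observed)) {
    stop("mismatched point counts: ", nrow(template), " vs ", nrow(observed),
         call. = FALSE)
  }
  n <- nrow(template)
  if (n < 3L) stop("degenerate geometry: need >= 3 points", call. = FALSE)
  ct <- colMeans(template)
  co <- colMeans(observed)
  A <- sweep(template, 2, ct)
  B <- sweep(observed, 2, co)
  # collinearity: centred template must have rank >= 2
  sv_t <- svd(A, nu = 0, nv = 0)$d
  if (sv_t[2] <= max(sv_t) * 1e-10) {
    stop("degenerate geometry: template points are collinear", call. = FALSE)
  }
  H <- crossprod(A, B)                       # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(co - R %*% ct)
  fitted <- template %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE)
  res <- sqrt(mean(rowSums((observed - fitted)^2)))
  structure(list(rotation = R, translation = t_vec, residual_rms = res),
            class = "segment_pose")
}

#' Compose a rotation matrix from Cardan knee angles
#'
#' Intrinsic rotation sequence flexion (mediolateral x axis) -> adduction
#' (y') -> internal rotation (z''): `R = Rx(flexion) Ry(adduction) Rz(rot)`.
#' Inverse of [knee_angles_from_rotation()].
#'
#' @param flexion_deg,adduction_deg,int_rot_deg Angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_knee_angles <- function(flexion_deg, adduction_deg,
                                      int_rot_deg) {
  a <- flexion_deg * pi / 180
  b <- adduction_deg * pi / 180
  c <- int_rot_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

#' Decompose a rotation matrix into Cardan knee angles
#'
#' @param R 3x3 rotation matrix (relative thigh-to-shank rotation).
#' @return Named numeric vector `(flexion_deg, adduction_deg, int_rot_deg)`.
#'   Emits a warning (not an error) when the middle angle is within 1e-6 rad
#'   of +/-90 degrees (gimbal proximity).
#' @export
knee_angles_from_rotation <- function(R) {
  s_b <- max(-1, min(1, R[1, 3]))
  b <- asin(s_b)
  if (abs(abs(b) - pi / 2) < 1e-6) {
    warning("gimbal proximity: |adduction| within 1e-6 rad of 90 degrees")
  }
  a <- atan2(-R[2, 3], R[3, 3])
  c <- atan2(-R[1, 2], R[1, 1])
  c(flexion_deg = a, adduction_deg = b, int_rot_deg = c) * 180 / pi
}

#' Knee joint angles from thigh and shank segment poses
#'
#' The relative rotation `t(thigh$rotation) %*% shank$rotation` is decomposed
#' in the flexion -> adduction -> internal-rotation Cardan sequence.
#'
#' @param thigh,shank `segment_pose` objects (from [fit_rigid_transform()]).
#' @return Named numeric vector of the three angles in degrees.
#' @export
knee_angles_from_poses <- function(thigh, shank) {
  stopifnot(inherits(thigh, "segment_pose"), inherits(shank, "segment_pose"))
  knee_angles_from_rotation(crossprod(thigh$rotation, shank$rotation))
}

#' Unwrap an angle series in degrees
#'
#' Removes artificial +/-360-degree jumps so angle traces are continuous
#' across frames before interpolation.
#'
#' @param x Angle series in degrees.
#' @param period Wrap period, default 360.
#' @return Unwrapped series, same length.
#' @export
unwrap_deg <- function(x, period = 360) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  jumps <- round(d / period)
  x - c(0, cumsum(jumps)) * period
}

#' Detect stance phases from vertical ground-reaction force
#'
#' Maximal intervals with force at or above the threshold. Onsets/offsets are
#' refined by linear interpolation of the threshold crossing and rounded to
#' the nearest sample; intervals shorter than `min_duration_s` are discarded.
#'
#' @param grf_vertical Force series (newtons), non-negative up to noise.
#' @param threshold_N Detection threshold (default 20 N).
#' @param rate_hz Sampling rate of the series.
#' @param min_duration_s Minimum stance duration (default 0.1 s).
#' @return List of `phase_interval` objects (possibly empty).
#' @export
detect_stance <- function(grf_vertical, threshold_N = 20, rate_hz,
                          min_duration_s = 0.1) {
  f <- as.double(grf_vertical)
  n <- length(f)
  above <- f >= threshold_N
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]           # inclusive run of above-threshold
    # sub-sample crossing refinement, rounded to nearest sample
    if (s > 1L && f[s] != f[s - 1L]) {
      frac <- (threshold_N - f[s - 1L]) / (f[s] - f[s - 1L])
      s <- as.integer(round(s - 1L + frac))
      s <- max(1L, s)
    }
    if (e < n && f[e] != f[e + 1L]) {
      frac <- (threshold_N - f[e]) / (f[e + 1L] - f[e])
      e <- as.integer(round(e + frac))
      e <- min(n, e)
    }
    dur <- (e - s + 1L) / rate_hz
    if (dur >= min_duration_s && e > s) {
      out[[length(out) + 1L]] <-
        phase_interval(s, e + 1L, kind = "stance", n_samples = n)
    }
  }
  out
}

#' Detect the eccentric phase of a movement
#'
#' The eccentric phase runs from the start of the search region to the sample
#' of maximum flexion within it (knee flexing under load). For a half-squat
#' the region is the whole trial; for running it is a stance interval.
#'
#' @param flexion Flexion series in degrees.
#' @param within Optional `phase_interval` restricting the search; default is
#'   the whole series.
#' @return A `phase_interval` of kind `"eccentric"` covering samples
#'   `[start, peak]` (half-open end at `peak + 1`).
#' @export
detect_eccentric_phase <- function(flexion, within = NULL) {
  n <- length(flexion)
  if (is.null(within)) {
    lo <- 1L; hi <- n
  } else {
    stopifnot(inherits(within, "phase_interval"))
    lo <- within$start_index
    hi <- min(within$end_index - 1L, n)
  }
  seg <- flexion[lo:hi]
  peak <- lo + which.max(seg) - 1L
  if (peak == lo) {
    stop("empty eccentric phase: flexion maximum at the first sample",
         call. = FALSE)
  }
  phase_interval(lo, peak + 1L, kind = "eccentric", n_samples = n)
}

#' Non-sagittal knee angles at the critical flexion angle
#'
#' Finds the first rising crossing of the critical flexion angle inside the
#' given phase and linearly interpolates the frontal (adduction) and
#' transverse (internal-rotation) angles at the exact crossing fraction. If a
#' sample hits the critical angle exactly (with rising flexion around it),
#' that sample's angles are returned.
#'
#' @param tr An `hmp_trial`.
#' @param phase A `phase_interval` to search in (typically the eccentric
#'   phase).
#' @param critical_deg Critical flexion angle in degrees (default 40).
#' @return Named numeric vector `(frontal_deg, transverse_deg)` plus
#'   attribute `crossing_time_s`.
#' @export
angles_at_critical_flexion <- function(tr, phase, critical_deg = 40) {
  stopifnot(inherits(tr, "hmp_trial"), inherits(phase, "phase_interval"))
  f <- unwrap_deg(tr$flexion_deg)
  fr <- unwrap_deg(tr$adduction_deg)
  tv <- unwrap_deg(tr$int_rot_deg)
  lo <- phase$start_index
  hi <- min(phase$end_index - 1L, length(f))
  for (i in lo:hi) {
    if (f[i] == critical_deg) {
      rising <- (i > lo && f[i] > f[i - 1L]) || (i < hi && f[i + 1L] > f[i])
      if (rising) {
        out <- c(frontal_deg = fr[i], transverse_deg = tv[i])
        attr(out, "crossing_time_s") <- tr$time[i]
        return(out)
      }
    }
    if (i < hi && f[i] < critical_deg && f[i + 1L] > critical_deg) {
      u <- (critical_deg - f[i]) / (f[i + 1L] - f[i])
      out <- c(frontal_deg = fr[i] + u * (fr[i + 1L] - fr[i]),
               transverse_deg = tv[i] + u * (tv[i + 1L] - tv[i]))
      attr(out, "crossing_time_s") <- tr$time[i] + u * (tr$time[i + 1L] -
                                                          tr$time[i])
      return(out)
    }
  }
  stop(sprintf(
    "no rising crossing of %.6g deg flexion in trial %s/%s/%s",
    critical_deg, tr$subject_id, tr$movement_kind, tr$condition),
    call. = FALSE)
}

#' Zero-phase low-pass filter
#'
#' Applies a squared 'Butterworth'-magnitude response
#' `|H(f)|^2 = 1 / (1 + (f/fc)^(2 order))` in the frequency domain, which is
#' the gain of a forward-backward (zero-phase) Butterworth pass. The series is
#' reflection-padded to suppress edge ringing; length is preserved and no
#' phase shift is introduced.
#'
#' @param x Numeric series.
#' @param cutoff_Hz Cutoff frequency; must be below the Nyquist frequency.
#' @param rate_hz Sampling rate.
#' @param order Filter order (default 4).
#' @return Filtered series, same length as `x`.
#' @export
lowpass <- function(x, cutoff_Hz, rate_hz, order = 4L) {
  n <- length(x)
  if (cutoff_Hz >= rate_hz / 2) {
    stop(sprintf("cutoff %.6g Hz >= Nyquist %.6g Hz", cutoff_Hz, rate_hz / 2),
         call. = FALSE)
  }
  if (n < 4L) return(x)
  pad <- min(n - 1L, max(8L, ceiling(rate_hz / cutoff_Hz) * 4L))
  xp <- c(2 * x[1] - x[(pad + 1L):2L],           # reflected head
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])      # reflected tail
  m <- length(xp)
  freqs <- (seq_len(m) - 1L) / m * rate_hz
  freqs <- pmin(freqs, rate_hz - freqs)          # two-sided spectrum
  gain <- 1 / (1 + (freqs / cutoff_Hz)^(2L * order))
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}
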
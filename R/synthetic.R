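#' Planar magnetometer grid
#'
#' Describes the sensor array of a magnetocardiograph: a regular
#' `n_rows` x `n_cols` grid of coplanar sensors that report the magnetic field
#' component perpendicular to the sensor plane (the component measured over
#' the chest wall).  The default matches the common map format: a 6 x 6 grid
#' covering 0.20 m x 0.20 m, held `height_m` above the heart-centred origin.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param extent_m side length of the square sensor array in metres.
#' @param height_m height of the sensor plane above the dipole frame origin,
#'   in metres.
#' @return An object of class `sensor_grid` with a `positions` matrix
#'   (one row per sensor, columns x/y/z in metres, row-major grid order).
#' @export
#' @examples
#' g <- sensor_grid()
#' nrow(g$positions)  # 36
sensor_grid <- function(n_rows = 6L, n_cols = 6L, extent_m = 0.20,
                        height_m = 0.10) {
  stopifnot(n_rows >= 1, n_cols >= 1, extent_m > 0, height_m > 0)
  xs <- seq_lin(-extent_m / 2, extent_m / 2, n_cols)
  ys <- seq_lin(extent_m / 2, -extent_m / 2, n_rows)
  pos <- cbind(
    x = rep(xs, times = n_rows),
    y = rep(ys, each = n_cols),
    z = height_m
  )
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         extent_m = extent_m, height_m = height_m, positions = pos),
    class = "sensor_grid"
  )
}

#' Time-resolved equivalent dipole
#'
#' A single moving point magnetic dipole: at each time step it has a position
#' (metres, heart-centred frame) and a moment vector (arbitrary linear field
#' units; the downstream QRS-strength normalisation removes absolute scale).
#'
#' @param times_ms strictly increasing numeric vector of times in
#'   milliseconds from beat onset (length >= 2).
#' @param positions numeric matrix, one 3-vector row per time.
#' @param moments numeric matrix, one 3-vector row per time.
#' @return An object of class `dipole_trajectory`.
#' @export
dipole_trajectory <- function(times_ms, positions, moments) {
  positions <- as.matrix(positions)
  moments <- as.matrix(moments)
  n <- length(times_ms)
  if (n < 2L) stop("dipole_trajectory: need at least 2 time points")
  if (any(diff(times_ms) <= 0)) {
    stop("dipole_trajectory: times must be strictly increasing")
  }
  if (nrow(positions) != n || nrow(moments) != n ||
      ncol(positions) != 3L || ncol(moments) != 3L) {
    stop("dipole_trajectory: positions and moments must be n x 3 matrices ",
         "matching length(times_ms)")
  }
  structure(
    list(times_ms = as.numeric(times_ms), positions = positions,
         moments = moments),
    class = "dipole_trajectory"
  )
}

# Linear interpolation of the trajectory state at arbitrary times (ms).
# Returns list(positions, moments) as length(t) x 3 matrices.
interp_trajectory <- function(traj, t_ms) {
  rng <- range(traj$times_ms)
  if (any(t_ms < rng[1] | t_ms > rng[2])) {
    stop("forward_field: evaluation time outside trajectory span [",
         rng[1], ", ", rng[2], "] ms")
  }
  interp_col <- function(m, j) {
    stats::approx(traj$times_ms, m[, j], xout = t_ms, method = "linear")$y
  }
  list(
    positions = cbind(interp_col(traj$positions, 1),
                      interp_col(traj$positions, 2),
                      interp_col(traj$positions, 3)),
    moments = cbind(interp_col(traj$moments, 1),
                    interp_col(traj$moments, 2),
                    interp_col(traj$moments, 3))
  )
}

#' Perpendicular dipole field at the sensor grid
#'
#' Evaluates the magnetostatic field of the point dipole at time `t_ms` and
#' returns the component perpendicular to the sensor plane at every sensor:
#' `Bz = 3 z_r (m . r) / |r|^5 - m_z / |r|^3`, with `r` the vector from the
#' dipole to the sensor.  The vacuum permeability prefactor is omitted — field
#' values are in arbitrary linear units, which the map normalisation cancels.
#'
#' @param traj a [dipole_trajectory()].
#' @param grid a [sensor_grid()].
#' @param t_ms evaluation time in milliseconds; must lie within the
#'   trajectory's time span.
#' @return Numeric vector with one field value per sensor (grid row-major
#'   order).
#' @export
forward_field <- function(traj, grid, t_ms) {
  stopifnot(inherits(traj, "dipole_trajectory"), inherits(grid, "sensor_grid"),
            length(t_ms) == 1L)
  st <- interp_trajectory(traj, t_ms)
  dipole_bz(grid$positions, st$positions[1, ], st$moments[1, ])
}

# Bz of one dipole (pos, mom are 3-vectors) at many sensors (n x 3 matrix).
dipole_bz <- function(sensors, pos, mom) {
  r <- sweep(sensors, 2, pos, "-")
  r2 <- rowSums(r * r)
  mdotr <- r %*% mom
  as.vector(3 * r[, 3] * mdotr / r2^2.5 - mom[3] / r2^1.5)
}

# Field time-course for a whole trajectory: n_sensors x n_times matrix,
# evaluated exactly at the trajectory's own time grid (no interpolation).
# Vectorised over time per sensor; this is the generator's inner loop.
trajectory_field_matrix <- function(traj, grid) {
  pos <- traj$positions
  mom <- traj$moments
  sens <- grid$positions
  n_s <- nrow(sens)
  n_t <- nrow(pos)
  out <- matrix(0, n_s, n_t)
  for (j in seq_len(n_s)) {
    r1 <- sens[j, 1] - pos[, 1]
    r2c <- sens[j, 2] - pos[, 2]
    r3 <- sens[j, 3] - pos[, 3]
    rr <- r1 * r1 + r2c * r2c + r3 * r3
    mdotr <- mom[, 1] * r1 + mom[, 2] * r2c + mom[, 3] * r3
    out[j, ] <- 3 * r3 * mdotr / rr^2.5 - mom[, 3] / rr^1.5
  }
  out
}

#' Synthetic cohort specification
#'
#' Collects every tunable of the synthetic magnetocardiogram generator.  The
#' defaults emulate the structure of a single-centre myocarditis case-control
#' study: 57 healthy controls versus 40 pathology subjects, 30 beats per
#' subject at 1,000 Hz (a 30-second resting recording at ~70 bpm), a tightly
#' clustered healthy group and a pathology group whose ventricular
#' repolarisation (STT-interval) field topology is perturbed in a
#' subject-specific direction.  Segment-length distributions are identical in
#' the two groups, so segment duration carries no class information.
#'
#' @param n_healthy,n_path group sizes.
#' @param effect_size magnitude of the pathology topology perturbation
#'   (dimensionless, >= 0; 0 makes the groups statistically exchangeable).
#' @param healthy_jitter inter-subject variability scale shared by both groups
#'   (dimensionless, >= 0).
#' @param beat_noise_sd standard deviation of i.i.d. Gaussian sensor noise per
#'   sample, in the generator's arbitrary field units (QRS peak amplitude is
#'   of order 1000 in those units).
#' @param n_beats beats per recording (>= 2 so that averaging is defined).
#' @param hr_mean_bpm,hr_sd_bpm mean and between-subject SD of resting heart
#'   rate; scalars apply to both groups, length-2 vectors give
#'   (healthy, pathology) values.
#' @param qrs_len_ms,stt_len_ms length-2 vectors `c(mean, sd)` of the
#'   between-subject QRS and STT segment-length distributions in ms (common to
#'   both groups).
#' @param pathology_target which segment the pathology perturbation acts on.
#' @param seed master seed; per-subject seeds are derived from it by a stable
#'   hash of the subject id, so extending a cohort never reshuffles existing
#'   subjects.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 57L, n_path = 40L,
                        effect_size = 2.0, healthy_jitter = 0.05,
                        beat_noise_sd = 900, n_beats = 30L,
                        hr_mean_bpm = 70, hr_sd_bpm = 6,
                        qrs_len_ms = c(90, 8), stt_len_ms = c(300, 30),
                        pathology_target = c("STT", "QRS"),
                        seed = 1L) {
  pathology_target <- match.arg(pathology_target)
  stopifnot(n_healthy >= 1, n_path >= 0, effect_size >= 0,
            healthy_jitter >= 0, beat_noise_sd >= 0, n_beats >= 2,
            all(hr_mean_bpm > 0), all(hr_sd_bpm >= 0),
            length(qrs_len_ms) == 2, length(stt_len_ms) == 2,
            qrs_len_ms[1] > 0, stt_len_ms[1] > 0)
  expand2 <- function(x) if (length(x) == 1L) c(x, x) else as.numeric(x[1:2])
  structure(
    list(n_healthy = as.integer(n_healthy), n_path = as.integer(n_path),
         effect_size = effect_size, healthy_jitter = healthy_jitter,
         beat_noise_sd = beat_noise_sd, n_beats = as.integer(n_beats),
         hr_mean_bpm = expand2(hr_mean_bpm), hr_sd_bpm = expand2(hr_sd_bpm),
         qrs_len_ms = as.numeric(qrs_len_ms),
         stt_len_ms = as.numeric(stt_len_ms),
         pathology_target = pathology_target,
         grid = sensor_grid(),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Rodrigues rotation of the rows of a matrix about unit axis `a` by angle `th`.
rotate_rows <- function(m, a, th) {
  if (th == 0) return(m)
  a <- a / sqrt(sum(a * a))
  ct <- cos(th); st <- sin(th)
  mdota <- m %*% a
  cross <- cbind(a[2] * m[, 3] - a[3] * m[, 2],
                 a[3] * m[, 1] - a[1] * m[, 3],
                 a[1] * m[, 2] - a[2] * m[, 1])
  m * ct + cross * st + outer(as.vector(mdota), a) * (1 - ct)
}

# Random unit 3-vector.
runit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v * v))
}

#' Per-subject equivalent-dipole beat template
#'
#' Draws one subject's dipole trajectory for a single 1,000-ms beat frame
#' (R peak at 332 ms from frame start, i.e. sample 333).  The moment has two
#' compact-support phases: a fast, large-moment rotation over the QRS window
#' and a slower, smaller-moment rotation over the STT window; the field is
#' exactly zero outside them, so concatenated beats never overlap.  Healthy
#' subjects are small i.i.d. perturbations (scale `healthy_jitter`) of one
#' canonical trajectory.  Pathology subjects additionally rotate and displace
#' the dipole during the target interval (default STT) about a
#' subject-specific random axis with magnitude set by `effect_size`, so
#' pathology maps differ from each other and not only from healthy maps.
#'
#' @param group `"healthy"` or `"pathology"`.
#' @param subject_seed integer seed for this subject's draws.
#' @param spec a [cohort_spec()].
#' @return A list with elements `trajectory` ([dipole_trajectory()]),
#'   `cursors_ms` (QRS onset/end, STT onset/end in ms relative to the R peak)
#'   and `r_ms` (R time within the 1,000-ms frame).
#' @export
synth_beat_template <- function(group = c("healthy", "pathology"),
                                subject_seed, spec) {
  group <- match.arg(group)
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(subject_seed, {
    j <- spec$healthy_jitter
    q_len <- max(60, min(140, stats::rnorm(1, spec$qrs_len_ms[1],
                                           spec$qrs_len_ms[2])))
    s_len <- max(180, min(420, stats::rnorm(1, spec$stt_len_ms[1],
                                            spec$stt_len_ms[2])))
    th0 <- -pi / 4 + stats::rnorm(1, 0, 0.3 * j)
    ph0 <- pi / 6 + stats::rnorm(1, 0, 0.3 * j)
    amp_q <- 1.0 * (1 + stats::rnorm(1, 0, j))
    amp_t <- 0.4 * (1 + stats::rnorm(1, 0, j))
    pos0 <- c(0, 0, 0) + stats::rnorm(3, 0, 0.010 * j)

    # pathology draw is always consumed so that effect_size = 0 reproduces
    # the healthy trajectory from the same seed.  The perturbation is an
    # in-plane (sensor-plane) rotation of the dipole moment during the target
    # interval, by a subject-specific angle uniform on (-pi, pi) at full
    # effect.  In-plane rotation relocates the field poles without changing
    # the pattern class, so pathology maps are each unique yet of the same
    # kind as healthy ones; and uniform angles cancel in the group mean, so
    # a pathology-built reference map loses the canonical pole topology.
    path_angle <- stats::runif(1, -pi, pi)

    r_ms <- 332
    q_on <- r_ms - 0.45 * q_len
    q_end <- q_on + q_len
    s_on <- q_end + 20
    s_end <- s_on + s_len

    # compact-support amplitude envelopes; they overhang the analysis cursors
    # by a few ms so the field is non-zero at the cursors themselves, yet
    # still vanish identically between beats (periods are >= 700 ms)
    t <- 0:999
    in_q <- t >= q_on - 8 & t <= q_end + 8
    in_s <- t >= s_on - 10 & t <= s_end + 10
    aq <- ifelse(in_q, sin(pi * (t - q_on + 8) / (q_len + 16))^2, 0)
    at <- ifelse(in_s, sin(pi * (t - s_on + 10) / (s_len + 20))^2, 0)
    th <- th0 + pi * (t - q_on) / q_len
    ph <- ph0 + 0.6 * (t - s_on) / s_len

    m_q <- cbind(cos(th), sin(th), 0.3) * (amp_q * aq)
    m_t <- cbind(cos(ph), sin(ph), 0) * (amp_t * at)

    pos <- matrix(rep(pos0, each = length(t)), ncol = 3)

    if (group == "pathology" && spec$effect_size > 0) {
      alpha <- min(spec$effect_size, 2) / 2 * path_angle
      if (spec$pathology_target == "STT") {
        m_t[in_s, ] <- rotate_rows(m_t[in_s, , drop = FALSE], c(0, 0, 1),
                                   alpha)
      } else {
        m_q[in_q, ] <- rotate_rows(m_q[in_q, , drop = FALSE], c(0, 0, 1),
                                   alpha)
      }
    }

    list(
      trajectory = dipole_trajectory(t, pos, m_q + m_t),
      cursors_ms = c(qrs_onset = q_on - r_ms, qrs_end = q_end - r_ms,
                     stt_onset = s_on - r_ms, stt_end = s_end - r_ms),
      r_ms = r_ms
    )
  })
}

#' Synthesize one multi-beat magnetocardiogram recording
#'
#' Renders the subject's beat template through the dipole forward model,
#' concatenates `n_beats` beats with heart-period jitter, and adds i.i.d.
#' Gaussian sensor noise.  Ground-truth R-peak positions and segment cursors
#' are carried in the result, mirroring the simultaneous ECG annotation used
#' to align real recordings.
#'
#' @param subject_id character id; the subject's seed is derived from it and
#'   the spec's master seed.
#' @param group `"healthy"` or `"pathology"`.
#' @param spec a [cohort_spec()].
#' @return An object of class `cmfm_recording`: `signal` (n_channels x
#'   n_samples), `fs_hz`, `r_peaks` (1-based sample indices), `cursors_ms`
#'   (QRS/STT onsets and ends in ms relative to the R peak), `subject_id`,
#'   `group`.
#' @export
synth_recording <- function(subject_id, group = c("healthy", "pathology"),
                            spec) {
  group <- match.arg(group)
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_beats < 2L) stop("synth_recording: n_beats must be >= 2")
  sseed <- subject_seed(spec$seed, subject_id)
  tmpl <- synth_beat_template(group, sseed, spec)
  field <- trajectory_field_matrix(tmpl$trajectory, spec$grid)  # 36 x 1000
  gi <- if (group == "healthy") 1L else 2L

  with_seed(sseed + 1L, {
    hr_subj <- max(40, stats::rnorm(1, spec$hr_mean_bpm[gi],
                                    spec$hr_sd_bpm[gi]))
    hr_beats <- pmax(40, stats::rnorm(spec$n_beats, hr_subj,
                                      spec$hr_sd_bpm[gi] / 2))
    periods <- pmax(700L, as.integer(round(60000 / hr_beats)))
    origins <- cumsum(c(1L, periods[-spec$n_beats]))
    n_samp <- origins[spec$n_beats] + 999L
    sig <- matrix(0, nrow(field), n_samp)
    for (k in seq_len(spec$n_beats)) {
      idx <- origins[k]:(origins[k] + 999L)
      sig[, idx] <- sig[, idx] + field
    }
    if (spec$beat_noise_sd > 0) {
      sig <- sig + stats::rnorm(length(sig), 0, spec$beat_noise_sd)
    }
    structure(
      list(subject_id = subject_id, group = group, signal = sig,
           fs_hz = 1000, r_peaks = origins + 332L,
           cursors_ms = tmpl$cursors_ms),
      class = "cmfm_recording"
    )
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param ids optional list with `healthy` and `pathology` character vectors
#'   of subject ids; defaults to `H01..` / `P01..`.
#' @return An object of class `mcg_cohort`: `recordings` (named list of
#'   [synth_recording()] results), `subjects` (data.frame of id and group)
#'   and the `spec`.
#' @export
simulate_cohort <- function(spec, ids = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(ids)) {
    ids <- list(
      healthy = sprintf("H%02d", seq_len(spec$n_healthy)),
      pathology = if (spec$n_path > 0) sprintf("P%02d", seq_len(spec$n_path))
                  else character(0)
    )
  }
  groups <- c(rep("healthy", length(ids$healthy)),
              rep("pathology", length(ids$pathology)))
  all_ids <- c(ids$healthy, ids$pathology)
  recs <- vector("list", length(all_ids))
  names(recs) <- all_ids
  for (i in seq_along(all_ids)) {
    recs[[i]] <- synth_recording(all_ids[i], groups[i], spec)
  }
  structure(
    list(recordings = recs,
         subjects = data.frame(subject_id = all_ids, group = groups,
                               stringsAsFactors = FALSE),
         spec = spec),
    class = "mcg_cohort"
  )
}

#' @export
print.mcg_cohort <- function(x, ...) {
  cat("Synthetic MCG cohort:", sum(x$subjects$group == "healthy"),
      "healthy /", sum(x$subjects$group == "pathology"), "pathology;",
      x$spec$n_beats, "beats/subject, effect size", x$spec$effect_size, "\n")
  invisible(x)
}
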
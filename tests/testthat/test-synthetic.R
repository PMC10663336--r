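test_that("forward field is linear in the dipole moment", {
  grid <- sensor_grid()
  tr0 <- dipole_trajectory(c(0, 10), matrix(0, 2, 3), matrix(0, 2, 3))
  expect_equal(forward_field(tr0, grid, 5), rep(0, 36))

  m <- c(0.3, -0.2, 0.5)
  tr1 <- dipole_trajectory(c(0, 10), matrix(0, 2, 3),
                           rbind(m, m))
  tr2 <- dipole_trajectory(c(0, 10), matrix(0, 2, 3),
                           rbind(2 * m, 2 * m))
  expect_equal(forward_field(tr2, grid, 3),
               2 * forward_field(tr1, grid, 3), tolerance = 1e-14)
})

test_that("forward field matches the closed-form point-dipole expression", {
  # single sensor directly above a vertical dipole at distance d: Bz = 2 m / d^3
  d <- 0.1
  grid1 <- sensor_grid(n_rows = 1, n_cols = 1, extent_m = 1e-9, height_m = d)
  m <- 0.7
  tr <- dipole_trajectory(c(0, 1), matrix(0, 2, 3),
                          rbind(c(0, 0, m), c(0, 0, m)))
  expect_equal(forward_field(tr, grid1, 0.5), 2 * m / d^3, tolerance = 1e-9)

  # tangential moment directly above the dipole: perpendicular component is 0
  expect_equal(
    mcgkle:::dipole_bz(matrix(c(0, 0, d), 1, 3), c(0, 0, 0), c(1, 0, 0)),
    0, tolerance = 1e-12)

  # generic off-axis sensor against the hand-expanded dipole equation
  sens <- c(0.10, 0.00, 0.10)
  mom <- c(0.3, -0.2, 0.5)
  r <- sens - c(0, 0, 0)
  rn <- sqrt(sum(r^2))
  expected <- 3 * r[3] * sum(mom * r) / rn^5 - mom[3] / rn^3
  got <- mcgkle:::dipole_bz(matrix(sens, 1, 3), c(0, 0, 0), mom)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("field evaluation outside the trajectory span errors", {
  tr <- dipole_trajectory(c(0, 10), matrix(0, 2, 3), matrix(1, 2, 3))
  expect_error(forward_field(tr, sensor_grid(), 11), "outside")
  expect_error(forward_field(tr, sensor_grid(), -1), "outside")
})

test_that("templates are reproducible and a null effect collapses the groups", {
  spec <- small_spec(effect_size = 0)
  t1 <- synth_beat_template("healthy", 123, spec)
  t2 <- synth_beat_template("healthy", 123, spec)
  expect_identical(t1, t2)

  tp <- synth_beat_template("pathology", 123, spec)
  expect_equal(tp$trajectory$moments, t1$trajectory$moments)
  expect_equal(tp$trajectory$positions, t1$trajectory$positions)

  # and with a non-zero effect the pathology trajectory does change
  spec2 <- small_spec(effect_size = 2)
  tp2 <- synth_beat_template("pathology", 123, spec2)
  expect_gt(max(abs(tp2$trajectory$moments - t1$trajectory$moments)), 0.01)
})

test_that("pathology maps differ from each other more than healthy maps do", {
  spec <- small_spec(n_healthy = 8, n_path = 2, effect_size = 2)
  tpeak_map <- function(group, id) {
    tmpl <- synth_beat_template(group, mcgkle:::subject_seed(spec$seed, id),
                                spec)
    tpk <- tmpl$r_ms + mean(tmpl$cursors_ms[c("stt_onset", "stt_end")])
    v <- forward_field(tmpl$trajectory, spec$grid, tpk)
    v / sqrt(sum(v^2))
  }
  healthy <- lapply(sprintf("H%02d", 1:8), tpeak_map, group = "healthy")
  path <- lapply(sprintf("P%02d", 1:2), tpeak_map, group = "pathology")
  hh <- combn(8, 2)
  d_hh <- apply(hh, 2, function(ij) {
    sqrt(sum((healthy[[ij[1]]] - healthy[[ij[2]]])^2))
  })
  d_pp <- sqrt(sum((path[[1]] - path[[2]])^2))
  expect_gt(d_pp, median(d_hh))
})

test_that("noiseless recordings average back to the beat template exactly", {
  spec <- small_spec(beat_noise_sd = 0, hr_sd_bpm = 0, n_beats = 3)
  rec <- synth_recording("H01", "healthy", spec)
  tmpl <- synth_beat_template("healthy",
                              mcgkle:::subject_seed(spec$seed, "H01"), spec)
  field <- mcgkle:::trajectory_field_matrix(tmpl$trajectory, spec$grid)
  avg <- average_beats(rec, baseline = FALSE)
  expect_equal(avg$B, field, tolerance = 1e-12)
  # the template is quiescent pre-QRS, so baseline correction changes nothing
  avg_bl <- average_beats(rec, baseline = TRUE)
  expect_equal(avg_bl$B, field, tolerance = 1e-12)
})

test_that("recording generation is deterministic and validates beat counts", {
  spec <- small_spec(beat_noise_sd = 150, seed = 9)
  r1 <- synth_recording("P01", "pathology", spec)
  r2 <- synth_recording("P01", "pathology", spec)
  expect_identical(r1, r2)
  expect_error(cohort_spec(n_beats = 1), "n_beats")

  coh1 <- simulate_cohort(small_spec(seed = 5, beat_noise_sd = 50))
  coh2 <- simulate_cohort(small_spec(seed = 5, beat_noise_sd = 50))
  expect_identical(coh1$recordings, coh2$recordings)
})

test_that("beat averaging attenuates sensor noise as 1/sqrt(n_beats)", {
  sd_noise <- 100
  n_beats <- 4
  reps <- 40
  avgs <- lapply(seq_len(reps), function(k) {
    spec <- small_spec(beat_noise_sd = sd_noise, n_beats = n_beats, seed = k)
    average_beats(synth_recording("H01", "healthy", spec),
                  baseline = FALSE)$B
  })
  # the deterministic template is identical across repeats (same subject id
  # and per-subject seed), so the across-repeat SD isolates the noise term
  arr <- simplify2array(avgs)
  cell_sd <- apply(arr, c(1, 2), sd)
  expect_equal(mean(cell_sd), sd_noise / sqrt(n_beats), tolerance = 0.15)
})

test_that("null cohorts are exchangeable: group tests hold their size", {
  reps <- 250
  alpha <- 0.05
  rejections <- vapply(seq_len(reps), function(rep) {
    spec <- cohort_spec(n_healthy = 12, n_path = 12, effect_size = 0,
                        n_beats = 2, seed = 1000 + rep)
    summary_of <- function(group, id) {
      tmpl <- synth_beat_template(group, mcgkle:::subject_seed(spec$seed, id),
                                  spec)
      tpk <- tmpl$r_ms + mean(tmpl$cursors_ms[c("stt_onset", "stt_end")])
      sum(abs(forward_field(tmpl$trajectory, spec$grid, tpk)))
    }
    h <- vapply(sprintf("H%02d", 1:12), summary_of, numeric(1),
                group = "healthy")
    p <- vapply(sprintf("P%02d", 1:12), summary_of, numeric(1),
                group = "pathology")
    mann_whitney(h, p)$p_value < alpha
  }, logical(1))
  expect_gte(mean(rejections), alpha - 0.03)
  expect_lte(mean(rejections), alpha + 0.03)
})
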
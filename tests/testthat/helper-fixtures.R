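# Shared fixtures: everything is generated in code at test time.

# Small, fast cohort spec for pipeline-level tests.
small_spec <- function(n_healthy = 6, n_path = 4, effect_size = 2,
                       beat_noise_sd = 0, n_beats = 4, seed = 42, ...) {
  cohort_spec(n_healthy = n_healthy, n_path = n_path,
              effect_size = effect_size, beat_noise_sd = beat_noise_sd,
              n_beats = n_beats, seed = seed, ...)
}

# Hand-built averaged map with a tiny QRS window: two positions whose QRS
# samples are {1,2,3} and {0,0,6}, giving a QRS-strength factor of exactly 2.
toy_gamma_map <- function() {
  B <- matrix(0, 2, 1000)
  B[1, 300:302] <- c(1, 2, 3)
  B[2, 300:302] <- c(0, 0, 6)
  B[, 400:500] <- 1  # non-trivial STT content
  mcgkle:::averaged_map(
    B,
    c(qrs_onset = 300, qrs_end = 302, stt_onset = 400, stt_end = 500),
    subject_id = "toy", r_index = 301L
  )
}

# Normalised averaged map with arbitrary smooth content and standard cursors.
synthetic_norm_map <- function(seed = 1, n_pos = 36) {
  set.seed(seed)
  t <- seq_len(1000)
  B <- t(sapply(seq_len(n_pos), function(i) {
    a <- rnorm(1, 1, 0.2)
    ph <- runif(1, 0, 2 * pi)
    a * sin(2 * pi * t / 400 + ph) + 0.1 * rnorm(1)
  }))
  m <- mcgkle:::averaged_map(
    B, c(qrs_onset = 290, qrs_end = 380, stt_onset = 400, stt_end = 700),
    subject_id = paste0("S", seed), r_index = 333L
  )
  normalize_map(m)
}

# Minimal hand-built recording: k beats pasted at given R peaks.
manual_recording <- function(beats, r_peaks, fs_hz = 1000,
                             subject_id = "M01", group = "healthy",
                             n_channels = NULL) {
  # beats: list of n_channels x 1000 windows, one per R peak
  n_channels <- n_channels %||% nrow(beats[[1]])
  n <- max(r_peaks) + 700L
  sig <- matrix(0, n_channels, n)
  for (k in seq_along(r_peaks)) {
    idx <- (r_peaks[k] - 332L):(r_peaks[k] + 667L)
    sig[, idx] <- sig[, idx] + beats[[k]]
  }
  structure(
    list(subject_id = subject_id, group = group, signal = sig, fs_hz = fs_hz,
         r_peaks = as.integer(r_peaks),
         cursors_ms = c(qrs_onset = -40, qrs_end = 50, stt_onset = 70,
                        stt_end = 370)),
    class = "cmfm_recording"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cohort -> per-subject normalised maps -> segment maps.
cohort_segments <- function(cohort, segment = "STT", mode = "resampled") {
  maps <- lapply(cohort$recordings,
                 function(r) normalize_map(average_beats(r)))
  lapply(maps, extract_segment, segment = segment, mode = mode)
}

# Independent brute-force KL oracle: plain accumulation loop, no vector maths.
kl_brute <- function(p, q) {
  acc <- 0
  for (i in seq_along(p)) acc <- acc + p[i] * log(p[i] / q[i])
  acc
}

# Independent exact Mann-Whitney oracle: U by pairwise counting, two-sided p
# by full enumeration of which ranks the first sample occupies.
mw_brute <- function(x, y) {
  U <- 0
  for (xi in x) for (yj in y) {
    U <- U + (xi > yj) + 0.5 * (xi == yj)
  }
  pooled <- c(x, y)
  n <- length(x)
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  mu <- length(x) * length(y) / 2
  p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
  list(U = U, p_value = p)
}
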
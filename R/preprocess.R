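#' Averaged cardiac magnetic field map
#'
#' Internal constructor for the common averaged-map format: 36 measurement
#' positions by 1,000 samples at 1,000 Hz with the R peak at sample 333
#' (1-based).  Cursors are stored as 1-based sample indices into the map.
#'
#' @keywords internal
averaged_map <- function(B, cursors, subject_id = NA_character_,
                         group = NA_character_, gamma = NA_real_,
                         normalized = FALSE, r_index = 333L) {
  B <- as.matrix(B)
  if (ncol(B) != 1000L) stop("averaged_map: expected 1000 samples, got ",
                             ncol(B))
  cursors <- as.integer(round(cursors[c("qrs_onset", "qrs_end",
                                        "stt_onset", "stt_end")]))
  names(cursors) <- c("qrs_onset", "qrs_end", "stt_onset", "stt_end")
  if (anyNA(cursors)) stop("averaged_map: incomplete cursors")
  with(as.list(cursors), {
    if (!(0 < qrs_onset && qrs_onset < qrs_end && qrs_end <= stt_onset &&
          stt_onset < stt_end && stt_end <= ncol(B))) {
      stop("averaged_map: cursor ordering violated: ",
           paste(names(cursors), cursors, sep = "=", collapse = ", "))
    }
  })
  if (!(cursors["qrs_onset"] < r_index && r_index < cursors["qrs_end"])) {
    stop("averaged_map: R index ", r_index, " not inside the QRS window")
  }
  structure(
    list(subject_id = subject_id, group = group, B = B, fs_hz = 1000,
         r_index = as.integer(r_index), cursors = cursors,
         gamma = gamma, normalized = normalized),
    class = "averaged_map"
  )
}

#' @export
print.averaged_map <- function(x, ...) {
  cat("Averaged CMFM", if (!is.na(x$subject_id)) paste0("[", x$subject_id, "]"),
      ":", nrow(x$B), "positions x", ncol(x$B), "samples,",
      if (x$normalized) "normalized" else "raw",
      sprintf("(gamma = %s)\n", format(x$gamma)))
  cat("  cursors (samples):",
      paste(names(x$cursors), x$cursors, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Resample every channel of a signal matrix onto a 1,000 Hz grid by linear
# interpolation.  Returns list(signal, r_peaks) with R peaks mapped to the
# nearest new sample.
resample_to_1khz <- function(signal, fs_hz, r_peaks) {
  if (fs_hz == 1000) return(list(signal = signal, r_peaks = r_peaks))
  if (fs_hz <= 0) stop("resample_to_1khz: invalid sampling frequency")
  n_old <- ncol(signal)
  t_old <- (seq_len(n_old) - 1) / fs_hz * 1000   # ms
  t_new <- seq(0, t_old[n_old], by = 1)          # 1 ms grid
  out <- matrix(0, nrow(signal), length(t_new))
  for (ch in seq_len(nrow(signal))) {
    out[ch, ] <- stats::approx(t_old, signal[ch, ], xout = t_new,
                               method = "linear")$y
  }
  new_r <- as.integer(round((r_peaks - 1) / fs_hz * 1000)) + 1L
  list(signal = out, r_peaks = new_r)
}

#' Beat-average a recording into the common map format
#'
#' Aligns all complete beat windows on their R peaks (333 samples up to and
#' including R, 667 after) and averages them per channel, improving the
#' signal-to-noise ratio by roughly the square root of the number of beats.
#' Input at a sampling rate other than 1,000 Hz is first linearly resampled
#' onto the 1,000 Hz grid.  Beats whose window would extend beyond the
#' recording are dropped (never zero-padded); the number dropped is reported
#' via a message.
#'
#' @param rec a `cmfm_recording` (from [synth_recording()] or
#'   [read_recording()]).
#' @param baseline if `TRUE` (default), subtract from each channel the mean of
#'   the first `baseline_window` samples of the averaged map (a pre-QRS
#'   quiescent stretch), removing slow offsets.
#' @param baseline_window number of leading samples used for the baseline
#'   estimate.
#' @return An `averaged_map` (36 x 1000, R at sample 333, un-normalised).
#' @export
average_beats <- function(rec, baseline = TRUE, baseline_window = 100L) {
  stopifnot(inherits(rec, "cmfm_recording"))
  rs <- resample_to_1khz(rec$signal, rec$fs_hz, rec$r_peaks)
  sig <- rs$signal
  r_peaks <- rs$r_peaks
  if (is.unsorted(r_peaks, strictly = TRUE)) {
    stop("average_beats: R peaks must be strictly increasing")
  }
  usable <- r_peaks - 332L >= 1L & r_peaks + 667L <= ncol(sig)
  if (sum(usable) < length(r_peaks)) {
    message("average_beats: dropped ", length(r_peaks) - sum(usable),
            " beat(s) with incomplete windows")
  }
  if (sum(usable) < 2L) {
    stop("average_beats: fewer than 2 usable beats; averaging undefined")
  }
  acc <- matrix(0, nrow(sig), 1000L)
  for (r in r_peaks[usable]) {
    acc <- acc + sig[, (r - 332L):(r + 667L)]
  }
  B <- acc / sum(usable)
  if (baseline) {
    bw <- seq_len(min(baseline_window, ncol(B)))
    B <- B - rowMeans(B[, bw, drop = FALSE])
  }
  # ms-relative cursors -> 1-based sample indices around R at sample 333
  cursors <- 333L + round(rec$cursors_ms)
  averaged_map(B, cursors, subject_id = rec$subject_id, group = rec$group)
}

#' QRS-strength normalisation factor
#'
#' The factor `gamma` is the mean absolute field strength over the QRS window
#' (closed interval from QRS onset to QRS end, inclusive at both cursors),
#' averaged over all 36 measurement positions:
#' `gamma = (1/36) * sum_i (1/t_QRS) * sum_t |B[i, t]|`.
#' Dividing a map by it compensates for fluctuations in the sensor-to-heart
#' distance between subjects and sessions.
#'
#' @param map an `averaged_map` (not yet normalised).
#' @return Non-negative scalar; zero only for an identically-zero QRS window.
#' @export
gamma_factor <- function(map) {
  stopifnot(inherits(map, "averaged_map"))
  on_s <- map$cursors[["qrs_onset"]]
  end_s <- map$cursors[["qrs_end"]]
  if (end_s <= on_s) stop("gamma_factor: degenerate QRS window")
  w <- map$B[, on_s:end_s, drop = FALSE]
  mean(rowMeans(abs(w)))
}

#' Normalise a map by its QRS strength
#'
#' Divides every sample by [gamma_factor()] and flags the map as normalised.
#' Idempotent: the recomputed factor of a normalised map is 1, so normalising
#' twice equals normalising once.  Any positive rescaling of the input yields
#' an identical normalised map.
#'
#' @param map an `averaged_map`.
#' @return The normalised `averaged_map` with `gamma` recorded.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "averaged_map"))
  if (isTRUE(map$normalized)) return(map)
  g <- gamma_factor(map)
  if (g <= 0) stop("normalize_map: gamma is zero (empty QRS window); ",
                   "cannot normalise")
  map$B <- map$B / g
  map$gamma <- g
  map$normalized <- TRUE
  map
}
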
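#' Extract a QRS or STT analysis window from an averaged map
#'
#' Two variants are supported.  Fixed mode takes a constant-duration excerpt
#' starting at the segment onset cursor: 80 samples (80 ms) for QRS, 250
#' samples for STT, with no interpolation.  Resampled mode takes the full
#' cursor-to-cursor segment (closed interval, both cursors included) and
#' linearly resamples each of the 36 channels onto `n_out` equispaced points
#' including both endpoints: 20 for QRS and 40 for STT.  Resampling removes
#' between-subject differences in segment duration and decorrelates
#' neighbouring time points, which the downstream discriminant analysis
#' assumes.
#'
#' @param map a normalised `averaged_map` (see [normalize_map()]).
#' @param segment `"QRS"` or `"STT"`.
#' @param mode `"fixed"` or `"resampled"`.
#' @param n_out override the output sample count (defaults: fixed 80/250,
#'   resampled 20/40 for QRS/STT).
#' @return An object of class `segment_maps`: `maps` (36 x n_out), `segment`,
#'   `mode`, `native_length_ms` (cursor-to-cursor duration before any
#'   truncation or resampling), `subject_id`, `group`.
#' @export
extract_segment <- function(map, segment = c("QRS", "STT"),
                            mode = c("fixed", "resampled"), n_out = NULL) {
  segment <- match.arg(segment)
  mode <- match.arg(mode)
  stopifnot(inherits(map, "averaged_map"))
  if (!isTRUE(map$normalized)) {
    stop("extract_segment: map must be normalised first (see normalize_map)")
  }
  cs <- map$cursors
  if (segment == "QRS") {
    onset <- cs[["qrs_onset"]]; end <- cs[["qrs_end"]]
    default_n <- if (mode == "fixed") 80L else 20L
  } else {
    onset <- cs[["stt_onset"]]; end <- cs[["stt_end"]]
    default_n <- if (mode == "fixed") 250L else 40L
  }
  if (is.null(n_out)) n_out <- default_n
  n_out <- as.integer(n_out)
  native_ms <- (end - onset) * 1000 / map$fs_hz

  if (mode == "fixed") {
    stop_s <- onset + n_out - 1L
    if (stop_s > ncol(map$B)) {
      stop("extract_segment: fixed ", segment, " window [", onset, ", ",
           stop_s, "] exceeds the map end (", ncol(map$B), " samples)")
    }
    maps <- map$B[, onset:stop_s, drop = FALSE]
  } else {
    if (end - onset < 1L) stop("extract_segment: degenerate ", segment,
                               " segment (fewer than 2 native samples)")
    native <- map$B[, onset:end, drop = FALSE]
    x_old <- seq_len(ncol(native))
    x_new <- seq_lin(1, ncol(native), n_out)
    maps <- t(apply(native, 1, function(ch) {
      stats::approx(x_old, ch, xout = x_new, method = "linear")$y
    }))
  }
  structure(
    list(subject_id = map$subject_id, group = map$group, segment = segment,
         mode = mode, maps = maps, native_length_ms = native_ms),
    class = "segment_maps"
  )
}

#' Maximum between-feature correlation within a segment
#'
#' Diagnostic for the discriminant analysis' independence assumption:
#' across subjects, computes Pearson correlations between the per-time-point
#' KLE features at distinct time points and reports the maximum absolute
#' off-diagonal value.  Reducing the per-segment sample count (resampled
#' mode) lowers this value; the published configuration (20 QRS / 40 STT
#' samples) was chosen to keep it below 0.2.  Feature pairs involving a
#' zero-variance time point are excluded with a warning.
#'
#' @param features a list of `kle_features` (one per subject) or a numeric
#'   matrix with one row per subject and one column per time point.
#' @param warn_threshold emit a warning when the maximum exceeds this value
#'   (default 0.2; set `NA` to disable).
#' @return A list: `max_abs` (scalar), `cor` (the full correlation matrix).
#' @export
intersample_correlation <- function(features, warn_threshold = 0.2) {
  X <- if (is.matrix(features)) features else feature_matrix_from_list(features)
  if (nrow(X) < 3L) stop("intersample_correlation: need >= 3 subjects")
  sds <- apply(X, 2, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate)) {
    warning("intersample_correlation: ", sum(degenerate),
            " zero-variance time point(s) excluded")
  }
  C <- suppressWarnings(stats::cor(X))
  C[degenerate, ] <- NA
  C[, degenerate] <- NA
  off <- abs(C)
  diag(off) <- NA
  max_abs <- if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  if (!is.na(warn_threshold) && isTRUE(max_abs > warn_threshold)) {
    warning(sprintf(
      "intersample_correlation: max |corr| = %.3f exceeds %.2f; consider a smaller per-segment sample count",
      max_abs, warn_threshold))
  }
  list(max_abs = max_abs, cor = C)
}

# Stack per-subject feature vectors (kle_features or plain numeric) into a
# subjects x time-points matrix.
feature_matrix_from_list <- function(features) {
  vecs <- lapply(features, function(f) {
    if (inherits(f, "kle_features")) f$values else as.numeric(f)
  })
  lens <- vapply(vecs, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("feature vectors have differing lengths")
  }
  do.call(rbind, vecs)
}

#' Between-group comparison of native segment lengths
#'
#' Two-sided Mann-Whitney U test on the cursor-to-cursor segment durations of
#' the two groups, plus per-group median and IQR.  Absence of a significant
#' length difference is the precondition for interpreting KLE differences as
#' topology rather than duration effects.
#'
#' @param lengths_ms numeric vector of native segment lengths in ms.
#' @param groups factor/character vector, `"healthy"` or `"pathology"`,
#'   parallel to `lengths_ms`.
#' @return A list: `p_value`, `U` (statistic for the pathology group),
#'   `summary` (data.frame of per-group n, median, IQR).
#' @export
segment_length_test <- function(lengths_ms, groups) {
  groups <- as.character(groups)
  stopifnot(length(lengths_ms) == length(groups))
  g <- split(lengths_ms, groups)
  if (length(g) != 2L || any(vapply(g, length, integer(1)) == 0L)) {
    stop("segment_length_test: need two non-empty groups")
  }
  ht <- mann_whitney(g[[1]], g[[2]])
  summary <- data.frame(
    group = names(g),
    n = vapply(g, length, integer(1)),
    median_ms = vapply(g, stats::median, numeric(1)),
    iqr_ms = vapply(g, stats::IQR, numeric(1)),
    row.names = NULL
  )
  list(p_value = ht$p_value, U = ht$U, summary = summary)
}

#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()] that reports the U statistic of
#' the first sample and the two-sided p-value.  The exact null distribution is
#' used when both groups have at most 20 observations and there are no ties;
#' otherwise the normal approximation with continuity and tie correction is
#' used.
#'
#' @param x,y numeric samples.
#' @return list with `U` and `p_value`.
#' @export
mann_whitney <- function(x, y) {
  exact <- length(x) <= 20 && length(y) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
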
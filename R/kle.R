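#' Convert a field-map time slice to a probability distribution
#'
#' The Kullback-Leibler entropy compares maps as distributions over the 36
#' measurement positions.  A signed field slice is converted by taking
#' absolute values (preserving the positions of the field poles, the
#' discriminative topology), adding a small smoothing mass, and normalising
#' to unit sum.  The smoothing constant is `eps` times the slice's maximum
#' absolute value, so the conversion is invariant to global rescaling.
#'
#' Alternative strategies: `"square"` (energy weighting, `b^2`) and
#' `"minshift"` (shift so the minimum is zero).  All share the same smoothing
#' and normalisation.
#'
#' @param b numeric vector of field values at one time point (one value per
#'   measurement position).
#' @param strategy conversion of signed fields to non-negative weights.
#' @param eps relative smoothing constant (default 1e-6).
#' @return Probability vector of the same length: strictly positive, sums
#'   to 1.
#' @export
to_distribution <- function(b, strategy = c("abs", "square", "minshift"),
                            eps = 1e-6) {
  strategy <- match.arg(strategy)
  b <- as.numeric(b)
  w <- switch(strategy,
              abs = abs(b),
              square = b^2,
              minshift = b - min(b))
  m <- max(w)
  if (m == 0) {
    stop("to_distribution: degenerate map slice (all weights zero)")
  }
  w <- w + eps * m
  w / sum(w)
}

#' Kullback-Leibler entropy between two distributions
#'
#' `KL(P, Q) = sum_i P_i * ln(P_i / Q_i)` over the measurement positions,
#' in nats.  Non-negative (Gibbs inequality), zero iff `P == Q`, and
#' asymmetric in its arguments: it is a statistical distance, not a metric.
#'
#' @param p,q probability vectors of equal length, each strictly positive
#'   and summing to 1 within 1e-9.
#' @return Non-negative scalar.
#' @export
kl_entropy <- function(p, q) {
  if (length(p) != length(q)) stop("kl_entropy: length mismatch")
  if (any(p <= 0) || any(q <= 0)) {
    stop("kl_entropy: distributions must be strictly positive")
  }
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("kl_entropy: inputs must sum to 1 (within 1e-9)")
  }
  sum(p * log(p / q))
}

# Columnwise KL over distribution matrices (positions x time points):
# returns one KL value per column.  Matrix form of kl_entropy used by the
# cross-validation inner loop.
kl_columns <- function(P, Q) {
  colSums(P * (log(P) - log(Q)))
}

# positions x time matrix -> columnwise distribution matrix
distribution_matrix <- function(maps, strategy = "abs", eps = 1e-6) {
  apply(maps, 2, to_distribution, strategy = strategy, eps = eps)
}

#' Build a group reference map
#'
#' The reference is the element-wise arithmetic mean of the segment maps of a
#' reference group (normally the healthy controls), computed on normalised
#' maps.  It is the `Q` against which every subject's map is scored.  The ids
#' it was built from are recorded so that cross-validation can verify the
#' held-out subject never leaks into its own reference.
#'
#' @param segments list of `segment_maps`, all with the same segment name and
#'   mode; at least 2 subjects.
#' @param group_label label of the group supplying the reference (metadata).
#' @return An object of class `reference_map`: `Q` (36 x n_out), `segment`,
#'   `mode`, `built_from`, `group_label`.
#' @export
build_reference <- function(segments, group_label = "healthy") {
  if (length(segments) < 2L) {
    stop("build_reference: need at least 2 subjects")
  }
  seg_names <- unique(vapply(segments, `[[`, character(1), "segment"))
  modes <- unique(vapply(segments, `[[`, character(1), "mode"))
  if (length(seg_names) != 1L || length(modes) != 1L) {
    stop("build_reference: mixed segments or modes: ",
         paste(seg_names, collapse = "/"), ", ", paste(modes, collapse = "/"))
  }
  dims <- vapply(segments, function(s) dim(s$maps), integer(2))
  if (any(dims != dims[, 1])) stop("build_reference: inconsistent map sizes")
  Q <- Reduce(`+`, lapply(segments, `[[`, "maps")) / length(segments)
  structure(
    list(segment = seg_names, mode = modes, Q = Q,
         built_from = vapply(segments, `[[`, character(1), "subject_id"),
         group_label = group_label),
    class = "reference_map"
  )
}

#' Per-time-point KLE features of a subject against a reference
#'
#' For each time point within the segment, the subject's map slice and the
#' reference slice are converted to distributions over the 36 positions and
#' their Kullback-Leibler entropy is computed, yielding one feature per time
#' point (80/250 fixed or 20/40 resampled for QRS/STT).  A subject identical
#' to the reference — or equal to it up to a positive scale factor — scores
#' exactly zero everywhere.
#'
#' @param seg the subject's `segment_maps`.
#' @param ref a `reference_map` with matching segment name, mode and size.
#' @param strategy,eps passed to [to_distribution()].
#' @return An object of class `kle_features`: `values` (numeric, length
#'   n_out), `segment`, `mode`, `subject_id`, `group`, `native_length_ms`.
#' @export
kle_features <- function(seg, ref, strategy = "abs", eps = 1e-6) {
  stopifnot(inherits(seg, "segment_maps"), inherits(ref, "reference_map"))
  if (seg$segment != ref$segment || seg$mode != ref$mode ||
      !all(dim(seg$maps) == dim(ref$Q))) {
    stop("kle_features: subject and reference segment/mode/size mismatch")
  }
  n_out <- ncol(seg$maps)
  vals <- numeric(n_out)
  for (t in seq_len(n_out)) {
    p <- tryCatch(
      to_distribution(seg$maps[, t], strategy = strategy, eps = eps),
      error = function(e) stop("kle_features: degenerate subject slice at ",
                               "time point ", t, ": ", conditionMessage(e))
    )
    q <- tryCatch(
      to_distribution(ref$Q[, t], strategy = strategy, eps = eps),
      error = function(e) stop("kle_features: degenerate reference slice at ",
                               "time point ", t, ": ", conditionMessage(e))
    )
    vals[t] <- kl_entropy(p, q)
  }
  structure(
    list(subject_id = seg$subject_id, group = seg$group,
         segment = seg$segment, mode = seg$mode, values = vals,
         native_length_ms = seg$native_length_ms),
    class = "kle_features"
  )
}
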
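#' Fisher linear discriminant for two classes
#'
#' Classical Fisher LDA with equal priors: the weight vector is
#' `w = S^-1 (mu1 - mu0)` with `S` the pooled within-class covariance, and
#' the decision threshold is the midpoint of the projected class means.  A
#' ridge term `S + lambda * trace(S)/p * I` keeps the fit defined when the
#' feature count approaches the training size (e.g. 40 STT features on a few
#' dozen subjects).  Fully deterministic.
#'
#' @param X numeric matrix, subjects x features.
#' @param y two-class labels parallel to the rows of `X`; the second factor
#'   level is treated as the positive class.
#' @param lambda ridge regularisation (>= 0, default 1e-3).
#' @return An object of class `lda_model`: `w`, `threshold`, `classes`,
#'   `means`, `lambda`.  Predict with [predict.lda_model()].
#' @export
lda_fit <- function(X, y, lambda = 1e-3) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("lda_fit: exactly two classes required, got ",
                             nlevels(y))
  if (anyNA(X)) stop("lda_fit: missing values in feature matrix")
  stopifnot(lambda >= 0, nrow(X) == length(y))
  cls <- levels(y)
  X0 <- X[y == cls[1], , drop = FALSE]
  X1 <- X[y == cls[2], , drop = FALSE]
  mu0 <- colMeans(X0)
  mu1 <- colMeans(X1)
  p <- ncol(X)
  scatter <- function(A, mu) {
    if (nrow(A) < 2L) return(matrix(0, p, p))
    crossprod(sweep(A, 2, mu))
  }
  S <- (scatter(X0, mu0) + scatter(X1, mu1)) / max(1L, nrow(X) - 2L)
  if (lambda > 0) {
    S <- S + diag(lambda * sum(diag(S)) / p, p)
  }
  w <- tryCatch(
    solve(S, mu1 - mu0),
    error = function(e) stop("lda_fit: pooled covariance is singular; ",
                             "set lambda > 0 to regularise")
  )
  structure(
    list(w = as.numeric(w),
         threshold = sum(w * (mu0 + mu1)) / 2,
         classes = cls, means = rbind(mu0, mu1), lambda = lambda),
    class = "lda_model"
  )
}

#' Predict classes or discriminant scores from a fitted LDA
#'
#' @param object an `lda_model`.
#' @param newdata numeric matrix (subjects x features) or vector (one
#'   subject).
#' @param type `"class"` for labels, `"score"` for the raw projection minus
#'   the threshold (positive values mean the positive class).
#' @param ... ignored.
#' @export
predict.lda_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  score <- as.numeric(as.matrix(newdata) %*% object$w) - object$threshold
  if (type == "score") return(score)
  object$classes[ifelse(score > 0, 2L, 1L)]
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Uses the pathology-positive convention: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/n.  Ratios with a zero
#' denominator are reported as `NA` with a warning, never silently as 0.
#'
#' @param tp,fn,tn,fp non-negative confusion counts.
#' @return A list: `sensitivity`, `specificity`, `accuracy`.
#' @export
classification_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("classification_metrics: negative counts")
  if (sum(counts) == 0) stop("classification_metrics: empty confusion matrix")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning("classification_metrics: ", what,
              " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  list(
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    accuracy = (tp + tn) / sum(counts)
  )
}

# Precompute the per-subject quantities the LOOCV inner loop needs for one
# feature set: distribution matrices and their entropy terms.
precompute_kle <- function(segments, strategy, eps) {
  lapply(segments, function(s) {
    P <- distribution_matrix(s$maps, strategy = strategy, eps = eps)
    list(maps = s$maps, P = P, plogp = colSums(P * log(P)))
  })
}

#' Leave-one-out cross-validated KLE/LDA classification
#'
#' The full published decision procedure, validated without leakage: for each
#' held-out subject, the reference map is rebuilt from the training-fold
#' members of the reference group only, every training subject's
#' per-time-point KLE features are recomputed against that reference, a
#' Fisher LDA is fitted on the training fold, and the held-out subject is
#' scored against the fold's own reference and model.  The held-out subject
#' therefore never influences the reference map or the discriminant.
#'
#' Feature sets from several segments (e.g. QRS + STT) are concatenated when
#' `segments` is a named list of per-subject lists.
#'
#' @param segments either a list of `segment_maps` (one per subject), or a
#'   named list of such lists sharing subject order (features concatenated).
#' @param groups optional label vector; defaults to the `group` field of the
#'   segment maps.
#' @param reference_group which group's training members supply the reference
#'   map (`"healthy"` for the published configuration; `"pathology"`
#'   reverses it).
#' @param positive_class label counted as positive for sensitivity (default
#'   `"pathology"`).
#' @param lambda ridge term for [lda_fit()].
#' @param strategy,eps distribution conversion, see [to_distribution()].
#' @param return_models if `TRUE`, attach the per-fold `lda_model` objects
#'   (used to audit that a held-out subject cannot influence its own fold).
#' @return An object of class `classification_report`: per-subject `truth`,
#'   `predicted`, `score`; confusion counts; `sensitivity`, `specificity`,
#'   `accuracy`; and a `config` fingerprint.
#' @export
kle_loocv <- function(segments, groups = NULL, reference_group = "healthy",
                      positive_class = "pathology", lambda = 1e-3,
                      strategy = "abs", eps = 1e-6, return_models = FALSE) {
  # normalise input to a named list of feature sets
  if (length(segments) && inherits(segments[[1]], "segment_maps")) {
    segments <- list(set1 = segments)
  }
  n <- length(segments[[1]])
  if (n < 3L) stop("kle_loocv: need at least 3 subjects")
  subj_ids <- vapply(segments[[1]], `[[`, character(1), "subject_id")
  if (is.null(groups)) {
    groups <- vapply(segments[[1]], `[[`, character(1), "group")
  }
  groups <- as.character(groups)
  if (length(unique(groups)) != 2L) {
    stop("kle_loocv: exactly two groups required")
  }
  if (!reference_group %in% groups) {
    stop("kle_loocv: reference group '", reference_group,
         "' not present in the cohort")
  }
  for (set in segments) {
    ids <- vapply(set, `[[`, character(1), "subject_id")
    if (!identical(ids, subj_ids)) {
      stop("kle_loocv: subject order differs between feature sets")
    }
  }
  pre <- lapply(segments, precompute_kle, strategy = strategy, eps = eps)
  segment_tags <- vapply(segments, function(set)
    paste0(set[[1]]$segment, ":", set[[1]]$mode), character(1))

  predicted <- character(n)
  scores <- numeric(n)
  models <- if (return_models) vector("list", n) else NULL
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    ref_idx <- train[groups[train] == reference_group]
    if (length(ref_idx) < 2L) {
      stop("kle_loocv: fewer than 2 reference-group subjects in fold ", i)
    }
    if (length(unique(groups[train])) < 2L) {
      stop("kle_loocv: single-class training set in fold ", i)
    }
    X <- matrix(0, n, 0)
    for (set in pre) {
      Qmap <- Reduce(`+`, lapply(set[ref_idx], `[[`, "maps")) /
        length(ref_idx)
      logQ <- log(distribution_matrix(Qmap, strategy = strategy, eps = eps))
      feats <- t(vapply(set, function(s) s$plogp - colSums(s$P * logQ),
                        numeric(ncol(logQ))))
      X <- cbind(X, feats)
    }
    model <- lda_fit(X[train, , drop = FALSE], groups[train], lambda = lambda)
    predicted[i] <- predict(model, X[i, , drop = FALSE])
    scores[i] <- predict(model, X[i, , drop = FALSE], type = "score")
    if (return_models) models[[i]] <- model
  }

  pos <- positive_class
  tp <- sum(predicted == pos & groups == pos)
  fn <- sum(predicted != pos & groups == pos)
  tn <- sum(predicted != pos & groups != pos)
  fp <- sum(predicted == pos & groups != pos)
  m <- classification_metrics(tp, fn, tn, fp)
  structure(
    list(subject_id = subj_ids, truth = groups, predicted = predicted,
         score = scores,
         confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
         sensitivity = m$sensitivity, specificity = m$specificity,
         accuracy = m$accuracy,
         models = models,
         config = list(segments = unname(segment_tags),
                       reference_group = reference_group,
                       positive_class = positive_class,
                       lambda = lambda, strategy = strategy, eps = eps)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("LOOCV KLE/LDA classification (", paste(x$config$segments,
      collapse = " + "), "; reference: ", x$config$reference_group, ")\n",
      sep = "")
  cat(sprintf("  n = %d | SN %.3f  SP %.3f  ACC %.3f\n",
              length(x$truth), x$sensitivity, x$specificity, x$accuracy))
  cat("  confusion:", paste(names(x$confusion), x$confusion, sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Principal component projection of a feature matrix
#'
#' Mean-centred PCA via singular value decomposition, with a fixed sign
#' convention (each component's largest-magnitude loading is positive) so
#' projections are reproducible across platforms.  Used to visualise the
#' tight healthy cluster versus the scattered pathology subjects in KLE
#' feature space.
#'
#' @param X numeric matrix, subjects x features.
#' @param n_components number of components (<= min(n_subjects, n_features)).
#' @return A list: `scores` (subjects x n_components), `loadings`,
#'   `explained` (variance fractions, length n_components).
#' @export
pca_project <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  if (n_components > min(dim(X))) {
    stop("pca_project: n_components exceeds min(n_subjects, n_features)")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  load <- pc$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    l <- load[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(pc$x[, k, drop = FALSE], 2, flip, `*`)
  total_var <- sum(pc$sdev^2)
  list(scores = scores, loadings = load,
       explained = pc$sdev[k]^2 / total_var)
}

#' Between-group heart-rate comparison
#'
#' Computes each subject's mean heart rate from the R-peak intervals of their
#' recording and compares the two groups with a two-sided Mann-Whitney U
#' test.  A significant difference would mean classification could ride on
#' sinus tachycardia (a known symptom) rather than on field-map topology, so
#' a non-significant result is the desired precondition.
#'
#' @param recordings list of `cmfm_recording` objects or an `mcg_cohort`.
#' @param groups optional label vector (defaults to each recording's group).
#' @return A list: `p_value`, `U`, `heart_rates_bpm` (per subject),
#'   `groups`.
#' @export
heart_rate_test <- function(recordings, groups = NULL) {
  if (inherits(recordings, "mcg_cohort")) recordings <- recordings$recordings
  hr <- vapply(recordings, function(r) {
    if (length(r$r_peaks) < 2L) {
      stop("heart_rate_test: subject ", r$subject_id,
           " has fewer than 2 R peaks")
    }
    intervals_ms <- diff(r$r_peaks) / r$fs_hz * 1000
    60000 / mean(intervals_ms)
  }, numeric(1))
  if (is.null(groups)) {
    groups <- vapply(recordings, `[[`, character(1), "group")
  }
  g <- split(hr, as.character(groups))
  if (length(g) != 2L || any(vapply(g, length, integer(1)) == 0L)) {
    stop("heart_rate_test: need two non-empty groups")
  }
  ht <- mann_whitney(g[[1]], g[[2]])
  list(p_value = ht$p_value, U = ht$U, heart_rates_bpm = hr, groups = groups)
}
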
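#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with defaults equal to the
#' published configuration: resampled QRS (20 samples) and STT (40 samples)
#' segments, absolute-value distribution conversion with relative smoothing
#' 1e-6, healthy-group reference, ridge 1e-3, baseline correction over the
#' first 100 samples, and a 0.2 warning threshold for the between-feature
#' correlation diagnostic.  Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    segments = c("QRS", "STT"),
    mode = "resampled",
    strategy = "abs",
    eps = 1e-6,
    lambda = 1e-3,
    baseline = TRUE,
    baseline_window = 100L,
    corr_warn_threshold = 0.2,
    reference_group = "healthy",
    positive_class = "pathology"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("pipeline_config: unknown option(s): ",
         paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "pipeline_config")
}

#' Configuration fingerprint
#'
#' Canonical single-line rendering of a [pipeline_config()], embedded in
#' every artefact so results can be traced to the settings that produced
#' them.
#'
#' @param config a `pipeline_config`.
#' @return character scalar.
#' @export
config_fingerprint <- function(config) {
  keys <- sort(names(config))
  paste(vapply(keys, function(k) {
    paste0(k, "=", paste(format(config[[k]]), collapse = ","))
  }, character(1)), collapse = "; ")
}

#' Run the full analysis pipeline
#'
#' Chains every stage on a cohort: beat averaging and QRS-strength
#' normalisation, segment extraction, per-time-point KLE features, LOOCV
#' LDA classification (each configured segment alone plus their
#' concatenation when there are several), the heart-rate confound test, the
#' segment-length comparison, the between-feature correlation diagnostic and
#' a 2-component PCA of the STT features.  Identical inputs produce
#' identical outputs; with `out_dir` set, the feature table, the report and
#' the PCA coordinates are persisted atomically.
#'
#' @param cohort an `mcg_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]), a [cohort_spec()] (simulated on the fly) or a
#'   manifest path.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artefacts (`features.csv`,
#'   `report.json`, `pca.csv`).
#' @return An object of class `pipeline_result`: `reports` (named list of
#'   `classification_report`), `features` (data.frame), `hr_test`,
#'   `length_tests`, `intersample`, `pca`, `config`, `fingerprint`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(cohort, "cohort_spec")) cohort <- simulate_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "mcg_cohort"))

  stage <- function(name, subject, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed",
           if (!is.null(subject)) paste0(" for subject ", subject), ": ",
           conditionMessage(e), call. = FALSE)
    })
  }

  maps <- lapply(cohort$recordings, function(rec) {
    stage("preprocess", rec$subject_id, {
      normalize_map(average_beats(rec, baseline = config$baseline,
                                  baseline_window = config$baseline_window))
    })
  })

  seg_sets <- lapply(config$segments, function(sg) {
    lapply(maps, function(m) {
      stage("segments", m$subject_id,
            extract_segment(m, segment = sg, mode = config$mode))
    })
  })
  names(seg_sets) <- config$segments

  groups <- vapply(maps, `[[`, character(1), "group")

  reports <- list()
  for (sg in config$segments) {
    reports[[sg]] <- stage(paste0("classify:", sg), NULL,
      kle_loocv(seg_sets[[sg]], reference_group = config$reference_group,
                positive_class = config$positive_class,
                lambda = config$lambda, strategy = config$strategy,
                eps = config$eps))
  }
  if (length(config$segments) > 1L) {
    joint <- paste(config$segments, collapse = "+")
    reports[[joint]] <- stage("classify:joint", NULL,
      kle_loocv(seg_sets, reference_group = config$reference_group,
                positive_class = config$positive_class,
                lambda = config$lambda, strategy = config$strategy,
                eps = config$eps))
  }

  hr_test <- stage("heart_rate", NULL, heart_rate_test(cohort))

  length_tests <- lapply(seg_sets, function(set) {
    segment_length_test(
      vapply(set, `[[`, numeric(1), "native_length_ms"),
      vapply(set, `[[`, character(1), "group")
    )
  })

  # descriptive features against the all-healthy reference (no held-out
  # subject; LOOCV above uses fold-wise references)
  feats <- list()
  intersample <- list()
  for (sg in config$segments) {
    ref <- build_reference(seg_sets[[sg]][groups == config$reference_group],
                           group_label = config$reference_group)
    f <- lapply(seg_sets[[sg]], kle_features, ref = ref,
                strategy = config$strategy, eps = config$eps)
    feats[[sg]] <- f
    intersample[[sg]] <- intersample_correlation(
      f, warn_threshold = config$corr_warn_threshold)
  }
  n_max <- max(vapply(feats, function(x) length(x[[1]]$values), integer(1)))
  canon <- c("subject_id", "group", "segment", "mode", "native_length_ms",
             sprintf("f_%d", seq_len(n_max)))
  features <- do.call(rbind, lapply(names(feats), function(sg) {
    tb <- features_table(feats[[sg]])
    # pad so QRS (20) and STT (40) rows can share one table
    for (cn in setdiff(canon, names(tb))) tb[[cn]] <- NA_real_
    tb[, canon]
  }))
  rownames(features) <- NULL

  pca_seg <- if ("STT" %in% config$segments) "STT" else config$segments[1]
  pca <- pca_project(feature_matrix_from_list(feats[[pca_seg]]),
                     n_components = 2L)

  result <- structure(
    list(reports = reports, features = features, hr_test = hr_test,
         length_tests = length_tests, intersample = intersample, pca = pca,
         subjects = cohort$subjects, config = config,
         fingerprint = config_fingerprint(config)),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    atomic_write(file.path(out_dir, "features.csv"), function(tmp) {
      data.table::fwrite(cbind(result$features,
                               fingerprint = result$fingerprint), tmp)
    })
    atomic_write(file.path(out_dir, "report.json"), function(tmp) {
      jsonlite::write_json(pipeline_report_json(result), tmp,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    atomic_write(file.path(out_dir, "pca.csv"), function(tmp) {
      data.table::fwrite(
        data.frame(subject_id = cohort$subjects$subject_id,
                   group = cohort$subjects$group,
                   pc1 = pca$scores[, 1], pc2 = pca$scores[, 2],
                   fingerprint = result$fingerprint),
        tmp)
    })
  }
  result
}

# JSON-serialisable view of a pipeline result
pipeline_report_json <- function(result) {
  list(
    fingerprint = result$fingerprint,
    classification = lapply(result$reports, function(r) {
      list(segments = r$config$segments,
           reference_group = r$config$reference_group,
           confusion = as.list(r$confusion),
           sensitivity = r$sensitivity, specificity = r$specificity,
           accuracy = r$accuracy,
           subjects = r$subject_id, truth = r$truth,
           predicted = r$predicted, score = r$score)
    }),
    heart_rate_p = result$hr_test$p_value,
    segment_length_p = lapply(result$length_tests, `[[`, "p_value"),
    max_intersample_correlation = lapply(result$intersample, `[[`, "max_abs"),
    pca_explained = result$pca$explained
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("KLE/LDA pipeline result (", nrow(x$subjects), " subjects)\n", sep = "")
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-10s SN %.3f  SP %.3f  ACC %.3f\n", nm,
                r$sensitivity, r$specificity, r$accuracy))
  }
  cat(sprintf("  heart-rate Mann-Whitney p = %.3f\n", x$hr_test$p_value))
  for (nm in names(x$length_tests)) {
    cat(sprintf("  %s length p = %.3f", nm, x$length_tests[[nm]]$p_value))
  }
  cat("\n")
  invisible(x)
}
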
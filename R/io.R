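#' Write a recording to a plain-text array file
#'
#' One tab-separated table per subject: one row per sample, one column per
#' channel (`ch01..ch36`, grid row-major order).  Written atomically
#' (temp-then-rename).
#'
#' @param rec a `cmfm_recording`.
#' @param path destination `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "cmfm_recording"))
  dt <- data.table::as.data.table(t(rec$signal))
  data.table::setnames(dt, sprintf("ch%02d", seq_len(nrow(rec$signal))))
  atomic_write(path, function(tmp) {
    data.table::fwrite(dt, tmp, sep = "\t")
  })
}

# Read one recording given its manifest row.
read_recording <- function(row, base_dir) {
  path <- file.path(base_dir, row$recording_path)
  dt <- data.table::fread(path, sep = "\t")
  sig <- t(as.matrix(dt))
  dimnames(sig) <- NULL
  structure(
    list(subject_id = row$subject_id, group = row$group,
         signal = sig, fs_hz = row$fs_hz,
         r_peaks = as.integer(strsplit(row$r_peaks, ";")[[1]]),
         cursors_ms = c(qrs_onset = row$qrs_onset_ms,
                        qrs_end = row$qrs_end_ms,
                        stt_onset = row$stt_onset_ms,
                        stt_end = row$stt_end_ms)),
    class = "cmfm_recording"
  )
}

manifest_columns <- c("subject_id", "group", "recording_path", "fs_hz",
                      "r_peaks", "qrs_onset_ms", "qrs_end_ms",
                      "stt_onset_ms", "stt_end_ms", "system_tag")

#' Write a cohort to disk (array files + manifest)
#'
#' Persists every recording as a per-subject TSV under `dir/recordings/` and
#' writes `dir/manifest.csv` with one row per subject: id, group, file path,
#' sampling rate, the R-peak sample list (semicolon-separated) and the four
#' segment cursors in milliseconds relative to the R peak.
#'
#' @param cohort an `mcg_cohort` (or any named list of `cmfm_recording`).
#' @param dir output directory (created if needed).
#' @param system_tag free-text tag recorded per subject.
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, system_tag = "synthetic") {
  recs <- if (inherits(cohort, "mcg_cohort")) cohort$recordings else cohort
  dir.create(file.path(dir, "recordings"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- lapply(recs, function(r) {
    rel <- file.path("recordings", paste0(r$subject_id, ".tsv"))
    write_recording(r, file.path(dir, rel))
    data.frame(subject_id = r$subject_id, group = r$group,
               recording_path = rel, fs_hz = r$fs_hz,
               r_peaks = paste(r$r_peaks, collapse = ";"),
               qrs_onset_ms = r$cursors_ms[["qrs_onset"]],
               qrs_end_ms = r$cursors_ms[["qrs_end"]],
               stt_onset_ms = r$cursors_ms[["stt_onset"]],
               stt_end_ms = r$cursors_ms[["stt_end"]],
               system_tag = system_tag,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  atomic_write(path, function(tmp) {
    data.table::fwrite(manifest, tmp)
  })
  invisible(path)
}

#' Validate a cohort manifest
#'
#' Checks the structural invariants a manifest must satisfy before the
#' pipeline will consume it: required columns present, unique subject ids,
#' recognised group labels, positive sampling rates, referenced recording
#' files existing, and well-ordered cursors.
#'
#' @param path path to a `manifest.csv`.
#' @param groups permitted group labels.
#' @return Character vector of violations, each naming the row and field;
#'   empty if the manifest is valid.
#' @export
validate_manifest <- function(path, groups = c("healthy", "pathology")) {
  if (!file.exists(path)) stop("validate_manifest: no such file: ", path)
  m <- data.table::fread(path, colClasses = list(character = "r_peaks"))
  v <- character(0)
  missing_cols <- setdiff(manifest_columns, names(m))
  if (length(missing_cols)) {
    return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  dup <- m$subject_id[duplicated(m$subject_id)]
  for (d in unique(dup)) v <- c(v, paste0("duplicate subject_id: ", d))
  base_dir <- dirname(path)
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    who <- paste0("row ", i, " (", row$subject_id, ")")
    if (!row$group %in% groups) {
      v <- c(v, paste0(who, ": unknown group '", row$group, "'"))
    }
    if (!file.exists(file.path(base_dir, row$recording_path))) {
      v <- c(v, paste0(who, ": missing recording file ", row$recording_path))
    }
    if (!is.finite(row$fs_hz) || row$fs_hz <= 0) {
      v <- c(v, paste0(who, ": invalid fs_hz"))
    }
    rp <- suppressWarnings(as.integer(strsplit(row$r_peaks, ";")[[1]]))
    if (length(rp) < 2L || anyNA(rp) || is.unsorted(rp, strictly = TRUE)) {
      v <- c(v, paste0(who, ": r_peaks must be >= 2 strictly increasing ",
                       "integers"))
    }
    if (!(row$qrs_onset_ms < row$qrs_end_ms &&
          row$qrs_end_ms <= row$stt_onset_ms &&
          row$stt_onset_ms < row$stt_end_ms)) {
      v <- c(v, paste0(who, ": cursor ordering violated"))
    }
  }
  v
}

#' Read a cohort from a manifest
#'
#' @param path path to a `manifest.csv` written by [write_cohort()] (or
#'   assembled by hand for imported data in the same layout).
#' @return An `mcg_cohort` (with `spec = NULL`).
#' @export
read_cohort <- function(path) {
  violations <- validate_manifest(path)
  if (length(violations)) {
    stop("read_cohort: invalid manifest:\n  ",
         paste(violations, collapse = "\n  "))
  }
  m <- data.table::fread(path, colClasses = list(character = "r_peaks"))
  base_dir <- dirname(path)
  recs <- lapply(seq_len(nrow(m)), function(i) read_recording(m[i, ], base_dir))
  names(recs) <- m$subject_id
  structure(
    list(recordings = recs,
         subjects = data.frame(subject_id = m$subject_id, group = m$group,
                               stringsAsFactors = FALSE),
         spec = NULL),
    class = "mcg_cohort"
  )
}

#' Write an averaged map with metadata sidecar
#'
#' The map is stored as a 1,000-row x 36-column tab-separated table (row =
#' sample, column = grid position in row-major order) with full `%.17g`
#' precision so that a write-read cycle reproduces the matrix bit-exactly.
#' Cursors, normalisation state and subject metadata go to a JSON sidecar
#' next to it.
#'
#' @param map an `averaged_map`.
#' @param path destination `.tsv`; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_averaged_map <- function(map, path) {
  stopifnot(inherits(map, "averaged_map"))
  atomic_write(path, function(tmp) {
    header <- paste(sprintf("pos%02d", seq_len(nrow(map$B))), collapse = "\t")
    lines <- apply(t(map$B), 1, function(r) {
      paste(sprintf("%.17g", r), collapse = "\t")
    })
    writeLines(c(header, lines), tmp)
  })
  meta <- list(subject_id = map$subject_id, group = map$group,
               fs_hz = map$fs_hz, r_index = map$r_index,
               cursors = as.list(map$cursors), gamma = map$gamma,
               normalized = map$normalized)
  atomic_write(paste0(path, ".json"), function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  })
  invisible(path)
}

#' Read an averaged map written by [write_averaged_map()]
#'
#' @param path the `.tsv` path (sidecar `<path>.json` must exist).
#' @return An `averaged_map`.
#' @export
read_averaged_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  B <- t(as.matrix(data.table::fread(path, sep = "\t")))
  dimnames(B) <- NULL
  map <- averaged_map(B, unlist(meta$cursors),
                      subject_id = meta$subject_id, group = meta$group,
                      gamma = if (is.null(meta$gamma)) NA_real_
                              else meta$gamma,
                      normalized = isTRUE(meta$normalized),
                      r_index = meta$r_index)
  map
}

#' Assemble a cohort KLE feature table
#'
#' @param features list of `kle_features` (one per subject, same segment and
#'   mode).
#' @return data.frame: subject_id, group, segment, mode, native_length_ms,
#'   then one `f_<t>` column per time point.
#' @export
features_table <- function(features) {
  stopifnot(length(features) >= 1L,
            all(vapply(features, inherits, logical(1), "kle_features")))
  X <- feature_matrix_from_list(features)
  colnames(X) <- sprintf("f_%d", seq_len(ncol(X)))
  cbind(
    data.frame(
      subject_id = vapply(features, `[[`, character(1), "subject_id"),
      group = vapply(features, `[[`, character(1), "group"),
      segment = vapply(features, `[[`, character(1), "segment"),
      mode = vapply(features, `[[`, character(1), "mode"),
      native_length_ms = vapply(features, `[[`, numeric(1),
                                "native_length_ms"),
      stringsAsFactors = FALSE
    ),
    as.data.frame(X)
  )
}
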
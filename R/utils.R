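#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit, so library internals never disturb a
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Stable integer hash of a character string
#'
#' Deterministic polynomial rolling hash over UTF-8 bytes, kept below 2^31 so
#' it is always a valid R integer seed.  Used to derive per-subject seeds from
#' a master seed, so adding subjects to a cohort never reshuffles the draws of
#' existing subjects.
#'
#' @param x character scalar.
#' @return integer in [0, 2^31 - 1].
#' @keywords internal
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# 32-bit helpers on doubles (all values kept in [0, 2^32); exact because
# intermediate products stay below 2^53).
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 +
    bitwXor(a %% 65536, b %% 65536)
}
mul32 <- function(a, b) {
  ((a %% 65536) * b + ((a %/% 65536) * (b %% 65536)) %% 65536 * 65536) %%
    4294967296
}

# murmur3 32-bit finalizer: avalanches every input bit so that structurally
# close inputs (consecutive subject numbers) land on unrelated seeds.  Plain
# arithmetic on nearby integers must not be fed to set.seed: streams from
# blocks of consecutive seeds carry small cross-correlations that are enough
# to bias cohort-level rank tests.
fmix32 <- function(h) {
  h <- h %% 4294967296
  h <- xor32(h, h %/% 65536)
  h <- mul32(h, 2246822507)
  h <- xor32(h, h %/% 8192)
  h <- mul32(h, 3266489909)
  xor32(h, h %/% 65536)
}

# Per-subject seed: the master seed and the subject-id hash are each
# avalanched, combined, and avalanched again; the result is reduced below
# 2^31 so it is always a valid set.seed argument.
subject_seed <- function(master_seed, subject_id) {
  x <- fmix32(as.numeric(master_seed))
  y <- fmix32(stable_hash(subject_id))
  as.integer(fmix32(xor32(x, y)) %% 2147483647)
}

#' Atomic file write
#'
#' Runs `writer(tmp_path)` against a temporary file in the destination
#' directory, then renames it into place, so an interrupted run never leaves a
#' truncated artefact.
#'
#' @param path final destination path.
#' @param writer function of one argument (the temporary path) that writes the
#'   content.
#' @return `path`, invisibly.
#' @keywords internal
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("atomic_write: failed to rename temporary file onto ", path)
  }
  invisible(path)
}

# linspace-style grid including both endpoints
seq_lin <- function(from, to, n) seq(from, to, length.out = n)
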
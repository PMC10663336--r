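test_that("Fisher LDA recovers the discriminant direction and threshold", {
  # isotropic classes: w is parallel to the mean difference
  set.seed(40)
  n <- 200
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(6, 2), `+`))
  y <- rep(c("healthy", "pathology"), each = n)
  fit <- lda_fit(X, y, lambda = 0)
  dmu <- c(6, 2) / sqrt(sum(c(6, 2)^2))
  cosine <- sum(fit$w * dmu) / sqrt(sum(fit$w^2))
  expect_gt(abs(cosine), 0.99)
  expect_equal(predict(fit, c(6, 2)), "pathology")
  expect_equal(predict(fit, c(0, 0)), "healthy")

  # 1-D worked example: midpoint threshold at 5.5, perfect training split
  fit1 <- lda_fit(matrix(c(0, 1, 10, 11), 4, 1),
                  c("a", "a", "b", "b"), lambda = 0)
  expect_equal(fit1$threshold / fit1$w, 5.5)
  expect_equal(predict(fit1, matrix(c(0, 1, 10, 11), 4, 1)),
               c("a", "a", "b", "b"))
})

test_that("the discriminant direction matches an independent LDA fit", {
  set.seed(46)
  n <- 150
  X <- rbind(matrix(rnorm(4 * n), n, 4) %*% diag(c(1, 2, 0.5, 1)),
             sweep(matrix(rnorm(4 * n), n, 4) %*% diag(c(1, 2, 0.5, 1)),
                   2, c(2, 1, -1, 0.5), `+`))
  y <- rep(c("healthy", "pathology"), each = n)
  w <- lda_fit(X, y, lambda = 0)$w
  w_ref <- as.numeric(MASS::lda(X, grouping = y)$scaling[, 1])
  cosine <- sum(w * w_ref) / sqrt(sum(w^2) * sum(w_ref^2))
  expect_gt(abs(cosine), 0.9999)
})

test_that("identical class means give chance-level discrimination", {
  set.seed(41)
  X <- matrix(rnorm(120 * 3), 120, 3)
  y <- rep(c("healthy", "pathology"), 60)
  fit <- lda_fit(X, y)
  acc <- mean(predict(fit, X) == y)
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
})

test_that("a singular pooled covariance demands regularisation", {
  v <- c(0, 1, 10, 11)
  X <- cbind(v, v)  # duplicated feature: rank-1 scatter
  y <- c("a", "a", "b", "b")
  expect_error(lda_fit(X, y, lambda = 0), "singular")
  fit <- lda_fit(X, y, lambda = 1e-3)
  expect_true(all(is.finite(fit$w)))
  expect_equal(predict(fit, X), y)
})

test_that("classification metrics follow the standard definitions", {
  expect_equal(classification_metrics(5, 0, 5, 0),
               list(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_equal(classification_metrics(0, 5, 0, 5),
               list(sensitivity = 0, specificity = 0, accuracy = 0))
  m <- classification_metrics(3, 1, 8, 2)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 11 / 14)
  m2 <- classification_metrics(29, 6, 17, 3)
  expect_equal(m2$sensitivity, 29 / 35, tolerance = 1e-12)
  expect_equal(m2$specificity, 0.85)
  expect_equal(m2$accuracy, 46 / 55, tolerance = 1e-12)

  expect_error(classification_metrics(-1, 0, 1, 0), "negative")
  expect_warning(m3 <- classification_metrics(0, 0, 3, 1), "sensitivity")
  expect_true(is.na(m3$sensitivity))
  expect_equal(m3$accuracy, 0.75)
})

test_that("a separable cohort cross-validates perfectly", {
  # constructed segment maps: a tight healthy cluster around one field
  # pattern, and pathology subjects whose pole pattern is relocated
  # subject-specifically — separable by construction
  set.seed(45)
  base <- matrix(rnorm(36 * 40), 36, 40)
  mk <- function(id, group, maps) {
    structure(list(subject_id = id, group = group, segment = "STT",
                   mode = "resampled", maps = maps, native_length_ms = 300),
              class = "segment_maps")
  }
  segs <- c(
    lapply(1:6, function(i) mk(paste0("H", i), "healthy",
                               base + 0.01 * matrix(rnorm(36 * 40), 36))),
    lapply(1:4, function(i) mk(paste0("P", i), "pathology",
                               base[sample(36), ] +
                                 0.01 * matrix(rnorm(36 * 40), 36)))
  )
  rep <- kle_loocv(segs)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(unname(rep$confusion), c(4L, 0L, 6L, 0L))

  # metrics equal a brute recount of the per-subject predictions
  expect_equal(rep$accuracy, mean(rep$predicted == rep$truth))
})

test_that("cross-validation is deterministic and leakage-free", {
  cohort <- simulate_cohort(small_spec(n_healthy = 6, n_path = 4,
                                       effect_size = 1.5,
                                       beat_noise_sd = 150, seed = 51))
  segs <- cohort_segments(cohort, "STT", "resampled")
  r1 <- kle_loocv(segs, return_models = TRUE)
  r2 <- kle_loocv(segs, return_models = TRUE)
  expect_identical(r1, r2)

  # sentinel: perturbing only the held-out subject leaves that fold's model
  # bit-identical (its data enter neither the reference nor the LDA fit)
  for (i in c(2L, 8L)) {
    pert <- segs
    pert[[i]]$maps <- pert[[i]]$maps * 5 + 0.37
    rp <- kle_loocv(pert, return_models = TRUE)
    expect_identical(rp$models[[i]], r1$models[[i]])
  }
})

test_that("permuted labels classify at chance", {
  cohort <- simulate_cohort(small_spec(n_healthy = 8, n_path = 8,
                                       effect_size = 2,
                                       beat_noise_sd = 150, seed = 52))
  segs <- cohort_segments(cohort, "STT", "resampled")
  set.seed(53)
  accs <- vapply(1:12, function(i) {
    perm <- sample(vapply(segs, `[[`, character(1), "group"))
    kle_loocv(segs, groups = perm)$accuracy
  }, numeric(1))
  # binomial chance band for n = 16 subjects, 12 permutations
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("PCA projection is variance-ordered with a fixed sign convention", {
  # collinear data: one component carries all variance
  set.seed(42)
  t <- rnorm(30)
  X <- cbind(2 * t, -t, 0.5 * t)
  p <- pca_project(X, 2)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  expect_equal(p$explained[2], 0, tolerance = 1e-10)
  # largest-magnitude loading of each component is positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)

  # two points: a single non-zero direction along their difference
  X2 <- rbind(c(0, 0, 0), c(1, 2, 2))
  p2 <- pca_project(X2, 1)
  expect_equal(abs(p2$loadings[, 1]), c(1, 2, 2) / 3, tolerance = 1e-12)

  # isotropic noise spreads variance evenly
  set.seed(43)
  p3 <- pca_project(matrix(rnorm(4000 * 4), 4000, 4), 4)
  expect_true(all(abs(p3$explained - 0.25) < 0.05))

  expect_error(pca_project(X2, 3), "n_components")
})

test_that("heart-rate comparison uses exact rank statistics on R-peak data", {
  rec_with_hr <- function(id, group, bpm) {
    period <- round(60000 / bpm)
    structure(
      list(subject_id = id, group = group,
           signal = matrix(0, 1, 10), fs_hz = 1000,
           r_peaks = cumsum(rep(period, 5)),
           cursors_ms = c(qrs_onset = -40, qrs_end = 50, stt_onset = 70,
                          stt_end = 370)),
      class = "cmfm_recording"
    )
  }
  recs <- c(
    lapply(1:3, function(i) rec_with_hr(paste0("H", i), "healthy", 59 + i)),
    lapply(1:3, function(i) rec_with_hr(paste0("P", i), "pathology", 89 + i))
  )
  ht <- heart_rate_test(recs)
  expect_equal(ht$p_value, 0.1)
  expect_equal(sort(round(ht$heart_rates_bpm)), c(60, 61, 62, 90, 91, 92))

  same <- c(lapply(1:3, function(i) rec_with_hr(paste0("H", i), "healthy",
                                                60 + i)),
            lapply(1:3, function(i) rec_with_hr(paste0("P", i), "pathology",
                                                60 + i)))
  expect_gt(heart_rate_test(same)$p_value, 0.99)

  bad <- recs
  bad[[1]]$r_peaks <- bad[[1]]$r_peaks[1]
  expect_error(heart_rate_test(bad), "fewer than 2 R peaks")
})

test_that("the U statistic matches a brute-force pairwise count", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    m <- sample(3:8, 1)
    pool <- sample(seq_len(100), n + m)  # tie-free by construction
    x <- pool[seq_len(n)]
    y <- pool[-seq_len(n)]
    got <- mann_whitney(x, y)
    oracle <- mw_brute(x, y)
    expect_equal(got$U, oracle$U)
    expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12)
  }
})
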
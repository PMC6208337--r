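# Pearson co-localization, ROC/AUC, balanced subsampling, group summaries.

test_that("Pearson correlation matches the direct-formula oracle", {
  x <- c(1, 2, 3, 4)
  ref <- c(1, 3, 2, 5)
  res <- pearson_colocalization(matrix(x, ncol = 1), ref)
  expect_equal(res$r, pearson_direct(x, ref), tolerance = 1e-12)
  set.seed(14)
  X <- matrix(rnorm(200), ncol = 5)
  r2 <- pearson_colocalization(X, X[, 3])
  expect_equal(r2$r[r2$rank == 1], 1.0, tolerance = 1e-12)
  expect_equal(pearson_colocalization(matrix(-X[, 3], ncol = 1), X[, 3])$r,
               -1.0, tolerance = 1e-12)
  for (j in 1:5) {
    expect_equal(r2$r[which(abs(r2$center - j) < .5)],
                 pearson_direct(X[, j], X[, 3]), tolerance = 1e-12)
  }
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(15)
  x <- rnorm(60); ref <- rnorm(60)
  r0 <- pearson_colocalization(matrix(x, ncol = 1), ref)$r
  r1 <- pearson_colocalization(matrix(3 * x + 7, ncol = 1), 0.5 * ref - 2)$r
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("zero-variance intervals and constant references are handled", {
  X <- cbind(rep(1, 10), rnorm(10))
  res <- pearson_colocalization(X, seq_len(10))
  expect_true(res$zero_variance[res$center == 1])
  expect_equal(res$r[res$center == 1], 0)
  expect_error(pearson_colocalization(X, rep(2, 10)),
               class = "msi3d_input_error")
})

test_that("AUC reproduces hand-derived cases with tie handling", {
  sep <- roc_discriminative(matrix(c(1, 2, 3, 4, 5, 6), ncol = 1), 1:3, 4:6)
  expect_equal(sep$auc, 1.0)
  expect_equal(sep$direction, "B")
  ties <- roc_discriminative(matrix(c(1, 2, 3, 1, 2, 3), ncol = 1), 1:3, 4:6)
  expect_equal(ties$auc, 0.5)
  mixed <- roc_discriminative(matrix(c(1, 2, 3, 2, 3, 4), ncol = 1), 1:3, 4:6)
  expect_equal(mixed$auc, 7 / 9, tolerance = 1e-12)
  expect_equal(mixed$direction, "B")
})

test_that("AUC equals the exhaustive pair-counting oracle on random instances", {
  set.seed(16)
  for (k in 1:20) {
    nA <- sample(3:40, 1); nB <- sample(3:40, 1)
    vals <- sample(0:6, nA + nB, replace = TRUE) + # heavy ties
      ifelse(runif(nA + nB) < 0.5, 0, runif(nA + nB))
    res <- roc_discriminative(matrix(vals, ncol = 1), seq_len(nA),
                              nA + seq_len(nB))
    oracle <- auc_bruteforce(vals[seq_len(nA)], vals[nA + seq_len(nB)])
    expect_equal(res$auc, max(oracle, 1 - oracle), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(17)
  vals <- rexp(50)
  a <- 1:20; b <- 21:50
  r0 <- roc_discriminative(matrix(vals, ncol = 1), a, b)$auc
  r1 <- roc_discriminative(matrix(log(vals + 1), ncol = 1), a, b)$auc
  r2 <- roc_discriminative(matrix(vals^3, ncol = 1), a, b)$auc
  expect_equal(r0, r1, tolerance = 1e-12)
  expect_equal(r0, r2, tolerance = 1e-12)
})

test_that("ROC rejects empty or overlapping groups", {
  X <- matrix(rnorm(20), ncol = 1)
  expect_error(roc_discriminative(X, 1:5, 5:10), class = "msi3d_input_error")
  expect_error(roc_discriminative(X, integer(0), 1:5))
})

test_that("balanced subsampling draws equally and reproducibly", {
  s <- balanced_subsample(1:50, 101:150, 40, seed = 3)
  expect_length(s, 40L)
  expect_equal(sum(s <= 50), 20L)
  expect_identical(s, balanced_subsample(1:50, 101:150, 40, seed = 3))
  odd <- balanced_subsample(1:50, 101:150, 41, seed = 3)
  expect_equal(abs(sum(odd <= 50) - sum(odd > 50)), 1L)
  expect_error(balanced_subsample(1:3, 1:3, 100), class = "msi3d_input_error")
})

test_that("group summaries flag out-of-band pixels", {
  set.seed(18)
  v <- rnorm(200, 10, 1)
  v[7] <- 10 + 5 * sd(v) + 3
  g <- rep("one", 200)
  gs <- group_intensity_summary(matrix(v, ncol = 1), g, ci_level = 0.95)
  expect_true(7 %in% gs$outliers$row)
  expect_true(all(gs$summary$ci_lower <= gs$summary$mean))
  expect_true(all(gs$summary$mean <= gs$summary$ci_upper))
  const <- group_intensity_summary(matrix(rep(2, 10), ncol = 1),
                                   rep("g", 10))
  expect_equal(const$summary$ci_lower, const$summary$ci_upper)
  expect_equal(nrow(const$outliers), 0L)
})

test_that("margin ions peak in the lesion segment on the phantom", {
  ph <- phantom_day3()
  j <- which.min(abs(ph$features$centers - 426.3578))
  gs <- group_intensity_summary(ph$features$values[, j, drop = FALSE],
                                ph$segments)
  means <- setNames(gs$summary$mean, gs$summary$group)
  expect_true(names(which.max(means)) == "L")
})
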
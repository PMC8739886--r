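test_that("regional mean series averages vertices within each region", {
  ts <- rbind(c(1, 2), c(3, 4))
  atlas <- label_map(c(1L, 1L))
  out <- regional_mean_series(ts, atlas)
  expect_equal(out$values, matrix(c(2, 3), 1), ignore_attr = TRUE)

  # singleton region passes its series through unchanged
  ts2 <- rbind(c(1, 2, 3), c(9, 9, 9))
  out2 <- regional_mean_series(ts2, label_map(c(1L, 2L)))
  expect_equal(out2$values[1, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(out2$values[2, ], c(9, 9, 9), ignore_attr = TRUE)

  # 3-region toy atlas on 6 vertices vs loop-based oracle
  set.seed(1)
  ts3 <- matrix(rnorm(6 * 10), 6)
  atlas3 <- label_map(c(1L, 2L, 3L, 1L, 2L, 3L))
  out3 <- regional_mean_series(ts3, atlas3)
  for (k in 1:3) {
    expect_equal(out3$values[k, ],
                 colMeans(ts3[atlas3$labels == k, , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("regional means handle unlabeled and empty regions", {
  ts <- matrix(rnorm(4 * 6), 4)
  atlas <- label_map(c(1L, 1L, 0L, 3L), num_classes = 3L)
  expect_warning(out <- regional_mean_series(ts, atlas), "zero vertices")
  expect_equal(out$region_ids, c(1L, 3L))
  expect_error(regional_mean_series(ts, label_map(rep(0L, 4), num_classes = 2L)),
               "unlabeled")
})

test_that("regional means are invariant to vertex order within regions", {
  set.seed(3)
  ts <- matrix(rnorm(8 * 12), 8)
  atlas <- label_map(rep(1:2, each = 4))
  perm <- c(4:1, 8:5)
  out1 <- regional_mean_series(ts, atlas)
  out2 <- regional_mean_series(ts[perm, ], label_map(atlas$labels[perm]))
  expect_equal(out1$values, out2$values)
})

test_that("connectivity features are vertex-to-region Pearson correlations", {
  set.seed(7)
  base <- rnorm(20)
  ts <- rbind(base, -base, rnorm(20), rnorm(20))
  atlas <- label_map(c(1L, 2L, 2L, 2L))
  reg <- regional_mean_series(ts, atlas)
  cf <- connectivity_features(ts, reg)
  # vertex identical to its region's mean (singleton region): r = 1
  expect_equal(cf$values[1, 1], 1, tolerance = 1e-12)
  # negated series: r = -1
  expect_equal(cf$values[2, 1], -1, tolerance = 1e-12)
  expect_true(all(cf$values >= -1 & cf$values <= 1))

  # definitional covariance/(sd*sd) oracle entry-wise (4 vertices, 2 regions)
  for (i in 1:4) {
    for (k in 1:2) {
      expect_equal(cf$values[i, k],
                   stats::cor(ts[i, ], reg$values[k, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("flat series yield zero correlations with a warning", {
  ts <- rbind(rep(1, 10), rnorm(10), rnorm(10))
  atlas <- label_map(c(1L, 2L, 2L))
  reg <- suppressWarnings(regional_mean_series(ts, atlas))
  expect_warning(cf <- connectivity_features(ts, reg), "zero variance")
  expect_equal(cf$values[1, ], c(0, 0), ignore_attr = TRUE)
})

test_that("dual regression recovers a planted noiseless factor model", {
  set.seed(11)
  n <- 60; t_n <- 50; C <- 3
  G <- matrix(rnorm(n * C), n)
  S <- qr.Q(qr(matrix(rnorm(t_n * C), t_n)))[, 1:C] |> t()  # orthonormal rows
  ts <- G %*% S
  dr <- dual_regression(G, ts)
  expect_equal(dr$time_courses, S, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(dr$subject_maps, G, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("single constant group map gives a time course proportional to the spatial mean", {
  set.seed(12)
  ts <- matrix(rnorm(30 * 25), 30)
  dr <- dual_regression(matrix(1, 30, 1), ts)
  expect_equal(as.numeric(dr$time_courses), colMeans(ts), tolerance = 1e-10)
})

test_that("dual regression tolerates noise at SNR 10", {
  set.seed(13)
  n <- 80; t_n <- 60; C <- 3
  G <- matrix(rnorm(n * C), n)
  S <- t(qr.Q(qr(matrix(rnorm(t_n * C), t_n)))[, 1:C])
  signal <- G %*% S
  noise <- matrix(rnorm(n * t_n, sd = stats::sd(signal) / 10), n)
  dr <- dual_regression(G, signal + noise)
  for (c in 1:C) {
    expect_gt(abs(stats::cor(dr$subject_maps[, c], G[, c])), 0.95)
  }
})

test_that("rank-deficient group maps are rejected with the collinear column", {
  G <- cbind(1:10, 2 * (1:10), rnorm(10))
  expect_error(dual_regression(G, matrix(rnorm(10 * 20), 10)), "rank deficient")
})

test_that("feature assembly concatenates blocks with unique names", {
  n <- 15
  set.seed(2)
  conn <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("conn_", 1:5)))
  spect <- matrix(rnorm(n * 3), n)
  scal <- matrix(rnorm(n * 4), n, dimnames = list(NULL, c("thick", "curv", "sulc", "myel")))
  X <- assemble_features(conn, spect, scal)
  expect_equal(ncol(X), 12L)
  expect_equal(colnames(X)[1:5], paste0("conn_", 1:5))
  expect_equal(colnames(X)[6:8], paste0("spectral_", 1:3))

  # connectivity-only config: F = K
  expect_equal(ncol(assemble_features(conn)), 5L)

  # mismatched N and duplicate names are errors
  expect_error(assemble_features(conn, spect[1:10, ]), "disagree on N")
  scal2 <- scal; colnames(scal2)[1] <- "conn_1"
  expect_error(assemble_features(conn, scalars = scal2), "duplicate")
})

test_that("assembly is a pure function of its inputs", {
  set.seed(4)
  n <- 10
  conn <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("conn_", 1:3)))
  spect <- matrix(rnorm(n * 2), n)
  X1 <- assemble_features(conn, spect)
  X2 <- assemble_features(conn, spect)
  expect_identical(X1, X2)
})

test_that("train-fitted standardization z-scores the right blocks", {
  set.seed(5)
  n <- 40
  conn <- matrix(runif(n * 3, -1, 1), n, dimnames = list(NULL, paste0("conn_", 1:3)))
  scal <- matrix(rnorm(n * 2, mean = 50, sd = 9), n,
                 dimnames = list(NULL, c("thick", "myel")))
  X <- assemble_features(conn, scalars = scal)
  sc <- fit_feature_scaling(X, "auto")
  Xs <- apply_feature_scaling(X, sc)
  # standardized columns have train mean 0, sd 1
  expect_equal(colMeans(Xs[, c("thick", "myel")]), c(thick = 0, myel = 0),
               tolerance = 1e-12)
  expect_equal(apply(Xs[, c("thick", "myel")], 2, sd), c(thick = 1, myel = 1),
               tolerance = 1e-12)
  # correlation block untouched
  expect_identical(Xs[, 1:3], X[, 1:3])
  # the identical transform applies at test time (train statistics reused)
  Xtest <- X + 5
  Xtest_s <- apply_feature_scaling(Xtest, sc)
  expect_equal(Xtest_s[, "thick"], (Xtest[, "thick"] - sc$center[["thick"]]) / sc$scale[["thick"]])
})
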
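test_that("accuracy counts labeled vertices only", {
  t4 <- label_map(c(1L, 2L, 2L, 3L), num_classes = 3L)
  expect_equal(accuracy(t4, t4)$accuracy, 100)
  flipped <- label_map(c(2L, 3L, 3L, 1L), num_classes = 3L)
  expect_equal(accuracy(flipped, t4)$accuracy, 0)
  # 4 labeled vertices, 3 correct -> 75%
  p <- label_map(c(1L, 2L, 2L, 1L), num_classes = 3L)
  expect_equal(accuracy(p, t4)$accuracy, 75)
  # unlabeled truth vertices excluded
  t5 <- label_map(c(1L, 2L, 0L, 3L), num_classes = 3L)
  p5 <- label_map(c(1L, 2L, 3L, 3L), num_classes = 3L)
  res <- accuracy(p5, t5)
  expect_equal(res$accuracy, 100)
  expect_true(is.na(res$correct[3]))
  expect_error(accuracy(p5, label_map(rep(0L, 4), num_classes = 2L)), "no labeled")
})

test_that("Dice matches hand-counted overlaps", {
  n <- 8
  a <- label_map(c(rep(1L, 4), rep(2L, 4)))                   # J = {1,2,3,4}
  b <- label_map(c(2L, 2L, 1L, 1L, 1L, 1L, 2L, 2L))           # K = {3,4,5,6}
  expect_equal(dice(a, b, 1L), 0.5)
  expect_equal(dice(a, a, 1L), 1)
  disj <- label_map(c(rep(2L, 4), rep(1L, 4)))
  expect_equal(dice(a, disj, 1L), 0)
  # absent from both maps: undefined, reported missing
  expect_true(is.na(dice(a, b, 5L)))
  # symmetry
  expect_equal(dice(a, b, 1L), dice(b, a, 1L))
  expect_equal(dice(a, b, 2L), dice(b, a, 2L))
})

test_that("accuracy and Dice are invariant under consistent relabeling", {
  set.seed(15)
  a <- rand_label_map(30, 4, seed = 1)
  b <- rand_label_map(30, 4, seed = 2)
  perm <- c(3L, 1L, 4L, 2L)
  ap <- label_map(perm[a$labels], num_classes = 4L)
  bp <- label_map(perm[b$labels], num_classes = 4L)
  expect_equal(accuracy(a, b)$accuracy, accuracy(ap, bp)$accuracy)
  expect_equal(dice(a, b, 2L), dice(ap, bp, perm[2]))
})

test_that("boundary-distance error profile matches hand BFS on a path", {
  p5 <- path_graph(5)
  truth <- label_map(c(1L, 1L, 1L, 2L, 2L))
  # boundary vertices are 3 and 4; misclassification at vertex 3 is distance 0
  pred <- label_map(c(1L, 1L, 2L, 2L, 2L))
  bp <- boundary_error_profile(pred, truth, p5)
  expect_equal(bp$n_errors, 1L)
  expect_equal(bp$fractions, c("0" = 1))

  # error at vertex 1: two hops from the nearest boundary vertex (3)
  pred2 <- label_map(c(2L, 1L, 1L, 2L, 2L))
  bp2 <- boundary_error_profile(pred2, truth, p5)
  expect_equal(bp2$fractions, c("2" = 1))

  # perfect prediction: flagged empty, not an error
  bp3 <- boundary_error_profile(truth, truth, p5)
  expect_equal(bp3$n_errors, 0L)
  expect_length(bp3$fractions, 0)

  # single-label truth has no boundary
  expect_error(boundary_error_profile(pred, label_map(rep(1L, 5)), p5),
               "single label")
})

test_that("boundary profile fractions sum to one whenever errors exist", {
  g <- make_mesh(2, radial_noise_sd = 0.02, seed = 3)
  truth <- make_parcellation(g, 5, seed = 4)
  set.seed(16)
  noisy <- truth$labels
  flip <- sample.int(g$n_vertices, 30)
  noisy[flip] <- sample.int(5, 30, replace = TRUE)
  bp <- boundary_error_profile(label_map(noisy, num_classes = 5L), truth, g)
  expect_gt(bp$n_errors, 0L)
  expect_equal(sum(bp$fractions), 1, tolerance = 1e-12)
  expect_true(all(bp$fractions >= 0))
})

test_that("functional homogeneity follows the SVD variance fraction", {
  # identical series within the parcel: rank-1 correlation block, rho = 100
  base <- rnorm(30)
  ts <- rbind(base, base, rnorm(30), rnorm(30))
  parcels <- label_map(c(1L, 1L, 2L, 2L))
  fh <- functional_homogeneity(ts, parcels)
  expect_equal(fh$per_parcel[["1"]], 100, tolerance = 1e-8)

  # orthogonal equal-norm correlation rows: equal singular values, rho = 50
  # build 2 parcel vertices whose correlation rows are orthogonal with equal norm
  set.seed(17)
  t_n <- 50
  x <- rnorm(t_n); x <- x - mean(x)
  y <- rnorm(t_n); y <- y - mean(y)
  y <- y - x * sum(x * y) / sum(x * x)     # exactly decorrelated from x
  ts2 <- rbind(x, y, x, y, x, y)
  parcels2 <- label_map(c(1L, 1L, 2L, 2L, 2L, 2L))
  fh2 <- functional_homogeneity(ts2, parcels2)
  expect_equal(fh2$per_parcel[["1"]], 50, tolerance = 1e-8)

  # toy case against a dense SVD oracle
  set.seed(18)
  ts3 <- matrix(rnorm(6 * 40), 6)
  parcels3 <- label_map(c(1L, 1L, 1L, 2L, 2L, 2L))
  fh3 <- functional_homogeneity(ts3, parcels3)
  for (l in 1:2) {
    vs <- which(parcels3$labels == l)
    Rl <- stats::cor(t(ts3[vs, ]), t(ts3))
    sv <- svd(Rl)$d
    expect_equal(fh3$per_parcel[[as.character(l)]], 100 * sv[1]^2 / sum(sv^2),
                 tolerance = 1e-8)
  }
  expect_equal(fh3$mean, mean(fh3$per_parcel))
  expect_true(all(fh3$per_parcel > 0 & fh3$per_parcel <= 100))
})

test_that("single-vertex parcels are flagged at homogeneity 100", {
  ts <- matrix(rnorm(3 * 20), 3)
  expect_warning(fh <- functional_homogeneity(ts, label_map(c(1L, 2L, 2L))),
                 "single vertex")
  expect_equal(fh$per_parcel[["1"]], 100)
})

test_that("scalar homogeneity is the within/between variance ratio", {
  # constant within parcels, different means: ratio 0
  parcels <- label_map(c(1L, 1L, 2L, 2L))
  expect_equal(scalar_homogeneity(c(3, 3, 7, 7), parcels), 0)

  # hand variance computation: (0,2) and (10,12) -> 2/50 = 0.04
  f <- c(0, 2, 10, 12)
  expect_equal(scalar_homogeneity(f, parcels), 0.04)

  # scale and shift invariance
  expect_equal(scalar_homogeneity(5 * f, parcels), 0.04)
  expect_equal(scalar_homogeneity(f + 100, parcels), 0.04)

  # zero between-parcel variance: missing
  expect_true(is.na(scalar_homogeneity(c(0, 2, 0, 2), parcels)))
  expect_error(scalar_homogeneity(1:4, label_map(rep(1L, 4))), "at least 2 parcels")
})

test_that("consensus takes the modal label with smallest-id ties", {
  a <- label_map(c(5L, 5L), num_classes = 9L)
  b <- label_map(c(5L, 9L), num_classes = 9L)
  c_ <- label_map(c(9L, 9L), num_classes = 9L)
  expect_equal(consensus(list(a, a))$labels, a$labels)      # unanimity
  expect_equal(consensus(list(a, b, c_))$labels[1], 5L)     # majority (5,5,9)
  expect_equal(consensus(list(a, c_))$labels[1], 5L)        # tie (5,9) -> 5
})

test_that("mean probability maps average and threshold correctly", {
  p1 <- rbind(c(1, 0), c(0.5, 0.5))
  p2 <- rbind(c(1, 0), c(0.2, 0.8))
  res <- mean_probability_maps(list(p1))
  expect_equal(res$mean, p1)
  res2 <- mean_probability_maps(list(p1, p2), threshold = 0)
  expect_equal(res2$mean, (p1 + p2) / 2)
  expect_equal(res2$thresholded, res2$mean)   # threshold 0: no zeroing
  # agreeing one-hot stacks stay one-hot
  oh <- rbind(c(1, 0), c(0, 1))
  expect_equal(mean_probability_maps(list(oh, oh))$mean, oh)
  # default threshold 1/C zeroes sub-chance probabilities
  res3 <- mean_probability_maps(list(rbind(c(0.7, 0.3), c(0.4, 0.6))))
  expect_equal(res3$thresholded[1, ], c(0.7, 0))
  expect_error(mean_probability_maps(list(p1, matrix(1, 2, 3))), "disagree on C")
})

test_that("bootstrap standard error behaves analytically", {
  expect_equal(bootstrap_se(rep(80, 10), reps = 100, seed = 1), 0)
  expect_identical(bootstrap_se(c(60, 70, 80), reps = 50, seed = 9),
                   bootstrap_se(c(60, 70, 80), reps = 50, seed = 9))
  # resampled-mean SD equals sqrt(population variance / n) for large reps
  acc <- c(60, 70, 80)
  se <- bootstrap_se(acc, sample_size = 3, reps = 10000, seed = 2)
  pop_var <- mean((acc - mean(acc))^2)
  expect_equal(se, sqrt(pop_var / 3), tolerance = 0.02 * sqrt(pop_var / 3) + 0.05)
})
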
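# Distance-method unit tests run on raw gaussian clusters (gaussian_fm),
# isolating each metric from the preprocessing pipeline.

test_that("ED-PCA equals raw-space centroid distances (orthogonality)", {
  fm <- gaussian_fm(60, p = 15, shifts = c(0, 1, 0.4, 1.2, 0.2), seed = 21)
  prot <- flat_protocol(5)
  prof <- edpca_distances(fm, prot)
  # independent oracle: centroid distances straight in the input space
  oracle <- vapply(2:5, function(i) {
    sqrt(sum((colMeans(fm$x[fm$phase == 1, ]) - colMeans(fm$x[fm$phase == i, ]))^2))
  }, numeric(1))
  expect_equal(unname(prof$D), oracle, tolerance = 1e-8)
  expect_equal(sum(prof$diagnostics$explained_variance), 1)
})

test_that("ED-PCA: identical distributions give near-zero distance, shifts give delta*sqrt(p)", {
  fm0 <- gaussian_fm(4000, p = 6, shifts = c(0, 0), seed = 4)
  prof0 <- edpca_distances(fm0, flat_protocol(2))
  expect_lt(prof0$D[["2"]], 0.12)  # ~ sqrt(p/n) scale

  fm <- gaussian_fm(50, p = 15, shifts = c(0, 0), seed = 5)
  delta <- 0.8
  fm$x[fm$phase == 2, ] <- fm$x[fm$phase == 2, ] -
    outer(rep(1, 50), colMeans(fm$x[fm$phase == 2, ]) -
            colMeans(fm$x[fm$phase == 1, ])) + delta
  prof <- edpca_distances(fm, flat_protocol(2))
  expect_equal(prof$D[["2"]], delta * sqrt(15), tolerance = 1e-8)
})

test_that("ED-PCA distances are invariant under orthogonal rotation", {
  fm <- gaussian_fm(40, p = 8, shifts = c(0, 0.7, 0.3), seed = 6)
  prof <- edpca_distances(fm, flat_protocol(3))
  Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  fm2 <- feature_matrix(fm$x %*% Q, fm$phase, fm$subject_id, fm$fs)
  prof2 <- edpca_distances(fm2, flat_protocol(3))
  expect_equal(prof$D, prof2$D, tolerance = 1e-8)
  # baseline self-distance is zero by construction (centroid methods)
  cent <- colMeans(fm$x[fm$phase == 1, ])
  expect_equal(sqrt(sum((cent - cent)^2)), 0)
})

test_that("Mahalanobis with identity covariance is mean Euclidean distance", {
  fm <- gaussian_fm(30, p = 4, shifts = c(0, 1), seed = 8)
  prot <- flat_protocol(2)
  res <- mahalanobis_phase_distance(fm, prot, 2, cov_matrix = diag(4))
  rows2 <- fm$x[fm$phase == 2, ]
  c1 <- colMeans(fm$x[fm$phase == 1, ])
  expect_equal(res$D, mean(sqrt(rowSums(sweep(rows2, 2, c1)^2))), tolerance = 1e-10)
})

test_that("Mahalanobis agrees with a per-point direct-solve oracle and is affine-invariant", {
  fm <- gaussian_fm(40, p = 3, shifts = c(0, 0.9), seed = 9)
  prot <- flat_protocol(2)
  res <- mahalanobis_phase_distance(fm, prot, 2)
  # brute-force oracle: solve(S) per point
  pooled <- fm$x
  S <- cov(pooled)
  c1 <- colMeans(fm$x[fm$phase == 1, ])
  rows2 <- fm$x[fm$phase == 2, ]
  oracle <- mean(vapply(seq_len(nrow(rows2)), function(k) {
    v <- rows2[k, ] - c1
    sqrt(drop(t(v) %*% solve(S, v)))
  }, numeric(1)))
  expect_equal(res$D, oracle, tolerance = 1e-8)

  # invariance under invertible affine map x -> xA + b
  A <- matrix(c(2, 0.3, 0, 0.1, 1.5, 0, 0, -0.2, 0.7), 3, 3)
  b <- c(5, -2, 1)
  fm2 <- feature_matrix(sweep(fm$x %*% A, 2, b, "+"), fm$phase, fm$subject_id, fm$fs)
  res2 <- mahalanobis_phase_distance(fm2, prot, 2)
  expect_equal(res$D, res2$D, tolerance = 1e-8)
})

test_that("Mahalanobis self-scatter concentrates near the chi-distribution mean", {
  # both phases iid standard normal: mean distance -> E[chi_p]
  p <- 15L; n <- 3000L
  fm <- gaussian_fm(n, p = p, shifts = c(0, 0), seed = 10)
  res <- mahalanobis_phase_distance(fm, flat_protocol(2), 2)
  chi_mean <- sqrt(2) * gamma((p + 1) / 2) / gamma(p / 2)
  expect_equal(res$D, chi_mean, tolerance = 0.02)
})

test_that("near-singular covariance engages the ridge and stays finite", {
  fm <- gaussian_fm(40, p = 3, shifts = c(0, 1), seed = 11)
  x <- cbind(fm$x, fm$x[, 3])  # duplicated column -> singular covariance
  fm2 <- feature_matrix(x, fm$phase, fm$subject_id, fm$fs)
  res <- mahalanobis_phase_distance(fm2, flat_protocol(2), 2)
  expect_true(res$diagnostics$ridge)
  expect_true(is.finite(res$D))
  expect_error(mahalanobis_phase_distance(fm, flat_protocol(2), 7),
               class = "rsi_bad_input")
})

test_that("silhouette matches the hand-computed four-point value", {
  fm <- feature_matrix(matrix(c(0, 1, 10, 11), 4, 1), c(1, 1, 2, 2), "H", 1)
  s <- cvid_score(fm, c(1, 2), cov_matrix = diag(1))
  # per-point silhouettes: 19/21, 17/19, 17/19, 19/21
  expect_equal(s, mean(c(19 / 21, 17 / 19, 17 / 19, 19 / 21)), tolerance = 1e-12)
  expect_equal(round(s, 5), 0.89975)
})

test_that("silhouette behaves at the separation extremes and is symmetric", {
  far <- gaussian_fm(40, p = 3, shifts = c(0, 60), seed = 12)
  expect_gt(cvid_score(far, c(1, 2), cov_matrix = diag(3)), 0.95)
  same <- gaussian_fm(80, p = 3, shifts = c(0, 0), seed = 13)
  expect_lt(abs(cvid_score(same, c(1, 2))), 0.1)
  mix <- gaussian_fm(30, p = 3, shifts = c(0, 1.5, 0.5), seed = 14)
  expect_equal(cvid_score(mix, c(2, 3)), cvid_score(mix, c(3, 2)))
  one <- feature_matrix(matrix(rnorm(6), 3, 2), c(1, 1, 2), "X", 1)
  expect_error(cvid_score(one, c(1, 2)), class = "rsi_cluster_too_small")
})

test_that("linear-kernel KPCA reduces to ED-PCA on the same input", {
  fm <- gaussian_fm(50, p = 6, shifts = c(0, 0.8, 0.3), seed = 15)
  prot <- flat_protocol(3)
  kp <- kpca_distances(fm, prot, kernel = "linear", n_components = 6L)
  ed <- edpca_distances(fm, prot)
  expect_equal(kp$D, ed$D, tolerance = 1e-6)
})

test_that("RBF KPCA flattens as bandwidth grows and vanishes on identical phases", {
  fm <- gaussian_fm(60, p = 4, shifts = c(0, 0), seed = 16)
  prof <- kpca_distances(fm, flat_protocol(2), kernel = "rbf")
  expect_lt(prof$D[["2"]], 0.3)
  wide <- kpca_distances(gaussian_fm(40, p = 4, shifts = c(0, 3), seed = 17),
                         flat_protocol(2), kernel = "rbf", gamma = 1e-8)
  expect_lt(wide$D[["2"]], 1e-2)  # gamma -> 0 collapses feature-space spread
})

test_that("all four methods rank a large-shift subject above a small-shift one", {
  prot <- tiny_protocol(20)  # 20-s phases so 1-Hz paths keep 20 points/phase
  cfg <- tiny_config()
  rec_small <- tiny_recording(seed = 31, fs = 32, protocol = prot,
                              shift_scale = 1, rho = 0.5)
  rec_large <- tiny_recording(seed = 32, fs = 32, protocol = prot,
                              shift_scale = 3, rho = 0.5)
  ps <- subject_profiles(rec_small, prot, cfg)
  pl <- subject_profiles(rec_large, prot, cfg)
  for (m in c("ED-PCA", "MD", "CVID", "ED-KPCA")) {
    expect_gt(subject_max_stretch(pl[[m]]), subject_max_stretch(ps[[m]]))
  }
})
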
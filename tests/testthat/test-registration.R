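test_that("centroid is the arithmetic mean and rejects empty input", {
  expect_equal(unname(centroid(matrix(c(0, 0, 0), 1, 3))), c(0, 0, 0))
  expect_equal(unname(centroid(rbind(c(1, 0, 0), c(-1, 0, 0)))), c(0, 0, 0))
  expect_equal(unname(centroid(rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))),
               c(4, 5, 6))
  expect_error(centroid(matrix(numeric(0), 0, 3)), "empty")
})

test_that("cross_covariance matches direct summation", {
  p <- matrix(c(2, -1, 3), 1, 3)
  expect_equal(unname(cross_covariance(p, p)), matrix(0, 3, 3))

  X <- diag(3)
  S <- cross_covariance(X, X)
  expect_equal(unname(S), unname(t(S)))
  expect_true(all(eigen(S, symmetric = TRUE)$values > -1e-12))

  X <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, -1, -1))
  Rz90 <- rotation_from_euler(c(0, 0, 90))
  Y <- X %*% t(Rz90)
  # independent brute-force evaluation of the definition
  n <- nrow(X)
  S_direct <- matrix(0, 3, 3)
  for (i in seq_len(n)) S_direct <- S_direct + Y[i, ] %*% t(X[i, ]) / n
  S_direct <- S_direct - colMeans(Y) %*% t(colMeans(X))
  expect_equal(unname(cross_covariance(Y, X)), S_direct, tolerance = 1e-12)

  expect_error(cross_covariance(X, X[1:2, ]), "equal size")
})

test_that("build_Q produces the symmetric 4x4 quaternion matrix", {
  expect_equal(build_Q(diag(3)), diag(c(3, -1, -1, -1)))
  expect_equal(build_Q(matrix(0, 3, 3)), matrix(0, 4, 4))

  # max eigenvector of Q is the quaternion of the 90-degree z-rotation
  # mapping the target set Y onto the reference set X
  X <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, -1, -1))
  Y <- X %*% t(rotation_from_euler(c(0, 0, -90)))
  Q <- build_Q(cross_covariance(Y, X))
  expect_equal(Q, t(Q))
  q <- eigen(Q, symmetric = TRUE)$vectors[, 1]
  if (q[1] < 0) q <- -q
  expect_equal(q, c(cos(pi / 4), 0, 0, sin(pi / 4)), tolerance = 1e-9)
})

test_that("quaternion/matrix conversions are mutually consistent", {
  expect_equal(quaternion_to_matrix(c(1, 0, 0, 0)), diag(3))
  R90 <- quaternion_to_matrix(c(cos(pi / 4), 0, 0, sin(pi / 4)))
  expect_equal(as.numeric(R90 %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  expect_error(quaternion_to_matrix(c(1, 1, 0, 0)), "unit")

  set.seed(5)
  for (k in 1:25) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- quaternion_to_matrix(q)
    expect_equal(quaternion_to_matrix(-q), R)
    expect_true(abs(det(R) - 1) < 1e-9)
    # matrix action equals quaternion algebra action (independent route)
    v <- rnorm(3)
    expect_equal(as.numeric(R %*% v), quat_rotate_vec(q, v), tolerance = 1e-9)
    # extraction round trip up to sign convention
    q2 <- matrix_to_quaternion(R)
    expect_equal(abs(sum(q2 * q)), 1, tolerance = 1e-9)
  }
})

test_that("horn_fit recovers exact rigid transforms and flags degeneracy", {
  set.seed(21)
  Y <- oracle_marker_set(4)
  expect_equal(horn_fit(Y, Y)$T, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(horn_fit(Y, Y)$R, diag(3), tolerance = 1e-9)

  X <- Y + matrix(c(1, 2, 3), 4, 3, byrow = TRUE)
  tf <- horn_fit(X, Y)
  expect_equal(tf$R, diag(3), tolerance = 1e-9)
  expect_equal(tf$T, c(1, 2, 3), tolerance = 1e-9)

  R <- rodrigues(c(0.05, -0.12, 0.08))  # ~10 degrees
  T <- c(4, -7, 11)
  X <- Y %*% t(R) + matrix(T, 4, 3, byrow = TRUE)
  tf <- horn_fit(X, Y)
  expect_lt(max(abs(tf$R - R)), 1e-9)
  expect_lt(max(abs(tf$T - T)), 1e-9)
  expect_lt(eq3_objective(X, Y, tf$R, tf$T), 1e-18)

  expect_error(horn_fit(X[1:2, ], Y[1:2, ]), "at least 3")
  expect_error(horn_fit(X, Y[c(1, 1, 1, 1), ] * 0), "coincide")
})

test_that("horn_fit matches the brute-force minimizer on random instances", {
  set.seed(33)
  for (k in 1:15) {
    n <- sample(3:6, 1)
    Y <- matrix(rnorm(n * 3, sd = 25), n, 3)
    X <- Y %*% t(random_rotation_oracle()) +
      matrix(rnorm(3, sd = 10), n, 3, byrow = TRUE)
    if (k %% 2 == 0) X <- X + matrix(rnorm(n * 3, sd = 0.5), n, 3)
    tf <- horn_fit(X, Y)
    bf <- brute_force_rigid_fit(X, Y, polish = TRUE)
    expect_lt(abs(eq3_objective(X, Y, tf$R, tf$T) - bf$value), 1e-6)
  }
})

test_that("translation_only_fit is the centroid difference", {
  set.seed(9)
  Y <- oracle_marker_set(4)
  expect_equal(translation_only_fit(Y, Y)$T, c(0, 0, 0))
  tf <- translation_only_fit(Y + matrix(c(5, 0, 0), 4, 3, byrow = TRUE), Y)
  expect_equal(tf$T, c(5, 0, 0), tolerance = 1e-12)
  expect_equal(tf$R, diag(3))

  # centered rotated set: T = 0, residual equals brute-force minimum over T
  Yc <- sweep(Y, 2, colMeans(Y))
  X <- Yc %*% t(rotation_from_euler(c(0, 0, 5)))
  tf <- translation_only_fit(X, Yc)
  expect_equal(tf$T, c(0, 0, 0), tolerance = 1e-9)
  obj_T <- function(T) eq3_objective(X, Yc, diag(3), T)
  bf <- optim(c(1, 1, 1), obj_T, method = "BFGS",
              control = list(reltol = 1e-15))
  expect_equal(eq3_objective(X, Yc, diag(3), tf$T), bf$value, tolerance = 1e-9)
  expect_gt(eq3_objective(X, Yc, diag(3), tf$T), 0)
})

test_that("svd_fit agrees with horn_fit but exposes the reflection pathology", {
  set.seed(41)
  Y <- oracle_marker_set(4)
  res <- svd_fit(Y, Y)
  expect_equal(res$transform$R, diag(3), tolerance = 1e-9)
  expect_equal(res$det_sign, 1)

  R <- rodrigues(c(0.1, 0.2, -0.15))
  X <- Y %*% t(R) + matrix(c(2, -3, 5), 4, 3, byrow = TRUE)
  expect_lt(max(abs(svd_fit(X, Y)$transform$R - horn_fit(X, Y)$R)), 1e-9)

  # mirrored coplanar instance: uncorrected SVD returns a reflection,
  # the quaternion fit never does
  tri <- cbind(matrix(c(0, 0, 40, 0, 15, 35), 3, 2, byrow = TRUE),
               rnorm(3, sd = 0.2))
  mirrored <- tri %*% diag(c(1, 1, -1)) + matrix(rnorm(9, sd = 0.05), 3, 3)
  res <- svd_fit(tri, mirrored, correct_reflection = FALSE)
  expect_equal(res$det_sign, -1)
  expect_equal(det(res$R_uncorrected), -1, tolerance = 1e-9)
  expect_equal(det(horn_fit(tri, mirrored)$R), 1, tolerance = 1e-9)
})

test_that("nearest neighbour matching recovers permutations and breaks ties low", {
  set.seed(13)
  X <- oracle_marker_set(4)
  expect_equal(nearest_neighbor_match(X, X), 1:4)
  perm <- c(3, 1, 4, 2)
  expect_equal(nearest_neighbor_match(X, X[perm, ]), perm)
  # two reference points equidistant from one target: lower index wins
  Xr <- rbind(c(-1, 0, 0), c(1, 0, 0))
  expect_equal(nearest_neighbor_match(Xr, matrix(0, 1, 3)), 1L)
})

test_that("ICP converges immediately on clean data and matches the oracle on noise", {
  set.seed(55)
  Y <- oracle_marker_set(4)
  res <- icp_register(Y, Y)
  expect_equal(res$iterations, 1)
  expect_true(res$converged)
  expect_equal(res$rms_residual, 0, tolerance = 1e-12)
  expect_equal(res$transform$T, c(0, 0, 0), tolerance = 1e-12)

  R <- rodrigues(c(0.08, -0.05, 0.1)); T <- c(5, -8, 14)
  X <- Y %*% t(R) + matrix(T, 4, 3, byrow = TRUE)
  res <- icp_register(X, Y)
  expect_lte(res$iterations, 3)
  expect_lt(res$rms_residual, 1e-9)
  expect_lt(max(abs(res$transform$R - R)), 1e-9)

  # permutation invariance for well-separated markers
  res_p <- icp_register(X, Y[c(4, 2, 1, 3), ])
  expect_equal(res_p$rms_residual, res$rms_residual, tolerance = 1e-9)

  # noisy instance: ICP residual equals the brute-force minimum
  Xn <- X + matrix(rnorm(12, sd = 0.5), 4, 3)
  res_n <- icp_register(Xn, Y)
  bf <- brute_force_rigid_fit(Xn[res_n$correspondence, , drop = FALSE], Y,
                              polish = TRUE)
  expect_lt(abs(res_n$rms_residual^2 - bf$value), 1e-6)
  expect_lte(res_n$iterations, 50)
})

test_that("every fitted transform is a proper rotation", {
  set.seed(77)
  for (k in 1:30) {
    n <- sample(3:4, 1)
    Y <- matrix(rnorm(n * 3, sd = 20), n, 3)
    if (n == 3) Y[, 3] <- 0  # coplanar: the hard case for SVD
    X <- Y %*% t(random_rotation_oracle()) + matrix(rnorm(n * 3, sd = 0.5), n, 3)
    tf <- horn_fit(X, Y)
    expect_lt(max(abs(crossprod(tf$R) - diag(3))), 1e-9)
    expect_equal(det(tf$R), 1, tolerance = 1e-9)
  }
})

test_that("residual_errors reports per-axis and 3D magnitudes", {
  set.seed(19)
  Y <- oracle_marker_set(3)
  tf <- identity_transform()
  res <- residual_errors(Y, Y, tf)
  expect_equal(unname(res$mean_abs), c(0, 0, 0))
  expect_equal(res$mean_3d, 0)

  # 3-4-5 offset on a single point
  X1 <- matrix(c(0.3, 0.4, 0), 1, 3)
  res <- residual_errors(X1, matrix(0, 1, 3), tf)
  expect_equal(unname(res$mean_abs), c(0.3, 0.4, 0))
  expect_equal(res$mean_3d, 0.5)

  # optimality: rigid residual never exceeds translation-only residual
  for (k in 1:10) {
    Yk <- oracle_marker_set(4)
    Xk <- Yk %*% t(random_rotation_oracle()) + matrix(rnorm(12, sd = 0.6), 4, 3)
    rms_h <- residual_errors(Xk, Yk, horn_fit(Xk, Yk))$rms
    rms_t <- residual_errors(Xk, Yk, translation_only_fit(Xk, Yk))$rms
    expect_lte(rms_h, rms_t + 1e-12)
  }
})
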
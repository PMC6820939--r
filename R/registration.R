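#' Rigid transform (rotation + translation)
#'
#' A rigid map \eqn{p \mapsto R p + T} with `R` a proper rotation (det +1),
#' stored both as a 3x3 matrix and as its unit quaternion (scalar-first,
#' canonical sign q0 >= 0).
#'
#' @param R 3x3 proper rotation matrix (exactly one of `R`/`q`).
#' @param q Unit quaternion `c(q0, q1, q2, q3)`, scalar first.
#' @param T Translation 3-vector in mm (default zero).
#' @return Object of class `rigid_transform` with elements `R`, `q`, `T`.
#' @examples
#' tf <- rigid_transform(q = c(cos(pi / 8), 0, 0, sin(pi / 8)), T = c(1, 2, 3))
#' apply_transform(tf, c(10, 0, 0))
#' @export
rigid_transform <- function(R = NULL, q = NULL, T = c(0, 0, 0)) {
  if (is.null(R) == is.null(q)) stop("supply exactly one of R or q")
  if (is.null(R)) {
    R <- quaternion_to_matrix(q)
  } else {
    R <- unname(as.matrix(R))
    if (!is_rotation_matrix(R)) {
      stop("R is not a proper rotation matrix (orthogonal, det = +1) within 1e-9")
    }
    q <- matrix_to_quaternion(R)
  }
  if (q[1] < 0) q <- -q
  stopifnot(length(T) == 3, all(is.finite(T)))
  structure(list(R = R, q = q, T = as.numeric(T)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- euler_angles(x$R)
  cat("<rigid_transform>\n")
  cat(sprintf("  T (mm):  % .4f % .4f % .4f\n", x$T[1], x$T[2], x$T[3]))
  cat(sprintf("  angles (deg, x-y-z): % .4f % .4f % .4f\n", ang[1], ang[2], ang[3]))
  cat(sprintf("  q: % .6f % .6f % .6f % .6f\n", x$q[1], x$q[2], x$q[3], x$q[4]))
  invisible(x)
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

#' Identity rigid transform
#' @return A `rigid_transform` with R = I, T = 0.
#' @export
identity_transform <- function() {
  rigid_transform(q = c(1, 0, 0, 0))
}

#' Apply a rigid transform to points
#'
#' @param tf A [rigid_transform()].
#' @param points 3-vector or n x 3 matrix (mm).
#' @return Transformed points, same shape as input.
#' @export
apply_transform <- function(tf, points) {
  single <- is.null(dim(points))
  p <- as_point_matrix(points)
  out <- p %*% t(tf$R) + matrix(tf$T, nrow(p), 3, byrow = TRUE)
  colnames(out) <- c("x", "y", "z")
  if (single) drop(out) else out
}

#' Compose rigid transforms
#'
#' `compose_transforms(a, b)` is the map "apply b, then a".
#' @param a,b [rigid_transform()] objects.
#' @return Their composition as a `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(R = a$R %*% b$R, T = as.numeric(a$R %*% b$T) + a$T)
}

#' Invert a rigid transform
#' @param tf A [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(tf) {
  rigid_transform(R = t(tf$R), T = as.numeric(-t(tf$R) %*% tf$T))
}

#' Quaternion from rotation axis and angle
#'
#' Encodes the axis-angle representation of a rotation as a unit quaternion:
#' scalar part `cos(theta/2)`, vector part `axis * sin(theta/2)`
#' (scalar-first component order).
#'
#' @param axis Rotation axis, any nonzero 3-vector (normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @return Unit quaternion `c(q0, q1, q2, q3)`.
#' @export
axis_angle_quaternion <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be nonzero")
  half <- angle_deg * pi / 360
  c(cos(half), (axis / n) * sin(half))
}

#' Rotation matrix of a unit quaternion
#'
#' Standard quadratic quaternion-to-matrix map (scalar-first components).
#' The result is always a proper rotation (det +1); `q` and `-q` give the
#' same matrix.
#'
#' @param q Unit quaternion `c(q0, q1, q2, q3)`; non-unit norm beyond `tol`
#'   is an error.
#' @param tol Unit-norm tolerance.
#' @return 3x3 rotation matrix.
#' @export
quaternion_to_matrix <- function(q, tol = 1e-6) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  if (abs(sum(q^2) - 1) > tol) stop("quaternion is not unit norm")
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 + q0 * q3),   2 * (q1 * q3 - q0 * q2),
    2 * (q1 * q2 - q0 * q3),   q0^2 + q2^2 - q1^2 - q3^2, 2 * (q2 * q3 + q0 * q1),
    2 * (q1 * q3 + q0 * q2),   2 * (q2 * q3 - q0 * q1),   q0^2 + q3^2 - q1^2 - q2^2
  ), nrow = 3, ncol = 3)
}

#' Unit quaternion of a rotation matrix
#'
#' Shepperd-style extraction choosing the numerically largest pivot;
#' returns the canonical representative with q0 >= 0.
#'
#' @param R 3x3 proper rotation matrix.
#' @return Unit quaternion `c(q0, q1, q2, q3)`.
#' @export
matrix_to_quaternion <- function(R) {
  if (!is_rotation_matrix(R, tol = 1e-6)) stop("input is not a proper rotation matrix")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  cand <- c(tr, R[1, 1], R[2, 2], R[3, 3])
  i <- which.max(cand)
  if (i == 1) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (i == 2) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (i == 3) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s, (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Centroid of a point set
#'
#' @param ps n x 3 matrix of points (mm).
#' @return Numeric 3-vector, the arithmetic mean of the points.
#' @export
centroid <- function(ps) {
  ps <- as_point_matrix(ps)
  if (nrow(ps) == 0) stop("empty point set has no centroid")
  colMeans(ps)
}

#' Cross-covariance matrix of two corresponding point sets
#'
#' Computes `(1/n) sum_i y_i x_i^T - mu_y mu_x^T` for index-corresponding
#' sets Y (target) and X (reference) — the 3x3 matrix whose symmetric and
#' antisymmetric parts feed the quaternion eigenproblem of [horn_fit()].
#'
#' @param Y,X n x 3 matrices with row-wise correspondence.
#' @return 3x3 numeric matrix.
#' @export
cross_covariance <- function(Y, X) {
  Y <- as_point_matrix(Y); X <- as_point_matrix(X)
  if (nrow(X) != nrow(Y)) stop("point sets must have equal size")
  if (nrow(X) < 1) stop("empty point sets")
  n <- nrow(X)
  crossprod(Y, X) / n - colMeans(Y) %*% t(colMeans(X))
}

#' Horn's 4x4 symmetric quaternion matrix
#'
#' Builds the symmetric 4x4 matrix whose maximum-eigenvalue unit eigenvector
#' is the quaternion of the least-squares rotation: with
#' `A = S - t(S)` and `delta = c(A[2,3], A[3,1], A[1,2])`,
#' `Q = rbind(c(tr(S), delta'), cbind(delta, S + t(S) - tr(S) * I3))`.
#'
#' @param sigma_yx 3x3 cross-covariance matrix from [cross_covariance()].
#' @return 4x4 symmetric matrix.
#' @export
build_Q <- function(sigma_yx) {
  S <- unname(as.matrix(sigma_yx))
  stopifnot(all(dim(S) == c(3, 3)), all(is.finite(S)))
  A <- S - t(S)
  delta <- c(A[2, 3], A[3, 1], A[1, 2])
  trS <- sum(diag(S))
  unname(rbind(c(trS, delta),
               cbind(delta, S + t(S) - trS * diag(3))))
}

#' Closed-form least-squares rigid fit (unit quaternion method)
#'
#' Finds the rigid transform (R, T) minimizing the mean squared residual
#' `(1/n) sum_i || x_i - (R y_i + T) ||^2` over proper rotations, by the
#' closed-form quaternion eigenvector solution: R is rebuilt from the unit
#' eigenvector of [build_Q()]'s matrix with maximum eigenvalue, and
#' `T = mu_x - R mu_y`. Unlike the unconstrained SVD solution the result is
#' always a proper rotation (det R = +1), including for coplanar 3-marker
#' sets where SVD may return a reflection.
#'
#' @param X Reference point set, n x 3 (mm).
#' @param Y Target point set, n x 3, index-corresponding with `X`.
#' @return A [rigid_transform()] mapping Y onto X.
#' @export
horn_fit <- function(X, Y) {
  X <- as_point_matrix(X); Y <- as_point_matrix(Y)
  if (nrow(X) != nrow(Y)) stop("point sets must have equal size")
  if (nrow(X) < 3) stop("rotational fitting needs at least 3 points")
  if (max(abs(sweep(Y, 2, colMeans(Y)))) < 1e-12) {
    stop("all target points coincide: rotation is undefined")
  }
  Q <- build_Q(cross_covariance(Y, X))
  e <- eigen(Q, symmetric = TRUE)
  ev <- e$values
  if (ev[1] - ev[2] <= 1e-9 * max(1, abs(ev[1]))) {
    warning("degenerate rotation fit: leading eigenvalue of Q is (numerically) repeated")
  }
  q <- e$vectors[, 1]
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  R <- quaternion_to_matrix(q)
  rigid_transform(R = R, T = centroid(X) - as.numeric(R %*% centroid(Y)))
}

#' Translation-only least-squares fit
#'
#' Baseline with the rotation fixed to identity: the optimal translation is
#' the centroid difference `T = mu_x - mu_y`.
#'
#' @inheritParams horn_fit
#' @return A [rigid_transform()] with R = I.
#' @export
translation_only_fit <- function(X, Y) {
  X <- as_point_matrix(X); Y <- as_point_matrix(Y)
  if (nrow(X) != nrow(Y)) stop("point sets must have equal size")
  if (nrow(X) < 1) stop("empty point sets")
  rigid_transform(R = diag(3), T = centroid(X) - centroid(Y))
}

#' SVD-based rigid fit with reflection diagnostic
#'
#' Least-squares rotation via singular value decomposition of the
#' cross-covariance (the Kabsch construction). The unconstrained solution
#' `V U'` can be an improper orthogonal matrix (a reflection, det = -1),
#' especially for coplanar 3-marker sets; `det_sign` reports the determinant
#' sign of that uncorrected solution. With `correct_reflection = TRUE`
#' (default) the standard sign fix `V diag(1, 1, det) U'` is applied.
#' Provided as a diagnostic/comparison fit; the tracking pipeline uses
#' [horn_fit()].
#'
#' @inheritParams horn_fit
#' @param correct_reflection Apply the determinant sign correction?
#' @return List with `transform` (a [rigid_transform()]; only valid when the
#'   corrected or naturally proper solution is a rotation), `det_sign`
#'   (+1/-1, determinant sign of the uncorrected `V U'`), and `R_uncorrected`.
#' @export
svd_fit <- function(X, Y, correct_reflection = TRUE) {
  X <- as_point_matrix(X); Y <- as_point_matrix(Y)
  if (nrow(X) != nrow(Y)) stop("point sets must have equal size")
  if (nrow(X) < 3) stop("rotational fitting needs at least 3 points")
  H <- cross_covariance(Y, X) # maps centered Y to centered X
  sv <- svd(H)
  R0 <- sv$v %*% t(sv$u)
  s <- sign(det(R0))
  R <- if (correct_reflection) sv$v %*% diag(c(1, 1, s)) %*% t(sv$u) else R0
  tf <- NULL
  if (abs(det(R) - 1) < 1e-6) {
    tf <- rigid_transform(R = R, T = centroid(X) - as.numeric(R %*% centroid(Y)))
  }
  list(transform = tf, det_sign = s, R_uncorrected = R0)
}

#' Nearest-neighbour correspondence between point sets
#'
#' Matches each (transformed) target point to its closest reference point by
#' Euclidean distance; ties are broken toward the lowest reference index.
#'
#' @param X Reference set, n x 3.
#' @param Y Target set, m x 3 (typically already moved by the current
#'   transform estimate).
#' @return Integer vector of length m: `idx[j]` is the reference row matched
#'   to target row j.
#' @export
nearest_neighbor_match <- function(X, Y) {
  X <- as_point_matrix(X); Y <- as_point_matrix(Y)
  if (nrow(X) == 0 || nrow(Y) == 0) stop("point sets must be non-empty")
  # squared distance matrix, m x n
  d2 <- outer(rowSums(Y^2), rowSums(X^2), "+") - 2 * Y %*% t(X)
  apply(d2, 1, which.min)
}

#' Iterative closest point rigid registration
#'
#' Alternates nearest-neighbour correspondence with the closed-form
#' quaternion fit until the root-mean-square residual stops improving:
#' iterate { match each transformed target point to its nearest reference
#' point; [horn_fit()] on the matched pairs; update the transform } until the
#' change in RMS residual between successive iterations falls below
#' `threshold` (default 0.001 mm) or `max_iter` is reached. With labelled
#' markers (`labelled = TRUE`) correspondence is fixed by row index and the
#' loop converges immediately to the closed-form solution.
#'
#' @param X Reference point set, n x 3 (mm), n >= 3.
#' @param Y Target point set, m x 3, m >= 3.
#' @param threshold Convergence threshold (mm) on the decrease in RMS
#'   residual between successive iterations.
#' @param max_iter Iteration safety cap; non-convergence is flagged, not an
#'   error.
#' @param labelled If TRUE, rows of `X` and `Y` correspond by index and no
#'   matching is performed.
#' @param init Optional initial [rigid_transform()] (e.g. the previous
#'   frame's solution as a warm start); default identity.
#' @return List of class `icp_result`: `transform` ([rigid_transform()]),
#'   `iterations`, `rms_residual` (mm), `per_point_residuals` (m x 3 matrix
#'   of residual vectors), `residual_norms`, `correspondence`, `converged`.
#' @export
icp_register <- function(X, Y, threshold = 0.001, max_iter = 50,
                         labelled = FALSE, init = NULL) {
  X <- as_point_matrix(X); Y <- as_point_matrix(Y)
  if (nrow(X) < 3 || nrow(Y) < 3) stop("ICP registration needs at least 3 points per set")
  stopifnot(threshold > 0, max_iter >= 1)
  tf <- if (is.null(init)) identity_transform() else init

  match_for <- function(tf) {
    if (labelled) {
      if (nrow(X) != nrow(Y)) stop("labelled mode requires equal-size sets")
      seq_len(nrow(Y))
    } else {
      nearest_neighbor_match(X, apply_transform(tf, Y))
    }
  }
  rms_for <- function(tf, idx) {
    e <- X[idx, , drop = FALSE] - apply_transform(tf, Y)
    sqrt(mean(rowSums(e^2)))
  }

  idx <- match_for(tf)
  rms_prev <- rms_for(tf, idx)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    tf <- horn_fit(X[idx, , drop = FALSE], Y)
    rms <- rms_for(tf, idx)
    idx_new <- match_for(tf)
    if (abs(rms_prev - rms) < threshold && identical(idx_new, idx)) {
      converged <- TRUE
      idx <- idx_new
      break
    }
    idx <- idx_new
    rms_prev <- rms
  }
  e <- X[idx, , drop = FALSE] - apply_transform(tf, Y)
  structure(
    list(
      transform = tf,
      iterations = iter,
      rms_residual = sqrt(mean(rowSums(e^2))),
      per_point_residuals = e,
      residual_norms = sqrt(rowSums(e^2)),
      correspondence = idx,
      converged = converged
    ),
    class = "icp_result"
  )
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> %d iteration(s), rms %.6g mm, %s\n",
              x$iterations, x$rms_residual,
              if (x$converged) "converged" else "NOT converged"))
  print(x$transform)
  invisible(x)
}

#' Per-axis and 3D registration residuals
#'
#' Residual vectors `e_i = x_i - (R y_i + T)` for index-corresponding sets,
#' summarized as the mean absolute per-axis components and the mean 3D
#' magnitude.
#'
#' @inheritParams horn_fit
#' @param tf A [rigid_transform()] mapping Y onto X.
#' @return List: `per_point` (n x 3 residual vectors, mm), `mean_abs`
#'   (named 3-vector of mean |e| per axis), `mean_3d` (mean ||e_i||),
#'   `rms` (root mean squared ||e_i||).
#' @export
residual_errors <- function(X, Y, tf) {
  X <- as_point_matrix(X); Y <- as_point_matrix(Y)
  if (nrow(X) != nrow(Y)) stop("point sets must have equal size")
  e <- X - apply_transform(tf, Y)
  list(
    per_point = e,
    mean_abs = c(x = mean(abs(e[, 1])), y = mean(abs(e[, 2])), z = mean(abs(e[, 3]))),
    mean_3d = mean(sqrt(rowSums(e^2))),
    rms = sqrt(mean(rowSums(e^2)))
  )
}
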
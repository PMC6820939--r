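# Independent oracles for the registration math. These deliberately avoid
# the package's quaternion/eigenvector code path: rotations come from the
# Rodrigues formula on a rotation vector, and fits from generic numerical
# minimization of the mean-squared objective.

# rotation matrix from a rotation vector (axis * angle, radians)
rodrigues <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-14) return(diag(3))
  ax <- r / th
  K <- matrix(c(0, ax[3], -ax[2],
                -ax[3], 0, ax[1],
                ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# mean squared registration objective: (1/n) sum ||x_i - (R y_i + T)||^2
eq3_objective <- function(X, Y, R, T) {
  mean(rowSums((X - (Y %*% t(R) + matrix(T, nrow(Y), 3, byrow = TRUE)))^2))
}

# uniform random rotation via Rodrigues (independent of the package path)
random_rotation_oracle <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  rodrigues(ax * stats::runif(1, 0, pi))
}

# brute-force minimizer of the rigid objective over rotation-vector +
# translation parameters: structured starts (identity, the three 180-degree
# flips and the six 90-degree quarter turns, covering the rotation group
# coarsely) plus random restarts, each refined by BFGS and optionally
# polished by Nelder-Mead.
brute_force_rigid_fit <- function(X, Y, n_random = 2, polish = FALSE) {
  n <- nrow(Y)
  obj <- function(par) {
    R <- rodrigues(par[1:3])
    mean(rowSums((X - (Y %*% t(R) + matrix(par[4:6], n, 3, byrow = TRUE)))^2))
  }
  t_for <- function(r) colMeans(X) - as.numeric(rodrigues(r) %*% colMeans(Y))
  starts <- list(c(0, 0, 0), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi),
                 c(pi / 2, 0, 0), c(-pi / 2, 0, 0), c(0, pi / 2, 0),
                 c(0, -pi / 2, 0), c(0, 0, pi / 2), c(0, 0, -pi / 2))
  for (k in seq_len(n_random)) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    starts[[length(starts) + 1]] <- ax * stats::runif(1, 0, pi)
  }
  best <- NULL
  for (s in starts) {
    p0 <- c(s, t_for(s))
    fit <- stats::optim(p0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-15))
    if (polish) {
      fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-15))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(value = best$value,
       R = rodrigues(best$par[1:3]),
       T = best$par[4:6])
}

# quaternion rotation of a vector via quaternion algebra (q v q*), used to
# cross-check the matrix form
quat_rotate_vec <- function(q, v) {
  qmul <- function(a, b) {
    c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
      a[1] * b[2:4] + b[1] * a[2:4] +
        c(a[3] * b[4] - a[4] * b[3],
          a[4] * b[2] - a[2] * b[4],
          a[2] * b[3] - a[3] * b[2]))
  }
  qc <- c(q[1], -q[2:4])
  qmul(qmul(q, c(0, v)), qc)[2:4]
}

# a well-separated random marker set obeying the implantation constraints
oracle_marker_set <- function(n = 4) {
  repeat {
    pts <- matrix(stats::runif(n * 3, -30, 30), n, 3)
    if (min(stats::dist(pts)) > 20) return(pts)
  }
}
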
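#' Euler angles of a rotation matrix
#'
#' Decomposes a proper rotation as extrinsic fixed-axes x-y-z rotations,
#' `R = Rz(theta_z) %*% Ry(theta_y) %*% Rx(theta_x)`, with the x/y/z axes the
#' patient LR/AP/SI axes. Angles are reported in degrees in (-180, 180].
#' At gimbal lock (theta_y = +/-90 deg) the x/z split is canonicalized with
#' theta_x = 0.
#'
#' For the small rotations seen in fiducial tracking (a few degrees) all
#' common conventions agree to first order.
#'
#' @param R 3x3 proper rotation matrix.
#' @return Named numeric vector `c(theta_x, theta_y, theta_z)` in degrees.
#' @seealso [rotation_from_euler()] for the inverse.
#' @export
euler_angles <- function(R) {
  R <- unname(as.matrix(R))
  if (!is_rotation_matrix(R, tol = 1e-6)) stop("input is not a proper rotation matrix")
  if (abs(R[3, 1]) < 1 - 1e-12) {
    ty <- asin(-R[3, 1])
    tx <- atan2(R[3, 2], R[3, 3])
    tz <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: only theta_z -/+ theta_x observable; fix theta_x = 0
    ty <- if (R[3, 1] < 0) pi / 2 else -pi / 2
    tx <- 0
    tz <- atan2(-R[1, 2], R[2, 2])
  }
  out <- c(theta_x = tx, theta_y = ty, theta_z = tz) * 180 / pi
  # map -180 to 180 for canonical range (-180, 180]
  out[out <= -180] <- out[out <= -180] + 360
  out
}

#' Rotation matrix from extrinsic x-y-z Euler angles
#'
#' Builds `Rz(theta_z) %*% Ry(theta_y) %*% Rx(theta_x)` (degrees), the
#' convention inverted by [euler_angles()].
#'
#' @param theta_x,theta_y,theta_z Angles in degrees about the LR/AP/SI axes,
#'   or a single 3-vector in `theta_x`.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_euler <- function(theta_x, theta_y = NULL, theta_z = NULL) {
  if (is.null(theta_y) && length(theta_x) == 3) {
    theta_z <- theta_x[3]; theta_y <- theta_x[2]; theta_x <- theta_x[1]
  }
  ax <- theta_x * pi / 180; ay <- theta_y * pi / 180; az <- theta_z * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Per-fraction motion ranges
#'
#' Peak-to-peak (max - min) range of each translation component and each
#' rotation angle over a motion trace, plus the 3D translational range
#' combining the three per-axis ranges as
#' `dd = sqrt(dx^2 + dy^2 + dz^2)`.
#'
#' @param trace A `motion_trace` data frame (see [track_fraction()]), needing
#'   columns `dx_mm`, `dy_mm`, `dz_mm`, `theta_x_deg`, `theta_y_deg`,
#'   `theta_z_deg`. A single-frame trace yields zero ranges with a warning.
#' @return Named numeric vector: `dx`, `dy`, `dz`, `dd` (mm) and
#'   `theta_x`, `theta_y`, `theta_z` (degrees).
#' @export
motion_range <- function(trace) {
  stopifnot(is.data.frame(trace))
  if (nrow(trace) < 1) stop("empty motion trace")
  if (nrow(trace) < 2) warning("single-frame trace: all motion ranges are zero")
  rng <- function(v) diff(range(v))
  dx <- rng(trace$dx_mm); dy <- rng(trace$dy_mm); dz <- rng(trace$dz_mm)
  c(dx = dx, dy = dy, dz = dz,
    dd = sqrt(dx^2 + dy^2 + dz^2),
    theta_x = rng(trace$theta_x_deg),
    theta_y = rng(trace$theta_y_deg),
    theta_z = rng(trace$theta_z_deg))
}

#' Cohort summary of motion ranges
#'
#' Mean and sample standard deviation (n - 1 denominator) across
#' patients/fractions of each per-fraction motion range. The per-fraction 3D
#' range `dd` is computed per patient from that patient's per-axis ranges and
#' then averaged (not recomputed from cohort-mean axis ranges).
#'
#' @param traces List of `motion_trace` data frames, one per
#'   patient/fraction.
#' @return Data frame with columns `quantity` (dx, dy, dz, dd, theta_x,
#'   theta_y, theta_z), `mean`, `sd`, `unit`. For a single trace the SD is
#'   reported as 0 with a warning.
#' @export
summarize_cohort <- function(traces) {
  if (is.data.frame(traces)) traces <- list(traces)
  if (length(traces) < 1) stop("no motion traces supplied")
  ranges <- t(vapply(traces, motion_range, numeric(7)))
  sds <- if (nrow(ranges) < 2) {
    warning("single trace: SD is undefined, reported as 0")
    rep(0, 7)
  } else {
    apply(ranges, 2, stats::sd)
  }
  data.frame(
    quantity = colnames(ranges),
    mean = colMeans(ranges),
    sd = sds,
    unit = c(rep("mm", 4), rep("deg", 3)),
    row.names = NULL
  )
}

#' Paired two-sided t-test (closed form)
#'
#' Textbook paired t statistic `t = mean(d) / (sd(d) / sqrt(n))` on
#' `d = a - b`, with `df = n - 1` and a two-sided p-value from the t
#' distribution. Zero-variance differences are handled explicitly: a
#' constant nonzero difference gives `t = +/-Inf`, `p = 0` (flagged
#' `degenerate`); an identically zero difference gives `t = 0`, `p = 1`.
#'
#' @param a,b Equal-length numeric vectors, n >= 2, paired by position.
#' @return List: `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (md == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, degenerate = TRUE))
    }
    return(list(t = sign(md) * Inf, df = n - 1, p = 0, mean_diff = md,
                degenerate = TRUE))
  }
  t <- md / (sd_d / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1),
       mean_diff = md, degenerate = FALSE)
}

#' Residual comparison: translation-only vs rigid correction
#'
#' Pools all frames of all traces and compares per-frame registration
#' residuals with translational correction only against full rigid
#' correction, for the mean absolute LR/AP/SI components and the mean 3D
#' magnitude. For each quantity a two-sided [paired_t_test()] over the
#' per-frame pairs is reported.
#'
#' @param traces List of `motion_trace` data frames carrying both residual
#'   variants (columns `res_{x,y,z,3d}_trans_mm` and `res_{x,y,z,3d}_rigid_mm`).
#' @return Data frame with one row per quantity (`ex`, `ey`, `ez`, `ed`):
#'   pooled `mean_trans`, `sd_trans`, `mean_rigid`, `sd_rigid` (mm), and
#'   `t`, `df`, `p` of the paired test. Attribute `n_frames` gives the pooled
#'   frame count.
#' @export
residual_comparison <- function(traces) {
  if (is.data.frame(traces)) traces <- list(traces)
  if (length(traces) < 1) stop("no motion traces supplied")
  need <- c(paste0("res_", c("x", "y", "z", "3d"), "_trans_mm"),
            paste0("res_", c("x", "y", "z", "3d"), "_rigid_mm"))
  for (tr in traces) {
    if (!all(need %in% names(tr))) {
      stop("every trace must carry both translation-only and rigid residuals")
    }
  }
  pooled <- do.call(rbind, lapply(traces, function(tr) tr[, need]))
  quantities <- c(ex = "x", ey = "y", ez = "z", ed = "3d")
  rows <- lapply(names(quantities), function(qn) {
    ax <- quantities[[qn]]
    a <- pooled[[paste0("res_", ax, "_trans_mm")]]
    b <- pooled[[paste0("res_", ax, "_rigid_mm")]]
    tt <- paired_t_test(a, b)
    data.frame(quantity = qn,
               mean_trans = mean(a), sd_trans = stats::sd(a),
               mean_rigid = mean(b), sd_rigid = stats::sd(b),
               t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_frames") <- nrow(pooled)
  out
}

#' Format a residual-comparison table
#'
#' Renders [residual_comparison()] output as a text table with
#' `mean +/- SD` columns; p-values below 0.001 print as "< 0.001" (exact
#' values remain in the data frame / JSON output).
#'
#' @param cmp Output of [residual_comparison()].
#' @return Character vector of table lines (also printed invisibly-friendly).
#' @export
format_residual_table <- function(cmp) {
  pfmt <- ifelse(cmp$p < 0.001, "< 0.001", sprintf("%.3g", cmp$p))
  lab <- c(ex = "|e^x| (mm)", ey = "|e^y| (mm)", ez = "|e^z| (mm)", ed = "|e^d| (mm)")
  lines <- sprintf("%-11s %5.2f ± %4.2f   %5.2f ± %4.2f   %s",
                   lab[cmp$quantity],
                   cmp$mean_trans, cmp$sd_trans,
                   cmp$mean_rigid, cmp$sd_rigid, pfmt)
  c(sprintf("%-11s %-14s %-14s %s", "", "w/o rotation", "with rotation", "p-value"),
    lines)
}
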
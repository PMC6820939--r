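test_that("euler angle decomposition inverts the fixed-axes composition", {
  expect_equal(unname(euler_angles(diag(3))), c(0, 0, 0))
  expect_equal(unname(euler_angles(rotation_from_euler(c(0, 0, 10)))),
               c(0, 0, 10), tolerance = 1e-9)
  expect_equal(unname(euler_angles(rotation_from_euler(c(2, 3, 4)))),
               c(2, 3, 4), tolerance = 1e-9)
  set.seed(23)
  for (k in 1:25) {
    ang <- runif(3, -80, 80)
    expect_equal(unname(euler_angles(rotation_from_euler(ang))), ang,
                 tolerance = 1e-9)
  }
  # gimbal lock: the returned canonical angles still reproduce the matrix
  Rg <- rotation_from_euler(c(12, 90, -30))
  ag <- euler_angles(Rg)
  expect_equal(ag[["theta_x"]], 0)
  expect_equal(rotation_from_euler(ag), Rg, tolerance = 1e-9)
  expect_error(euler_angles(diag(c(1, 1, -1))), "rotation")
})

make_trace <- function(dx, dy, dz, tx = 0, ty = 0, tz = 0,
                       rr = 0.1, rt = 0.2) {
  n <- length(dx)
  rec <- function(v) rep(v, length.out = n)
  structure(data.frame(
    frame_index = seq_len(n), time_s = (seq_len(n) - 1) * 40,
    dx_mm = dx, dy_mm = dy, dz_mm = dz,
    theta_x_deg = rec(tx), theta_y_deg = rec(ty), theta_z_deg = rec(tz),
    res_x_rigid_mm = rec(rr), res_y_rigid_mm = rec(rr),
    res_z_rigid_mm = rec(rr), res_3d_rigid_mm = rec(rr),
    res_x_trans_mm = rec(rt), res_y_trans_mm = rec(rt),
    res_z_trans_mm = rec(rt), res_3d_trans_mm = rec(rt)
  ), class = c("motion_trace", "data.frame"))
}

test_that("motion_range computes peak-to-peak and the 3D combination", {
  tr <- make_trace(rep(1, 5), rep(2, 5), rep(-1, 5))
  expect_equal(unname(motion_range(tr)[1:4]), c(0, 0, 0, 0))
  expect_warning(motion_range(make_trace(1, 2, 3)), "single-frame")

  # 3-4-5: dx range 3, dy range 4, dz range 0
  tr <- make_trace(c(0, 3), c(-2, 2), c(5, 5))
  r <- motion_range(tr)
  expect_equal(unname(r[c("dx", "dy", "dz", "dd")]), c(3, 4, 0, 5))

  # sinusoidal SI motion, amplitude 8, two periods densely sampled
  t <- seq(0, 8, by = 0.05)
  tr <- make_trace(0 * t, 0 * t, 8 * sin(2 * pi * t / 4))
  expect_equal(unname(motion_range(tr)["dz"]), 16, tolerance = 0.01)

  # invariances: time reversal and constant per-axis offsets
  tr <- make_trace(rnorm(20), rnorm(20), rnorm(20), rnorm(20), rnorm(20), rnorm(20))
  rev_tr <- tr[rev(seq_len(nrow(tr))), ]
  off_tr <- tr; off_tr$dx_mm <- off_tr$dx_mm + 5; off_tr$dz_mm <- off_tr$dz_mm - 3
  expect_equal(motion_range(rev_tr), motion_range(tr))
  expect_equal(motion_range(off_tr), motion_range(tr))
})

test_that("summarize_cohort averages per-patient ranges with sample SD", {
  tr1 <- make_trace(c(0, 3), c(0, 4), c(0, 0))
  expect_warning(s1 <- summarize_cohort(list(tr1)), "SD is undefined")
  expect_equal(s1$mean[s1$quantity == "dd"], 5)
  expect_true(all(s1$sd == 0))

  s2 <- summarize_cohort(list(tr1, tr1))
  expect_true(all(s2$sd == 0))
  expect_equal(s2$mean, s1$mean)

  tr2 <- make_trace(c(0, 5), c(0, 12), c(0, 0))
  s3 <- summarize_cohort(list(tr1, tr2))
  expect_equal(s3$mean[s3$quantity == "dd"], mean(c(5, 13)))
  expect_equal(s3$sd[s3$quantity == "dd"], sd(c(5, 13)))
  expect_equal(s3$quantity, c("dx", "dy", "dz", "dd", "theta_x", "theta_y", "theta_z"))
  expect_error(summarize_cohort(list()), "no motion traces")
})

test_that("paired_t_test matches the closed form and the reference implementation", {
  r <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  expect_equal(paired_t_test(c(2, 0), c(1, 1))$t, 0)  # d = {1, -1}

  # hand-computed: d = {1,2,3,4}, mean 2.5, sd 1.2909..., t = 2.5/(sd/2)
  r <- paired_t_test(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(r$df, 3)
  expect_equal(r$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(r$t, 3.872983, tolerance = 1e-6)

  # dual route: agrees with stats::t.test on random data
  set.seed(31)
  a <- rnorm(40, mean = 1.2); b <- rnorm(40)
  ref <- t.test(a, b, paired = TRUE)
  r <- paired_t_test(a, b)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)
  expect_equal(r$df, unname(ref$parameter))

  # zero-variance guard
  r <- paired_t_test(c(1, 1, 1), c(0, 0, 0))
  expect_equal(r$t, Inf)
  expect_equal(r$p, 0)
  expect_true(r$degenerate)

  expect_error(paired_t_test(1:3, 1:4), "equal length")
  expect_error(paired_t_test(1, 1), "at least 2")
})

test_that("residual_comparison pools frames and tests each quantity", {
  tr <- make_trace(rnorm(4), rnorm(4), rnorm(4))
  tr$res_3d_trans_mm <- c(2.0, 2.5, 1.8, 2.2)
  tr$res_3d_rigid_mm <- c(1.0, 1.2, 0.9, 1.1)
  cmp <- residual_comparison(list(tr))
  expect_equal(cmp$quantity, c("ex", "ey", "ez", "ed"))
  expect_equal(attr(cmp, "n_frames"), 4)

  ed <- cmp[cmp$quantity == "ed", ]
  ref <- t.test(tr$res_3d_trans_mm, tr$res_3d_rigid_mm, paired = TRUE)
  expect_equal(ed$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ed$p, ref$p.value, tolerance = 1e-9)
  expect_equal(ed$mean_trans, mean(c(2.0, 2.5, 1.8, 2.2)))
  expect_equal(ed$mean_rigid, mean(c(1.0, 1.2, 0.9, 1.1)))

  # constant nonzero per-axis difference: degenerate t reported as infinite
  ex <- cmp[cmp$quantity == "ex", ]
  expect_equal(ex$t, Inf)
  expect_equal(ex$p, 0)

  tr_same <- make_trace(rnorm(5), rnorm(5), rnorm(5), rr = 0.4, rt = 0.4)
  cmp_same <- residual_comparison(list(tr_same))
  expect_true(all(cmp_same$t == 0))
  expect_true(all(cmp_same$p == 1))

  bad <- tr; bad$res_3d_rigid_mm <- NULL
  expect_error(residual_comparison(list(bad)), "both")

  # formatted table renders small p as < 0.001
  lines <- format_residual_table(cmp)
  expect_length(lines, 5)
  expect_match(lines[5], "\\|e\\^d\\|")
})
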
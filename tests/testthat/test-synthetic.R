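test_that("generate_fiducials respects the implantation constraints deterministically", {
  f1 <- generate_fiducials(4, seed = 99)
  f2 <- generate_fiducials(4, seed = 99)
  expect_identical(unclass(f1), unclass(f2))

  for (s in 1:100) {
    n <- if (s %% 2 == 0) 3 else 4
    pts <- generate_fiducials(n, seed = s)
    expect_gt(min(dist(pts)), 20)
    expect_true(fiducials_valid(pts, min_dist = 20, min_angle = 15))
  }
  expect_error(generate_fiducials(4, bounds = c(5, 5, 5)), "bounds")
})

test_that("fiducials_valid rejects close or near-collinear configurations", {
  good <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0))
  expect_true(fiducials_valid(good))
  expect_false(fiducials_valid(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 30, 0))))
  # collinear: zero angles
  expect_false(fiducials_valid(rbind(c(0, 0, 0), c(25, 0, 0), c(50, 0, 0))))
  # angle at the middle vertex small
  expect_false(fiducials_valid(rbind(c(0, 0, 0), c(50, 3, 0), c(100, 0, 0))))
})

test_that("sample_motion realizes the sinusoid model with frame-0 normalization", {
  still <- breathing_model(amplitudes = c(0, 0, 0), rot_amplitudes = c(0, 0, 0),
                           deformation_sigma = 0)
  m <- sample_motion(still, seq(0, 400, by = 40), seed = 1)
  for (tf in m$transforms) {
    expect_equal(tf$R, diag(3), tolerance = 1e-12)
    expect_equal(tf$T, c(0, 0, 0), tolerance = 1e-12)
  }

  # peak-to-peak of one densely sampled period equals twice the amplitude
  bm <- breathing_model(amplitudes = c(0, 0, 8), rot_amplitudes = c(0, 0, 0),
                        period_s = 4, phases = c(0, 0, 0), phase_jitter = FALSE,
                        deformation_sigma = 0)
  m <- sample_motion(bm, seq(0, 4, by = 0.01))
  expect_equal(diff(range(m$translations_mm[, 3])), 16, tolerance = 1e-3)
  expect_equal(m$transforms[[1]]$T, c(0, 0, 0))

  # determinism under a fixed seed
  bmj <- breathing_model()
  t40 <- seq(0, 2240, by = 40)
  a <- sample_motion(bmj, t40, seed = 5)
  b <- sample_motion(bmj, t40, seed = 5)
  expect_identical(a, b)
  c_ <- sample_motion(bmj, t40, seed = 6)
  expect_false(identical(a$phase_times, c_$phase_times))
})

test_that("apply_deformation adds unbiased Gaussian offsets of the nominal SD", {
  pts <- generate_fiducials(4, seed = 2)
  same <- apply_deformation(pts, 0)
  expect_equal(unclass(same)[, ], unclass(pts)[, ], ignore_attr = TRUE)

  big <- matrix(0, 10000, 3)
  out <- apply_deformation(big, 0.5, seed = 8)
  off <- attr(out, "offsets")
  expect_lt(max(abs(apply(off, 2, sd) - 0.5)), 0.02 * 0.5 * 2)
  se <- 0.5 / sqrt(nrow(off))
  expect_lt(max(abs(colMeans(off))), 3 * se)
})

test_that("simulate_fraction retains consistent ground truth", {
  frozen <- simulation_config(
    breathing = breathing_model(amplitudes = c(0, 0, 0),
                                rot_amplitudes = c(0, 0, 0),
                                deformation_sigma = 0),
    n_frames = 5, seed = 3
  )
  sim <- simulate_fraction(frozen)
  for (i in 2:5) {
    expect_equal(sim$projections[[i]], sim$projections[[1]], tolerance = 1e-12)
  }

  cfg <- simulation_config(n_frames = 8, seed = 12)
  sim <- simulate_fraction(cfg)
  # invariant: positions = transform(base markers) + recorded offsets
  for (i in 1:8) {
    expect_equal(sim$truth_positions[[i]],
                 apply_transform(sim$truth_transforms[[i]], sim$markers) +
                   sim$deformation[[i]],
                 tolerance = 1e-12)
  }
  expect_equal(sim$truth_transforms[[1]]$R, diag(3), tolerance = 1e-12)
  expect_equal(sim$truth_transforms[[1]]$T, c(0, 0, 0), tolerance = 1e-12)

  sim2 <- simulate_fraction(cfg)
  expect_identical(sim$projections, sim2$projections)
})

test_that("noise-free simulation is exactly recoverable end to end", {
  cfg <- simulation_config(
    breathing = breathing_model(deformation_sigma = 0),
    n_frames = 10, seed = 42
  )
  sim <- simulate_fraction(cfg)
  trace <- track_fraction(sim)
  tfs <- attr(trace, "transforms")
  for (i in 2:10) {
    tf <- tfs[[as.character(i)]]
    expect_lt(max(abs(tf$T - sim$truth_transforms[[i]]$T)), 1e-6)
    expect_lt(max(abs(euler_angles(tf$R) -
                        euler_angles(sim$truth_transforms[[i]]$R))), 1e-6)
  }
})

test_that("render_projection_image places sub-pixel Gaussian blobs deterministically", {
  g <- imaging_geometry(detector_size_px = 128)
  flat <- render_projection_image(NULL, g, params = list(background = 0.15))
  expect_true(all(flat == 0.15))

  # intensity-weighted centroid of a clean blob matches the request to 0.05 px
  pos <- rbind(c(3.7, -6.2))
  img <- render_projection_image(pos, g, params = list(background = 0))
  w <- img / sum(img)
  rows <- rowSums(w) ; cols <- colSums(w)
  r_c <- sum((seq_len(128) - 1) * rows)
  c_c <- sum((seq_len(128) - 1) * cols)
  expect_lt(abs(c_c - mm_to_pixels(pos[1], g)), 0.05)
  expect_lt(abs(r_c - mm_to_pixels(pos[2], g)), 0.05)

  # identical seeds give identical pixels; markers off-detector are dropped
  p1 <- render_projection_image(pos, g, params = list(noise_sd = 0.05), seed = 4)
  p2 <- render_projection_image(pos, g, params = list(noise_sd = 0.05), seed = 4)
  expect_identical(p1, p2)
  expect_warning(
    out <- render_projection_image(rbind(c(1e4, 0)), g),
    "outside the detector"
  )
  expect_true(all(out == 0.1))
})
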
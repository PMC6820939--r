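# Run expr with a local RNG state seeded by `seed`; the caller's RNG stream
# is untouched. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Breathing-driven rigid motion model
#'
#' Sinusoid-plus-drift model of respiratory liver motion, dominant in the
#' superior-inferior (SI) direction: each translation component c follows
#' `A_c * sin(2*pi*t_eff/period + phi_c) + drift_c * t/60`, each rotation
#' angle analogously with amplitudes `rot_amplitudes` (no drift). All
#' components share the breathing phase `t_eff`.
#'
#' Stereo imaging samples the fraction sparsely (every 40 s) relative to the
#' ~4 s breathing cycle, so acquisition effectively catches random breathing
#' phases. With `phase_jitter = TRUE` (default) each frame's phase is
#' dithered uniformly over one period, realizing exactly that behaviour;
#' disable it for strictly periodic sampling (e.g. analytic range checks).
#'
#' Default amplitudes (1.5, 2.8, 8.0) mm and (2, 2.5, 2) degrees place
#' simulated per-fraction ranges in the regime reported for liver SBRT
#' patients (peak-to-peak ~3/5.5/16 mm LR/AP/SI and ~4-5 degrees).
#'
#' @param amplitudes Half-peak translation amplitudes (LR, AP, SI), mm.
#' @param rot_amplitudes Half-peak rotation amplitudes about (LR, AP, SI),
#'   degrees.
#' @param period_s Breathing period, seconds.
#' @param phases,rot_phases Per-component phase offsets, radians.
#' @param drift Linear baseline drift per translation axis, mm/min.
#' @param deformation_sigma Per-marker isotropic Gaussian jitter SD (mm)
#'   emulating tumor deformation; 0 disables.
#' @param phase_jitter Dither each frame's breathing phase uniformly over
#'   one period?
#' @return Object of class `breathing_model`.
#' @export
breathing_model <- function(amplitudes = c(1.5, 2.8, 8.0),
                            rot_amplitudes = c(2, 2.5, 2),
                            period_s = 4,
                            phases = c(0, 2 * pi / 3, 4 * pi / 3),
                            rot_phases = c(pi / 2, 7 * pi / 6, 11 * pi / 6),
                            drift = c(0, 0, 0),
                            deformation_sigma = 0.5,
                            phase_jitter = TRUE) {
  stopifnot(length(amplitudes) == 3, all(amplitudes >= 0),
            length(rot_amplitudes) == 3, all(rot_amplitudes >= 0),
            period_s > 0, deformation_sigma >= 0,
            length(phases) == 3, length(rot_phases) == 3, length(drift) == 3)
  structure(list(amplitudes = amplitudes, rot_amplitudes = rot_amplitudes,
                 period_s = period_s, phases = phases, rot_phases = rot_phases,
                 drift = drift, deformation_sigma = deformation_sigma,
                 phase_jitter = isTRUE(phase_jitter)),
            class = "breathing_model")
}

#' Generate an implantation-compliant fiducial configuration
#'
#' Rejection-samples marker positions uniformly in a box until the clinical
#' implantation constraints hold: every pairwise distance exceeds `min_dist`
#' (default 20 mm, avoiding overlap/mismatching) and every interior angle of
#' every marker triple exceeds `min_angle` (default 15 degrees, avoiding
#' near-collinear configurations). Deterministic given `seed`.
#'
#' @param n Number of markers, 3 or 4.
#' @param bounds Box half-widths (mm) per axis; markers are sampled in
#'   `[-bounds, +bounds]` centered on the tumor.
#' @param seed RNG seed (NULL uses the current stream).
#' @param min_dist Minimum pairwise distance, mm.
#' @param min_angle Minimum triple angle, degrees.
#' @param max_attempts Sampling attempts before giving up.
#' @return n x 3 matrix of marker positions (mm) with attribute `seed`.
#' @export
generate_fiducials <- function(n = 4, bounds = c(30, 30, 30), seed = NULL,
                               min_dist = 20, min_angle = 15,
                               max_attempts = 10000) {
  stopifnot(n %in% c(3, 4), all(bounds > 0))
  if (2 * max(bounds) < min_dist) {
    stop("bounds too small to admit the minimum inter-marker distance")
  }
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      pts <- cbind(stats::runif(n, -bounds[1], bounds[1]),
                   stats::runif(n, -bounds[2], bounds[2]),
                   stats::runif(n, -bounds[3], bounds[3]))
      if (fiducials_valid(pts, min_dist, min_angle)) {
        colnames(pts) <- c("x", "y", "z")
        attr(pts, "seed") <- seed
        return(pts)
      }
    }
    stop(sprintf(paste0("no fiducial configuration satisfying distance > %g mm and ",
                        "angle > %g deg found in %d attempts; enlarge the bounds"),
                 min_dist, min_angle, max_attempts))
  })
}

#' Check fiducial implantation constraints
#'
#' @param pts n x 3 marker matrix (mm).
#' @param min_dist Minimum pairwise distance, mm.
#' @param min_angle Minimum angle of any marker triple, degrees.
#' @return TRUE when all constraints hold.
#' @export
fiducials_valid <- function(pts, min_dist = 20, min_angle = 15) {
  pts <- as_point_matrix(pts)
  n <- nrow(pts)
  if (min(stats::dist(pts)) <= min_dist) return(FALSE)
  if (n >= 3) {
    for (tri in utils::combn(n, 3, simplify = FALSE)) {
      p <- pts[tri, ]
      for (v in 1:3) {
        a <- p[setdiff(1:3, v)[1], ] - p[v, ]
        b <- p[setdiff(1:3, v)[2], ] - p[v, ]
        ang <- acos(pmin(1, pmax(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
        if (ang * 180 / pi <= min_angle) return(FALSE)
      }
    }
  }
  TRUE
}

#' Sample rigid breathing motion at given times
#'
#' Evaluates a [breathing_model()] at the acquisition times and returns one
#' rigid transform per frame, normalized so that the first frame is the
#' identity (reference frame): the raw per-frame map `M_t` (rotation about
#' the origin from the model's Euler angles, then translation) is reported
#' as `M_t o M_0^{-1}`. Rotation-center handling is applied downstream by
#' [simulate_fraction()].
#'
#' @param model A [breathing_model()].
#' @param times Non-decreasing acquisition times, seconds.
#' @param seed RNG seed for the phase jitter (unused when
#'   `model$phase_jitter` is FALSE).
#' @return List: `transforms` (list of [rigid_transform()], first = identity),
#'   `translations_mm` / `angles_deg` (raw per-frame model values, n x 3),
#'   `times`, `phase_times`.
#' @export
sample_motion <- function(model, times, seed = NULL) {
  stopifnot(inherits(model, "breathing_model"), length(times) >= 1,
            !is.unsorted(times))
  n <- length(times)
  jitter <- if (model$phase_jitter) {
    with_seed(seed, stats::runif(n, 0, model$period_s))
  } else {
    rep(0, n)
  }
  t_eff <- times + jitter
  w <- 2 * pi / model$period_s
  trans <- sapply(1:3, function(c) {
    model$amplitudes[c] * sin(w * t_eff + model$phases[c]) +
      model$drift[c] * times / 60
  })
  ang <- sapply(1:3, function(c) {
    model$rot_amplitudes[c] * sin(w * t_eff + model$rot_phases[c])
  })
  trans <- matrix(trans, n, 3); ang <- matrix(ang, n, 3)
  raw <- lapply(seq_len(n), function(i) {
    rigid_transform(R = rotation_from_euler(ang[i, ]), T = trans[i, ])
  })
  inv0 <- invert_transform(raw[[1]])
  transforms <- lapply(raw, compose_transforms, b = inv0)
  list(transforms = transforms, translations_mm = trans, angles_deg = ang,
       times = times, phase_times = t_eff)
}

#' Apply per-marker deformation jitter
#'
#' Adds independent zero-mean isotropic Gaussian offsets (SD `sigma` per
#' axis per marker), emulating non-rigid tumor deformation that a rigid
#' model cannot capture. The drawn offsets are recorded in the `offsets`
#' attribute for ground truth.
#'
#' @param points n x 3 marker matrix (mm).
#' @param sigma Per-axis offset SD, mm (0 returns the input unchanged).
#' @param seed RNG seed.
#' @return Deformed n x 3 matrix with attribute `offsets`.
#' @export
apply_deformation <- function(points, sigma, seed = NULL) {
  points <- as_point_matrix(points)
  stopifnot(sigma >= 0)
  off <- if (sigma == 0) {
    matrix(0, nrow(points), 3)
  } else {
    with_seed(seed, matrix(stats::rnorm(3 * nrow(points), sd = sigma),
                           nrow(points), 3))
  }
  out <- points + off
  attr(out, "offsets") <- off
  out
}

#' Render a synthetic detector image of projected markers
#'
#' Draws each marker as an isotropic Gaussian-profile bright blob on a
#' uniform background, honouring sub-pixel blob centers, with optional
#' additive pixel noise, low-frequency clutter (emulating bone-structure
#' shading) and single-pixel bright specks. Image rows index the v axis,
#' columns the u axis; intensities are clipped to [0, 1].
#'
#' @param proj_points n x 2 matrix of (u, v) marker positions, mm. Markers
#'   outside the detector field of view are omitted with a warning.
#' @param g An [imaging_geometry()].
#' @param params List of rendering parameters (missing entries take
#'   defaults): `blob_sigma_px` (Gaussian blob SD, px, default 1.5),
#'   `contrast` (blob peak amplitude, default 0.6), `background` (default
#'   0.1), `noise_sd` (additive Gaussian pixel noise SD, default 0),
#'   `clutter` (logical, low-frequency shading, default FALSE),
#'   `clutter_amp` (default 0.08), `n_specks` (count of single-pixel bright
#'   specks, default 0), `speck_amp` (default 0.8).
#' @param seed RNG seed for noise/clutter/specks.
#' @return Numeric matrix `detector_size_px` x `detector_size_px`.
#' @export
render_projection_image <- function(proj_points, g, params = list(), seed = NULL) {
  p <- list(blob_sigma_px = 1.5, contrast = 0.6, background = 0.1,
            noise_sd = 0, clutter = FALSE, clutter_amp = 0.08,
            n_specks = 0, speck_amp = 0.8)
  p[names(params)] <- params
  N <- g$detector_size_px
  img <- matrix(p$background, N, N)
  if (!is.null(proj_points) && length(proj_points)) {
    pts <- matrix(proj_points, ncol = 2)
    cols <- mm_to_pixels(pts[, 1], g)   # u -> column
    rows <- mm_to_pixels(pts[, 2], g)   # v -> row
    half <- ceiling(5 * p$blob_sigma_px)
    for (i in seq_len(nrow(pts))) {
      r0 <- rows[i]; c0 <- cols[i]
      if (r0 < 0 || r0 > N - 1 || c0 < 0 || c0 > N - 1) {
        warning(sprintf("marker %d projects outside the detector; omitted", i))
        next
      }
      rr <- max(0, floor(r0 - half)):min(N - 1, ceiling(r0 + half))
      cc <- max(0, floor(c0 - half)):min(N - 1, ceiling(c0 + half))
      blob <- p$contrast *
        exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / (2 * p$blob_sigma_px^2))
      img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + blob
    }
  }
  with_seed(seed, {
    if (p$clutter) {
      x <- matrix(seq_len(N) / N, N, N)
      y <- t(x)
      for (k in 1:3) {
        f <- stats::runif(2, 0.5, 3)
        ph <- stats::runif(1, 0, 2 * pi)
        img <- img + p$clutter_amp / 3 * sin(2 * pi * (f[1] * x + f[2] * y) + ph)
      }
    }
    if (p$n_specks > 0) {
      ij <- cbind(sample.int(N, p$n_specks, replace = TRUE),
                  sample.int(N, p$n_specks, replace = TRUE))
      img[ij] <- img[ij] + p$speck_amp
    }
    if (p$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(N * N, sd = p$noise_sd), N, N)
    }
  })
  pmin(pmax(img, 0), 1)
}

#' Simulation scenario configuration
#'
#' Bundles everything [simulate_fraction()] needs: imaging geometry,
#' breathing model, marker configuration (or the request to generate one),
#' sampling schedule and rendering parameters. Defaults emulate one
#' treatment fraction: 57 stereo acquisitions 40 s apart (~38 min).
#'
#' @param geometry An [imaging_geometry()].
#' @param breathing A [breathing_model()].
#' @param n_frames Number of stereo acquisitions (>= 2).
#' @param frame_interval_s Time between acquisitions, seconds.
#' @param n_markers Number of fiducials (3 or 4) when `markers` is NULL.
#' @param markers Optional fixed n x 3 marker matrix (mm); NULL generates a
#'   configuration via [generate_fiducials()].
#' @param rotation_center Rotation origin of the motion model; NULL uses the
#'   marker centroid.
#' @param render Render detector images for each frame?
#' @param image_params Rendering parameter list, see
#'   [render_projection_image()].
#' @param seed Master seed; all stage seeds are derived from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = imaging_geometry(),
                              breathing = breathing_model(),
                              n_frames = 57,
                              frame_interval_s = 40,
                              n_markers = 4,
                              markers = NULL,
                              rotation_center = NULL,
                              render = FALSE,
                              image_params = list(),
                              seed = 1) {
  stopifnot(inherits(geometry, "imaging_geometry"),
            inherits(breathing, "breathing_model"),
            n_frames >= 2, frame_interval_s > 0)
  if (!is.null(markers)) markers <- as_point_matrix(markers)
  structure(list(geometry = geometry, breathing = breathing,
                 n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 n_markers = n_markers, markers = markers,
                 rotation_center = rotation_center,
                 render = isTRUE(render), image_params = image_params,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate one treatment fraction with ground truth
#'
#' Generates a complete synthetic fraction: a fiducial configuration, a
#' breathing-driven rigid transform per frame (rotations about the marker
#' centroid, first frame normalized to identity), per-marker deformation
#' jitter, stereo projections of every marker, and (optionally) rendered
#' detector image pairs. All ground truth is retained.
#'
#' Per frame: `positions[t] = truth_transform[t](base markers) +
#' deformation[t]`; projections and images derive from `positions[t]`.
#'
#' @param config A [simulation_config()].
#' @return Object of class `simulated_fraction`: `config`, `markers` (base
#'   configuration), `rotation_center`, `times`, `truth_transforms` (list of
#'   [rigid_transform()]), `truth_positions` (list of n x 3), `deformation`
#'   (list of n x 3 offsets), `projections` (list of n x 4 matrices with
#'   columns u_a, v_a, u_b, v_b), `images` (list of `list(A =, B =)` or
#'   NULL).
#' @export
simulate_fraction <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sub <- with_seed(config$seed, sample.int(.Machine$integer.max - 1, 4))
  markers <- config$markers
  if (is.null(markers)) {
    markers <- generate_fiducials(config$n_markers, seed = sub[1])
  }
  center <- if (is.null(config$rotation_center)) centroid(markers) else config$rotation_center
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval_s
  motion <- sample_motion(config$breathing, times, seed = sub[2])
  # conjugate the origin-centered transforms by the rotation center
  truth <- lapply(motion$transforms, function(tf) {
    rigid_transform(R = tf$R,
                    T = tf$T + center - as.numeric(tf$R %*% center))
  })
  sigma <- config$breathing$deformation_sigma
  def <- with_seed(sub[3], lapply(seq_len(config$n_frames), function(i) {
    if (sigma == 0) matrix(0, nrow(markers), 3)
    else matrix(stats::rnorm(3 * nrow(markers), sd = sigma), nrow(markers), 3)
  }))
  positions <- lapply(seq_len(config$n_frames), function(i) {
    apply_transform(truth[[i]], markers) + def[[i]]
  })
  projections <- lapply(positions, project_set, g = config$geometry)
  images <- NULL
  if (config$render) {
    img_seeds <- with_seed(sub[4], sample.int(.Machine$integer.max - 1,
                                              2 * config$n_frames))
    images <- lapply(seq_len(config$n_frames), function(i) {
      pp <- projections[[i]]
      list(A = render_projection_image(pp[, c("u_a", "v_a")], config$geometry,
                                       config$image_params, seed = img_seeds[2 * i - 1]),
           B = render_projection_image(pp[, c("u_b", "v_b")], config$geometry,
                                       config$image_params, seed = img_seeds[2 * i]))
    })
  }
  structure(list(config = config, markers = markers, rotation_center = center,
                 times = times, truth_transforms = truth,
                 truth_positions = positions, deformation = def,
                 projections = projections, images = images),
            class = "simulated_fraction")
}

#' @export
print.simulated_fraction <- function(x, ...) {
  cat(sprintf("<simulated_fraction> %d frames, %d markers, %s images\n",
              length(x$times), nrow(x$markers),
              if (is.null(x$images)) "no" else "with"))
  invisible(x)
}
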
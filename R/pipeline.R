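#' Detect and pair markers across a fraction's image pairs
#'
#' Runs [detect_markers()] on both views of every frame and pairs the
#' detections with [pair_views()]. Frames whose detection or pairing fails
#' yield NULL entries (handled downstream by [track_projections()]).
#'
#' @param images List of per-frame image pairs `list(A =, B =)`.
#' @param g An [imaging_geometry()].
#' @param seg Named list of [detect_markers()] arguments (window, threshold,
#'   invert, min_area, max_area, weighted).
#' @param pair_tol Pairing tolerance on the v difference, mm.
#' @return List of projection-pair matrices (columns u_a, v_a, u_b, v_b),
#'   one per frame; NULL where the frame was unusable.
#' @export
detect_fraction <- function(images, g, seg = list(), pair_tol = 2) {
  lapply(seq_along(images), function(i) {
    det <- function(img) do.call(detect_markers, c(list(img = img, g = g), seg))
    out <- tryCatch({
      a <- det(images[[i]]$A)
      b <- det(images[[i]]$B)
      pair_views(a, b, tol = pair_tol)
    }, error = function(e) {
      warning(sprintf("frame %d: %s", i, conditionMessage(e)))
      NULL
    })
    out
  })
}

#' Track rigid motion over a fraction from projection coordinates
#'
#' The core tracking pipeline: reconstructs each frame's 3D marker set from
#' its stereo projection pairs, registers every frame to the reference frame
#' both with the full rigid model (quaternion ICP) and with translation
#' only, and assembles a per-frame motion trace. The estimated transform
#' maps reference markers onto the current frame, so its translation and
#' Euler angles are the tumor motion relative to the reference acquisition.
#'
#' Reported `dx/dy/dz` are the displacement of the reference marker centroid
#' under the fitted transform. Frames with fewer than 3 paired markers are
#' skipped with a warning; an unusable reference frame is an error.
#'
#' @param pps List of per-frame projection matrices (columns u_a, v_a, u_b,
#'   v_b, mm); NULL entries mark unusable frames.
#' @param g An [imaging_geometry()].
#' @param times Optional acquisition times (s); defaults to 40 s spacing.
#' @param reference Index of the reference frame (default 1, the acquisition
#'   near the beginning of treatment).
#' @param labelled Markers correspond by row index across frames? FALSE
#'   (default) uses nearest-neighbour ICP correspondence.
#' @param threshold ICP convergence threshold (mm), see [icp_register()].
#' @param max_iter ICP iteration cap.
#' @param warm_start Initialize each frame's ICP with the previous frame's
#'   transform instead of the identity?
#' @param patient_id Optional identifier stored on the trace.
#' @return A `motion_trace` data frame, one row per usable frame:
#'   `frame_index`, `time_s`, `dx_mm`, `dy_mm`, `dz_mm`, `theta_x_deg`,
#'   `theta_y_deg`, `theta_z_deg`, per-axis and 3D mean absolute residuals
#'   for both models (`res_*_rigid_mm`, `res_*_trans_mm`), per-frame RMS
#'   residuals for both models (`res_rms_rigid_mm`, `res_rms_trans_mm`;
#'   the rigid RMS is guaranteed not to exceed the translation-only RMS,
#'   since that is the quantity the fit minimizes), `rms_mm`,
#'   `iterations`, `converged`. Attributes: `patient_id`,
#'   `reference_frame_index`, `transforms` (list of per-frame
#'   [rigid_transform()]s), `skipped` (frame indices).
#' @export
track_projections <- function(pps, g, times = NULL, reference = 1,
                              labelled = FALSE, threshold = 0.001,
                              max_iter = 50, warm_start = FALSE,
                              patient_id = NA_character_) {
  stopifnot(length(pps) >= 1, reference >= 1, reference <= length(pps))
  if (is.null(times)) times <- (seq_along(pps) - 1) * 40
  usable <- !vapply(pps, is.null, logical(1)) &
    vapply(pps, function(x) !is.null(x) && nrow(x) >= 3, logical(1))
  if (!usable[reference]) {
    stop("reference frame has fewer than 3 paired markers: cannot track")
  }
  ref <- reconstruct_set(pps[[reference]], g)
  skipped <- which(!usable)
  if (length(skipped)) {
    warning(sprintf("skipping %d frame(s) with < 3 paired markers: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  ref_center <- centroid(ref)
  rows <- list(); tfs <- list()
  prev_tf <- NULL
  for (i in which(usable)) {
    X <- reconstruct_set(pps[[i]], g)
    init <- if (warm_start) prev_tf else NULL
    icp <- icp_register(X, ref, threshold = threshold, max_iter = max_iter,
                        labelled = labelled, init = init)
    prev_tf <- icp$transform
    idx <- icp$correspondence
    Xm <- X[idx, , drop = FALSE]
    rigid_res <- residual_errors(Xm, ref, icp$transform)
    tr_tf <- translation_only_fit(Xm, ref)
    tr_res <- residual_errors(Xm, ref, tr_tf)
    disp <- apply_transform(icp$transform, ref_center) - ref_center
    ang <- euler_angles(icp$transform$R)
    rows[[length(rows) + 1]] <- data.frame(
      frame_index = i, time_s = times[i],
      dx_mm = disp[1], dy_mm = disp[2], dz_mm = disp[3],
      theta_x_deg = ang[["theta_x"]], theta_y_deg = ang[["theta_y"]],
      theta_z_deg = ang[["theta_z"]],
      res_x_rigid_mm = rigid_res$mean_abs[["x"]],
      res_y_rigid_mm = rigid_res$mean_abs[["y"]],
      res_z_rigid_mm = rigid_res$mean_abs[["z"]],
      res_3d_rigid_mm = rigid_res$mean_3d,
      res_x_trans_mm = tr_res$mean_abs[["x"]],
      res_y_trans_mm = tr_res$mean_abs[["y"]],
      res_z_trans_mm = tr_res$mean_abs[["z"]],
      res_3d_trans_mm = tr_res$mean_3d,
      res_rms_rigid_mm = rigid_res$rms,
      res_rms_trans_mm = tr_res$rms,
      rms_mm = icp$rms_residual,
      iterations = icp$iterations,
      converged = icp$converged
    )
    tfs[[as.character(i)]] <- icp$transform
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  attr(trace, "patient_id") <- patient_id
  attr(trace, "reference_frame_index") <- reference
  attr(trace, "transforms") <- tfs
  attr(trace, "skipped") <- skipped
  class(trace) <- c("motion_trace", "data.frame")
  trace
}

#' Track a (simulated) fraction end to end
#'
#' Convenience wrapper around the pipeline for a [simulate_fraction()]
#' result: uses the exact projection coordinates (`use_images = FALSE`) or
#' runs the full image path (segmentation + pairing) on the rendered
#' detector images.
#'
#' @param sim A `simulated_fraction`.
#' @param use_images Run segmentation on rendered images instead of using
#'   the projection coordinates directly? Requires `sim$images`.
#' @param seg,pair_tol Segmentation/pairing parameters for the image path,
#'   see [detect_fraction()].
#' @param ... Passed to [track_projections()].
#' @return A `motion_trace` (see [track_projections()]).
#' @export
track_fraction <- function(sim, use_images = FALSE, seg = list(),
                           pair_tol = 2, ...) {
  stopifnot(inherits(sim, "simulated_fraction"))
  pps <- if (use_images) {
    if (is.null(sim$images)) stop("fraction was simulated without rendered images")
    detect_fraction(sim$images, sim$config$geometry, seg = seg,
                    pair_tol = pair_tol)
  } else {
    sim$projections
  }
  track_projections(pps, sim$config$geometry, times = sim$times, ...)
}
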
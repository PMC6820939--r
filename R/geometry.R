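#' Stereo imaging geometry
#'
#' Describes the parallel-ray stereo projection model of a robotic
#' radiosurgery kV imaging system: two orthogonal detectors whose image
#' frame is rotated by `theta_deg` about the superior-inferior (z) axis
#' relative to the patient frame, plus the raster scale of the detectors.
#'
#' Patient axes follow the radiotherapy convention: x = left-right (LR),
#' y = anterior-posterior (AP), z = superior-inferior (SI).
#'
#' @param theta_deg Rotation (degrees) between the image coordinate frame and
#'   the patient frame, about the z axis. Oblique kV sources correspond to
#'   45 degrees, the default. Either sign is accepted (the in-plane rotation
#'   direction is a convention of the installation).
#' @param pixel_spacing_mm Detector pixel pitch in mm/pixel. Default 0.39,
#'   plausible for a 1024x1024 amorphous-silicon flat panel.
#' @param detector_size_px Detector side length in pixels (square detector).
#' @param detector_offset_mm Physical position (mm) of pixel (0,0). The
#'   default centers the detector so that mm coordinate 0 falls at the
#'   detector midpoint: `-(detector_size_px - 1) / 2 * pixel_spacing_mm`.
#'
#' @return An object of class `imaging_geometry`.
#' @examples
#' g <- imaging_geometry(theta_deg = 45)
#' reconstruct_point(project_point(c(10, 5, -3), g), g)
#' @export
imaging_geometry <- function(theta_deg = 45,
                             pixel_spacing_mm = 0.39,
                             detector_size_px = 1024,
                             detector_offset_mm = NULL) {
  stopifnot(is.finite(theta_deg), pixel_spacing_mm > 0, detector_size_px > 0)
  if (is.null(detector_offset_mm)) {
    detector_offset_mm <- -(detector_size_px - 1) / 2 * pixel_spacing_mm
  }
  structure(
    list(
      theta_deg = theta_deg,
      pixel_spacing_mm = pixel_spacing_mm,
      detector_size_px = as.integer(detector_size_px),
      detector_offset_mm = detector_offset_mm
    ),
    class = "imaging_geometry"
  )
}

#' @export
print.imaging_geometry <- function(x, ...) {
  cat("<imaging_geometry>\n")
  cat(sprintf("  theta: %g deg | pixel spacing: %g mm | detector: %d px | offset: %g mm\n",
              x$theta_deg, x$pixel_spacing_mm, x$detector_size_px, x$detector_offset_mm))
  invisible(x)
}

# z-axis rotation matrix of the image->patient frame change
frame_rotation <- function(g) {
  th <- g$theta_deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), nrow = 3, ncol = 3)
}

as_pp_matrix <- function(pp) {
  nm <- c("u_a", "v_a", "u_b", "v_b")
  if (is.data.frame(pp)) pp <- as.matrix(pp[, nm, drop = FALSE])
  if (is.null(dim(pp))) pp <- matrix(pp, nrow = 1)
  if (ncol(pp) != 4) stop("projection pairs must have 4 columns (u_a, v_a, u_b, v_b)")
  if (!all(is.finite(pp))) stop("projection coordinates must be finite")
  colnames(pp) <- nm
  pp
}

as_point_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) != 3) stop("points must have 3 columns (x, y, z)")
  if (!all(is.finite(p))) stop("point coordinates must be finite")
  colnames(p) <- c("x", "y", "z")
  p
}

#' Reconstruct a 3D point from its orthogonal stereo projections
#'
#' Back-projects one marker's projection pair into patient coordinates under
#' the parallel-ray model: the vector `(u_a, u_b, (v_a + v_b)/2)` expressed in
#' the image frame is rotated into the patient frame by the z-axis rotation of
#' angle theta. The two views' SI coordinates `v_a`, `v_b` are theoretically
#' equal and are averaged even when they differ (e.g. under segmentation
#' noise).
#'
#' @param pp Projection pair: numeric vector `c(u_a, v_a, u_b, v_b)` in mm.
#' @param g An [imaging_geometry()].
#' @return Numeric vector `c(x, y, z)` in mm (patient frame: LR, AP, SI).
#' @seealso [project_point()] for the exact inverse, [reconstruct_set()].
#' @export
reconstruct_point <- function(pp, g) {
  drop(reconstruct_set(matrix(as_pp_matrix(pp)[1, ], nrow = 1), g))
}

#' Reconstruct a set of 3D points from projection pairs
#'
#' Vectorized [reconstruct_point()]: each row of `pps` is one marker's
#' `(u_a, v_a, u_b, v_b)`. Order is preserved.
#'
#' @param pps Numeric matrix (or data frame) with columns u_a, v_a, u_b, v_b.
#' @param g An [imaging_geometry()].
#' @return n x 3 matrix of patient coordinates (mm).
#' @export
reconstruct_set <- function(pps, g) {
  pps <- as_pp_matrix(pps)
  if (nrow(pps) == 0) stop("no projection pairs to reconstruct (no markers)")
  img_vec <- cbind(pps[, "u_a"], pps[, "u_b"], (pps[, "v_a"] + pps[, "v_b"]) / 2)
  out <- img_vec %*% t(frame_rotation(g))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Project a 3D point onto the two detectors
#'
#' Exact algebraic inverse of [reconstruct_point()] under the parallel-ray
#' model: applies the transpose of the frame rotation and reads off detector
#' coordinates, with `v_a == v_b` (both views share the SI coordinate).
#'
#' @param p Numeric vector `c(x, y, z)` in mm, patient frame.
#' @param g An [imaging_geometry()].
#' @return Named numeric vector `c(u_a, v_a, u_b, v_b)` in mm.
#' @export
project_point <- function(p, g) {
  drop(project_set(matrix(as_point_matrix(p)[1, ], nrow = 1), g))
}

#' Project a set of 3D points onto the two detectors
#'
#' @param points n x 3 matrix of patient coordinates (mm).
#' @param g An [imaging_geometry()].
#' @return n x 4 matrix with columns u_a, v_a, u_b, v_b (mm).
#' @export
project_set <- function(points, g) {
  points <- as_point_matrix(points)
  img_vec <- points %*% frame_rotation(g) # right-multiplication == R^T %*% p
  out <- cbind(u_a = img_vec[, 1], v_a = img_vec[, 3],
               u_b = img_vec[, 2], v_b = img_vec[, 3])
  out
}

#' Convert detector pixel coordinates to physical mm
#'
#' Affine map `mm = offset + px * spacing` with 0-based pixel indices and
#' pixel centers at integer coordinates. Invertible via [mm_to_pixels()].
#'
#' @param px Numeric vector/matrix of 0-based pixel coordinates.
#' @param g An [imaging_geometry()].
#' @return Coordinates in mm, same shape as `px`.
#' @export
pixels_to_mm <- function(px, g) {
  g$detector_offset_mm + px * g$pixel_spacing_mm
}

#' Convert physical mm to detector pixel coordinates
#'
#' @inheritParams pixels_to_mm
#' @param mm Numeric vector/matrix of mm coordinates.
#' @return 0-based (continuous) pixel coordinates, same shape as `mm`.
#' @export
mm_to_pixels <- function(mm, g) {
  (mm - g$detector_offset_mm) / g$pixel_spacing_mm
}
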
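# CSV/JSON readers and writers. Floats are serialized with 9 significant
# digits ('.' decimal, comma separator, header row) so reruns with identical
# config + seed are byte-identical.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.9g", x))
}

write_csv9 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read imaging geometry JSON
#'
#' JSON object with fields `theta_deg`, `pixel_spacing_mm`,
#' `detector_size_px`, `detector_offset_mm`.
#'
#' @param g An [imaging_geometry()].
#' @param path File path.
#' @return `write_geometry_json` the path; `read_geometry_json` an
#'   [imaging_geometry()].
#' @export
write_geometry_json <- function(g, path) {
  stopifnot(inherits(g, "imaging_geometry"))
  jsonlite::write_json(unclass(g), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  imaging_geometry(theta_deg = x$theta_deg,
                   pixel_spacing_mm = x$pixel_spacing_mm,
                   detector_size_px = x$detector_size_px,
                   detector_offset_mm = x$detector_offset_mm)
}

#' Write / read a simulation scenario config JSON
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @return The path / a [simulation_config()].
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- list(
    geometry = unclass(config$geometry),
    breathing = unclass(config$breathing),
    n_frames = config$n_frames,
    frame_interval_s = config$frame_interval_s,
    n_markers = config$n_markers,
    markers = if (is.null(config$markers)) NULL else unname(apply(config$markers, 1, as.list)),
    rotation_center = config$rotation_center,
    render = config$render,
    image_params = config$image_params,
    seed = config$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  markers <- x$markers
  if (!is.null(markers) && length(markers)) {
    markers <- matrix(unlist(markers), ncol = 3, byrow = !is.matrix(markers))
    if (is.matrix(x$markers)) markers <- x$markers
  } else {
    markers <- NULL
  }
  simulation_config(
    geometry = do.call(imaging_geometry, as.list(x$geometry)),
    breathing = do.call(breathing_model, as.list(x$breathing)),
    n_frames = x$n_frames,
    frame_interval_s = x$frame_interval_s,
    n_markers = x$n_markers,
    markers = markers,
    rotation_center = x$rotation_center,
    render = isTRUE(x$render),
    image_params = as.list(x$image_params),
    seed = x$seed
  )
}

#' Write / read per-frame projection coordinates CSV
#'
#' Schema: one marker-frame per row with columns `frame_index`, `marker_id`,
#' `u_a_mm`, `v_a_mm`, `u_b_mm`, `v_b_mm`. Reading returns a list indexed by
#' frame with NULL for frames absent from the file.
#'
#' @param pps List of per-frame projection matrices (columns u_a, v_a, u_b,
#'   v_b); NULL entries are skipped.
#' @param path File path.
#' @return The path / a list of projection matrices.
#' @export
write_projections_csv <- function(pps, path) {
  rows <- list()
  for (i in seq_along(pps)) {
    pp <- pps[[i]]
    if (is.null(pp)) next
    pp <- as_pp_matrix(pp)
    rows[[length(rows) + 1]] <- data.frame(
      frame_index = i, marker_id = seq_len(nrow(pp)),
      u_a_mm = pp[, "u_a"], v_a_mm = pp[, "v_a"],
      u_b_mm = pp[, "u_b"], v_b_mm = pp[, "v_b"]
    )
  }
  write_csv9(do.call(rbind, rows), path)
}

#' @rdname write_projections_csv
#' @export
read_projections_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame_index", "marker_id", "u_a_mm", "v_a_mm", "u_b_mm", "v_b_mm")
  if (!all(need %in% names(df))) stop("not a projections CSV: missing columns")
  out <- vector("list", max(df$frame_index))
  for (fi in unique(df$frame_index)) {
    sub <- df[df$frame_index == fi, , drop = FALSE]
    sub <- sub[order(sub$marker_id), , drop = FALSE]
    m <- cbind(u_a = sub$u_a_mm, v_a = sub$v_a_mm,
               u_b = sub$u_b_mm, v_b = sub$v_b_mm)
    out[[fi]] <- m
  }
  out
}

#' Write / read a motion trace CSV
#'
#' @param trace A `motion_trace` from [track_projections()].
#' @param path File path.
#' @return The path / a `motion_trace` data frame.
#' @export
write_trace_csv <- function(trace, path) {
  write_csv9(as.data.frame(trace), path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("motion_trace", "data.frame")
  df
}

write_markers_csv <- function(markers, path) {
  write_csv9(data.frame(marker_id = seq_len(nrow(markers)),
                        x_mm = markers[, 1], y_mm = markers[, 2],
                        z_mm = markers[, 3]), path)
}

write_truth_csv <- function(sim, path) {
  tf <- sim$truth_transforms
  df <- data.frame(
    frame_index = seq_along(tf),
    time_s = sim$times,
    q0 = vapply(tf, function(t) t$q[1], numeric(1)),
    q1 = vapply(tf, function(t) t$q[2], numeric(1)),
    q2 = vapply(tf, function(t) t$q[3], numeric(1)),
    q3 = vapply(tf, function(t) t$q[4], numeric(1)),
    tx_mm = vapply(tf, function(t) t$T[1], numeric(1)),
    ty_mm = vapply(tf, function(t) t$T[2], numeric(1)),
    tz_mm = vapply(tf, function(t) t$T[3], numeric(1))
  )
  write_csv9(df, path)
}

#' Write per-frame registration results JSON
#'
#' One record per tracked frame: `frame_index`, `q` (scalar-first unit
#' quaternion), `T_mm`, `rms_residual_mm`, `iterations`, `converged`.
#'
#' @param trace A `motion_trace` carrying its `transforms` attribute.
#' @param path File path.
#' @export
write_registration_json <- function(trace, path) {
  tfs <- attr(trace, "transforms")
  recs <- lapply(seq_len(nrow(trace)), function(k) {
    tf <- tfs[[as.character(trace$frame_index[k])]]
    list(frame_index = trace$frame_index[k],
         q = tf$q, T_mm = tf$T,
         rms_residual_mm = trace$rms_mm[k],
         iterations = trace$iterations[k],
         converged = trace$converged[k])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

write_manifest <- function(dir, inputs = character(), counts = list(),
                           config_file = NULL) {
  manifest <- list(
    tool = "fidtrack",
    version = as.character(utils::packageVersion("fidtrack")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = if (!is.null(config_file) && file.exists(config_file)) {
      unname(tools::md5sum(config_file))
    } else NULL,
    inputs = as.list(inputs),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(manifest)
}

#' Simulate a fraction and persist it to a directory
#'
#' Runs [simulate_fraction()] and writes the standard layout: `config.json`,
#' `markers.csv` (base fiducials), `truth.csv` (per-frame transforms as
#' quaternion + translation), `projections.csv`, `images/{frame}_{A|B}.png`
#' (when rendering), and `manifest.json`.
#'
#' @param config A [simulation_config()] or path to a scenario config JSON.
#' @param out_dir Output directory (created if needed).
#' @return The `simulated_fraction`, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_config_json(config)
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_fraction(config)
  cfg_path <- file.path(out_dir, "config.json")
  write_config_json(config, cfg_path)
  write_markers_csv(sim$markers, file.path(out_dir, "markers.csv"))
  write_truth_csv(sim, file.path(out_dir, "truth.csv"))
  write_projections_csv(sim$projections, file.path(out_dir, "projections.csv"))
  n_img <- 0
  if (!is.null(sim$images)) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_along(sim$images)) {
      png::writePNG(sim$images[[i]]$A, file.path(img_dir, sprintf("%03d_A.png", i)))
      png::writePNG(sim$images[[i]]$B, file.path(img_dir, sprintf("%03d_B.png", i)))
      n_img <- n_img + 2
    }
  }
  write_manifest(out_dir, inputs = character(),
                 counts = list(frames = length(sim$times),
                               markers = nrow(sim$markers),
                               images = n_img),
                 config_file = cfg_path)
  invisible(sim)
}

read_image_pairs <- function(img_dir) {
  fa <- sort(list.files(img_dir, pattern = "_A\\.(png|tif|tiff)$", full.names = TRUE))
  fb <- sort(list.files(img_dir, pattern = "_B\\.(png|tif|tiff)$", full.names = TRUE))
  if (length(fa) == 0 || length(fa) != length(fb)) {
    stop("image directory must hold matching {frame}_A / {frame}_B files")
  }
  read1 <- function(f) {
    if (grepl("\\.png$", f)) {
      img <- png::readPNG(f)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("TIFF input needs the 'tiff' package")
      img <- tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  }
  lapply(seq_along(fa), function(i) list(A = read1(fa[i]), B = read1(fb[i])))
}

#' Track a persisted fraction and write trace + summaries
#'
#' Reads a fraction directory produced by [cmd_simulate()] (or a bare
#' projections CSV), runs the tracking pipeline against the reference
#' frame, and writes `trace.csv`, `registration.json`, `summary.json`
#' (per-fraction motion ranges and pooled residuals) and `manifest.json`.
#'
#' @param input Fraction directory or projections CSV path.
#' @param out_dir Output directory.
#' @param geometry Optional [imaging_geometry()]; defaults to the one in the
#'   input directory's `config.json`, else package defaults.
#' @param use_images Run the image path (segmentation) instead of the
#'   coordinate path when images are present.
#' @param seg,pair_tol Segmentation parameters, see [detect_fraction()].
#' @param ... Passed to [track_projections()] (reference, labelled,
#'   threshold, ...).
#' @return The `motion_trace`, invisibly.
#' @export
cmd_track <- function(input, out_dir, geometry = NULL, use_images = FALSE,
                      seg = list(), pair_tol = 2, ...) {
  frame_interval <- 40
  if (dir.exists(input)) {
    cfg_path <- file.path(input, "config.json")
    if (is.null(geometry) && file.exists(cfg_path)) {
      cfg <- read_config_json(cfg_path)
      geometry <- cfg$geometry
      frame_interval <- cfg$frame_interval_s
    }
    if (use_images) {
      images <- read_image_pairs(file.path(input, "images"))
      if (is.null(geometry)) geometry <- imaging_geometry()
      pps <- detect_fraction(images, geometry, seg = seg, pair_tol = pair_tol)
      inputs <- file.path(input, "images")
    } else {
      pps <- read_projections_csv(file.path(input, "projections.csv"))
      inputs <- file.path(input, "projections.csv")
    }
  } else {
    pps <- read_projections_csv(input)
    inputs <- input
  }
  if (is.null(geometry)) geometry <- imaging_geometry()
  times <- (seq_along(pps) - 1) * frame_interval
  trace <- track_projections(pps, geometry, times = times, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trace_csv(trace, file.path(out_dir, "trace.csv"))
  write_registration_json(trace, file.path(out_dir, "registration.json"))
  rng <- motion_range(trace)
  cmp <- residual_comparison(list(trace))
  jsonlite::write_json(
    list(motion_range = as.list(rng),
         residuals = cmp,
         n_frames = nrow(trace)),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = I(17), dataframe = "rows"
  )
  write_manifest(out_dir, inputs = inputs,
                 counts = list(frames_tracked = nrow(trace),
                               frames_skipped = length(attr(trace, "skipped"))))
  invisible(trace)
}

#' Summarize a cohort of motion traces
#'
#' Aggregates per-fraction traces into the cohort tables: mean and SD across
#' fractions of each motion range (translations, 3D range, rotations) and
#' the pooled translation-only vs rigid residual comparison with paired
#' t-tests. Writes `cohort_summary.json` and a formatted `tables.txt`.
#'
#' @param traces List of `motion_trace` objects, or character vector of
#'   trace CSV paths.
#' @param out_dir Output directory.
#' @return List with elements `ranges` ([summarize_cohort()] output) and
#'   `residuals` ([residual_comparison()] output), invisibly.
#' @export
cmd_summarize <- function(traces, out_dir) {
  if (is.character(traces)) traces <- lapply(traces, read_trace_csv)
  if (length(traces) < 1) stop("no traces to summarize")
  ranges <- summarize_cohort(traces)
  cmp <- residual_comparison(traces)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(motion_ranges = ranges, residuals = cmp,
         n_fractions = length(traces), n_frames = attr(cmp, "n_frames")),
    file.path(out_dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = I(17), dataframe = "rows"
  )
  range_lines <- c(
    sprintf("%-9s %8s %8s %5s", "quantity", "mean", "SD", "unit"),
    sprintf("%-9s %8.2f %8.2f %5s", ranges$quantity, ranges$mean, ranges$sd,
            ranges$unit)
  )
  writeLines(c("Motion ranges (per-fraction peak-to-peak):", range_lines, "",
               "Residual errors (pooled frames):", format_residual_table(cmp)),
             file.path(out_dir, "tables.txt"))
  write_manifest(out_dir, counts = list(fractions = length(traces)))
  invisible(list(ranges = ranges, residuals = cmp))
}
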
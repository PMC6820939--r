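#' Binarize a grayscale image
#'
#' Thresholds an image to exactly 0.0 (background, black) / 1.0 (foreground,
#' white): pixels `>= threshold` map to 1.0. When no threshold is supplied,
#' an Otsu threshold is computed from the image histogram
#' (via [EBImage::otsu()]). Radiographs show gold seeds dark on bright
#' anatomy; `invert = TRUE` flips the image (`max - img`) first so that
#' markers come out white.
#'
#' Otsu is a good default for images with a substantial foreground
#' fraction. Fiducial markers, however, occupy only a few dozen of ~10^6
#' pixels, where Otsu's between-class criterion can land inside the
#' background noise; the `"halfmax"` rule (midpoint between the median and
#' the maximum intensity) is robust for such sparse bright blobs and is the
#' default of [detect_markers()].
#'
#' @param img Numeric matrix of intensities.
#' @param threshold Absolute intensity threshold, or `"otsu"` / `"halfmax"`
#'   for automatic selection; `NULL` (default) means `"otsu"`.
#' @param invert Invert intensities before thresholding?
#' @return Matrix of the same shape containing only 0.0 and 1.0.
#' @export
binarize <- function(img, threshold = NULL, invert = FALSE) {
  img <- as.matrix(img)
  stopifnot(all(is.finite(img)))
  if (invert) img <- max(img) - img
  if (is.null(threshold)) threshold <- "otsu"
  if (is.character(threshold)) {
    threshold <- switch(
      match.arg(threshold, c("otsu", "halfmax")),
      otsu = {
        rg <- range(img)
        if (rg[1] == rg[2]) rg <- rg + c(0, 1)  # constant image: all foreground
        EBImage::otsu(img, range = rg)
      },
      halfmax = (stats::median(img) + max(img)) / 2
    )
  }
  (img >= threshold) * 1.0
}

#' Mean (box) filter with edge replication
#'
#' Replaces each pixel by the arithmetic mean over a square `window`
#' neighbourhood; image borders are handled by edge replication. `window = 1`
#' is the identity. Uses [EBImage::filter2()] with a uniform kernel.
#'
#' @param img Numeric matrix.
#' @param window Odd window width in pixels (>= 1).
#' @return Filtered matrix, same shape.
#' @export
mean_filter <- function(img, window = 3) {
  img <- as.matrix(img)
  if (length(window) != 1 || window < 1 || window %% 2 == 0) {
    stop("mean filter window must be an odd positive integer")
  }
  if (window == 1) return(img)
  kern <- matrix(1 / window^2, window, window)
  out <- EBImage::filter2(img, kern, boundary = "replicate")
  as.matrix(out)
}

#' Find white blobs in a binary image
#'
#' 8-connected components of value-1.0 pixels, filtered to
#' `min_area <= area <= max_area` and sorted by area (descending), ties by
#' centroid row. Labelling uses [EBImage::bwlabel()] (4-connected) followed
#' by merging of labels that touch diagonally, which yields exact
#' 8-connectivity.
#'
#' @param bin Binary matrix (values 0.0/1.0) as from [binarize()].
#' @param min_area Minimum blob size in pixels (rejects noise specks).
#' @param max_area Maximum blob size in pixels (rejects large shadows, e.g.
#'   bone structures).
#' @return List of blobs; each is a list with `pixels` (k x 2 matrix of
#'   0-based (row, col) members), `area`, and `centroid` (0-based continuous
#'   (row, col), the unweighted mean of member coordinates). Possibly empty.
#' @export
find_blobs <- function(bin, min_area = 4, max_area = 400) {
  bin <- as.matrix(bin)
  stopifnot(min_area >= 1, max_area >= min_area)
  if (!all(bin %in% c(0, 1))) stop("find_blobs expects a 0/1 binary image")
  lab <- as.matrix(EBImage::bwlabel(bin))
  nlab <- max(lab)
  if (nlab == 0) return(list())

  # union-find over the 4-connected labels, merging diagonal contacts
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  diag_pairs <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    unique(cbind(a[keep], b[keep]))
  }
  # down-right diagonal neighbours
  p1 <- diag_pairs(lab[-nr, -nc], lab[-1, -1])
  # down-left diagonal neighbours
  p2 <- diag_pairs(lab[-nr, -1], lab[-1, -nc])
  for (pr in list(p1, p2)) {
    if (length(pr)) for (k in seq_len(nrow(pr))) union(pr[k, 1], pr[k, 2])
  }
  roots <- vapply(seq_len(nlab), find, integer(1))

  idx <- which(lab > 0)
  rows0 <- (idx - 1) %% nr        # 0-based row
  cols0 <- (idx - 1) %/% nr       # 0-based col
  comp <- roots[lab[idx]]
  blobs <- lapply(split(seq_along(idx), comp), function(ii) {
    px <- cbind(row = rows0[ii], col = cols0[ii])
    list(pixels = px, area = nrow(px), centroid = colMeans(px))
  })
  areas <- vapply(blobs, `[[`, numeric(1), "area")
  blobs <- blobs[areas >= min_area & areas <= max_area]
  if (length(blobs) == 0) return(list())
  areas <- vapply(blobs, `[[`, numeric(1), "area")
  crow <- vapply(blobs, function(b) b$centroid[["row"]], numeric(1))
  unname(blobs[order(-areas, crow)])
}

#' Detect fiducial marker centroids in a projection image
#'
#' Full 2D detection chain: mean filter (denoise) -> binarize -> 8-connected
#' blob extraction with area filtering -> blob centroid -> conversion of
#' pixel centroids to detector mm via [pixels_to_mm()]. The denoise-then-
#' threshold order preserves blob shape for sub-pixel centroid accuracy.
#'
#' Image rows index the detector v axis (superior direction) and columns the
#' u axis, matching [render_projection_image()].
#'
#' @param img Numeric matrix (grayscale projection image).
#' @param g An [imaging_geometry()] providing the pixel-to-mm map.
#' @param window Mean-filter window (odd px); 1 disables filtering.
#' @param threshold Binarization threshold: a number, `"otsu"`, or the
#'   default `"halfmax"` (robust when markers cover only a tiny pixel
#'   fraction, see [binarize()]).
#' @param invert Set TRUE when markers are dark on a bright background.
#' @param min_area,max_area Blob area limits in pixels.
#' @param weighted Use intensity-weighted centroids (weights from the
#'   filtered image) instead of the unweighted binary-blob mean.
#' @param expected Optional expected marker count; a mismatch is flagged in
#'   the result attribute `count_ok` (not an error).
#' @return Data frame with one row per detection: `u_mm`, `v_mm`,
#'   `row_px`, `col_px` (0-based centroid), `area_px`; rows ordered by `v_mm`.
#'   Attribute `count_ok` is FALSE when `expected` was given and missed.
#' @export
detect_markers <- function(img, g, window = 3, threshold = "halfmax", invert = FALSE,
                           min_area = 4, max_area = 400, weighted = FALSE,
                           expected = NULL) {
  img <- as.matrix(img)
  stopifnot(nrow(img) > 0, ncol(img) > 0)
  filt <- mean_filter(img, window)
  bin <- binarize(filt, threshold = threshold, invert = invert)
  blobs <- find_blobs(bin, min_area = min_area, max_area = max_area)
  if (length(blobs) == 0) {
    out <- data.frame(u_mm = numeric(0), v_mm = numeric(0),
                      row_px = numeric(0), col_px = numeric(0),
                      area_px = numeric(0))
  } else {
    cent <- t(vapply(blobs, function(b) {
      if (weighted) {
        w <- if (invert) max(filt) - filt else filt
        wv <- w[b$pixels + 1L]  # 0-based (row,col) -> 1-based matrix index
        c(sum(b$pixels[, 1] * wv), sum(b$pixels[, 2] * wv)) / sum(wv)
      } else {
        b$centroid
      }
    }, numeric(2)))
    out <- data.frame(
      u_mm = pixels_to_mm(cent[, 2], g),
      v_mm = pixels_to_mm(cent[, 1], g),
      row_px = cent[, 1],
      col_px = cent[, 2],
      area_px = vapply(blobs, `[[`, numeric(1), "area")
    )
    out <- out[order(out$v_mm), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "count_ok") <- is.null(expected) || nrow(out) == expected
  out
}

#' Pair marker detections across the two stereo views
#'
#' Under the parallel-ray model the two views of one marker share the SI
#' coordinate (v). Detections are paired by the assignment minimizing the
#' total |v_a - v_b| (exact enumeration for up to 7 detections per view,
#' greedy beyond); pairs with |v_a - v_b| > `tol` are rejected.
#'
#' @param centroids_A,centroids_B Data frames with columns `u_mm`, `v_mm`
#'   (detections in views A and B), both non-empty.
#' @param tol Pairing tolerance (mm) on the v difference.
#' @return Matrix of projection pairs (columns u_a, v_a, u_b, v_b), one row
#'   per accepted pair, ordered by v_a. Attribute `unmatched` lists the
#'   unpaired detection indices per view. Errors when no pair is acceptable.
#' @export
pair_views <- function(centroids_A, centroids_B, tol = 2) {
  for (cc in list(centroids_A, centroids_B)) {
    if (!is.data.frame(cc) || nrow(cc) == 0 || !all(c("u_mm", "v_mm") %in% names(cc))) {
      stop("both views need non-empty detections with u_mm/v_mm columns")
    }
  }
  stopifnot(tol >= 0)
  va <- centroids_A$v_mm; vb <- centroids_B$v_mm
  nA <- length(va); nB <- length(vb)
  cost <- abs(outer(va, vb, "-"))  # nA x nB

  # assignment of the smaller side into the larger, minimizing total cost
  swap <- nA > nB
  C <- if (swap) t(cost) else cost  # rows = smaller set
  k <- nrow(C); m <- ncol(C)
  if (k <= 7) {
    combs <- utils::combn(m, k, simplify = FALSE)
    perms <- permutations_of(k)
    best <- NULL; best_cost <- Inf
    for (cb in combs) {
      for (p in perms) {
        tot <- sum(C[cbind(seq_len(k), cb[p])])
        if (tot < best_cost) { best_cost <- tot; best <- cb[p] }
      }
    }
    assign_col <- best
  } else {
    # greedy fallback: repeatedly take the globally cheapest remaining pair
    assign_col <- rep(NA_integer_, k)
    Cw <- C
    for (s in seq_len(k)) {
      ij <- arrayInd(which.min(Cw), dim(Cw))
      assign_col[ij[1]] <- ij[2]
      Cw[ij[1], ] <- Inf; Cw[, ij[2]] <- Inf
    }
  }

  iA <- if (swap) assign_col else seq_len(k)
  iB <- if (swap) seq_len(k) else assign_col
  ok <- cost[cbind(iA, iB)] <= tol
  if (!any(ok)) stop("no acceptable pairing between views within tolerance: view mismatch")
  iA <- iA[ok]; iB <- iB[ok]
  out <- cbind(u_a = centroids_A$u_mm[iA], v_a = centroids_A$v_mm[iA],
               u_b = centroids_B$u_mm[iB], v_b = centroids_B$v_mm[iB])
  out <- out[order(out[, "v_a"]), , drop = FALSE]
  attr(out, "unmatched") <- list(A = setdiff(seq_len(nA), iA),
                                 B = setdiff(seq_len(nB), iB))
  out
}

# all permutations of 1..n (n small)
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, ifelse(p >= i, p + 1L, p))
    }
  }
  out
}
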
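#' 2D bounding box with confidence
#'
#' @param left,top,right,bottom box edges in image coordinates (pixels);
#'   `left < right`, `top < bottom`.
#' @param confidence finite detector score.
#' @return object of class `bounding_box`.
#' @export
bounding_box <- function(left, top, right, bottom, confidence = 1) {
  if (!(left < right) || !(top < bottom))
    stop("degenerate bounding box")
  if (!is.finite(confidence)) stop("confidence must be finite")
  structure(list(left = left, top = top, right = right, bottom = bottom,
                 confidence = confidence), class = "bounding_box")
}

#' Select the highest-confidence bounding box
#'
#' At most one face is assumed per scan, so when the detector returns several
#' boxes only the one with the maximum confidence is kept; ties are broken by
#' first occurrence.
#'
#' @param boxes non-empty list of [bounding_box()] objects.
#' @return a single [bounding_box()].
#' @export
select_best_box <- function(boxes) {
  if (!length(boxes)) stop("no bounding boxes to select from")
  conf <- vapply(boxes, function(b) b$confidence, 0)
  boxes[[which.max(conf)]]
}

#' Reserved fixture marker colors
#'
#' Twelve saturated, mutually well-separated RGB colors, one per landmark, in
#' the canonical [landmark_names()] order. The synthetic fixture generator
#' paints a disk of each color around the corresponding ground-truth landmark
#' and [fixture_detector()] recognizes them by nearest RGB color within a
#' Euclidean tolerance.
#'
#' @return 12 x 3 numeric matrix with landmark names as row names.
#' @export
marker_colors <- function() {
  m <- rbind(
    en_r = c(1, 0, 0),
    en_l = c(0, 1, 0),
    ex_r = c(0, 0, 1),
    ex_l = c(1, 1, 0),
    n    = c(1, 0, 1),
    prn  = c(0, 1, 1),
    sn   = c(1, 0.5, 0),
    gn   = c(0.5, 0, 1),
    ch_r = c(0, 0.5, 0.1),
    ch_l = c(1, 1, 1),
    ls   = c(0.55, 1, 0.1),
    li   = c(0, 0.45, 1))
  colnames(m) <- c("r", "g", "b")
  m
}

#' Fixture marker detector / landmarker
#'
#' A deterministic stand-in for the pretrained 2D face-detection and 68-point
#' landmarking models: it finds pixels whose color matches one of the twelve
#' reserved [marker_colors()] (Euclidean RGB distance below `tol`) and
#' reports one bounding box around all marker pixels with confidence 1, or no
#' box when fewer than `min_markers` distinct marker colors are visible. As a
#' landmarker it fills the twelve mapped iBUG-68 indices with the centroids of
#' the marker-color blobs inside the box; the remaining 56 indices (unused
#' downstream) are set to the box center.
#'
#' @param min_markers minimum number of distinct marker colors required for a
#'   detection, default 8.
#' @param tol RGB matching tolerance, default 0.15.
#' @return object of class `fixture_detector`, usable as both `detector` and
#'   `landmarker` in [run_pipeline()].
#' @export
fixture_detector <- function(min_markers = 8, tol = 0.15) {
  structure(list(min_markers = min_markers, tol = tol),
            class = "fixture_detector")
}

# Per-pixel marker assignment: integer matrix H x W, 0 = no marker, k = index
# into marker_colors() rows. A pixel matches the nearest marker color if the
# distance is below tol.
match_marker_pixels <- function(image, tol) {
  H <- dim(image)[1]
  W <- dim(image)[2]
  px <- matrix(image, H * W, 3)
  mc <- marker_colors()
  best_d2 <- rep(Inf, H * W)
  best_k <- integer(H * W)
  for (k in seq_len(nrow(mc))) {
    d2 <- (px[, 1] - mc[k, 1])^2 + (px[, 2] - mc[k, 2])^2 +
      (px[, 3] - mc[k, 3])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_k[upd] <- k
  }
  best_k[best_d2 >= tol^2] <- 0L
  matrix(best_k, H, W)
}

#' Detect faces in a rendered image
#'
#' Generic detector interface: implementations return zero or more
#' [bounding_box()] objects (an empty list means "no face").
#'
#' @param detector a detector object ([fixture_detector()] or
#'   [external_adapter()]).
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @return list of [bounding_box()] objects.
#' @export
detect_faces <- function(detector, image) UseMethod("detect_faces")

#' @export
detect_faces.fixture_detector <- function(detector, image) {
  lab <- match_marker_pixels(image, detector$tol)
  present <- sort(unique(lab[lab > 0L]))
  if (length(present) < detector$min_markers) return(list())
  idx <- which(lab > 0L, arr.ind = TRUE)
  # box in continuous image coordinates covering the matched pixels
  list(bounding_box(left = min(idx[, 2]) - 1, top = min(idx[, 1]) - 1,
                    right = max(idx[, 2]), bottom = max(idx[, 1]),
                    confidence = 1.0))
}

#' Locate 68 facial landmarks in an image
#'
#' Generic 68-point landmarker interface (iBUG-68 ordering). The fixture
#' implementation derives the twelve mapped points from marker-color blob
#' centroids restricted to `box`; an external adapter returns its model's
#' output verbatim (length 68 enforced).
#'
#' @inheritParams detect_faces
#' @param landmarker a landmarker object.
#' @param box a [bounding_box()] inside the image.
#' @return 68 x 2 matrix of image coordinates (class `landmark_set2d`).
#' @export
landmark_face <- function(landmarker, image, box) UseMethod("landmark_face")

#' @export
landmark_face.fixture_detector <- function(landmarker, image, box) {
  lab <- match_marker_pixels(image, landmarker$tol)
  H <- nrow(lab)
  W <- ncol(lab)
  rows <- pmin(pmax(ceiling(box$top + 0.5), 1L), H):pmin(floor(box$bottom + 0.5), H)
  cols <- pmin(pmax(ceiling(box$left + 0.5), 1L), W):pmin(floor(box$right + 0.5), W)
  sub <- lab[rows, cols, drop = FALSE]
  mc <- marker_colors()
  pts68 <- matrix(rep(c((box$left + box$right) / 2,
                        (box$top + box$bottom) / 2), each = 68), 68, 2)
  map <- ibug12_indices()
  missing <- character(0)
  centroids <- matrix(NA_real_, 12, 2, dimnames = list(rownames(mc), NULL))
  for (k in seq_len(nrow(mc))) {
    hit <- which(sub == k, arr.ind = TRUE)
    if (!nrow(hit)) {
      missing <- c(missing, rownames(mc)[k])
      next
    }
    # pixel centers in full-image coordinates
    centroids[k, ] <- c(mean(cols[hit[, 2]] - 0.5), mean(rows[hit[, 1]] - 0.5))
  }
  if (length(missing))
    stop("marker color(s) not visible for landmark(s): ",
         paste(missing, collapse = ", "))
  pts68[map[rownames(mc)], ] <- centroids
  landmark_set2d(pts68)
}

#' 68-point 2D landmark set
#'
#' @param points 68 x 2 matrix of finite image coordinates (iBUG-68 order).
#' @return matrix of class `landmark_set2d`.
#' @export
landmark_set2d <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 68 || ncol(points) != 2 || !all(is.finite(points)))
    stop("a 2D landmark set must be 68 finite image points")
  class(points) <- c("landmark_set2d", class(points))
  points
}

#' Adapter for external pretrained 2D models
#'
#' Wraps user-supplied functions around pretrained face-detection and
#' 68-point landmarking models (e.g. the dlib models). `detect_fn(image)`
#' must return a list of [bounding_box()] objects; `landmark_fn(image, box)`
#' a 68 x 2 point matrix. No model files are vendored and none are needed by
#' the package's own tests.
#'
#' @param detect_fn function(image) -> list of boxes.
#' @param landmark_fn function(image, box) -> 68 x 2 matrix.
#' @return object of class `external_adapter`.
#' @export
external_adapter <- function(detect_fn, landmark_fn) {
  stopifnot(is.function(detect_fn), is.function(landmark_fn))
  structure(list(detect_fn = detect_fn, landmark_fn = landmark_fn),
            class = "external_adapter")
}

#' @export
detect_faces.external_adapter <- function(detector, image) {
  boxes <- detector$detect_fn(image)
  if (!all(vapply(boxes, inherits, TRUE, "bounding_box")))
    stop("external detector must return bounding_box objects")
  boxes
}

#' @export
landmark_face.external_adapter <- function(landmarker, image, box) {
  landmark_set2d(landmarker$landmark_fn(image, box))
}

#' Mapping from iBUG-68 indices to the twelve landmarks
#'
#' One-to-one table (1-based indices into the 68-point set): gnathion from the
#' chin point 9, eye corners from 37/40/43/46, nasion from the nose-bridge top
#' 28, pronasale from the nose tip 31, subnasale 34, mouth corners 49/55,
#' upper/lower lip midpoints 52/58. Note that iBUG "left eye" in image
#' coordinates is the subject's anatomical right. The table can be overridden
#' via the `index_map` argument of [map_68_to_12()] / [pipeline_config()].
#'
#' @return named integer vector (names = [landmark_names()]).
#' @export
ibug12_indices <- function() {
  c(en_r = 40L, en_l = 43L, ex_r = 37L, ex_l = 46L, n = 28L, prn = 31L,
    sn = 34L, gn = 9L, ch_r = 49L, ch_l = 55L, ls = 52L, li = 58L)
}

#' Extract the twelve named landmarks from a 68-point set
#'
#' @param lm68 a [landmark_set2d()] (or plain 68 x 2 matrix).
#' @param index_map named integer vector mapping landmark names to 1-based
#'   iBUG-68 indices; default [ibug12_indices()].
#' @return 12 x 2 matrix with landmark names as row names.
#' @export
map_68_to_12 <- function(lm68, index_map = ibug12_indices()) {
  lm68 <- as.matrix(lm68)
  if (nrow(lm68) != 68) stop("expected 68 landmark points")
  nm <- landmark_names()
  if (!setequal(names(index_map), nm))
    stop("index_map must name exactly the 12 landmarks")
  out <- lm68[index_map[nm], , drop = FALSE]
  rownames(out) <- nm
  out
}
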
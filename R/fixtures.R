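#' Synthetic face fixture specification
#'
#' Parameters of the parametric face-like test surface: an ellipsoid head
#' with a Gaussian nose bump and two shallow eye-socket depressions,
#' per-vertex skin color, and a colored marker disk painted around each of
#' the twelve ground-truth landmarks (see [marker_colors()]). The canonical
#' pose matches the scanner frame: the face looks toward +z with +y up, so
#' the central camera of [initial_camera_array()] is frontal. The fixture
#' stands in for a real facial surface scan; it exercises the exact
#' color-rendering and ray back-projection path of the pipeline with known
#' ground truth.
#'
#' @param semi_axes ellipsoid semi-axes (x, y, z) in mm, default
#'   `c(80, 110, 70)`.
#' @param nose_amplitude,nose_width nose bump height / Gaussian width, mm.
#' @param eye_depth,eye_width eye-socket depression depth / width, mm.
#' @param n_lat,n_mer latitude rings / meridians of the sphere grid; the
#'   default 100 x 100 gives ~19.8k triangles (10k vertices). The grid stops
#'   short of the poles, so the surface is open there like a real scan.
#' @param skin_color base RGB.
#' @param marker_radius marker disk radius, mm; must be smaller than half the
#'   smallest inter-landmark distance so the patches stay disjoint. `0`
#'   disables marker painting (uniform skin color; useful for low-resolution
#'   geometry-only fixtures whose vertex spacing cannot keep patches apart).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(semi_axes = c(80, 110, 70), nose_amplitude = 25,
                         nose_width = 20, eye_depth = 5, eye_width = 15,
                         n_lat = 100, n_mer = 100,
                         skin_color = c(0.8, 0.6, 0.5), marker_radius = 4) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), nose_amplitude >= 0,
            nose_width > 0, eye_depth >= 0, eye_width > 0,
            n_lat >= 8, n_mer >= 8, marker_radius >= 0)
  if (any(skin_color < 0) || any(skin_color > 1))
    stop("skin_color channels must lie in [0, 1]")
  structure(list(semi_axes = semi_axes, nose_amplitude = nose_amplitude,
                 nose_width = nose_width, eye_depth = eye_depth,
                 eye_width = eye_width, n_lat = as.integer(n_lat),
                 n_mer = as.integer(n_mer), skin_color = skin_color,
                 marker_radius = marker_radius),
            class = "fixture_spec")
}

# Canonical landmark directions on the unit sphere (unnormalized), chosen to
# put anatomical right at -x for a face looking toward +z with +y up.
fixture_landmark_directions <- function() {
  rbind(
    en_r = c(-0.17, 0.33, 1),
    en_l = c(0.17, 0.33, 1),
    ex_r = c(-0.45, 0.33, 1),
    ex_l = c(0.45, 0.33, 1),
    n    = c(0, 0.35, 1),
    prn  = c(0, 0.05, 1),
    sn   = c(0, -0.12, 1),
    gn   = c(0, -0.95, 0.55),
    ch_r = c(-0.25, -0.28, 0.95),
    ch_l = c(0.25, -0.28, 0.95),
    ls   = c(0, -0.28, 1),
    li   = c(0, -0.42, 1))
}

# Evaluate the parametric surface at unit directions (rows of d).
fixture_surface <- function(d, spec) {
  d <- d / sqrt(rowSums(d^2))
  base <- cbind(spec$semi_axes[1] * d[, 1], spec$semi_axes[2] * d[, 2],
                spec$semi_axes[3] * d[, 3])
  feature_dirs <- rbind(nose = c(0, 0.05, 1),
                        eye_r = c(-0.30, 0.33, 1),
                        eye_l = c(0.30, 0.33, 1))
  feature_dirs <- feature_dirs / sqrt(rowSums(feature_dirs^2))
  feat <- cbind(spec$semi_axes[1] * feature_dirs[, 1],
                spec$semi_axes[2] * feature_dirs[, 2],
                spec$semi_axes[3] * feature_dirs[, 3])
  amp <- c(spec$nose_amplitude, -spec$eye_depth, -spec$eye_depth)
  width <- c(spec$nose_width, spec$eye_width, spec$eye_width)
  off <- numeric(nrow(d))
  for (k in 1:3) {
    d2 <- rowSums(sweep(base, 2, feat[k, ])^2)
    off <- off + amp[k] * exp(-d2 / (2 * width[k]^2))
  }
  base + d * off
}

#' Generate a synthetic face fixture with ground-truth landmarks
#'
#' Builds the parametric surface on a latitude/meridian sphere grid (open at
#' the poles), snaps each canonical landmark to its nearest mesh vertex
#' (pronasale to the highest-z vertex near the nose apex, so it is the local
#' z maximum by construction), and paints a [marker_colors()] disk of
#' vertices around each landmark; all other vertices take the skin color.
#' The construction is fully deterministic.
#'
#' @param spec a [fixture_spec()].
#' @return list with `mesh` (a colored [triangle_mesh()]) and `landmarks`
#'   (a [landmark_set3d()] of ground-truth positions, each exactly a mesh
#'   vertex). The mesh carries the landmark vertex indices as attribute
#'   `landmark_vertices`.
#' @export
make_face_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  nl <- spec$n_lat
  nm <- spec$n_mer
  theta <- seq(0.08 * pi, 0.95 * pi, length.out = nl)  # from +y pole
  psi <- seq(0, 2 * pi, length.out = nm + 1)[-(nm + 1)]  # from +z, wraps
  dirs <- cbind(
    rep(sin(theta), each = nm) * sin(rep(psi, nl)),
    rep(cos(theta), each = nm),
    rep(sin(theta), each = nm) * cos(rep(psi, nl)))
  vertices <- fixture_surface(dirs, spec)
  # quad grid -> triangles; meridian index wraps
  idx <- function(i, j) (i - 1L) * nm + ((j - 1L) %% nm) + 1L
  tris <- vector("list", (nl - 1L))
  for (i in seq_len(nl - 1L)) {
    j <- seq_len(nm)
    a <- idx(i, j); b <- idx(i + 1L, j); c2 <- idx(i + 1L, j + 1L)
    d2 <- idx(i, j + 1L)
    tris[[i]] <- rbind(cbind(a, b, c2), cbind(a, c2, d2))
  }
  triangles <- do.call(rbind, tris)

  ld <- fixture_landmark_directions()
  ideal <- fixture_surface(ld, spec)
  lm_idx <- integer(nrow(ld))
  names(lm_idx) <- rownames(ld)
  for (k in seq_len(nrow(ld))) {
    d2 <- rowSums(sweep(vertices, 2, ideal[k, ])^2)
    lm_idx[k] <- which.min(d2)
  }
  # prn: the local apex -- highest z among vertices near the nose tip
  near_nose <- which(sqrt(rowSums(sweep(vertices, 2,
                                        vertices[lm_idx["prn"], ])^2)) < 15)
  lm_idx["prn"] <- near_nose[which.max(vertices[near_nose, 3])]

  lm_pts <- vertices[lm_idx, , drop = FALSE]
  rownames(lm_pts) <- names(lm_idx)
  colors <- matrix(rep(spec$skin_color, each = nrow(vertices)),
                   nrow(vertices), 3)
  if (spec$marker_radius > 0) {
    dmin <- min(stats::dist(lm_pts))
    if (spec$marker_radius >= dmin / 2)
      stop(sprintf(
        "marker radius %.1f mm >= half the minimum inter-landmark distance (%.1f mm)",
        spec$marker_radius, dmin / 2))
    mc <- marker_colors()
    for (k in seq_len(nrow(lm_pts))) {
      d2 <- rowSums(sweep(vertices, 2, lm_pts[k, ])^2)
      colors[d2 <= spec$marker_radius^2, ] <-
        rep(mc[names(lm_idx)[k], ], each = sum(d2 <= spec$marker_radius^2))
    }
  }
  mesh <- triangle_mesh(vertices, triangles, colors)
  attr(mesh, "landmark_vertices") <- lm_idx
  list(mesh = mesh, landmarks = landmark_set3d(lm_pts))
}

#' Apply a proper rigid motion to a fixture
#'
#' Transforms mesh vertices and ground-truth landmarks identically:
#' `p' = R p + t`.
#'
#' @param mesh a [triangle_mesh()].
#' @param landmarks a [landmark_set3d()] (or NULL).
#' @param rotation 3 x 3 proper rotation (det +1).
#' @param translation length-3 vector (mm).
#' @return list with transformed `mesh` and `landmarks`.
#' @export
apply_rigid <- function(mesh, landmarks, rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-8 ||
      det(rotation) < 0)
    stop("rotation must be a proper (det +1) orthogonal matrix")
  out_mesh <- triangle_mesh(transform_points(mesh$vertices, rotation,
                                             translation),
                            mesh$triangles, mesh$colors)
  attr(out_mesh, "landmark_vertices") <- attr(mesh, "landmark_vertices")
  out_lm <- NULL
  if (!is.null(landmarks)) {
    out_lm <- landmark_set3d(transform_points(unclass(landmarks), rotation,
                                              translation))
  }
  list(mesh = out_mesh, landmarks = out_lm)
}

#' Rotation matrices about coordinate axes
#'
#' @param deg angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_x <- function(deg) {
  a <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
}

#' @rdname rotation_x
#' @export
rotation_y <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
}

#' @rdname rotation_x
#' @export
rotation_z <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

#' Simulate observer noise on a landmark set
#'
#' Adds iid Gaussian per-axis noise to every landmark; deterministic given
#' `seed`. Used to emulate human observer placements for the evaluation
#' machinery.
#'
#' @param lm a [landmark_set3d()].
#' @param sigma_mm per-axis standard deviation, mm (>= 0).
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @return a perturbed [landmark_set3d()].
#' @export
perturb_landmarks <- function(lm, sigma_mm, seed = NULL) {
  stopifnot(sigma_mm >= 0)
  lm <- landmark_set3d(lm)
  if (!is.null(seed)) set.seed(seed)
  noise <- matrix(stats::rnorm(length(lm), 0, sigma_mm), nrow(lm), 3)
  landmark_set3d(unclass(lm) + noise)
}

#' Generate a synthetic population of deformed fixtures
#'
#' Applies a smooth band-limited random radial deformation field to the
#' canonical fixture for each member: a sum of ten low-frequency cosine
#' modes of random orientation and phase (zero mean over the sphere),
#' displacing every vertex along its radial direction. All members share the
#' canonical topology, and the ground-truth landmarks move with the surface
#' (they are mesh vertices). Used to probe population-level behavior of the
#' registration, e.g. its bias toward the atlas shape.
#'
#' @param n number of members, >= 2.
#' @param deformation_scale approximate amplitude (mm) of the radial field;
#'   default 5.
#' @param seed integer seed.
#' @param spec fixture specification shared by all members.
#' @return list of `n` elements, each a list with `mesh` and `landmarks` as
#'   in [make_face_fixture()].
#' @export
make_population <- function(n, deformation_scale = 5, seed = 1,
                            spec = fixture_spec()) {
  stopifnot(n >= 2, deformation_scale >= 0)
  base <- make_face_fixture(spec)
  set.seed(seed)
  lm_idx <- attr(base$mesh, "landmark_vertices")
  v <- base$mesh$vertices
  d <- v / sqrt(rowSums(v^2))
  lapply(seq_len(n), function(i) {
    # ten low-frequency modes; RMS over the sphere ~ deformation_scale
    f <- numeric(nrow(d))
    for (k in 1:10) {
      w <- stats::rnorm(3)
      w <- w / sqrt(sum(w^2))
      omega <- stats::runif(1, 1.5, 3.5)
      phase <- stats::runif(1, 0, 2 * pi)
      amp <- stats::rnorm(1)
      f <- f + amp * cos(omega * (d %*% w) + phase)
    }
    f <- f * deformation_scale / sqrt(5)  # 10 modes x RMS 1/sqrt(2)
    vi <- v + d * as.numeric(f)
    mesh <- triangle_mesh(vi, base$mesh$triangles, base$mesh$colors)
    attr(mesh, "landmark_vertices") <- lm_idx
    pts <- vi[lm_idx, , drop = FALSE]
    rownames(pts) <- names(lm_idx)
    list(mesh = mesh, landmarks = landmark_set3d(pts))
  })
}
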
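#' NICP configuration
#'
#' Parameters of the locally-affine-regularized non-rigid ICP registration.
#' The stiffness schedule anneals the regularization from rigid-like to
#' flexible; within each stiffness the algorithm alternates closest-point
#' correspondence assignment with an exact sparse linear least-squares solve
#' for all per-vertex affine transforms. Correspondences are rejected when
#' the matched surface point is too far, faces away, or lies on the target's
#' boundary.
#'
#' @param stiffness_schedule strictly decreasing positive values; default 8
#'   geometric steps from 50 to 1.
#' @param gamma weight of the translational column in the stiffness term
#'   (the `G = diag(1, 1, 1, gamma)` matrix), default 1.
#' @param max_inner_iter inner iterations per stiffness, default 10.
#' @param inner_tol convergence threshold on the mean per-vertex transform
#'   change (Frobenius, per vertex), default 1e-4.
#' @param max_normal_angle_deg reject correspondences whose surface normals
#'   disagree by more than this angle, default 60.
#' @param max_distance_mm reject correspondences farther than this, default 20.
#' @param reject_border reject closest points on the target border, default
#'   TRUE.
#' @param landmark_weight weight of the optional guide-point term; 0 (the
#'   default) disables it. Guide points are used for atlas building, never
#'   when evaluating the registration against ground-truth landmarks.
#' @return object of class `nicp_config`.
#' @export
nicp_config <- function(stiffness_schedule = exp(seq(log(50), log(1),
                                                     length.out = 8)),
                        gamma = 1, max_inner_iter = 10, inner_tol = 1e-4,
                        max_normal_angle_deg = 60, max_distance_mm = 20,
                        reject_border = TRUE, landmark_weight = 0) {
  if (any(stiffness_schedule <= 0) || any(diff(stiffness_schedule) >= 0))
    stop("stiffness_schedule must be strictly decreasing and positive")
  stopifnot(gamma > 0, max_inner_iter >= 1, inner_tol > 0,
            max_distance_mm > 0, landmark_weight >= 0)
  structure(list(stiffness_schedule = stiffness_schedule, gamma = gamma,
                 max_inner_iter = max_inner_iter, inner_tol = inner_tol,
                 max_normal_angle_deg = max_normal_angle_deg,
                 max_distance_mm = max_distance_mm,
                 reject_border = reject_border,
                 landmark_weight = landmark_weight),
            class = "nicp_config")
}

#' Landmark-guided affine initialization
#'
#' The 3 x 4 affine transform minimizing the sum of squared distances between
#' the transformed atlas landmarks and the subject landmarks (ordinary least
#' squares on homogeneous coordinates). Applied to the whole atlas before
#' NICP; the landmarks play no further role in the registration.
#'
#' @param atlas_lm,subject_lm [landmark_set3d()]s (12 matching names).
#' @return 3 x 4 matrix `A` such that atlas points map as
#'   `A %*% c(p, 1)`.
#' @export
affine_init <- function(atlas_lm, subject_lm) {
  atlas_lm <- landmark_set3d(atlas_lm)
  subject_lm <- landmark_set3d(subject_lm)
  X <- cbind(unclass(atlas_lm), 1)
  Y <- unclass(subject_lm)
  if (qr(X)$rank < 4)
    stop("degenerate (coplanar) landmark configuration; affine transform not unique")
  t(qr.solve(X, Y))
}

# Apply a 3 x 4 affine to a point matrix.
apply_affine <- function(points, A) {
  cbind(as.matrix(points), 1) %*% t(A)
}

#' Non-rigid ICP registration of an atlas mesh to a target scan
#'
#' Deforms the atlas with one 3 x 4 affine transform per vertex, minimizing
#' for each stiffness value `alpha` the energy
#' `E(X) = sum_i w_i ||X_i v_i - u_i||^2 +
#'  alpha * sum_(i,j in edges) ||(X_i - X_j) G||_F^2`
#' where `u_i` is the closest compatible point on the target surface
#' (point-to-triangle, recomputed every inner iteration; `w_i = 0` for
#' rejected correspondences) and `G = diag(1, 1, 1, gamma)`. Each inner
#' iteration performs the exact sparse least-squares solve for all `X_i`
#' jointly, so the energy at fixed correspondences cannot increase.
#'
#' @param atlas connected [triangle_mesh()] to deform.
#' @param target [triangle_mesh()] to register onto.
#' @param init 3 x 4 affine applied to the atlas before registration
#'   (e.g. from [affine_init()]); default identity.
#' @param config a [nicp_config()].
#' @param guide_idx,guide_targets optional guide-point correspondences for
#'   atlas-building workflows: atlas vertex indices and matching m x 3 target
#'   positions, added to the energy with weight `config$landmark_weight`.
#'   Ignored (with a warning) when `landmark_weight` is 0, the default --
#'   when evaluating a registration against ground-truth landmarks the guide
#'   term must stay off.
#' @return object of class `deformed_atlas`: list with `atlas`, `transforms`
#'   (4n x 3 stacked per-vertex affines, acting on the *initialized* atlas),
#'   `deformed_vertices` (n x 3), `init`, and `energy_log` (data.frame with
#'   one row per inner iteration: stiffness, iter, n_active, e_before,
#'   e_after -- energies at that iteration's fixed correspondence set before
#'   and after the solve).
#' @export
nicp_register <- function(atlas, target, init = NULL,
                          config = nicp_config(),
                          guide_idx = NULL, guide_targets = NULL) {
  n <- n_vertices(atlas)
  if (n < 3 || n_triangles(atlas) < 1) stop("atlas too small")
  edges <- mesh_edges(atlas)
  comp <- length(unique(c(edges))) == n
  if (!comp || nrow(edges) < n - 1)
    stop("atlas mesh must be connected")
  if (is.null(init)) init <- cbind(diag(3), 0)
  V0 <- apply_affine(atlas$vertices, init)

  # D: n x 4n block row [v_i 1] per vertex
  ii <- rep(seq_len(n), each = 4)
  jj <- as.numeric(t(cbind((seq_len(n) - 1) * 4 + 1, (seq_len(n) - 1) * 4 + 2,
                           (seq_len(n) - 1) * 4 + 3, (seq_len(n) - 1) * 4 + 4)))
  xx <- as.numeric(t(cbind(V0, 1)))
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, 4 * n))

  # M kron G: 4 rows per edge
  ne <- nrow(edges)
  g <- c(1, 1, 1, config$gamma)
  ei <- rep(seq_len(4 * ne), 2)
  ej <- c(as.numeric(vapply(seq_len(ne), function(e)
            (edges[e, 1] - 1) * 4 + 1:4, numeric(4))),
          as.numeric(vapply(seq_len(ne), function(e)
            (edges[e, 2] - 1) * 4 + 1:4, numeric(4))))
  ex <- c(rep(g, ne), rep(-g, ne))
  MG <- Matrix::sparseMatrix(i = ei, j = ej, x = ex, dims = c(4 * ne, 4 * n))

  tb <- border_vertices(target)
  tri_normals <- function(mesh) {
    v <- mesh$vertices
    f <- mesh$triangles
    e1 <- v[f[, 2], ] - v[f[, 1], ]
    e2 <- v[f[, 3], ] - v[f[, 1], ]
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nrm / pmax(sqrt(rowSums(nrm^2)), 1e-14)
  }
  target_tri_n <- tri_normals(target)
  cos_max <- cos(config$max_normal_angle_deg * pi / 180)

  # unknowns: X (4n x 3), identity blocks initially
  X <- do.call(rbind, rep(list(rbind(diag(3), 0)), n))
  atlas_init <- triangle_mesh(V0, atlas$triangles)
  log_rows <- list()
  lw <- config$landmark_weight
  has_guides <- !is.null(guide_idx)
  if (has_guides && lw == 0) {
    warning("guide points supplied but landmark_weight is 0; ignoring them")
    has_guides <- FALSE
  }

  # constant normal-equation pieces; the Cholesky symbolic analysis of the
  # (fixed) sparsity pattern is reused across iterations
  MGtMG <- Matrix::crossprod(MG)
  Dt <- Matrix::t(D)
  guide_AtA <- NULL
  guide_Atb <- NULL
  if (has_guides) {
    guide_idx <- as.integer(guide_idx)
    guide_targets <- as.matrix(guide_targets)
    if (any(guide_idx < 1 | guide_idx > n) ||
        nrow(guide_targets) != length(guide_idx))
      stop("guide_idx / guide_targets mismatch")
    DL <- D[guide_idx, , drop = FALSE]
    guide_AtA <- lw * Matrix::crossprod(DL)
    guide_Atb <- lw * as.matrix(Matrix::t(DL) %*% guide_targets)
  }
  chol_fac <- NULL

  for (alpha in config$stiffness_schedule) {
    for (it in seq_len(config$max_inner_iter)) {
      def <- as.matrix(D %*% X)
      cp <- cpp_closest_points(def, target$vertices, target$triangles - 1L, tb)
      w <- rep(1, n)
      w[cp$distance > config$max_distance_mm] <- 0
      if (config$reject_border) w[cp$on_border] <- 0
      # normal compatibility: deformed-atlas vertex normals vs target
      # triangle normal at the matched point
      an <- cpp_vertex_normals(def, atlas$triangles - 1L)
      tn <- target_tri_n[cp$triangle, , drop = FALSE]
      cosang <- rowSums(an * tn)
      w[cosang < cos_max] <- 0
      if (sum(w) < 4) stop("all correspondences rejected; registration failed")
      U <- cp$point

      energy <- function(Xc) {
        defc <- as.matrix(D %*% Xc)
        e <- sum(w * rowSums((defc - U)^2)) + alpha * sum((MG %*% Xc)^2)
        if (has_guides)
          e <- e + lw * sum((defc[guide_idx, , drop = FALSE] -
                               guide_targets)^2)
        e
      }
      e_before <- energy(X)
      AtA <- alpha * MGtMG + Matrix::crossprod(D * sqrt(w))
      Atb <- as.matrix(Dt %*% (w * U))
      if (has_guides) {
        AtA <- AtA + guide_AtA
        Atb <- Atb + guide_Atb
      }
      AtA <- Matrix::forceSymmetric(AtA)
      if (is.null(chol_fac)) chol_fac <- Matrix::Cholesky(AtA, LDL = FALSE)
      else chol_fac <- Matrix::update(chol_fac, AtA)
      Xnew <- as.matrix(Matrix::solve(chol_fac, Atb))
      e_after <- energy(Xnew)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(stiffness = alpha, iter = it, n_active = sum(w > 0),
                   e_before = e_before, e_after = e_after)
      # mean per-vertex Frobenius change of the 4x3 transform blocks
      delta <- mean(sqrt(colSums(matrix(rowSums((Xnew - X)^2), nrow = 4))))
      X <- Xnew
      if (delta < config$inner_tol) break
    }
  }
  structure(list(atlas = atlas_init, transforms = X,
                 deformed_vertices = as.matrix(D %*% X), init = init,
                 energy_log = do.call(rbind, log_rows)),
            class = "deformed_atlas")
}

#' @export
print.deformed_atlas <- function(x, ...) {
  disp <- sqrt(rowSums((x$deformed_vertices - x$atlas$vertices)^2))
  cat(sprintf(
    "deformed_atlas: %d vertices, mean displacement %.3f mm, %d inner iterations\n",
    n_vertices(x$atlas), mean(disp), nrow(x$energy_log)))
  invisible(x)
}

#' Deformed atlas as a mesh
#'
#' @param d a [nicp_register()] result.
#' @return a [triangle_mesh()] with the deformed vertex positions.
#' @export
deformed_mesh <- function(d) {
  stopifnot(inherits(d, "deformed_atlas"))
  triangle_mesh(d$deformed_vertices, d$atlas$triangles, d$atlas$colors)
}

#' Read landmarks off a deformed atlas
#'
#' The registration transfers the atlas's dense anatomical correspondence to
#' the subject; the subject's landmarks are simply the deformed positions of
#' the atlas vertices that carry the landmark labels.
#'
#' @param d a [nicp_register()] result.
#' @param idx named integer vector (the 12 landmark names) of atlas vertex
#'   indices.
#' @return a [landmark_set3d()].
#' @export
landmarks_from_atlas <- function(d, idx) {
  stopifnot(inherits(d, "deformed_atlas"))
  if (!setequal(names(idx), landmark_names()))
    stop("idx must name exactly the 12 landmarks")
  idx <- idx[landmark_names()]
  if (any(idx < 1 | idx > n_vertices(d$atlas)))
    stop("atlas landmark index out of range")
  pts <- d$deformed_vertices[idx, , drop = FALSE]
  rownames(pts) <- names(idx)
  landmark_set3d(pts)
}

#' Read / write atlas landmark index files
#'
#' JSON object `{"name": vertex_index, ...}` (1-based indices).
#'
#' @param path file path.
#' @return named integer vector.
#' @export
read_atlas_indices <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- unlist(obj)
  if (!setequal(names(idx), landmark_names()))
    stop("atlas index file must name exactly the 12 landmarks: ", path)
  storage.mode(idx) <- "integer"
  idx[landmark_names()]
}

#' Dense atlas averaging
#'
#' Averages registered meshes in dense correspondence: rigid-body Procrustes
#' alignment (translation and rotation only, no scaling) of the vertex sets
#' to their evolving mean, then the per-vertex arithmetic mean. Topology is
#' copied from the first mesh.
#'
#' @param registered list (>= 1) of [triangle_mesh()]es sharing vertex count
#'   and triangle topology.
#' @param tol,max_iter convergence controls of the alignment loop.
#' @return a [triangle_mesh()].
#' @export
average_atlas <- function(registered, tol = 1e-8, max_iter = 100) {
  if (!length(registered)) stop("no meshes to average")
  f1 <- registered[[1]]$triangles
  for (m in registered) {
    if (n_vertices(m) != n_vertices(registered[[1]]) ||
        !identical(m$triangles, f1))
      stop("meshes are not in correspondence (topology mismatch)")
  }
  if (length(registered) == 1L) return(registered[[1]])
  confs <- lapply(registered, function(m) m$vertices)
  mean_v <- confs[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(confs, function(v) {
      tr <- rigid_align(v, mean_v)
      transform_points(v, tr$rotation, tr$translation)
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    delta <- sqrt(sum((new_mean - mean_v)^2))
    mean_v <- new_mean
    if (delta < tol) break
  }
  triangle_mesh(mean_v, f1)
}

#' Mean symmetric surface distance between two meshes
#'
#' Average of vertex-to-surface distances in both directions; the standard
#' summary of registration quality on surfaces.
#'
#' @param a,b [triangle_mesh()]es.
#' @return scalar (mm).
#' @export
mean_symmetric_surface_distance <- function(a, b) {
  da <- cpp_closest_points(a$vertices, b$vertices, b$triangles - 1L,
                           logical(n_vertices(b)))$distance
  db <- cpp_closest_points(b$vertices, a$vertices, a$triangles - 1L,
                           logical(n_vertices(a)))$distance
  (mean(da) + mean(db)) / 2
}
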
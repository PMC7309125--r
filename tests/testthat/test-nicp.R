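test_that("affine_init recovers a known affine and the identity", {
  fx <- small_fixture()
  lm <- fx$landmarks
  expect_equal(affine_init(lm, lm), cbind(diag(3), 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  set.seed(41)
  A0 <- cbind(diag(3) + matrix(stats::rnorm(9, 0, 0.1), 3), c(5, -3, 8))
  moved <- landmark_set3d(facemark3d:::apply_affine(unclass(lm), A0))
  expect_equal(affine_init(lm, moved), A0, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("affine_init rejects coplanar configurations", {
  flat <- unclass(small_fixture()$landmarks)
  flat[, 3] <- 0
  flat <- landmark_set3d(flat)
  expect_error(affine_init(flat, flat), "degenerate|coplanar")
})

test_that("affine_init residual is locally optimal under noise", {
  fx <- small_fixture()
  lm <- unclass(fx$landmarks)
  set.seed(42)
  subj <- landmark_set3d(lm + matrix(stats::rnorm(36, 0, 2), 12, 3))
  A <- affine_init(fx$landmarks, subj)
  ssd <- sum((facemark3d:::apply_affine(lm, A) - unclass(subj))^2)
  for (i in 1:1000) {
    Ap <- A + matrix(stats::rnorm(12, 0, 0.001), 3, 4)
    expect_lte(ssd, sum((facemark3d:::apply_affine(lm, Ap) -
                           unclass(subj))^2) + 1e-9)
  }
})

test_that("self-registration is a fixpoint", {
  fx <- small_fixture()
  d <- nicp_register(fx$mesh, fx$mesh)
  disp <- sqrt(rowSums((d$deformed_vertices - fx$mesh$vertices)^2))
  expect_lt(mean(disp), 0.01)
})

test_that("NICP recovers a rigidly moved target after affine init", {
  fx <- small_fixture()
  R <- rotation_y(20) %*% rotation_x(10)
  tgt <- apply_rigid(fx$mesh, fx$landmarks, R, c(15, -10, 5))
  init <- affine_init(fx$landmarks, tgt$landmarks)
  d <- nicp_register(fx$mesh, tgt$mesh, init)
  expect_lt(mean_symmetric_surface_distance(deformed_mesh(d), tgt$mesh), 0.1)
  # read-off landmarks match the rigidly moved ground truth
  idx <- attr(fx$mesh, "landmark_vertices")
  lm <- landmarks_from_atlas(d, idx)
  expect_lt(max(landmark_dist(lm, tgt$landmarks)), 0.1)
})

test_that("registration improves on the affine initialization for a deformed target", {
  fx <- small_fixture()
  spec <- fixture_spec(n_lat = 45, n_mer = 45)
  tgt <- make_population(2, deformation_scale = 5, seed = 3, spec = spec)[[2]]
  init <- affine_init(fx$landmarks, tgt$landmarks)
  aff <- triangle_mesh(facemark3d:::apply_affine(fx$mesh$vertices, init),
                       fx$mesh$triangles)
  d <- nicp_register(fx$mesh, tgt$mesh, init)
  expect_lt(mean_symmetric_surface_distance(deformed_mesh(d), tgt$mesh),
            mean_symmetric_surface_distance(aff, tgt$mesh))
})

test_that("the exact solve never increases the energy within an iteration", {
  fx <- small_fixture()
  spec <- fixture_spec(n_lat = 45, n_mer = 45)
  tgt <- make_population(2, deformation_scale = 5, seed = 9, spec = spec)[[2]]
  init <- affine_init(fx$landmarks, tgt$landmarks)
  d <- nicp_register(fx$mesh, tgt$mesh, init)
  log <- d$energy_log
  expect_true(all(log$e_after <= log$e_before * (1 + 1e-9) + 1e-12))
  # post-solve energies are non-increasing across inner iterations at each
  # fixed stiffness on this fixture
  for (alpha in unique(log$stiffness)) {
    e <- log$e_after[log$stiffness == alpha]
    if (length(e) > 1)
      expect_true(all(diff(e) <= abs(e[-length(e)]) * 1e-6 + 1e-9))
  }
})

test_that("the solution is a minimum against random transform perturbations", {
  fx <- test_fixture("nicp-tiny", fixture_spec(n_lat = 20, n_mer = 20, marker_radius = 0))
  tgt <- make_population(2, deformation_scale = 3, seed = 5,
                         spec = fixture_spec(n_lat = 20, n_mer = 20, marker_radius = 0))[[2]]
  init <- affine_init(fx$landmarks, tgt$landmarks)
  cfg <- nicp_config(stiffness_schedule = c(10, 5), max_inner_iter = 3)
  d <- nicp_register(fx$mesh, tgt$mesh, init, cfg)
  # rebuild the final energy pieces and probe around the solution
  n <- n_vertices(fx$mesh)
  X <- d$transforms
  V0 <- d$atlas$vertices
  edges <- facemark3d:::mesh_edges(fx$mesh)
  tb <- facemark3d:::border_vertices(tgt$mesh)
  energy_at <- function(Xc) {
    def <- t(vapply(seq_len(n), function(i)
      as.numeric(c(V0[i, ], 1) %*% Xc[(4 * i - 3):(4 * i), ]), numeric(3)))
    cp <- facemark3d:::cpp_closest_points(def, tgt$mesh$vertices,
                                          tgt$mesh$triangles - 1L, tb)
    stiff <- sum(vapply(seq_len(nrow(edges)), function(e) {
      di <- Xc[(4 * edges[e, 1] - 3):(4 * edges[e, 1]), ] -
        Xc[(4 * edges[e, 2] - 3):(4 * edges[e, 2]), ]
      sum((di * c(1, 1, 1, 1))^2)
    }, 0))
    sum((def - cp$point)^2) + 5 * stiff
  }
  e0 <- energy_at(X)
  set.seed(6)
  worse <- 0
  for (i in 1:30) {
    Xp <- X + matrix(stats::rnorm(length(X), 0, 1e-3), nrow(X), 3)
    if (energy_at(Xp) >= e0 - 1e-8) worse <- worse + 1
  }
  expect_gte(worse, 29)  # allow one borderline case from correspondence switches
})

test_that("registration is equivariant under a common rigid motion", {
  fx <- test_fixture("nicp-tiny", fixture_spec(n_lat = 20, n_mer = 20, marker_radius = 0))
  tgt <- make_population(2, deformation_scale = 3, seed = 11,
                         spec = fixture_spec(n_lat = 20, n_mer = 20, marker_radius = 0))[[2]]
  init <- affine_init(fx$landmarks, tgt$landmarks)
  d0 <- nicp_register(fx$mesh, tgt$mesh, init)
  R <- rotation_z(30) %*% rotation_x(15)
  tr <- c(30, -20, 10)
  tgt2 <- apply_rigid(tgt$mesh, tgt$landmarks, R, tr)
  init2 <- affine_init(fx$landmarks, tgt2$landmarks)
  d1 <- nicp_register(fx$mesh, tgt2$mesh, init2)
  expect_equal(d1$deformed_vertices,
               transform_points(d0$deformed_vertices, R, tr),
               tolerance = 1e-2)
})

test_that("landmarks_from_atlas reads deformed vertex positions", {
  fx <- small_fixture()
  idx <- attr(fx$mesh, "landmark_vertices")
  d <- nicp_register(fx$mesh, fx$mesh)
  lm <- landmarks_from_atlas(d, idx)
  expect_setequal(rownames(lm), landmark_names())
  expect_lt(max(landmark_dist(lm, fx$landmarks)), 0.01)
  bad <- idx
  bad["prn"] <- n_vertices(fx$mesh) + 1L
  expect_error(landmarks_from_atlas(d, bad), "out of range")
})

test_that("atlas index files round-trip as JSON", {
  fx <- small_fixture()
  idx <- attr(fx$mesh, "landmark_vertices")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.list(idx), path, auto_unbox = TRUE)
  back <- read_atlas_indices(path)
  expect_identical(back, idx[landmark_names()])
})

test_that("average_atlas averages dense correspondences rigidly", {
  fx <- test_fixture("nicp-tiny", fixture_spec(n_lat = 20, n_mer = 20, marker_radius = 0))
  m <- fx$mesh
  # identical inputs -> that mesh
  expect_equal(average_atlas(list(m, m))$vertices, m$vertices,
               tolerance = 1e-9)
  # two inputs symmetric about a constructed mean (radial in/out scaling, so
  # the optimal rigid alignment between them is the identity by construction)
  delta <- 0.01 * sweep(m$vertices, 2, colMeans(m$vertices))
  a <- triangle_mesh(m$vertices + delta, m$triangles)
  b <- triangle_mesh(m$vertices - delta, m$triangles)
  avg <- average_atlas(list(a, b))
  tr <- rigid_align(avg$vertices, m$vertices)
  expect_lt(max(abs(transform_points(avg$vertices, tr$rotation,
                                     tr$translation) - m$vertices)), 1e-6)
  # rigidly scattered copies collapse back to the mesh up to rigid motion
  set.seed(14)
  copies <- lapply(1:4, function(i)
    triangle_mesh(transform_points(m$vertices, random_rotation(),
                                   stats::rnorm(3, 0, 40)), m$triangles))
  avg2 <- average_atlas(copies)
  tr2 <- rigid_align(avg2$vertices, m$vertices)
  expect_lt(max(abs(transform_points(avg2$vertices, tr2$rotation,
                                     tr2$translation) - m$vertices)), 1e-6)
  # topology mismatch
  other <- triangle_mesh(m$vertices[-1, , drop = FALSE],
                         matrix(c(1L, 2L, 3L), 1))
  expect_error(average_atlas(list(m, other)), "correspondence")
})

test_that("the optional guide-point term pins guided vertices", {
  fx <- test_fixture("nicp-tiny", fixture_spec(n_lat = 20, n_mer = 20,
                                               marker_radius = 0))
  tgt <- make_population(2, deformation_scale = 3, seed = 21,
                         spec = fixture_spec(n_lat = 20, n_mer = 20,
                                             marker_radius = 0))[[2]]
  init <- affine_init(fx$landmarks, tgt$landmarks)
  idx <- attr(fx$mesh, "landmark_vertices")
  cfg_on <- nicp_config(landmark_weight = 10)
  d_on <- nicp_register(fx$mesh, tgt$mesh, init, cfg_on,
                        guide_idx = idx, guide_targets = unclass(tgt$landmarks))
  d_off <- nicp_register(fx$mesh, tgt$mesh, init)
  gap_on <- mean(sqrt(rowSums((d_on$deformed_vertices[idx, ] -
                                 unclass(tgt$landmarks))^2)))
  gap_off <- mean(sqrt(rowSums((d_off$deformed_vertices[idx, ] -
                                  unclass(tgt$landmarks))^2)))
  expect_lt(gap_on, gap_off)
  expect_lt(gap_on, 0.5)
  # guides without a weight are refused with a warning
  expect_warning(
    nicp_register(fx$mesh, tgt$mesh, init, guide_idx = idx,
                  guide_targets = unclass(tgt$landmarks)),
    "landmark_weight")
  expect_true(all(d_on$energy_log$e_after <=
                    d_on$energy_log$e_before * (1 + 1e-9) + 1e-12))
})
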
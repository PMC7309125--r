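test_that("minimal hand-written PLY fixture loads with colors", {
  m <- read_mesh(test_path("fixtures", "triangle_red.ply"))
  expect_equal(n_vertices(m), 3L)
  expect_equal(n_triangles(m), 1L)
  expect_equal(m$colors, matrix(rep(c(1, 0, 0), each = 3), 3, 3))
  expect_equal(m$triangles, matrix(c(1L, 2L, 3L), 1, 3))
})

test_that("PLY and OBJ round-trip vertices, triangles and colors", {
  fx <- test_fixture("tiny", fixture_spec(n_lat = 12, n_mer = 12, marker_radius = 0))
  m <- fx$mesh
  for (fmt in c("ply", "obj")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_identical(m2$triangles, m$triangles)
    expect_true(max(abs(m2$colors - m$colors)) <= 1 / 255 + 1e-9)
  }
})

test_that("the same geometry read from PLY and OBJ is identical", {
  fx <- test_fixture("tiny", fixture_spec(n_lat = 12, n_mer = 12, marker_radius = 0))
  p1 <- withr::local_tempfile(fileext = ".ply")
  p2 <- withr::local_tempfile(fileext = ".obj")
  write_mesh(fx$mesh, p1)
  write_mesh(fx$mesh, p2)
  a <- read_mesh(p1)
  b <- read_mesh(p2)
  expect_equal(a$vertices, b$vertices, tolerance = 1e-9)
  expect_identical(a$triangles, b$triangles)
  expect_equal(a$colors, b$colors, tolerance = 1 / 255)
})

test_that("binary little-endian PLY is read", {
  # craft the file byte-by-byte, independent of the package writer
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  header <- c("ply", "format binary_little_endian 1.0",
              "element vertex 3",
              "property float x", "property float y", "property float z",
              "property uchar red", "property uchar green",
              "property uchar blue",
              "element face 1",
              "property list uchar int vertex_indices", "end_header")
  writeLines(header, con)
  verts <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  cols <- rbind(c(255L, 0L, 0L), c(0L, 255L, 0L), c(0L, 0L, 255L))
  for (i in 1:3) {
    writeBin(as.numeric(verts[i, ]), con, size = 4, endian = "little")
    writeBin(as.integer(cols[i, ]), con, size = 1)
  }
  writeBin(3L, con, size = 1)
  writeBin(c(0L, 1L, 2L), con, size = 4, endian = "little")
  close(con)
  m <- read_mesh(path)
  expect_equal(m$vertices, verts, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(m$colors, cols / 255, ignore_attr = TRUE)
  expect_identical(m$triangles, matrix(c(1L, 2L, 3L), 1, 3))
})

test_that("meshes without colors round-trip without color properties", {
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     rbind(c(1L, 2L, 3L)))
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, path)
  expect_false(any(grepl("red", readLines(path))))
  expect_null(read_mesh(path)$colors)
})

test_that("non-triangular faces and malformed records are rejected", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3"), path)
  expect_error(read_mesh(path), "non-triangular")

  path2 <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 1 1 0", "f 1 2 3 4"),
             path2)
  expect_error(read_mesh(path2), "non-triangular")

  path3 <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 oops", "f 1 2 3"), path3)
  expect_error(read_mesh(path3), "line 1")
})

test_that("triangle_mesh invariants are enforced", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(triangle_mesh(v, rbind(c(1L, 2L, 4L))), "out of range")
  expect_error(triangle_mesh(v, rbind(c(1L, 1L, 2L))), "repeated")
  expect_error(triangle_mesh(rbind(v, c(NA, 0, 0)), rbind(c(1L, 2L, 3L))),
               "finite")
  expect_error(triangle_mesh(v, rbind(c(1L, 2L, 3L)),
                             colors = rbind(c(0, 0, 2), c(0, 0, 0),
                                            c(0, 0, 0))),
               "\\[0, 1\\]")
})

test_that("mesh_centroid is the vertex mean and is rigid-equivariant", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  m <- triangle_mesh(cube, rbind(c(1L, 2L, 3L)))
  expect_equal(mesh_centroid(m), c(0.5, 0.5, 0.5), ignore_attr = TRUE)

  single <- triangle_mesh(matrix(c(1, 2, 3), 1, 3), matrix(integer(0), 0, 3))
  expect_equal(mesh_centroid(single), c(1, 2, 3), ignore_attr = TRUE)

  fx <- small_fixture()
  expect_equal(mesh_centroid(fx$mesh),
               colMeans(fx$mesh$vertices))  # brute-force re-summation

  set.seed(11)
  R <- random_rotation()
  t0 <- stats::rnorm(3, 0, 50)
  moved <- apply_rigid(fx$mesh, NULL, R, t0)
  expect_equal(mesh_centroid(moved$mesh),
               as.numeric(R %*% mesh_centroid(fx$mesh)) + t0,
               tolerance = 1e-9)
})
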
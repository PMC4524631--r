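# Mesh container, validation, I/O, normals and the umbrella Laplacian.

test_that("mesh validation catches bad indices, degenerate faces and
           non-manifold input", {
  tet <- tetra_mesh()
  expect_equal(nrow(tet$vertices), 4L)
  expect_equal(nrow(tet$faces), 4L)
  # out-of-range face index
  expect_error(triangle_mesh(tet$vertices, rbind(tet$faces, c(1, 2, 5))),
               "out of range")
  # degenerate face
  expect_error(triangle_mesh(tet$vertices, rbind(tet$faces[-1, ], c(2, 2, 3))),
               "degenerate")
  # same face twice -> repeated directed edge (orientation violation)
  expect_error(triangle_mesh(tet$vertices, rbind(tet$faces, tet$faces[1, ])),
               "oriented")
})

test_that("PLY round-trip preserves vertices, faces, region and scalars", {
  m <- generate_tooth(tooth_spec(resolution = 200L, seed = 3L))
  m$scalars$wear_depth <- seq_len(nrow(m$vertices)) * 1e-3
  path <- withr::local_tempfile(fileext = ".ply")
  save_mesh(m, path, scalar_name = "wear_depth")
  m2 <- load_mesh(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-12)
  expect_identical(m2$faces, m$faces)
  expect_identical(m2$region, m$region)
  expect_equal(m2$scalars$wear_depth, m$scalars$wear_depth, tolerance = 1e-12)
})

test_that("OBJ and STL round-trip geometry; STL drops scalars with a
           warning", {
  tet <- tetra_mesh()
  p_obj <- withr::local_tempfile(fileext = ".obj")
  save_mesh(tet, p_obj)
  t2 <- load_mesh(p_obj)
  expect_equal(t2$vertices, tet$vertices, tolerance = 1e-12)
  expect_identical(t2$faces, tet$faces)

  tet$scalars$depth <- rep(0, 4)
  p_stl <- withr::local_tempfile(fileext = ".stl")
  expect_warning(save_mesh(tet, p_stl, scalar_name = "depth"),
                 "dropped")
  t3 <- load_mesh(p_stl)
  # STL welds identical coordinates; geometry is preserved up to vertex order
  expect_equal(nrow(t3$vertices), 4L)
  expect_equal(nrow(t3$faces), 4L)
})

test_that("binary little-endian PLY is read correctly", {
  tet <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4",
               "property list uchar int vertex_indices", "end_header"), con)
  for (i in 1:4)
    writeBin(as.numeric(tet$vertices[i, ]), con, size = 4, endian = "little")
  for (f in 1:4) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(tet$faces[f, ] - 1L), con, size = 4,
             endian = "little")
  }
  close(con)
  m <- load_mesh(path)
  expect_equal(m$vertices, tet$vertices, tolerance = 1e-6)
  expect_identical(m$faces, tet$faces)
})

test_that("vertex normals: planar grid, icosphere accuracy, orientation
           flip", {
  g <- grid_mesh(5)
  n <- vertex_normals(g)
  expect_equal(n, matrix(rep(c(0, 0, 1), each = nrow(n)), ncol = 3),
               tolerance = 1e-12)

  sph <- icosphere_mesh(2)
  ns <- vertex_normals(sph)
  # analytic sphere normal is the position direction; within 5 degrees
  cosang <- rowSums(ns * sph$vertices) /
    sqrt(rowSums(sph$vertices^2))
  expect_gt(min(cosang), cos(5 * pi / 180))

  flipped <- triangle_mesh(g$vertices, g$faces[, c(1, 3, 2)])
  expect_equal(vertex_normals(flipped), -n, tolerance = 1e-12)
})

test_that("vertex normals rotate with the mesh (rigid invariance)", {
  set.seed(42)
  sph <- icosphere_mesh(1)
  R <- rotation_about(rnorm(3), 0.83)
  rot <- sph
  rot$vertices <- sph$vertices %*% t(R)
  expect_equal(vertex_normals(rot), vertex_normals(sph) %*% t(R),
               tolerance = 1e-10)
})

test_that("umbrella Laplacian: zero row sums, tetrahedron deltas, translation
           invariance, brute-force oracle equivalence", {
  for (m in list(tetra_mesh(), grid_mesh(5), icosphere_mesh(1),
                 generate_tooth(tooth_spec(resolution = 300L, seed = 5L)))) {
    L <- build_laplacian(m)
    expect_lt(max(abs(Matrix::rowSums(L$W))), 1e-12)
    # constant vertex array -> zero deltas
    const <- matrix(1, nrow(m$vertices), 3)
    expect_lt(max(abs(L$W %*% const)), 1e-12)
    # sparse operator equals direct per-vertex summation
    expect_equal(as.matrix(L$W %*% m$vertices), brute_force_deltas(m),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # translation leaves deltas unchanged
    shifted <- sweep(m$vertices, 2, c(3, -2, 7), `+`)
    expect_equal(as.matrix(L$W %*% shifted), as.matrix(L$W %*% m$vertices),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # regular tetrahedron with unit circumradius: delta_i = (4/3) v_i
  tet <- tetra_mesh()
  d <- as.matrix(build_laplacian(tet)$W %*% tet$vertices)
  expect_equal(d, (4 / 3) * tet$vertices, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("region mask CSV sidecar round-trips", {
  m <- generate_tooth(tooth_spec(resolution = 200L, seed = 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_mask(m$region, path)
  expect_identical(read_region_mask(path, nrow(m$vertices)), m$region)
})
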
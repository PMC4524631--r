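# Laplacian-coordinate interpolation, sparse reconstruction and wear maps.

test_that("differential coordinates vanish at 1-ring centroids and match the
           brute-force oracle", {
  g <- grid_mesh(5)
  lc <- laplacian_coords(g)
  # interior grid vertices sit at their 1-ring centroid
  interior <- which(g$vertices[, 1] > 0 & g$vertices[, 1] < 1 &
                      g$vertices[, 2] > 0 & g$vertices[, 2] < 1)
  expect_lt(max(abs(lc$deltas[interior, ])), 1e-12)
  for (m in list(tetra_mesh(), icosphere_mesh(1))) {
    expect_equal(laplacian_coords(m)$deltas, brute_force_deltas(m),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("bilinear interpolation of deltas: endpoints exact, hand-computed
           midpoint, magnitude linear to machine precision", {
  m <- icosphere_mesh(1)
  L <- build_laplacian(m)
  ds <- laplacian_coords(m, L)
  m2 <- m
  m2$vertices <- m$vertices * 1.4 + matrix(rep(c(1, 0, -2), each = nrow(m$vertices)), ncol = 3)
  dt <- laplacian_coords(m2, L)
  expect_equal(interpolate_delta(ds, dt, 0)$deltas, ds$deltas,
               tolerance = 1e-14)
  expect_equal(interpolate_delta(ds, dt, 1)$deltas, dt$deltas,
               tolerance = 1e-14)
  for (u in c(0.25, 0.5, 0.9)) {
    dm <- interpolate_delta(ds, dt, u)
    expect_equal(dm$target_magnitudes,
                 (1 - u) * ds$magnitudes + u * dt$magnitudes,
                 tolerance = 1e-15)
  }

  # literal application of the direction/magnitude rule on one vertex:
  # delta_s = (2,0,0), delta_t = (0,4,0), u = 0.5
  fake <- function(d) {
    mags <- sqrt(rowSums(d^2))
    structure(list(deltas = d, magnitudes = mags, directions = d / mags,
                   defined = mags > 1e-12), class = "LaplacianCoords")
  }
  dm <- interpolate_delta(fake(rbind(c(2, 0, 0))), fake(rbind(c(0, 4, 0))),
                          0.5)
  expect_equal(dm$deltas[1, ], c(1.5, 1.5, 0), tolerance = 1e-14)

  # degenerate endpoint magnitude falls back to linear interpolation
  dz <- interpolate_delta(fake(rbind(c(0, 0, 0))), fake(rbind(c(0, 4, 0))),
                          0.25)
  expect_equal(dz$deltas[1, ], c(0, 1, 0), tolerance = 1e-14)
})

test_that("reconstruction: identity from own deltas, translation follows the
           anchors, dense solve agrees on a tetrahedron", {
  m <- generate_tooth(tooth_spec(resolution = 400L, seed = 13L))
  L <- build_laplacian(m)
  lc <- laplacian_coords(m, L)
  ax <- toothwear:::axial_vertices(m)
  anch <- anchor_set(ax, m$vertices[ax, ], weight = 1)
  rec <- reconstruct_mesh(lc, L, anch, m)
  bb <- toothwear:::bbox_diagonal(m)
  expect_lt(max(sqrt(rowSums((rec$vertices - m$vertices)^2))), 1e-6 * bb)

  t <- c(1, 2, 3)
  anch2 <- anchor_set(ax, sweep(m$vertices[ax, ], 2, t, `+`), weight = 1)
  rec2 <- reconstruct_mesh(lc, L, anch2, m)
  expect_equal(rec2$vertices, sweep(rec$vertices, 2, t, `+`),
               tolerance = 1e-6)

  # tetrahedron: augmented dense least squares vs sparse route
  tet <- tetra_mesh()
  Lt <- build_laplacian(tet)
  lt <- laplacian_coords(tet, Lt)
  a <- anchor_set(1:2, tet$vertices[1:2, ], weight = 1)
  sparse <- reconstruct_mesh(lt, Lt, a, tet)
  Ad <- rbind(as.matrix(Lt$W), cbind(diag(2), matrix(0, 2, 2)))
  bd <- rbind(lt$deltas, tet$vertices[1:2, ])
  dense <- qr.solve(Ad, bd)
  expect_equal(sparse$vertices, dense, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("morph frames: endpoint fidelity, degenerate morph, monotone and
           continuous wear, stationary axial walls", {
  fx <- std_fixture()
  s0 <- fx$aligned
  sh <- fx$sh
  bb <- toothwear:::bbox_diagonal(s0)
  u_grid <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  frames <- morph_sequence(s0, sh, u_grid)
  expect_lt(max(sqrt(rowSums((frames[[1]]$mesh$vertices - s0$vertices)^2))),
            1e-6 * bb)
  expect_lt(max(sqrt(rowSums((frames[[6]]$mesh$vertices - sh$vertices)^2))),
            1e-6 * bb)
  # wear depth non-decreasing in u at every vertex (tiny solver slack)
  d <- sapply(frames, function(f) f$wear_depth)
  expect_true(all(diff(t(d)) > -1e-8))
  # axial walls never move
  ax <- toothwear:::axial_vertices(s0)
  for (f in frames)
    expect_lt(max(abs(f$mesh$vertices[ax, ] - s0$vertices[ax, ])), 1e-9)

  # degenerate morph: sh = s0 keeps every frame at s0
  same <- morph_sequence(s0, s0, c(0, 0.5, 1))
  for (f in same)
    expect_lt(max(sqrt(rowSums((f$mesh$vertices - s0$vertices)^2))),
              1e-6 * bb)

  # frame continuity: displacement between consecutive frames shrinks when
  # the u grid is halved
  step_disp <- function(us) {
    fs <- morph_sequence(s0, sh, us)
    max(vapply(seq_len(length(fs) - 1), function(k) {
      max(sqrt(rowSums((fs[[k + 1]]$mesh$vertices -
                          fs[[k]]$mesh$vertices)^2)))
    }, numeric(1)))
  }
  expect_lt(step_disp(seq(0, 1, 0.25)), step_disp(seq(0, 1, 0.5)) + 1e-12)
})

test_that("wear maps measure displacement and colour it yellow to red", {
  m <- generate_tooth(tooth_spec(resolution = 300L, seed = 14L))
  wm <- wear_map(m, m)
  expect_true(all(wm$depth == 0))
  expect_true(all(wm$colors == 200L))  # neutral base colour at zero depth

  moved <- m
  moved$vertices[10, ] <- moved$vertices[10, ] + c(0, 0, -0.3)
  wm2 <- wear_map(m, moved)
  expect_equal(max(wm2$depth), 0.3, tolerance = 1e-12)
  expect_equal(which.max(wm2$depth), 10L)
  expect_identical(wm2$colors[10, ], c(red = 255L, green = 0L, blue = 0L))
})
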
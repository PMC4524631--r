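# RBF distance field, normal projection and contraction-and-bounding.

test_that("normal projection onto a plane patch gives signed distances and
           closest-point fallback", {
  g <- grid_mesh(5)  # z = 0 patch over [0,1]^2
  pr <- project_along_normal(rbind(c(0.5, 0.5, 1)), rbind(c(0, 0, 1)), g)
  expect_equal(pr$points[1, ], c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(pr$signed_distances[1], -1, tolerance = 1e-12)
  expect_true(pr$hit[1])

  # a point already on the target has distance 0
  on <- project_along_normal(rbind(c(0.25, 0.25, 0)), rbind(c(0, 0, 1)), g)
  expect_equal(on$signed_distances[1], 0, tolerance = 1e-12)

  # normal ray exits past the patch boundary -> closest-point fallback
  off <- project_along_normal(rbind(c(2, 0.5, 1)), rbind(c(0, 0, 1)), g)
  expect_false(off$hit[1])
  expect_equal(off$points[1, ], c(1, 0.5, 0), tolerance = 1e-12)
  expect_equal(abs(off$signed_distances[1]), sqrt(2), tolerance = 1e-12)
})

test_that("RBF fit reproduces affine data with zero radial weights", {
  set.seed(21)
  ctr <- matrix(runif(30, -2, 2), ncol = 3)
  d <- 2 + 3 * ctr[, 1]
  f <- fit_rbf(ctr, d)
  expect_lt(max(abs(f$weights)), 1e-8)
  expect_equal(f$poly, c(2, 3, 0, 0), tolerance = 1e-8)
  expect_equal(evaluate_rbf(f, c(1, 1, 1)), 5, tolerance = 1e-8)

  z <- fit_rbf(ctr, rep(0, nrow(ctr)))
  q <- matrix(runif(15, -3, 3), ncol = 3)
  expect_lt(max(abs(evaluate_rbf(z, q))), 1e-10)
})

test_that("RBF interpolation exactness and orthogonality conditions hold,
           matching an independent dense solve", {
  set.seed(22)
  ctr <- matrix(runif(30, -1, 1), ncol = 3)
  d <- rnorm(10)
  f <- fit_rbf(ctr, d)
  # exactness at the centers
  expect_lt(max(abs(evaluate_rbf(f, ctr) - d)), 1e-8 * max(abs(d)))
  # orthogonality side conditions
  expect_lt(abs(sum(f$weights)), 1e-8)
  for (k in 1:3) expect_lt(abs(sum(f$weights * ctr[, k])), 1e-8)
  # independent oracle: QR solve of the freshly assembled saddle system
  A <- as.matrix(dist(ctr))^3
  P <- cbind(1, ctr)
  M <- rbind(cbind(A, P), cbind(t(P), matrix(0, 4, 4)))
  sol <- unname(qr.solve(M, c(d, rep(0, 4))))
  expect_equal(f$weights, sol[1:10], tolerance = 1e-8)
  expect_equal(f$poly, sol[11:14], tolerance = 1e-8)
})

test_that("the radial part of the field is rigid-motion equivariant", {
  set.seed(23)
  ctr <- matrix(runif(24, -1, 1), ncol = 3)
  d <- rnorm(8)
  f <- fit_rbf(ctr, d)
  R <- rotation_about(c(1, 2, 3), 0.7)
  t <- c(0.4, -1, 2)
  f2 <- fit_rbf(sweep(ctr %*% t(R), 2, t, `+`), d)
  q <- matrix(runif(9, -1, 1), ncol = 3)
  q2 <- sweep(q %*% t(R), 2, t, `+`)
  expect_equal(evaluate_rbf(f2, q2), evaluate_rbf(f, q), tolerance = 1e-8)
})

test_that("duplicate centers are reported by position", {
  ctr <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(fit_rbf(ctr, rep(1, 5)), "duplicate centers")
})

test_that("initial homogeneous surface: identical worn surface gives S0
           back; constant normal offset is reproduced", {
  m <- generate_tooth(tooth_spec(resolution = 600L, seed = 10L))
  feats <- extract_feature_points(m, 60L)
  sh_same <- build_initial_homogeneous(m, feats, m)
  expect_equal(sh_same$vertices, m$vertices, tolerance = 1e-6)

  # a constant 0.5 mm offset along the vertex normals is reproduced
  # exactly: every occlusal feature measures exactly -0.5 and the field's
  # polynomial part carries the constant to every vertex (features must be
  # occlusal — axial features would measure 0 and the smooth field would
  # ramp across the wear step at the crown margin)
  n <- vertex_normals(m)
  worn <- m
  occ <- toothwear:::occlusal_vertices(m)
  worn$vertices[occ, ] <- worn$vertices[occ, ] - 0.5 * n[occ, ]
  ofeats <- extract_feature_points(m, 40L, region = "occlusal")
  sh <- build_initial_homogeneous(m, ofeats, worn)
  err <- sqrt(rowSums((sh$vertices[occ, ] - worn$vertices[occ, ])^2))
  expect_lt(max(err), 1e-6)
})

test_that("contraction step matches the update rule on a single free
           vertex", {
  # one occlusal vertex at the apex of a shallow pyramid over an axial ring;
  # target plane z = -1 below it
  ring <- 8
  ang <- 2 * pi * (seq_len(ring) - 1) / ring
  V <- rbind(c(0, 0, 0.05), cbind(2 * cos(ang), 2 * sin(ang), 0))
  F <- cbind(1, 1 + seq_len(ring), 1 + c(seq_len(ring)[-1], 1))
  pyr <- triangle_mesh(V, F, region = c(1L, rep(0L, ring)))
  tgt <- grid_mesh(7, 8)
  tgt$vertices[, 1:2] <- tgt$vertices[, 1:2] - 4
  tgt$vertices[, 3] <- -1
  params <- contraction_params(lambda = 0.4, smoothing_weight = 0,
                               max_iterations = 1L)
  out <- contract_and_bound(pyr, tgt, params)
  # apex normal is +z; Q = (0, 0, -1); P' = P + 0.4 (Q - P)
  expect_equal(out$mesh$vertices[1, ], c(0, 0, 0.05 + 0.4 * (-1 - 0.05)),
               tolerance = 1e-9)
  expect_equal(out$trace[1], 1.05, tolerance = 1e-9)
})

test_that("a surface already on target converges in zero iterations", {
  m <- generate_tooth(tooth_spec(resolution = 400L, seed = 12L))
  out <- contract_and_bound(m, m, contraction_params())
  expect_equal(out$iterations, 0L)
  expect_lt(out$trace[1], 1e-6)
  expect_true(out$converged)
})

test_that("contraction error decreases strictly to below the stopping
           threshold on the synthetic pair", {
  fx <- std_fixture()
  expect_true(fx$converged)
  expect_true(all(diff(fx$trace) < 0))
  expect_lt(utils::tail(fx$trace, 1), 0.001)
  # connectivity and axial positions preserved exactly
  expect_identical(fx$sh$faces, fx$aligned$faces)
  ax <- toothwear:::axial_vertices(fx$aligned)
  expect_identical(fx$sh$vertices[ax, ], fx$aligned$vertices[ax, ])
})

test_that("mean per-vertex projection distance after convergence is far
           below the stopping threshold", {
  fx <- std_fixture()
  occ <- toothwear:::occlusal_vertices(fx$aligned)
  expect_lt(utils::tail(fx$trace, 1) / length(occ), 1e-5)
})

test_that("converged surface does not gain self-intersections over the
           initial surface", {
  fx <- std_fixture()
  occ <- toothwear:::occlusal_vertices(fx$aligned)
  sub <- function(m) {
    out <- toothwear:::faces_in_vertex_set(m$faces, occ)
    used <- sort(unique(as.vector(out)))
    id <- integer(nrow(m$vertices)); id[used] <- seq_along(used)
    triangle_mesh(m$vertices[used, ], matrix(id[out], ncol = 3),
                  validate = FALSE)
  }
  expect_lte(self_intersection_count(sub(fx$sh)),
             self_intersection_count(sub(fx$init)))
})
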
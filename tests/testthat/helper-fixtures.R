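# Shared fixtures and independent oracles for the test suite. The expensive
# end-to-end synthetic run is computed once per session and memoised.

# regular tetrahedron with unit circumradius, centred at the origin
tetra_mesh <- function() {
  V <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  F <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(V, F)
}

# n x n planar grid on [0, L]^2 at z = 0, faces counter-clockwise from +z
grid_mesh <- function(n = 5, L = 1) {
  xy <- seq(0, L, length.out = n)
  V <- as.matrix(expand.grid(x = xy, y = xy))
  V <- cbind(V, 0)
  idx <- function(i, j) (j - 1L) * n + i
  F <- NULL
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    F <- rbind(F,
               c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  triangle_mesh(V, F)
}

# regular icosahedron with unit circumradius
icosahedron_mesh <- function() {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2)
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  triangle_mesh(V, F)
}

# icosphere: subdivided icosahedron projected to the unit sphere
icosphere_mesh <- function(levels = 2) {
  m <- icosahedron_mesh()
  V <- m$vertices
  F <- m$faces
  for (l in seq_len(levels)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mid_env <- new.env()
    midpoint <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid_env[[k]])) return(mid_env[[k]])
      p <- (V[a, ] + V[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      V <<- rbind(V, p)
      mid_env[[k]] <- nrow(V)
      nrow(V)
    }
    Fn <- matrix(0L, 4 * nrow(F), 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      Fn[4 * f - 3, ] <- c(a, ab, ca)
      Fn[4 * f - 2, ] <- c(b, bc, ab)
      Fn[4 * f - 1, ] <- c(c, ca, bc)
      Fn[4 * f, ] <- c(ab, bc, ca)
    }
    F <- Fn
  }
  triangle_mesh(V, F)
}

# brute-force umbrella differential coordinates (independent of the sparse
# operator route)
brute_force_deltas <- function(mesh) {
  nb <- toothwear:::vertex_neighbors(mesh)
  V <- mesh$vertices
  t(vapply(seq_len(nrow(V)), function(i) {
    V[i, ] - colMeans(V[nb[[i]], , drop = FALSE])
  }, numeric(3)))
}

# rotation matrix about a unit axis by angle (radians)
rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# standard synthetic study pair: 5 cusps, ~2000 vertices, per-cusp Gaussian
# wear of max depth 0.5 mm, independently retessellated worn surface; the
# full homogenize run is shared across tests
std_fixture_env <- new.env()
std_fixture <- function() {
  if (!is.null(std_fixture_env$fx)) return(std_fixture_env$fx)
  spec <- tooth_spec(n_cusps = 5L, resolution = 2000L, seed = 1L)
  s0 <- generate_tooth(spec)
  w <- apply_wear(s0, wear_field_spec(max_depth = 0.5, pattern = "per-cusp"),
                  retessellate = TRUE)
  al <- align_axial(s0, w$worn)
  feats <- extract_feature_points(al$mesh, 150L)
  init <- build_initial_homogeneous(al$mesh, feats, w$worn)
  cb <- contract_and_bound(init, w$worn,
                           contraction_params(max_iterations = 150L))
  std_fixture_env$fx <- list(spec = spec, s0 = s0, worn = w$worn,
                             truth = w$truth, aligned = al$mesh,
                             transform = al$transform, features = feats,
                             init = init, sh = cb$mesh, trace = cb$trace,
                             converged = cb$converged,
                             iterations = cb$iterations)
  std_fixture_env$fx
}
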
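# Generation of intermediate wear morphologies. Both endpoint surfaces (the
# intact crown and the homogeneous wear surface, which share connectivity)
# are transformed into Laplacian differential coordinates; direction and
# magnitude of each per-vertex delta are interpolated separately (bilinear
# interpolation), and world coordinates are recovered by solving the sparse
# Laplacian system with soft positional anchors on the axial region, which
# wear never moves.

#' Laplacian differential coordinates of a mesh
#'
#' \eqn{\delta_i = v_i - (1/d_i) \sum_{j \in N(i)} v_j}: the offset of each
#' vertex from its 1-ring centroid. Translation-invariant; encodes the local
#' surface detail that the morph must preserve.
#'
#' @param mesh a `TriangleMesh`.
#' @param laplacian optional pre-built `LaplacianMatrix` for the mesh.
#' @return an object of class `LaplacianCoords`: `deltas` (m x 3),
#'   `magnitudes`, `directions` (unit rows; zero rows where the magnitude
#'   vanishes) and `defined` flags.
#' @export
laplacian_coords <- function(mesh, laplacian = NULL) {
  if (is.null(laplacian)) laplacian <- build_laplacian(mesh)
  deltas <- as.matrix(laplacian$W %*% mesh$vertices)
  mags <- sqrt(rowSums(deltas^2))
  defined <- mags > 1e-12
  dirs <- deltas
  dirs[defined, ] <- deltas[defined, , drop = FALSE] / mags[defined]
  dirs[!defined, ] <- 0
  structure(list(deltas = deltas, magnitudes = mags, directions = dirs,
                 defined = defined),
            class = "LaplacianCoords")
}

#' @export
print.LaplacianCoords <- function(x, ...) {
  cat("LaplacianCoords:", nrow(x$deltas), "vertices, |delta| in [",
      signif(min(x$magnitudes), 4), ",", signif(max(x$magnitudes), 4), "]\n")
  invisible(x)
}

#' Bilinear interpolation of Laplacian coordinates
#'
#' Directions and magnitudes are interpolated separately:
#' \deqn{\delta_{MU} = (1-u)\,\delta_S/|\delta_S| + u\,\delta_T/|\delta_T|}
#' \deqn{|\delta_M| = (1-u)|\delta_S| + u|\delta_T|}
#' \deqn{\delta_M = |\delta_M| \cdot \delta_{MU}}
#' The direction term is the literal convex combination of unit vectors (not
#' renormalised); `renormalize = TRUE` selects the common variant that
#' renormalises \eqn{\delta_{MU}} before scaling. Where either endpoint
#' magnitude vanishes the vertex degrades to plain linear interpolation of
#' the raw vectors.
#'
#' @param delta_s,delta_t `LaplacianCoords` of the two endpoint surfaces
#'   (identical connectivity).
#' @param u interpolation factor in `[0, 1]`.
#' @param renormalize renormalise the interpolated direction (off by
#'   default).
#' @return a `LaplacianCoords` for the intermediate state.
#' @export
interpolate_delta <- function(delta_s, delta_t, u, renormalize = FALSE) {
  if (nrow(delta_s$deltas) != nrow(delta_t$deltas))
    stop("Laplacian coordinate sets have different vertex counts")
  if (u < 0 || u > 1) stop("u must lie in [0, 1]")
  both <- delta_s$defined & delta_t$defined
  dir <- (1 - u) * delta_s$directions + u * delta_t$directions
  mag <- (1 - u) * delta_s$magnitudes + u * delta_t$magnitudes
  if (renormalize) {
    dl <- sqrt(rowSums(dir^2))
    ok <- dl > 1e-12
    dir[ok, ] <- dir[ok, , drop = FALSE] / dl[ok]
  }
  deltas <- mag * dir
  # degenerate vertices: plain linear interpolation of the raw vectors
  if (any(!both))
    deltas[!both, ] <- (1 - u) * delta_s$deltas[!both, , drop = FALSE] +
      u * delta_t$deltas[!both, , drop = FALSE]
  mags <- sqrt(rowSums(deltas^2))
  defined <- mags > 1e-12
  dirs <- deltas
  dirs[defined, ] <- deltas[defined, , drop = FALSE] / mags[defined]
  dirs[!defined, ] <- 0
  structure(list(deltas = deltas, magnitudes = mags, directions = dirs,
                 defined = defined, u = u,
                 target_magnitudes = mag),
            class = "LaplacianCoords")
}

#' Positional anchors for Laplacian reconstruction
#'
#' The pure Laplacian system is translation-invariant (the operator
#' annihilates constants), so at least one positional constraint is required
#' to pin the reconstruction in space.
#'
#' @param indices anchored vertex indices.
#' @param positions k x 3 matrix of target positions.
#' @param weight soft-constraint weight of the anchor rows; `Inf` (the
#'   default in [morph_sequence()]) makes the anchors hard constraints,
#'   eliminated from the system, so anchored vertices are reproduced exactly.
#' @return a list of class `AnchorSet`.
#' @export
anchor_set <- function(indices, positions, weight = Inf) {
  indices <- as.integer(indices)
  positions <- as.matrix(positions)
  if (length(indices) == 0) stop("anchor set must be non-empty")
  if (nrow(positions) != length(indices))
    stop("one target position per anchored vertex is required")
  stopifnot(weight > 0)
  structure(list(indices = indices, positions = positions, weight = weight),
            class = "AnchorSet")
}

#' Reconstruct world coordinates from Laplacian coordinates
#'
#' Solves the sparse system \eqn{L V = \delta} with positional anchors in
#' least squares, via the normal equations and a sparse Cholesky
#' factorisation. With `weight = Inf` the anchored vertices are substituted
#' into the right-hand side and only the free vertices are solved for, so the
#' anchors are met exactly; a finite weight appends soft rows
#' (weight x identity) instead.
#'
#' @param delta_m a `LaplacianCoords` (the target differential coordinates).
#' @param laplacian the `LaplacianMatrix` of the template connectivity.
#' @param anchors an [anchor_set()].
#' @param template a `TriangleMesh` providing faces, region mask and scalars
#'   for the output.
#' @return a `TriangleMesh` with the template's connectivity.
#' @export
reconstruct_mesh <- function(delta_m, laplacian, anchors, template) {
  m <- nrow(delta_m$deltas)
  if (nrow(laplacian$W) != m)
    stop("Laplacian dimension does not match the coordinate set")
  solve_ls <- function(A, b) {
    tryCatch(as.matrix(Matrix::solve(Matrix::crossprod(A),
                                     Matrix::crossprod(A, b))),
             error = function(e)
               stop("Laplacian reconstruction system is rank deficient: ",
                    conditionMessage(e)))
  }
  if (is.infinite(anchors$weight)) {
    fixed <- anchors$indices
    free <- setdiff(seq_len(m), fixed)
    V <- matrix(0, m, 3)
    V[fixed, ] <- anchors$positions
    if (length(free) > 0) {
      Wf <- laplacian$W[, free, drop = FALSE]
      rhs <- delta_m$deltas -
        laplacian$W[, fixed, drop = FALSE] %*% anchors$positions
      V[free, ] <- solve_ls(Wf, rhs)
    }
  } else {
    k <- length(anchors$indices)
    Crows <- Matrix::sparseMatrix(i = seq_len(k), j = anchors$indices,
                                  x = rep(anchors$weight, k), dims = c(k, m))
    A <- rbind(laplacian$W, Crows)
    b <- rbind(delta_m$deltas, anchors$weight * anchors$positions)
    V <- solve_ls(A, b)
  }
  out <- template
  out$vertices <- unname(as.matrix(V))
  out
}

#' Morph sequence between the intact and homogeneous surfaces
#'
#' For each interpolation factor `u`, interpolates the Laplacian coordinates
#' of the two endpoint surfaces ([interpolate_delta()]), reconstructs world
#' coordinates with the axial vertices anchored at their (shared) positions,
#' and attaches the per-vertex wear depth relative to the intact surface.
#'
#' @param s0 intact `TriangleMesh` (with region mask).
#' @param sh homogeneous wear `TriangleMesh`, same connectivity.
#' @param u_values sorted ascending interpolation factors in `[0, 1]`.
#' @param anchor_weight anchor weight; `Inf` (default) pins the axial region exactly.
#' @param renormalize passed to [interpolate_delta()].
#' @return a list of `MorphFrame` objects: each has `mesh`, `u` and
#'   `wear_depth`.
#' @export
morph_sequence <- function(s0, sh, u_values, anchor_weight = Inf,
                           renormalize = FALSE) {
  if (!identical(dim(s0$faces), dim(sh$faces)) ||
      !identical(s0$faces, sh$faces))
    stop("s0 and sh must share connectivity")
  if (is.unsorted(u_values)) stop("u_values must be sorted ascending")
  if (any(u_values < 0 | u_values > 1)) stop("u values must lie in [0, 1]")
  L <- build_laplacian(s0)
  ds <- laplacian_coords(s0, L)
  dt <- laplacian_coords(sh, L)
  ax <- axial_vertices(s0)
  anchors <- anchor_set(ax, s0$vertices[ax, , drop = FALSE],
                        weight = anchor_weight)
  lapply(u_values, function(u) {
    dm <- interpolate_delta(ds, dt, u, renormalize = renormalize)
    mesh <- reconstruct_mesh(dm, L, anchors, s0)
    wm <- wear_map(s0, mesh)
    mesh$scalars$wear_depth <- wm$depth
    structure(list(mesh = mesh, u = u, wear_depth = wm$depth),
              class = "MorphFrame")
  })
}

#' @export
print.MorphFrame <- function(x, ...) {
  cat(sprintf("MorphFrame u = %.3f: max wear depth %.4f mm\n",
              x$u, max(x$wear_depth)))
  invisible(x)
}

#' Yellow-to-red wear colour map
#'
#' Linearly maps `[0, max(depth)]` to yellow (255,255,0) .. red (255,0,0);
#' zero-depth vertices are drawn in a neutral grey.
#'
#' @param depth non-negative per-vertex depths.
#' @param max_depth optional fixed scale maximum (defaults to `max(depth)`).
#' @return integer matrix (m x 3) of RGB values in 0..255.
#' @export
wear_colors <- function(depth, max_depth = NULL) {
  if (is.null(max_depth)) max_depth <- max(depth)
  m <- length(depth)
  cols <- matrix(200L, m, 3)  # neutral base
  if (max_depth > 0) {
    pos <- depth > 0
    f <- pmin(depth[pos] / max_depth, 1)
    cols[pos, 1] <- 255L
    cols[pos, 2] <- as.integer(round(255 * (1 - f)))
    cols[pos, 3] <- 0L
  }
  colnames(cols) <- c("red", "green", "blue")
  cols
}

#' Per-vertex wear depth and colours of a morph frame
#'
#' @param s0 intact `TriangleMesh`.
#' @param frame a `TriangleMesh` with identical connectivity.
#' @return list with `depth` (per-vertex Euclidean displacement from `s0`,
#'   mm) and `colors` (RGB matrix from [wear_colors()]).
#' @export
wear_map <- function(s0, frame) {
  if (!identical(s0$faces, frame$faces))
    stop("meshes must share connectivity")
  depth <- sqrt(rowSums((frame$vertices - s0$vertices)^2))
  list(depth = depth, colors = wear_colors(depth))
}
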
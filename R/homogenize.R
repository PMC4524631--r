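# Construction of the homogeneous wear surface: a mesh with the intact
# crown's connectivity whose geometry coincides with the worn scan. The
# initial guess interpolates the feature points' signed normal distances with
# a cubic (phi(x) = x^3) RBF field plus a first-order polynomial, applied as
# an offset along each vertex normal; a contraction-and-bounding iteration
# then converges every occlusal vertex onto the worn surface.

#' Project points along their normals onto a target mesh
#'
#' Each point's line \eqn{p + t n} is intersected with the target; the hit
#' with the smallest absolute ray parameter wins and `t` is the signed
#' distance (positive along the outward normal). Points whose line misses the
#' target fall back to the closest surface point with `hit = FALSE`.
#'
#' @param points k x 3 matrix.
#' @param normals k x 3 matrix of unit vectors.
#' @param target a `TriangleMesh`.
#' @return an object of class `ProjectionResult`: list with `points` (the
#'   projections Q on the target), `signed_distances` (mm), `hit` flags and
#'   `face` indices.
#' @export
project_along_normal <- function(points, normals, target) {
  points <- as.matrix(points)
  normals <- as.matrix(normals)
  if (nrow(target$faces) == 0) stop("target mesh has no faces")
  len <- sqrt(rowSums(normals^2))
  if (any(abs(len - 1) > 1e-6))
    stop("normals must be unit vectors")
  res <- cpp_project_normals(points, normals, target$vertices,
                             target$faces - 1L)
  structure(list(points = res$points, signed_distances = res$dist,
                 hit = res$hit, face = res$face),
            class = "ProjectionResult")
}

#' @export
print.ProjectionResult <- function(x, ...) {
  cat("ProjectionResult:", length(x$signed_distances), "points,",
      sum(x$hit), "normal-ray hits,", sum(!x$hit), "closest-point fallbacks\n")
  invisible(x)
}

#' Fit a cubic RBF distance field
#'
#' Solves the dense symmetric (n+4) x (n+4) interpolation system for the
#' radial weights and the first-order polynomial: \eqn{D_i = \sum_j
#' \lambda_j |V_i - V_j|^3 + c_0 + c_1 V_i^x + c_2 V_i^y + c_3 V_i^z},
#' subject to the four orthogonality conditions \eqn{\sum\lambda_j =
#' \sum\lambda_j V_j^x = \sum\lambda_j V_j^y = \sum\lambda_j V_j^z = 0}.
#'
#' @param centers n x 3 matrix of pairwise-distinct points (n >= 4, not all
#'   coplanar-degenerate).
#' @param distances length-n values to interpolate.
#' @return an object of class `RBFField`: `centers`, `weights` (lambda),
#'   `poly` (c0..c3), `kernel = "cubic"`.
#' @export
fit_rbf <- function(centers, distances) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n < 4) stop("RBF fit needs at least 4 centers")
  if (length(distances) != n)
    stop("distances must match the number of centers")
  d2 <- as.matrix(stats::dist(centers))
  dup <- which(d2 < 1e-12 & upper.tri(d2), arr.ind = TRUE)
  if (nrow(dup) > 0)
    stop("duplicate centers at rows ", dup[1, 1], " and ", dup[1, 2])
  A <- d2^3
  P <- cbind(1, centers)
  M <- rbind(cbind(A, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- c(distances, rep(0, 4))
  sol <- tryCatch(solve(M, rhs), error = function(e)
    stop("RBF system is singular: ", conditionMessage(e)))
  structure(list(centers = centers, weights = unname(sol[seq_len(n)]),
                 poly = unname(sol[n + 1:4]), kernel = "cubic"),
            class = "RBFField")
}

#' @export
print.RBFField <- function(x, ...) {
  cat("RBFField (cubic kernel):", nrow(x$centers), "centers\n")
  cat(sprintf("  poly: %.4g + %.4g x + %.4g y + %.4g z\n",
              x$poly[1], x$poly[2], x$poly[3], x$poly[4]))
  invisible(x)
}

#' Evaluate an RBF field
#'
#' @param field an `RBFField`.
#' @param query k x 3 matrix (or length-3 vector) of query points.
#' @return numeric vector of field values.
#' @export
evaluate_rbf <- function(field, query) {
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  query <- as.matrix(query)
  ctr <- field$centers
  # |q - V_j| for all pairs, blockwise to bound memory
  out <- numeric(nrow(query))
  blk <- 2048L
  for (s in seq(1L, nrow(query), by = blk)) {
    e <- min(s + blk - 1L, nrow(query))
    q <- query[s:e, , drop = FALSE]
    d <- sqrt(pmax(outer(rowSums(q^2), rowSums(ctr^2), `+`) -
                     2 * tcrossprod(q, ctr), 0))
    out[s:e] <- as.numeric(d^3 %*% field$weights) +
      field$poly[1] + q %*% field$poly[2:4]
  }
  out
}

#' Build the initial homogeneous wear surface
#'
#' The feature points of the intact surface are projected along their vertex
#' normals onto the worn surface; the signed projection distances are
#' interpolated by a cubic RBF field, which is then evaluated at every intact
#' vertex, and each occlusal vertex is offset along its normal by the field
#' value. Axial vertices receive zero offset (the side walls are unchanged by
#' wear). The output keeps the intact mesh's exact connectivity.
#'
#' @param s0 intact `TriangleMesh` (already aligned onto `s1`).
#' @param features a `FeaturePointSet` drawn from `s0`.
#' @param s1 worn `TriangleMesh`.
#' @return a `TriangleMesh` (the initial homogeneous surface), with the
#'   fitted `RBFField` attached as an attribute `rbf`.
#' @export
build_initial_homogeneous <- function(s0, features, s1) {
  normals <- vertex_normals(s0)
  fidx <- features$source_indices
  proj <- project_along_normal(features$positions,
                               normals[fidx, , drop = FALSE], s1)
  field <- fit_rbf(features$positions, proj$signed_distances)
  offset <- evaluate_rbf(field, s0$vertices)
  if (!is.null(s0$region)) offset[s0$region == 0L] <- 0
  sh <- s0
  sh$vertices <- s0$vertices + offset * normals
  attr(sh, "rbf") <- field
  sh
}

#' Contraction-and-bounding parameters
#'
#' @param lambda contraction factor in `[0, 1]`; each step moves a vertex
#'   this fraction of the way to its projection on the worn surface.
#' @param epsilon stopping threshold on the summed per-vertex projection
#'   distance `E` (mm). Note `E` is a sum, so the threshold scales with the
#'   vertex count; `mean_error = TRUE` switches the test to `E/m`.
#' @param max_iterations iteration cap.
#' @param smoothing_weight 1-ring blend weight `w` in `[0, 1]` applied to the
#'   contraction displacement field.
#' @param smooth_positions if `TRUE`, smoothing blends vertex positions with
#'   their 1-ring centroid instead of smoothing the displacement field. This
#'   regularises triangle shape but biases vertices off the target by the
#'   local curvature, so the error plateaus above `epsilon` on curved
#'   surfaces; it is off by default.
#' @param mean_error if `TRUE`, stop on `E/m < epsilon` instead of
#'   `E < epsilon` (useful for very dense meshes).
#' @return a list of class `ContractionParams`.
#' @export
contraction_params <- function(lambda = 0.4, epsilon = 0.001,
                               max_iterations = 50L, smoothing_weight = 0.5,
                               smooth_positions = FALSE, mean_error = FALSE) {
  stopifnot(lambda >= 0, lambda <= 1, epsilon > 0,
            smoothing_weight >= 0, smoothing_weight <= 1)
  structure(list(lambda = lambda, epsilon = epsilon,
                 max_iterations = as.integer(max_iterations),
                 smoothing_weight = smoothing_weight,
                 smooth_positions = smooth_positions,
                 mean_error = mean_error),
            class = "ContractionParams")
}

#' Converge the homogeneous surface onto the worn surface
#'
#' Iterates: recompute vertex normals, project every free (occlusal) vertex
#' \eqn{P_i} along its normal to \eqn{Q_i} on the worn surface, move
#' \eqn{P_i' = P_i + \lambda (Q_i - P_i)}, and apply one pass of 1-ring
#' weighted smoothing to the contraction displacements; axial vertices are
#' pinned. Stops when \eqn{E = \sum_i |P_i - Q_i| < \epsilon} (evaluated
#' before moving, so a surface already on target runs zero iterations).
#' Aborts with an error when `E` fails to decrease for five consecutive
#' iterations.
#'
#' @param sh the initial homogeneous `TriangleMesh` (intact connectivity).
#' @param s1 the worn `TriangleMesh`, aligned with `sh`.
#' @param params a [contraction_params()] object.
#' @return list with `mesh` (the converged surface), `trace` (the per-
#'   iteration `E` values, starting with the initial error), `converged`,
#'   and `iterations`.
#' @export
contract_and_bound <- function(sh, s1, params = contraction_params()) {
  free <- if (!is.null(sh$region)) occlusal_vertices(sh)
          else seq_len(nrow(sh$vertices))
  m_free <- length(free)
  if (m_free == 0) stop("no free (occlusal) vertices to contract")
  # 1-ring averaging operator (row-normalised adjacency)
  A1 <- Matrix::Diagonal(nrow(sh$vertices)) - build_laplacian(sh)$W
  V <- sh$vertices
  V1 <- s1$vertices
  F1 <- s1$faces - 1L
  trace <- numeric(0)
  stall <- 0L
  it <- 0L
  threshold <- if (params$mean_error) params$epsilon * m_free else params$epsilon
  repeat {
    normals <- vertex_normals(modifyList(sh, list(vertices = V)))
    proj <- cpp_project_normals(V[free, , drop = FALSE],
                                normals[free, , drop = FALSE], V1, F1)
    E <- sum(abs(proj$dist))
    trace <- c(trace, E)
    if (E < threshold || it >= params$max_iterations) break
    if (length(trace) > 1 && E >= trace[length(trace) - 1]) {
      stall <- stall + 1L
      if (stall >= 5L)
        stop("contraction stalled: E non-decreasing for 5 consecutive ",
             "iterations (E = ", signif(E, 6), "); the smoothing weight may ",
             "be too aggressive for this mesh")
    } else stall <- 0L

    disp <- matrix(0, nrow(V), 3)
    disp[free, ] <- params$lambda * (proj$points - V[free, , drop = FALSE])
    w <- params$smoothing_weight
    if (w > 0 && !params$smooth_positions) {
      smoothed <- (1 - w) * disp + w * as.matrix(A1 %*% disp)
      disp[free, ] <- smoothed[free, , drop = FALSE]
    }
    V[free, ] <- V[free, , drop = FALSE] + disp[free, , drop = FALSE]
    if (params$smooth_positions && w > 0) {
      Vs <- (1 - w) * V + w * as.matrix(A1 %*% V)
      V[free, ] <- Vs[free, , drop = FALSE]
    }
    it <- it + 1L
  }
  out <- sh
  out$vertices <- V
  list(mesh = out, trace = trace, converged = trace[length(trace)] < threshold,
       iterations = it)
}

#' Full homogeneous-surface construction
#'
#' Convenience wrapper: feature extraction on the intact surface, RBF
#' initialisation, then contraction and bounding.
#'
#' @param s0 intact `TriangleMesh`, aligned with `s1`.
#' @param s1 worn `TriangleMesh`.
#' @param n_features feature point count for the RBF stage.
#' @param params a [contraction_params()] object.
#' @return as [contract_and_bound()], plus `features` and `initial`.
#' @export
homogenize <- function(s0, s1, n_features = 150L,
                       params = contraction_params()) {
  feats <- extract_feature_points(s0, n_features)
  init <- build_initial_homogeneous(s0, feats, s1)
  res <- contract_and_bound(init, s1, params)
  res$features <- feats
  res$initial <- init
  res
}
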
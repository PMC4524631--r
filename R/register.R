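# Rigid registration of the intact and worn crowns. Wear only changes the
# occlusal surface, so the alignment is fitted exclusively on the axial
# (side-wall) region and then applied to the whole mesh. Classic
# point-to-point ICP with point-to-triangle closest-point matching, so the
# result does not depend on the target's tessellation density.

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @param translation length-3 translation vector (mm).
#' @return an object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)))
    stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1))
  cat(sprintf("RigidTransform: rotation %.4f deg, translation (%.4f, %.4f, %.4f)\n",
              ang * 180 / pi, x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

#' Invert a rigid transform
#' @param transform a `RigidTransform`.
#' @return the inverse `RigidTransform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Rigid transform as a 4 x 4 homogeneous matrix
#' @param transform a `RigidTransform`.
#' @return 4 x 4 matrix.
#' @export
transform_matrix4 <- function(transform) {
  M <- diag(4)
  M[1:3, 1:3] <- transform$rotation
  M[1:3, 4] <- transform$translation
  M
}

transform_points <- function(points, transform) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

# least-squares rigid fit (Kabsch/SVD) mapping src onto dst
kabsch_fit <- function(src, dst) {
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(Rm, cd - as.numeric(Rm %*% cs))
}

#' Align points onto a target surface by iterative closest point
#'
#' Alternates closest-point matching (point to triangle, on the target's
#' surface) with a least-squares rigid fit until the RMS closest-point
#' distance changes by less than `tolerance` or `max_iterations` is reached.
#' For selective alignment, pass only the axial-region points of the source
#' and the axial submesh of the target.
#'
#' @param source_points k x 3 matrix of source points (k >= 3,
#'   non-collinear).
#' @param target_mesh a `TriangleMesh` (typically the axial submesh of the
#'   worn scan).
#' @param max_iterations iteration cap.
#' @param tolerance stop when the RMS distance changes by less than this.
#' @return a `RigidTransform` mapping source into the target frame, with
#'   attributes `rms_trace` (per-iteration RMS distance) and `converged`.
#'   Non-convergence returns the best transform with a warning.
#' @export
icp_align <- function(source_points, target_mesh, max_iterations = 50L,
                      tolerance = 1e-6) {
  P <- as.matrix(source_points)
  if (nrow(P) < 3) stop("ICP needs at least 3 source points")
  ctr <- sweep(P, 2, colMeans(P))
  if (svd(ctr, nu = 0, nv = 0)$d[2] < 1e-12 * max(1, svd(ctr, nu = 0, nv = 0)$d[1]))
    stop("source points are collinear or coincident; ICP is degenerate")
  if (nrow(target_mesh$faces) == 0) stop("target region is empty")
  V <- target_mesh$vertices
  F0 <- target_mesh$faces - 1L
  total <- rigid_transform()
  cur <- P
  rms_trace <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    cl <- cpp_closest_points(cur, V, F0)
    rms <- sqrt(mean(cl$dist^2))
    rms_trace <- c(rms_trace, rms)
    step <- kabsch_fit(cur, cl$points)
    cur <- transform_points(cur, step)
    total <- rigid_transform(step$rotation %*% total$rotation,
                             as.numeric(step$rotation %*% total$translation) +
                               step$translation)
    if (abs(prev_rms - rms) < tolerance) { converged <- TRUE; break }
    prev_rms <- rms
  }
  if (!converged)
    warning("ICP did not converge within ", max_iterations, " iterations")
  attr(total, "rms_trace") <- rms_trace
  attr(total, "converged") <- converged
  total
}

#' Apply a rigid transform to a mesh
#'
#' Vertex positions are mapped; topology, region mask and scalars are
#' untouched.
#'
#' @param mesh a `TriangleMesh`.
#' @param transform a `RigidTransform`.
#' @return the transformed `TriangleMesh`.
#' @export
apply_transform <- function(mesh, transform) {
  out <- mesh
  out$vertices <- transform_points(mesh$vertices, transform)
  out
}

#' Extract the submesh spanned by a region label
#'
#' Faces whose three corners all carry the label are kept and vertices are
#' re-indexed. The original vertex indices are attached as
#' `attr(, "parent_index")`.
#'
#' @param mesh a `TriangleMesh` with a region mask.
#' @param region `"axial"` or `"occlusal"`.
#' @return a `TriangleMesh`.
#' @export
region_submesh <- function(mesh, region = c("axial", "occlusal")) {
  region <- match.arg(region)
  lab <- if (region == "occlusal") 1L else 0L
  vset <- which(mesh$region == lab)
  Fs <- faces_in_vertex_set(mesh$faces, vset)
  if (nrow(Fs) == 0) stop("region '", region, "' spans no complete face")
  used <- sort(unique(as.vector(Fs)))
  new_id <- integer(nrow(mesh$vertices))
  new_id[used] <- seq_along(used)
  out <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                       matrix(new_id[Fs], ncol = 3),
                       region = mesh$region[used], validate = FALSE)
  attr(out, "parent_index") <- used
  out
}

#' Selectively align an intact mesh onto a worn mesh using the axial region
#'
#' Fits ICP on the axial regions of both meshes (the surfaces unchanged by
#' wear) and applies the recovered transform to the whole intact mesh.
#'
#' @param s0 intact `TriangleMesh` with region mask.
#' @param s1 worn `TriangleMesh` with region mask.
#' @param max_iterations,tolerance passed to [icp_align()].
#' @return list with `mesh` (s0 aligned into s1's frame) and `transform`.
#' @export
align_axial <- function(s0, s1, max_iterations = 50L, tolerance = 1e-6) {
  src <- s0$vertices[axial_vertices(s0), , drop = FALSE]
  tgt <- region_submesh(s1, "axial")
  tf <- icp_align(src, tgt, max_iterations, tolerance)
  list(mesh = apply_transform(s0, tf), transform = tf)
}
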
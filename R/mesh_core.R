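# Mesh representation and the differential-geometry primitives shared by the
# whole pipeline: validation, adjacency, vertex normals and the uniform-weight
# (umbrella) Laplacian.

#' Construct a triangle mesh
#'
#' A `TriangleMesh` is the package's central container: an `m x 3` matrix of
#' vertex positions (model units, treated as millimetres), an `f x 3` integer
#' matrix of 1-based vertex indices, an optional per-vertex region mask
#' separating the occlusal (chewing) surface from the axial (side wall)
#' surface, and optional named per-vertex scalar fields such as wear depth.
#'
#' @param vertices numeric matrix (m x 3) of vertex positions.
#' @param faces integer matrix (f x 3) of 1-based vertex indices, oriented
#'   counter-clockwise seen from outside.
#' @param region optional per-vertex region mask: integer vector with
#'   0 = axial, 1 = occlusal, or a character vector with those labels.
#' @param scalars optional named list of per-vertex numeric vectors.
#' @param validate if `TRUE` (default) the mesh is checked for valid indices,
#'   degenerate faces, edge-manifoldness and consistent orientation.
#' @return an object of class `TriangleMesh`.
#' @export
triangle_mesh <- function(vertices, faces, region = NULL, scalars = list(),
                          validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an m x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an f x 3 matrix")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (!is.null(region)) {
    if (is.character(region)) {
      bad <- setdiff(unique(region), c("axial", "occlusal"))
      if (length(bad) > 0)
        stop("unknown region label: ", bad[1])
      region <- ifelse(region == "occlusal", 1L, 0L)
    }
    region <- as.integer(region)
    if (length(region) != nrow(vertices))
      stop("region mask length must equal the vertex count")
    if (!all(region %in% c(0L, 1L)))
      stop("region mask values must be 0 (axial) or 1 (occlusal)")
  }
  if (length(scalars) > 0) {
    if (is.null(names(scalars)) || any(names(scalars) == ""))
      stop("scalars must be a named list")
    for (nm in names(scalars)) {
      if (length(scalars[[nm]]) != nrow(vertices))
        stop("scalar '", nm, "' length must equal the vertex count")
      scalars[[nm]] <- as.numeric(scalars[[nm]])
    }
  }
  mesh <- structure(list(vertices = vertices, faces = faces,
                         region = region, scalars = scalars),
                    class = "TriangleMesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate a triangle mesh
#'
#' Checks that every face references valid, pairwise-distinct vertices, that
#' every undirected edge is shared by at most two faces (edge-manifold), and
#' that no directed edge occurs twice (consistent orientation). Violations
#' raise an error naming the first offending face.
#'
#' @param mesh a `TriangleMesh`.
#' @return the mesh, invisibly.
#' @export
validate_mesh <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  m <- nrow(V)
  if (any(!is.finite(V))) stop("mesh has non-finite vertex coordinates")
  bad <- which(F < 1L | F > m)
  if (length(bad) > 0) {
    f <- ((bad[1] - 1L) %% nrow(F)) + 1L
    stop("face ", f, " references vertex index out of range [1, ", m, "]")
  }
  degen <- which(F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 1] == F[, 3])
  if (length(degen) > 0)
    stop("face ", degen[1], " is degenerate (repeated vertex index)")
  # directed edges; a consistently oriented mesh never repeats one
  de <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  dkey <- (de[, 1] - 1) * m + de[, 2]
  dup <- which(duplicated(dkey))
  if (length(dup) > 0) {
    f <- ((dup[1] - 1L) %% nrow(F)) + 1L
    stop("face ", f, " repeats a directed edge: mesh is not consistently ",
         "oriented (or not edge-manifold)")
  }
  # undirected edges in > 2 faces break edge-manifoldness
  ukey <- (pmin(de[, 1], de[, 2]) - 1) * m + pmax(de[, 1], de[, 2])
  cnt <- table(ukey)
  if (any(cnt > 2L)) {
    badk <- as.numeric(names(cnt)[which(cnt > 2L)[1]])
    f <- ((which(ukey == badk)[1] - 1L) %% nrow(F)) + 1L
    stop("face ", f, " lies on an edge shared by more than two faces: ",
         "mesh is not edge-manifold")
  }
  invisible(mesh)
}

#' @export
print.TriangleMesh <- function(x, ...) {
  cat("TriangleMesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  if (!is.null(x$region))
    cat("  region mask: ", sum(x$region == 1L), " occlusal / ",
        sum(x$region == 0L), " axial\n", sep = "")
  if (length(x$scalars) > 0)
    cat("  scalars:", paste(names(x$scalars), collapse = ", "), "\n")
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bounding box: [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Undirected edge list (e x 2, each row sorted), deduplicated.
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e[, 1] * (max(faces) + 1) + e[, 2]), , drop = FALSE]
}

# Boundary edges: undirected edges used by exactly one face.
boundary_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (max(faces) + 1) + pmax(e[, 1], e[, 2])
  tab <- table(key)
  single <- as.numeric(names(tab)[tab == 1L])
  e[match(single, key), , drop = FALSE]
}

# Adjacency (1-ring) as a list of sorted integer vectors per vertex.
vertex_neighbors <- function(mesh) {
  e <- mesh_edges(mesh$faces)
  m <- nrow(mesh$vertices)
  nb <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(m)))
  lapply(nb, function(v) sort(unique(as.integer(v))))
}

face_normals_areas <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n * n))
  list(normals = n / pmax(len, .Machine$double.eps), areas = len / 2,
       weighted = n / 2)  # n/2 = unit normal * area
}

#' Per-vertex unit normals
#'
#' Area-weighted average of the incident face normals, normalised to unit
#' length. The mesh must be consistently oriented; vertices without any
#' incident face are an error.
#'
#' @param mesh a `TriangleMesh`.
#' @return an m x 3 matrix of unit vectors.
#' @export
vertex_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  m <- nrow(V)
  fa <- face_normals_areas(V, F)
  idx <- as.vector(F)
  w <- fa$weighted[rep(seq_len(nrow(F)), 3), , drop = FALSE]
  acc <- rowsum(w, group = idx, reorder = FALSE)
  n <- matrix(0, m, 3)
  n[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(n * n))
  if (any(len == 0)) {
    iso <- which(len == 0)[1]
    stop("vertex ", iso, " has no incident face (isolated vertex)")
  }
  n / len
}

#' Build the mesh Laplacian operator
#'
#' Returns the m x m sparse operator with rows
#' \eqn{L(v_i) = v_i - \sum_{j \in N(i)} \omega_{ij} v_j}, where the weights
#' over the 1-ring sum to one, so every row sums to zero. The default uniform
#' (umbrella) weighting uses \eqn{\omega_{ij} = 1/d_i} with \eqn{d_i} the
#' vertex degree; cotangent weighting (normalised per row) is available as an
#' opt-in alternative.
#'
#' @param mesh a `TriangleMesh` with at least 4 vertices.
#' @param weighting `"uniform"` (default) or `"cotangent"`.
#' @return an object of class `LaplacianMatrix`: list with the sparse matrix
#'   `W` and the weighting tag.
#' @export
build_laplacian <- function(mesh, weighting = c("uniform", "cotangent")) {
  weighting <- match.arg(weighting)
  m <- nrow(mesh$vertices)
  if (m < 4L) stop("Laplacian needs at least 4 vertices")
  e <- mesh_edges(mesh$faces)
  if (weighting == "uniform") {
    i <- c(e[, 1], e[, 2])
    j <- c(e[, 2], e[, 1])
    deg <- tabulate(i, nbins = m)
    if (any(deg == 0)) stop("vertex ", which(deg == 0)[1], " has degree 0")
    w <- 1 / deg[i]
  } else {
    V <- mesh$vertices
    F <- mesh$faces
    cot3 <- function(p, q, r) {
      # cotangent of the angle at p in triangle (p,q,r)
      u <- V[q, , drop = FALSE] - V[p, , drop = FALSE]
      v <- V[r, , drop = FALSE] - V[p, , drop = FALSE]
      d <- rowSums(u * v)
      cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                  u[, 3] * v[, 1] - u[, 1] * v[, 3],
                  u[, 1] * v[, 2] - u[, 2] * v[, 1])
      d / pmax(sqrt(rowSums(cr * cr)), .Machine$double.eps)
    }
    # each face contributes cot(angle at k) to edge (i,j) opposite k
    ii <- c(F[, 1], F[, 2], F[, 3])
    jj <- c(F[, 2], F[, 3], F[, 1])
    ww <- c(cot3(F[, 3], F[, 1], F[, 2]),
            cot3(F[, 1], F[, 2], F[, 3]),
            cot3(F[, 2], F[, 3], F[, 1])) / 2
    Wn <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                               dims = c(m, m))
    rs <- Matrix::rowSums(Wn)
    if (any(rs <= 0)) stop("cotangent weights degenerate at vertex ",
                           which(rs <= 0)[1])
    W <- Matrix::Diagonal(m) - Matrix::Diagonal(m, 1 / rs) %*% Wn
    return(structure(list(W = methods::as(W, "CsparseMatrix"),
                          weighting = weighting), class = "LaplacianMatrix"))
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(m, m))
  W <- Matrix::Diagonal(m) - A
  structure(list(W = methods::as(W, "CsparseMatrix"), weighting = weighting),
            class = "LaplacianMatrix")
}

#' @export
print.LaplacianMatrix <- function(x, ...) {
  cat("LaplacianMatrix (", x$weighting, " weights): ",
      nrow(x$W), " x ", ncol(x$W), " sparse\n", sep = "")
  invisible(x)
}

bbox_diagonal <- function(mesh) {
  r <- apply(mesh$vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

# indices of occlusal / axial vertices; errors when no mask is present
occlusal_vertices <- function(mesh) {
  if (is.null(mesh$region)) stop("mesh has no region mask")
  which(mesh$region == 1L)
}
axial_vertices <- function(mesh) {
  if (is.null(mesh$region)) stop("mesh has no region mask")
  which(mesh$region == 0L)
}

# faces whose three corners all lie in a vertex subset
faces_in_vertex_set <- function(faces, vset) {
  keep <- rep(FALSE, max(faces))
  keep[vset] <- TRUE
  faces[keep[faces[, 1]] & keep[faces[, 2]] & keep[faces[, 3]], , drop = FALSE]
}

#' Count self-intersecting triangle pairs
#'
#' Brute-force count of intersecting, non-adjacent triangle pairs; intended
#' as an audit for small meshes (a few thousand faces).
#'
#' @param mesh a `TriangleMesh`.
#' @return integer count.
#' @export
self_intersection_count <- function(mesh) {
  cpp_self_intersection_count(mesh$vertices, mesh$faces - 1L)
}
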
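# Anatomical feature identification by quadric-error-metric (QEM) mesh
# simplification (Garland-Heckbert edge collapse). The vertices that survive
# aggressive simplification sit on the shape-defining anatomy (cusp apices,
# ridge crests, groove floors); mapped back to the nearest original vertices
# they become the feature point set that seeds the RBF distance field.

# pack a plane (unit normal n, offset d: n.x + d = 0) into its 4x4 quadric
plane_quadric <- function(n, d, w = 1) {
  p <- c(n, d)
  w * tcrossprod(p)
}

# per-vertex fundamental quadrics: area-weighted sum of incident face planes,
# plus high-weight perpendicular constraint planes along boundary edges so
# that the open rim may only be simplified along itself
vertex_quadrics <- function(V, F, boundary_weight = 1e3) {
  m <- nrow(V)
  fa <- face_normals_areas(V, F)
  Q <- vector("list", m)
  zero <- matrix(0, 4, 4)
  for (i in seq_len(m)) Q[[i]] <- zero
  for (f in seq_len(nrow(F))) {
    n <- fa$normals[f, ]
    d <- -sum(n * V[F[f, 1], ])
    Kf <- plane_quadric(n, d, fa$areas[f])
    for (c3 in 1:3) {
      v <- F[f, c3]
      Q[[v]] <- Q[[v]] + Kf
    }
  }
  be <- boundary_edges(F)
  if (nrow(be) > 0) {
    # face normal adjacent to each boundary edge
    ukey <- function(a, b) pmin(a, b) * (m + 1) + pmax(a, b)
    fkeys <- cbind(ukey(F[, 1], F[, 2]), ukey(F[, 2], F[, 3]),
                   ukey(F[, 3], F[, 1]))
    for (e in seq_len(nrow(be))) {
      i <- be[e, 1]; j <- be[e, 2]
      k <- ukey(i, j)
      f <- which(fkeys[, 1] == k | fkeys[, 2] == k | fkeys[, 3] == k)[1]
      ed <- V[j, ] - V[i, ]
      len2 <- sum(ed * ed)
      nc <- c(ed[2] * fa$normals[f, 3] - ed[3] * fa$normals[f, 2],
              ed[3] * fa$normals[f, 1] - ed[1] * fa$normals[f, 3],
              ed[1] * fa$normals[f, 2] - ed[2] * fa$normals[f, 1])
      nl <- sqrt(sum(nc * nc))
      if (nl < .Machine$double.eps) next
      nc <- nc / nl
      d <- -sum(nc * V[i, ])
      Kb <- plane_quadric(nc, d, boundary_weight * len2)
      Q[[i]] <- Q[[i]] + Kb
      Q[[j]] <- Q[[j]] + Kb
    }
  }
  Q
}

quadric_error <- function(Q, p) {
  ph <- c(p, 1)
  as.numeric(ph %*% Q %*% ph)
}

# optimal collapse position + cost for edge (i, j) under merged quadric;
# boundary vertices may not leave the boundary
collapse_candidate <- function(Q, V, i, j, bvert) {
  Qe <- Q[[i]] + Q[[j]]
  bi <- bvert[i]; bj <- bvert[j]
  if (bi && bj) {
    cands <- rbind(V[i, ], V[j, ])
  } else if (bi) {
    cands <- rbind(V[i, ])
  } else if (bj) {
    cands <- rbind(V[j, ])
  } else {
    A <- Qe[1:3, 1:3]
    b <- Qe[1:3, 4]
    cands <- NULL
    ok <- FALSE
    if (rcond(A) > 1e-10) {
      p <- tryCatch(solve(A, -b), error = function(e) NULL)
      if (!is.null(p) && all(is.finite(p))) {
        cands <- rbind(p)
        ok <- TRUE
      }
    }
    if (!ok) cands <- rbind(V[i, ], V[j, ], (V[i, ] + V[j, ]) / 2)
  }
  errs <- apply(cands, 1, function(p) quadric_error(Qe, p))
  k <- which.min(errs)
  list(pos = cands[k, ], cost = errs[k])
}

#' Simplify a mesh by quadric-error edge collapse
#'
#' Garland-Heckbert simplification: every vertex carries the sum of squared
#' distances to its incident face planes (plus boundary constraint planes);
#' edges are collapsed in order of increasing quadric error at the optimal
#' merged position. Collapses that would break edge-manifoldness (link
#' condition) or fold a face over are skipped. Ties in collapse cost are
#' broken by the lowest edge index, so the result is deterministic.
#'
#' @param mesh a `TriangleMesh`.
#' @param target_vertex_count desired vertex count, `4 <= target < m`.
#' @param boundary_weight weight of the boundary constraint planes.
#' @return list with `mesh` (the simplified `TriangleMesh`), `orig_index`
#'   (for each simplified vertex, the index of the nearest original vertex)
#'   and `achieved` (vertex count reached; less than requested only when no
#'   legal collapse remained, which is reported with a warning).
#' @export
simplify_qem <- function(mesh, target_vertex_count, boundary_weight = 1e3) {
  V0 <- mesh$vertices
  m <- nrow(V0)
  target_vertex_count <- as.integer(target_vertex_count)
  if (target_vertex_count < 4L || target_vertex_count > m)
    stop("target_vertex_count must be in [4, m]")
  if (target_vertex_count == m) {
    return(list(mesh = mesh, orig_index = seq_len(m), achieved = m))
  }
  V <- V0
  F <- mesh$faces
  nf <- nrow(F)
  Q <- vertex_quadrics(V, F, boundary_weight)
  be <- boundary_edges(F)
  bvert <- rep(FALSE, m)
  if (nrow(be) > 0) bvert[unique(as.vector(be))] <- TRUE

  # edge table ordered by (min, max) for deterministic tie-breaking
  E <- mesh_edges(F)
  E <- E[order(E[, 1], E[, 2]), , drop = FALSE]
  ne <- nrow(E)
  cost <- numeric(ne)
  pos <- matrix(0, ne, 3)
  for (e in seq_len(ne)) {
    cc <- collapse_candidate(Q, V, E[e, 1], E[e, 2], bvert)
    cost[e] <- cc$cost
    pos[e, ] <- cc$pos
  }
  ekey <- function(a, b) pmin(a, b) * (m + 1) + pmax(a, b)
  bkey <- if (nrow(be) > 0) ekey(be[, 1], be[, 2]) else numeric(0)
  is_boundary_edge <- ekey(E[, 1], E[, 2]) %in% bkey

  valive <- rep(TRUE, m)
  falive <- rep(TRUE, nf)
  ealive <- rep(TRUE, ne)
  # vertex -> incident face ids
  vf <- vector("list", m)
  for (c3 in 1:3) {
    sp <- split(seq_len(nf), F[, c3])
    for (nm in names(sp))
      vf[[as.integer(nm)]] <- c(vf[[as.integer(nm)]], sp[[nm]])
  }
  # vertex -> incident edge ids
  ve <- vector("list", m)
  for (c2 in 1:2) {
    sp <- split(seq_len(ne), E[, c2])
    for (nm in names(sp))
      ve[[as.integer(nm)]] <- c(ve[[as.integer(nm)]], sp[[nm]])
  }

  n_alive <- m
  while (n_alive > target_vertex_count) {
    live <- which(ealive)
    if (length(live) == 0 || all(!is.finite(cost[live]))) {
      warning("no legal collapse remains; achieved ", n_alive,
              " vertices instead of ", target_vertex_count)
      break
    }
    k <- live[which.min(cost[live])]
    if (!is.finite(cost[k])) {
      warning("no legal collapse remains; achieved ", n_alive,
              " vertices instead of ", target_vertex_count)
      break
    }
    i <- E[k, 1]; j <- E[k, 2]
    if (!valive[i] || !valive[j] || i == j) { ealive[k] <- FALSE; next }

    # mixed-boundary rule: an interior edge joining two boundary vertices
    # would pinch the rim; skip it
    if (bvert[i] && bvert[j] && !is_boundary_edge[k]) {
      cost[k] <- Inf; next
    }
    # link condition: common neighbours must be exactly the opposite
    # vertices of the faces shared by (i, j)
    fi <- vf[[i]][falive[vf[[i]]]]
    fj <- vf[[j]][falive[vf[[j]]]]
    shared_faces <- intersect(fi, fj)
    nbr <- function(fs, v) setdiff(unique(as.vector(F[fs, , drop = FALSE])), v)
    common <- intersect(nbr(fi, i), nbr(fj, j))
    opposite <- setdiff(unique(as.vector(F[shared_faces, , drop = FALSE])),
                        c(i, j))
    if (length(shared_faces) == 0 ||
        !setequal(common, opposite)) {
      cost[k] <- Inf; next
    }

    p_new <- pos[k, ]
    # reject collapses that flip a surviving face
    surv <- setdiff(union(fi, fj), shared_faces)
    flip <- FALSE
    for (f in surv) {
      tri <- F[f, ]
      a <- V[tri[1], ]; b <- V[tri[2], ]; cc <- V[tri[3], ]
      n_old <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
                 (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
                 (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
      tri2 <- tri
      tri2[tri2 == j] <- i
      Vt <- V
      Vt[i, ] <- p_new
      a <- Vt[tri2[1], ]; b <- Vt[tri2[2], ]; cc <- Vt[tri2[3], ]
      n_new <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
                 (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
                 (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
      if (sum(n_old * n_new) <= 0) { flip <- TRUE; break }
    }
    if (flip) { cost[k] <- Inf; next }

    # ---- perform the collapse: j merges into i at p_new ----
    V[i, ] <- p_new
    Q[[i]] <- Q[[i]] + Q[[j]]
    bvert[i] <- bvert[i] || bvert[j]
    valive[j] <- FALSE
    falive[shared_faces] <- FALSE
    relabel <- setdiff(fj, shared_faces)
    for (f in relabel) F[f, ][F[f, ] == j] <- i
    vf[[i]] <- unique(c(fi, relabel))
    vf[[i]] <- vf[[i]][falive[vf[[i]]]]
    vf[[j]] <- integer(0)

    # remap edges ending at j; drop self-loops and duplicates
    ej <- ve[[j]][ealive[ve[[j]]]]
    seen_keys <- ekey(E[ve[[i]][ealive[ve[[i]]]], 1],
                      E[ve[[i]][ealive[ve[[i]]]], 2])
    for (e in ej) {
      E[e, ][E[e, ] == j] <- i
      if (E[e, 1] == E[e, 2]) { ealive[e] <- FALSE; next }
      a <- min(E[e, ]); b <- max(E[e, ])
      E[e, ] <- c(a, b)
      kk <- ekey(a, b)
      if (kk %in% seen_keys) {
        ealive[e] <- FALSE
      } else {
        seen_keys <- c(seen_keys, kk)
        ve[[i]] <- c(ve[[i]], e)
        is_boundary_edge[e] <- is_boundary_edge[e] || (kk %in% bkey)
      }
    }
    ve[[i]] <- unique(ve[[i]][ealive[ve[[i]]]])
    ve[[j]] <- integer(0)

    # recompute costs of all edges incident to the merged vertex
    for (e in ve[[i]]) {
      cc <- collapse_candidate(Q, V, E[e, 1], E[e, 2], bvert)
      cost[e] <- cc$cost
      pos[e, ] <- cc$pos
    }
    ealive[k] <- FALSE
    n_alive <- n_alive - 1L
  }

  keep <- which(valive)
  new_id <- integer(m)
  new_id[keep] <- seq_along(keep)
  Fs <- F[falive, , drop = FALSE]
  Fs <- matrix(new_id[Fs], ncol = 3)
  storage.mode(Fs) <- "integer"
  Vs <- V[keep, , drop = FALSE]
  simp <- triangle_mesh(Vs, Fs, validate = FALSE)

  # nearest original vertex for each surviving vertex
  orig_index <- integer(nrow(Vs))
  for (r in seq_len(nrow(Vs))) {
    d2 <- (V0[, 1] - Vs[r, 1])^2 + (V0[, 2] - Vs[r, 2])^2 +
      (V0[, 3] - Vs[r, 3])^2
    orig_index[r] <- which.min(d2)
  }
  list(mesh = simp, orig_index = orig_index, achieved = length(keep))
}

#' Extract anatomical feature points
#'
#' Runs [simplify_qem()] down to `n_features` vertices and maps each
#' surviving vertex back to the nearest original vertex, so the feature set
#' lies exactly on the input surface (which the RBF interpolation stage
#' assumes). Duplicate mappings are resolved to the next-nearest unused
#' vertex, keeping the set pairwise distinct.
#'
#' @param mesh a `TriangleMesh`.
#' @param n_features desired number of feature points (>= 4).
#' @param region optional region label (`"occlusal"` or `"axial"`): when
#'   given, simplification runs on the submesh of faces whose corners all
#'   carry that label, and feature indices refer to the full mesh. The cut
#'   border of such a submesh is an artefact of the mask, not anatomy, so
#'   boundary constraint planes are disabled for region-restricted
#'   extraction (the full-mesh default protects a real open scan border).
#' @return an object of class `FeaturePointSet` with `source_indices`,
#'   `positions` and `count`.
#' @export
extract_feature_points <- function(mesh, n_features = 150L, region = NULL) {
  n_features <- as.integer(n_features)
  if (n_features < 4L) stop("n_features must be at least 4")
  sub_map <- NULL
  target <- mesh
  if (!is.null(region)) {
    lab <- if (region == "occlusal") 1L else 0L
    vset <- which(mesh$region == lab)
    Fs <- faces_in_vertex_set(mesh$faces, vset)
    used <- sort(unique(as.vector(Fs)))
    new_id <- integer(nrow(mesh$vertices))
    new_id[used] <- seq_along(used)
    target <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                            matrix(new_id[Fs], ncol = 3), validate = FALSE)
    sub_map <- used
  }
  bw <- if (is.null(region)) 1e3 else 0
  res <- simplify_qem(target, min(n_features, nrow(target$vertices)),
                      boundary_weight = bw)
  idx <- res$orig_index
  if (!is.null(sub_map)) idx <- sub_map[idx]

  # resolve duplicates to the next-nearest unused original vertex
  if (anyDuplicated(idx)) {
    V0 <- mesh$vertices
    taken <- rep(FALSE, nrow(V0))
    taken[idx[!duplicated(idx)]] <- TRUE
    for (r in which(duplicated(idx))) {
      p <- res$mesh$vertices[r, ]
      d2 <- (V0[, 1] - p[1])^2 + (V0[, 2] - p[2])^2 + (V0[, 3] - p[3])^2
      d2[taken] <- Inf
      idx[r] <- which.min(d2)
      taken[idx[r]] <- TRUE
    }
  }
  idx <- sort(idx)
  structure(list(source_indices = idx,
                 positions = mesh$vertices[idx, , drop = FALSE],
                 count = length(idx)),
            class = "FeaturePointSet")
}

#' @export
print.FeaturePointSet <- function(x, ...) {
  cat("FeaturePointSet:", x$count, "feature points\n")
  invisible(x)
}

#' Write feature points to CSV (index, x, y, z)
#'
#' @param features a `FeaturePointSet`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_points <- function(features, path) {
  write.csv(data.frame(index = features$source_indices,
                       x = features$positions[, 1],
                       y = features$positions[, 2],
                       z = features$positions[, 3]),
            path, row.names = FALSE)
  invisible(path)
}
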
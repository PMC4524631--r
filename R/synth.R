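# Synthetic cusp-and-fossa tooth generator. A parametric height field over a
# disk (sum of Gaussian cusp bumps on a shallow dome, minus a central fossa)
# is triangulated with concentric rings and extruded downward into a vertical
# axial skirt. Wear is a known smooth depth field applied along the analytic
# surface normal, so every downstream stage can be checked against ground
# truth. All randomness (vertex jitter) is driven by the seed in the spec;
# the same spec always reproduces the identical mesh.

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parameters of a synthetic tooth crown
#'
#' @param n_cusps number of Gaussian cusp bumps (0 gives a smooth dome).
#' @param cusp_height cusp bump amplitude (mm).
#' @param base_radius radius of the occlusal cap (mm).
#' @param skirt_depth height of the vertical axial skirt below the cap
#'   margin (mm).
#' @param resolution approximate total vertex count of the generated mesh.
#' @param seed integer seed driving the (small) vertex jitter.
#' @param fossa_depth depth of the central fossa (mm).
#' @param dome_height height of the underlying occlusal dome (mm).
#' @param cusp_radius radial position of the cusp apices as a fraction of
#'   `base_radius`.
#' @param cusp_sigma Gaussian width of each cusp (mm).
#' @param jitter in-plane vertex jitter as a fraction of the local vertex
#'   spacing (breaks the exact rotational symmetry of the sampling, as a
#'   scanner would).
#' @return a list of class `SyntheticToothSpec`.
#' @export
tooth_spec <- function(n_cusps = 5L, cusp_height = 1.2, base_radius = 5,
                       skirt_depth = 3, resolution = 2000L, seed = 1L,
                       fossa_depth = 0.7, dome_height = 0.6,
                       cusp_radius = 0.55, cusp_sigma = 1.1,
                       jitter = 0.15, lobes = c(0.12, 0.06)) {
  stopifnot(n_cusps >= 0, base_radius > 0, skirt_depth > 0)
  if (resolution < 50) stop("resolution must be at least 50")
  structure(list(n_cusps = as.integer(n_cusps), cusp_height = cusp_height,
                 base_radius = base_radius, skirt_depth = skirt_depth,
                 resolution = as.integer(resolution), seed = as.integer(seed),
                 fossa_depth = fossa_depth, dome_height = dome_height,
                 cusp_radius = cusp_radius, cusp_sigma = cusp_sigma,
                 jitter = jitter, lobes = lobes),
            class = "SyntheticToothSpec")
}

# lobed crown cross-section: radius scale factor s(theta) >= 0.8. Molar
# crowns are square-ish rather than circular; the lobes also break the
# rotational symmetry of the axial wall, without which a rotation about the
# tooth axis would be unobservable to surface registration.
crown_profile <- function(spec, theta) {
  a <- spec$lobes
  if (is.null(a)) a <- c(0.12, 0.06)
  1 + a[1] * cos(2 * theta) + a[2] * cos(3 * theta + 0.8)
}

# radius normalised by the local (lobed) crown radius, in units of
# base_radius: equals base_radius exactly on the crown margin
norm_radius <- function(spec, x, y) {
  sqrt(x^2 + y^2) / crown_profile(spec, atan2(y, x))
}

# analytic cusp apex (x, y) centres for a spec
cusp_centers <- function(spec) {
  if (spec$n_cusps == 0L) return(matrix(numeric(0), 0, 2))
  ang <- 2 * pi * (seq_len(spec$n_cusps) - 1) / spec$n_cusps + pi / 7
  r <- spec$cusp_radius * spec$base_radius
  cbind(r * cos(ang), r * sin(ang))
}

# occlusal height field z(x, y) and its gradient
tooth_height_field <- function(spec) {
  ctr <- cusp_centers(spec)
  R <- spec$base_radius
  sig2 <- spec$cusp_sigma^2
  fsig2 <- (0.35 * R)^2
  # the fossa is the central pit between cusps; a cuspless crown is a
  # smooth dome without one
  fdepth <- if (spec$n_cusps > 0) spec$fossa_depth else 0
  a <- spec$lobes
  if (is.null(a)) a <- c(0.12, 0.06)
  function(x, y, gradient = FALSE) {
    # dome and fossa decay with the lobe-normalised radius, so the cap
    # falls off monotonically toward the whole crown margin
    r <- sqrt(x^2 + y^2)
    th <- atan2(y, x)
    s <- 1 + a[1] * cos(2 * th) + a[2] * cos(3 * th + 0.8)
    sp <- -2 * a[1] * sin(2 * th) - 3 * a[2] * sin(3 * th + 0.8)
    rn <- r / s
    z <- spec$dome_height * (1 - rn^2 / R^2) -
      fdepth * exp(-rn^2 / (2 * fsig2))
    # dH/drn, then chain rule through rn(x, y)
    Hp <- spec$dome_height * (-2 * rn / R^2) +
      fdepth * (rn / fsig2) * exp(-rn^2 / (2 * fsig2))
    safe_r <- pmax(r, 1e-12)
    rn_x <- x / (safe_r * s) + (y * sp) / (safe_r * s^2)
    rn_y <- y / (safe_r * s) - (x * sp) / (safe_r * s^2)
    rn_x[r < 1e-12] <- 0
    rn_y[r < 1e-12] <- 0
    gx <- Hp * rn_x
    gy <- Hp * rn_y
    if (nrow(ctr) > 0) {
      for (k in seq_len(nrow(ctr))) {
        d2 <- (x - ctr[k, 1])^2 + (y - ctr[k, 2])^2
        g <- spec$cusp_height * exp(-d2 / (2 * sig2))
        z <- z + g
        gx <- gx - g * (x - ctr[k, 1]) / sig2
        gy <- gy - g * (y - ctr[k, 2]) / sig2
      }
    }
    if (gradient) list(z = z, gx = gx, gy = gy) else z
  }
}

# stitch two concentric sorted-angle rings of vertex indices into a triangle
# strip (zip by advancing whichever ring's next angle is smaller); returns
# faces oriented counter-clockwise seen from +z when outer follows inner
stitch_rings <- function(inner_idx, inner_ang, outer_idx, outer_ang) {
  ni <- length(inner_idx)
  no <- length(outer_idx)
  faces <- matrix(0L, ni + no, 3)
  i <- 1L; o <- 1L; f <- 0L
  nexta <- function(a, k, n) if (k < n) a[k + 1L] else a[1L] + 2 * pi
  while (i <= ni || o <= no) {
    adv_inner <- if (i > ni) FALSE
      else if (o > no) TRUE
      else nexta(inner_ang, i, ni) <= nexta(outer_ang, o, no)
    f <- f + 1L
    if (adv_inner) {
      i2 <- if (i < ni) i + 1L else 1L
      faces[f, ] <- c(inner_idx[i], outer_idx[if (o <= no) o else 1L],
                      inner_idx[i2])
      i <- i + 1L
    } else {
      o2 <- if (o < no) o + 1L else 1L
      faces[f, ] <- c(outer_idx[o], outer_idx[o2],
                      inner_idx[if (i <= ni) i else 1L])
      o <- o + 1L
    }
  }
  faces[seq_len(f), , drop = FALSE]
}

#' Generate a synthetic tooth mesh
#'
#' Builds the intact crown described by a [tooth_spec()]: an occlusal cap
#' (Gaussian cusps on a dome with a central fossa) over concentric vertex
#' rings, and a vertical axial skirt. The region mask is set (cap interior =
#' occlusal, cap margin and skirt = axial) and the analytic cusp apex
#' positions are attached as `attr(mesh, "cusp_apices")`.
#'
#' @param spec a `SyntheticToothSpec`.
#' @return a validated `TriangleMesh` with attributes `cusp_apices` (matrix
#'   of apex positions) and `tooth_spec`.
#' @export
generate_tooth <- function(spec = tooth_spec()) {
  if (spec$resolution < 50) stop("resolution must be at least 50")
  R <- spec$base_radius
  # choose ring count so cap + skirt vertex total approximates resolution;
  # cap has 1 + 3K(K+1) vertices, skirt adds n_rows * 6K
  n_rows <- 4L
  K <- max(4L, round((-(3 + 6 * n_rows) +
                        sqrt((3 + 6 * n_rows)^2 + 12 * (spec$resolution - 1))) / 6))
  hf <- tooth_height_field(spec)

  with_seed(spec$seed, {
    xs <- list(0); ys <- list(0)
    ring_of <- list(1L)
    idx0 <- 1L
    ring_ang <- list(numeric(0))
    ring_idx <- list(idx0)
    for (k in seq_len(K)) {
      nk <- 6L * k
      ang <- 2 * pi * (seq_len(nk) - 1) / nk
      rr <- rep(R * k / K, nk)
      if (k < K && spec$jitter > 0) {
        ang <- ang + rnorm(nk, 0, spec$jitter * 2 * pi / nk / 2)
        rr <- rr + rnorm(nk, 0, spec$jitter * R / K / 2)
      } else if (spec$jitter > 0) {
        # boundary ring: angular jitter only, stays on the rim circle
        ang <- ang + rnorm(nk, 0, spec$jitter * 2 * pi / nk / 2)
      }
      ord <- order(ang)
      ang <- ang[ord]; rr <- rr[ord]
      sc <- crown_profile(spec, ang)
      xs[[k + 1L]] <- rr * sc * cos(ang)
      ys[[k + 1L]] <- rr * sc * sin(ang)
      ring_idx[[k + 1L]] <- idx0 + seq_len(nk)
      ring_ang[[k + 1L]] <- ang
      idx0 <- idx0 + nk
    }
    x <- unlist(xs); y <- unlist(ys)
    z <- hf(x, y)
    n_cap <- length(x)

    # faces: centre fan to ring 1, then ring-to-ring strips
    faces <- list()
    r1 <- ring_idx[[2]]
    n1 <- length(r1)
    faces[[1]] <- cbind(1L, r1, r1[c(2:n1, 1L)])
    for (k in seq_len(K - 1L)) {
      faces[[k + 1L]] <- stitch_rings(ring_idx[[k + 1L]], ring_ang[[k + 1L]],
                                      ring_idx[[k + 2L]], ring_ang[[k + 2L]])
    }

    # axial skirt: extrude the rim straight down in n_rows quad strips
    rim_idx <- ring_idx[[K + 1L]]
    rim_ang <- ring_ang[[K + 1L]]
    nrim <- length(rim_idx)
    rim_z <- z[rim_idx]
    V <- cbind(x, y, z)
    prev_idx <- rim_idx
    rim_sc <- crown_profile(spec, rim_ang)
    for (s in seq_len(n_rows)) {
      new_idx <- nrow(V) + seq_len(nrim)
      V <- rbind(V, cbind(R * rim_sc * cos(rim_ang),
                          R * rim_sc * sin(rim_ang),
                          rim_z - s * spec$skirt_depth / n_rows))
      nxt <- c(2:nrim, 1L)
      # outward-facing wall quads split into two triangles
      faces[[length(faces) + 1L]] <-
        rbind(cbind(prev_idx, new_idx, new_idx[nxt]),
              cbind(prev_idx, new_idx[nxt], prev_idx[nxt]))
      prev_idx <- new_idx
    }
    F <- do.call(rbind, faces)
    storage.mode(F) <- "integer"

    region <- integer(nrow(V))           # 0 = axial
    region[seq_len(n_cap)] <- 1L         # cap = occlusal
    region[rim_idx] <- 0L                # rim circle belongs to the wall

    apices_xy <- cusp_centers(spec)
    apices <- cbind(apices_xy, hf(apices_xy[, 1], apices_xy[, 2]))
    mesh <- triangle_mesh(V, F, region = region)
    attr(mesh, "cusp_apices") <- apices
    attr(mesh, "tooth_spec") <- spec
    mesh
  })
}

#' Parameters of a synthetic wear field
#'
#' @param max_depth maximum wear depth (mm).
#' @param pattern `"per-cusp"` (Gaussian wear facets centred on the cusp
#'   apices) or `"uniform-occlusal"` (constant depth on every occlusal
#'   vertex).
#' @param sigma Gaussian width of the per-cusp facets (mm).
#' @param seed integer seed for the retessellation of the worn surface.
#' @return a list of class `WearFieldSpec`.
#' @export
wear_field_spec <- function(max_depth = 0.5,
                            pattern = c("per-cusp", "uniform-occlusal"),
                            sigma = 1.4, seed = 2L) {
  pattern <- match.arg(pattern)
  stopifnot(max_depth >= 0)
  structure(list(max_depth = max_depth, pattern = pattern, sigma = sigma,
                 seed = as.integer(seed)),
            class = "WearFieldSpec")
}

# smooth taper to zero over the outer fraction of the cap radius
rim_taper <- function(r, R, frac = 0.15) {
  s <- pmin(pmax((R - r) / (frac * R), 0), 1)
  s * s * (3 - 2 * s)
}

# analytic wear depth d(x, y) for a tooth spec + wear spec
wear_depth_field <- function(tspec, wspec) {
  ctr <- cusp_centers(tspec)
  R <- tspec$base_radius
  function(x, y) {
    rn <- norm_radius(tspec, x, y)  # = R on the lobed crown margin
    if (wspec$pattern == "uniform-occlusal") {
      d <- rep(wspec$max_depth, length(x))
    } else {
      d <- 0
      if (nrow(ctr) > 0) {
        for (k in seq_len(nrow(ctr)))
          d <- d + exp(-((x - ctr[k, 1])^2 + (y - ctr[k, 2])^2) /
                         (2 * wspec$sigma^2))
        d <- wspec$max_depth * d / max(d[rn <= R])
      } else {
        d <- wspec$max_depth * exp(-rn^2 / (2 * (0.5 * R)^2))
      }
      d <- d * rim_taper(rn, R)
    }
    d
  }
}

# analytic outward unit normal of the intact height field at (x, y)
height_field_normal <- function(tspec, x, y) {
  g <- tooth_height_field(tspec)(x, y, gradient = TRUE)
  n <- cbind(-g$gx, -g$gy, 1)
  n / sqrt(rowSums(n * n))
}

#' Apply a synthetic wear field to a tooth
#'
#' Occlusal vertices are displaced inward (material loss) by the analytic
#' depth field of the wear spec, along the intact surface's analytic normal;
#' axial vertices never move. With `retessellate = TRUE` the worn surface is
#' re-sampled on an independent vertex layout (different resolution and
#' jitter stream), mimicking a second, unregistered scan with no vertex
#' correspondence to the input. The ground-truth depth is always returned on
#' the ORIGINAL tessellation.
#'
#' @param mesh an intact tooth from [generate_tooth()] (the tooth spec
#'   attribute is required for retessellation and for uniform wear it is
#'   optional).
#' @param wear a `WearFieldSpec`.
#' @param retessellate logical; re-sample the worn surface independently.
#' @return list with `worn` (a `TriangleMesh`) and `truth` (per-vertex depth
#'   on the input tessellation, mm).
#' @export
apply_wear <- function(mesh, wear = wear_field_spec(), retessellate = FALSE) {
  if (is.null(mesh$region)) stop("mesh needs a region mask to apply wear")
  tspec <- attr(mesh, "tooth_spec")
  if (is.null(tspec))
    stop("apply_wear needs the generating tooth_spec attribute")
  if (wear$max_depth >= tspec$cusp_height && tspec$n_cusps > 0)
    warning("max_depth >= cusp_height: cusps will be obliterated")
  dfun <- wear_depth_field(tspec, wear)
  occ <- occlusal_vertices(mesh)
  depth <- numeric(nrow(mesh$vertices))
  depth[occ] <- dfun(mesh$vertices[occ, 1], mesh$vertices[occ, 2])

  displace <- function(m) {
    oc <- occlusal_vertices(m)
    d <- dfun(m$vertices[oc, 1], m$vertices[oc, 2])
    n <- height_field_normal(tspec, m$vertices[oc, 1], m$vertices[oc, 2])
    m$vertices[oc, ] <- m$vertices[oc, ] - d * n
    m
  }

  if (!retessellate) {
    worn <- displace(mesh)
    worn$scalars$wear_depth <- depth
    validate_mesh(worn)
    return(list(worn = worn, truth = depth))
  }
  # independent sampling of the same continuous worn surface
  tspec2 <- tspec
  tspec2$resolution <- as.integer(round(tspec$resolution * 1.45))
  tspec2$seed <- tspec$seed + 1000L + wear$seed
  base2 <- generate_tooth(tspec2)
  worn <- displace(base2)
  attr(worn, "tooth_spec") <- NULL
  attr(worn, "cusp_apices") <- NULL
  validate_mesh(worn)
  list(worn = worn, truth = depth)
}
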
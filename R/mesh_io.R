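# Mesh file input/output. PLY (ASCII and binary little-endian) with
# per-vertex attributes, plus OBJ and ASCII STL. Written against the format
# descriptions; vertex order is always preserved.

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_bin <- function(con, type, n) {
  switch(type,
    char = , int8 = readBin(con, integer(), n, size = 1L, signed = TRUE,
                            endian = "little"),
    uchar = , uint8 = readBin(con, integer(), n, size = 1L, signed = FALSE,
                              endian = "little"),
    short = , int16 = readBin(con, integer(), n, size = 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(con, integer(), n, size = 2L, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(con, integer(), n, size = 4L, endian = "little"),
    float = , float32 = readBin(con, double(), n, size = 4L, endian = "little"),
    double = , float64 = readBin(con, double(), n, size = 8L,
                                 endian = "little"),
    stop("unsupported PLY property type: ", type))
}

parse_ply_header <- function(lines) {
  stopifnot(trimws(lines[1]) == "ply")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                    type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      break
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(fmt)) stop("PLY header has no format line")
  list(format = fmt, elements = elements)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header_lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0) stop("unexpected end of file in PLY header")
    header_lines <- c(header_lines, ln)
    if (trimws(ln) == "end_header") break
  }
  hd <- parse_ply_header(header_lines)
  if (is.null(hd$elements$vertex) || is.null(hd$elements$face))
    stop("PLY file must contain vertex and face elements")
  binary <- hd$format == "binary_little_endian"
  if (!binary && hd$format != "ascii")
    stop("unsupported PLY format: ", hd$format)

  if (binary) {
    elem_data <- list()
    for (el in hd$elements) {
      props <- el$props
      has_list <- any(vapply(props, function(p) p$list, logical(1)))
      if (!has_list) {
        sizes <- vapply(props, function(p) ply_type_size[[p$type]], integer(1))
        rec <- sum(sizes)
        raw <- readBin(con, "raw", n = rec * el$count)
        offs <- cumsum(c(0L, sizes))
        vals <- vector("list", length(props))
        names(vals) <- names(props)
        for (k in seq_along(props)) {
          idx <- as.vector(outer(seq_len(sizes[k]) + offs[k],
                                 (seq_len(el$count) - 1L) * rec, `+`))
          rc <- rawConnection(raw[idx])
          vals[[k]] <- ply_read_bin(rc, props[[k]]$type, el$count)
          close(rc)
        }
        elem_data[[el$name]] <- vals
      } else {
        # list properties read record by record (face element)
        if (length(props) != 1L)
          stop("PLY element '", el$name,
               "' mixes list and scalar properties; unsupported")
        p <- props[[1]]
        rows <- vector("list", el$count)
        for (r in seq_len(el$count)) {
          cnt <- ply_read_bin(con, p$count_type, 1L)
          rows[[r]] <- ply_read_bin(con, p$type, cnt)
        }
        elem_data[[el$name]] <- setNames(list(rows), names(props))
      }
    }
  } else {
    txt <- readLines(con)
    tok <- scan(text = paste(txt, collapse = "\n"), what = character(),
                quiet = TRUE)
    pos <- 1L
    elem_data <- list()
    for (el in hd$elements) {
      props <- el$props
      has_list <- any(vapply(props, function(p) p$list, logical(1)))
      if (!has_list) {
        np <- length(props)
        block <- matrix(as.numeric(tok[pos:(pos + np * el$count - 1L)]),
                        ncol = np, byrow = TRUE)
        pos <- pos + np * el$count
        vals <- lapply(seq_len(np), function(k) block[, k])
        names(vals) <- names(props)
        elem_data[[el$name]] <- vals
      } else {
        rows <- vector("list", el$count)
        for (r in seq_len(el$count)) {
          cnt <- as.integer(tok[pos])
          rows[[r]] <- as.numeric(tok[pos + seq_len(cnt)])
          pos <- pos + 1L + cnt
        }
        elem_data[[el$name]] <- setNames(list(rows), names(props)[1])
      }
    }
  }

  vx <- elem_data$vertex
  if (!all(c("x", "y", "z") %in% names(vx)))
    stop("PLY vertex element lacks x/y/z properties")
  V <- cbind(vx$x, vx$y, vx$z)
  flist <- elem_data$face[[1]]
  if (any(lengths(flist) != 3L))
    stop("PLY faces must be triangles")
  F <- matrix(as.integer(unlist(flist)), ncol = 3, byrow = TRUE) + 1L
  region <- if ("region" %in% names(vx)) as.integer(vx$region) else NULL
  reserved <- c("x", "y", "z", "nx", "ny", "nz", "red", "green", "blue",
                "alpha", "region")
  scalars <- vx[setdiff(names(vx), reserved)]
  scalars <- lapply(scalars, as.numeric)
  list(V = V, F = F, region = region, scalars = scalars)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  vlines <- txt[startsWith(txt, "v ")]
  flines <- txt[startsWith(txt, "f ")]
  V <- matrix(scan(text = sub("^v\\s+", "", vlines), what = numeric(),
                   quiet = TRUE), ncol = 3, byrow = TRUE)
  faces <- lapply(strsplit(sub("^f\\s+", "", flines), "\\s+"), function(tk) {
    as.integer(vapply(strsplit(tk, "/"), `[[`, character(1), 1L))
  })
  tris <- do.call(rbind, lapply(faces, function(ix) {
    if (length(ix) < 3L) stop("OBJ face with fewer than 3 vertices")
    # fan-triangulate polygons
    cbind(ix[1], ix[2:(length(ix) - 1L)], ix[3:length(ix)])
  }))
  list(V = V, F = tris, region = NULL, scalars = list())
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  coords <- matrix(scan(text = sub("^\\s*vertex\\s+", "", vl),
                        what = numeric(), quiet = TRUE),
                   ncol = 3, byrow = TRUE)
  if (nrow(coords) %% 3L != 0L) stop("STL vertex count not a multiple of 3")
  # weld exactly coincident vertices to recover connectivity
  key <- apply(coords, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  ids <- match(key, key[uniq])
  V <- coords[uniq, , drop = FALSE]
  F <- matrix(ids, ncol = 3, byrow = TRUE)
  list(V = V, F = F, region = NULL, scalars = list())
}

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(tolower(format))
  switch(tolower(tools::file_ext(path)),
         ply = "ply", obj = "obj", stl = "stl",
         stop("cannot infer mesh format from extension of '", path, "'"))
}

#' Load a triangle mesh from PLY, OBJ or STL
#'
#' PLY files may carry a per-vertex integer property `region`
#' (0 = axial, 1 = occlusal) and arbitrary per-vertex scalar properties,
#' which are attached to the returned mesh. The mesh is validated on load:
#' non-manifold or inconsistently oriented input is an error.
#'
#' @param path file path.
#' @param format `"ply"`, `"obj"` or `"stl"`; inferred from the extension
#'   when omitted.
#' @return a validated `TriangleMesh`.
#' @export
load_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- infer_format(path, format)
  raw <- switch(format,
                ply = read_ply(path),
                obj = read_obj(path),
                stl = read_stl_ascii(path),
                stop("unsupported format: ", format))
  triangle_mesh(raw$V, raw$F, region = raw$region, scalars = raw$scalars)
}

#' Save a triangle mesh
#'
#' PLY output (ASCII) embeds the region mask as an integer property `region`,
#' any per-vertex scalars as double properties, and — when `scalar_name` is
#' given — an RGB vertex colour rendering that scalar through the
#' yellow-to-red wear colour map (zero maps to a neutral grey). OBJ and STL
#' carry geometry only; asking for a scalar there logs a warning and drops it.
#'
#' @param mesh a `TriangleMesh`.
#' @param path output file path.
#' @param scalar_name optional name of a per-vertex scalar to colour by.
#' @param format `"ply"`, `"obj"` or `"stl"`; inferred from the extension
#'   when omitted.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, scalar_name = NULL, format = NULL) {
  format <- infer_format(path, format)
  if (!is.null(scalar_name)) {
    if (!scalar_name %in% names(mesh$scalars))
      stop("mesh has no scalar named '", scalar_name, "'")
    if (format != "ply") {
      warning(toupper(format), " has no per-vertex attributes; scalar '",
              scalar_name, "' dropped")
      scalar_name <- NULL
    }
  }
  V <- mesh$vertices
  F <- mesh$faces
  if (format == "ply") {
    props <- c("property double x", "property double y", "property double z")
    cols <- NULL
    if (!is.null(mesh$region))
      props <- c(props, "property int region")
    for (nm in names(mesh$scalars))
      props <- c(props, paste0("property double ", nm))
    if (!is.null(scalar_name)) {
      props <- c(props, "property uchar red", "property uchar green",
                 "property uchar blue")
      cols <- wear_colors(mesh$scalars[[scalar_name]])
    }
    vtab <- format(V, digits = 17, scientific = FALSE, trim = TRUE)
    rows <- cbind(vtab)
    if (!is.null(mesh$region)) rows <- cbind(rows, mesh$region)
    for (nm in names(mesh$scalars))
      rows <- cbind(rows, format(mesh$scalars[[nm]], digits = 17,
                                 scientific = FALSE, trim = TRUE))
    if (!is.null(cols)) rows <- cbind(rows, cols)
    header <- c("ply", "format ascii 1.0",
                "comment produced by the toothwear package",
                paste("element vertex", nrow(V)), props,
                paste("element face", nrow(F)),
                "property list uchar int vertex_indices", "end_header")
    flines <- paste(3L, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
    writeLines(c(header, apply(rows, 1, paste, collapse = " "), flines), path)
  } else if (format == "obj") {
    writeLines(c(paste("v", V[, 1], V[, 2], V[, 3]),
                 paste("f", F[, 1], F[, 2], F[, 3])), path)
  } else {
    fn <- face_normals_areas(V, F)$normals
    out <- character(2L + 7L * nrow(F))
    out[1] <- "solid toothwear"
    k <- 2L
    for (f in seq_len(nrow(F))) {
      out[k] <- sprintf("  facet normal %g %g %g", fn[f, 1], fn[f, 2], fn[f, 3])
      out[k + 1L] <- "    outer loop"
      for (c3 in 1:3)
        out[k + 1L + c3] <- sprintf("      vertex %.17g %.17g %.17g",
                                    V[F[f, c3], 1], V[F[f, c3], 2],
                                    V[F[f, c3], 3])
      out[k + 5L] <- "    endloop"
      out[k + 6L] <- "  endfacet"
      k <- k + 7L
    }
    out[k] <- "endsolid toothwear"
    writeLines(out, path)
  }
  invisible(path)
}

#' Read a region mask from a sidecar CSV
#'
#' The CSV lists occlusal vertex indices (1-based, column `index`); all other
#' vertices are axial.
#'
#' @param path CSV path.
#' @param n_vertices vertex count of the mesh the mask belongs to.
#' @return integer vector, 0 = axial, 1 = occlusal.
#' @export
read_region_mask <- function(path, n_vertices) {
  tab <- read.csv(path)
  idx <- as.integer(tab[[if ("index" %in% names(tab)) "index" else 1L]])
  if (any(idx < 1L | idx > n_vertices))
    stop("region mask index out of range")
  mask <- integer(n_vertices)
  mask[idx] <- 1L
  mask
}

#' Write a region mask to a sidecar CSV of occlusal vertex indices
#'
#' @param mask integer vector, 0 = axial, 1 = occlusal.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_mask <- function(mask, path) {
  write.csv(data.frame(index = which(mask == 1L)), path, row.names = FALSE)
  invisible(path)
}
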
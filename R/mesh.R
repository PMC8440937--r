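#' Triangulated surface meshes
#'
#' A `surface_mesh` is a minimal triangle-mesh container: an `n x 3` numeric
#' matrix of vertex coordinates (mm) and an `m x 3` integer matrix of 1-based
#' vertex indices per triangular face.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must have 3 columns")
  if (ncol(faces) != 3L) stopf("faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stopf("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x[%.1f, %.1f] y[%.1f, %.1f] z[%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

## Connected components of the vertex adjacency graph.
mesh_components <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::components(g)
}

#' Build a tube mesh around an arbitrary centerline
#'
#' Sweeps a closed cross-section profile `rho(s, theta)` along a space curve
#' using a rotation-minimizing frame, producing a structured quad grid that is
#' triangulated consistently. Optionally closes both ends with triangle fans.
#'
#' @param centerline function mapping a vector of `s` in `[0,1]` to an
#'   `n x 3` matrix of points (mm).
#' @param radius function `(s, theta) -> rho` (mm), vectorized over both.
#' @param n_axial,n_circumferential grid resolution (both at least 16 for
#'   anatomical use; at least 3 accepted here for degenerate test cases).
#' @param cap close the ends with fans (default `TRUE`).
#' @param noise_sd radial Gaussian noise in mm added to the wall (default 0).
#' @return A `surface_mesh`; attributes `s_grid`, `frames` carry the sweep
#'   stations and frames used.
#' @export
tube_mesh <- function(centerline, radius, n_axial = 48, n_circumferential = 32,
                      cap = TRUE, noise_sd = 0) {
  if (n_axial < 3 || n_circumferential < 3) stopf("degenerate tube resolution")
  s <- seq(0, 1, length.out = n_axial)
  fr <- rmf_along(centerline, s)
  th <- seq(0, 2 * pi, length.out = n_circumferential + 1)[-(n_circumferential + 1)]
  sg <- rep(s, each = n_circumferential)
  tg <- rep(th, times = n_axial)
  rho <- radius(sg, tg)
  if (any(!is.finite(rho)) || any(rho <= 0)) stopf("radius must be positive and finite")
  if (noise_sd > 0) rho <- rho + stats::rnorm(length(rho), sd = noise_sd)
  ctr <- fr$origin[rep(seq_len(n_axial), each = n_circumferential), , drop = FALSE]
  v1 <- fr$v1[rep(seq_len(n_axial), each = n_circumferential), , drop = FALSE]
  v2 <- fr$v2[rep(seq_len(n_axial), each = n_circumferential), , drop = FALSE]
  verts <- ctr + rho * (cos(tg) * v1 + sin(tg) * v2)

  idx <- function(i, j) (i - 1L) * n_circumferential + ((j - 1L) %% n_circumferential) + 1L
  faces <- vector("list", n_axial - 1L)
  jj <- seq_len(n_circumferential)
  for (i in seq_len(n_axial - 1L)) {
    a <- idx(i, jj); b <- idx(i, jj + 1L); cc <- idx(i + 1L, jj); d <- idx(i + 1L, jj + 1L)
    ## alternate the quad diagonal (checkerboard) so the edge graph has no
    ## preferred helical direction
    even <- (i + jj) %% 2L == 0L
    faces[[i]] <- rbind(
      cbind(a[even], b[even], d[even]), cbind(a[even], d[even], cc[even]),
      cbind(a[!even], b[!even], cc[!even]), cbind(b[!even], d[!even], cc[!even]))
  }
  faces <- do.call(rbind, faces)
  if (cap) {
    c0 <- nrow(verts) + 1L
    c1 <- nrow(verts) + 2L
    verts <- rbind(verts, fr$origin[1, ], fr$origin[n_axial, ])
    f0 <- cbind(idx(1L, jj + 1L), idx(1L, jj), c0)
    f1 <- cbind(idx(n_axial, jj), idx(n_axial, jj + 1L), c1)
    faces <- rbind(faces, f0, f1)
  }
  m <- surface_mesh(verts, faces)
  attr(m, "s_grid") <- s
  attr(m, "frames") <- fr
  m
}

## --- plain-text mesh I/O (ASCII STL / PLY / OBJ) ------------------------

#' Read and write surface meshes
#'
#' Minimal readers and writers for the ASCII variants of the common surface
#' formats STL, PLY and OBJ (triangles only). The format is inferred from the
#' file extension.
#'
#' @param mesh a `surface_mesh`.
#' @param path file path ending in `.stl`, `.ply` or `.obj`.
#' @return `read_mesh` returns a `surface_mesh`; `write_mesh` returns `path`
#'   invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "stl") {
    writeLines("solid aorta", con)
    for (i in seq_len(nrow(f))) {
      p <- v[f[i, ], , drop = FALSE]
      n <- unit(pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ]))
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid aorta", con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else stopf("unsupported mesh format: .%s", ext)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    key <- apply(round(xyz, 9), 1, paste, collapse = ",")
    uid <- match(key, unique(key))
    verts <- xyz[!duplicated(key), , drop = FALSE]
    faces <- matrix(uid, ncol = 3, byrow = TRUE)
    surface_mesh(verts, faces)
  } else if (ext == "ply") {
    nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub(".*face\\s+", "", grep("element face", lines, value = TRUE)[1]))
    i0 <- which(lines == "end_header")
    verts <- do.call(rbind, lapply(strsplit(trimws(lines[i0 + seq_len(nv)]), "\\s+"),
                                   function(p) as.numeric(p[1:3])))
    faces <- do.call(rbind, lapply(strsplit(trimws(lines[i0 + nv + seq_len(nf)]), "\\s+"),
                                   function(p) as.integer(p[2:4]) + 1L))
    surface_mesh(verts, faces)
  } else if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
    faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
      as.integer(sub("/.*", "", p[2:4]))))
    surface_mesh(verts, faces)
  } else stopf("unsupported mesh format: .%s", ext)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

## Symmetric (two-sided) mean surface distance between two meshes:
## vertex-to-surface, where each vertex is measured against the exact
## triangles incident to its nearest vertex in the other mesh.
mesh_distance <- function(m1, m2) {
  (mean(surf_dist(m1$vertices, m2)) + mean(surf_dist(m2$vertices, m1))) / 2
}

surf_dist <- function(A, mesh) {
  B <- mesh$vertices
  nn <- nn_index(A, B)
  ## vertex -> incident faces map
  f <- mesh$faces
  vf <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    tris <- vf[[as.character(nn[i])]]
    if (is.null(tris)) { out[i] <- sqrt(sum((A[i, ] - B[nn[i], ])^2)); next }
    d <- vapply(tris, function(t) {
      point_triangle_dist(A[i, ], B[f[t, 1], ], B[f[t, 2], ], B[f[t, 3], ])
    }, numeric(1))
    out[i] <- min(d)
  }
  out
}

## Exact Euclidean distance from point p to triangle (a, b, c).
point_triangle_dist <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((ap - v * ab)^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((ap - w * ac)^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((bp - w * (c - b))^2)))
  }
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  sqrt(sum((ap - v * ab - w * ac)^2))
}

nn_index <- function(A, B) {
  nb <- nrow(B)
  out <- integer(nrow(A))
  bs <- max(1L, floor(2e6 / nb))
  b2 <- rowSums(B^2)
  for (i0 in seq(1L, nrow(A), by = bs)) {
    ii <- i0:min(nrow(A), i0 + bs - 1L)
    G <- A[ii, , drop = FALSE] %*% t(B)
    d2 <- outer(rowSums(A[ii, , drop = FALSE]^2), b2, "+") - 2 * G
    out[ii] <- max.col(-d2, ties.method = "first")
  }
  out
}

nn_dist <- function(A, B) {
  ## blockwise to bound memory
  nb <- nrow(B)
  out <- numeric(nrow(A))
  bs <- max(1L, floor(2e6 / nb))
  b2 <- rowSums(B^2)
  for (i0 in seq(1L, nrow(A), by = bs)) {
    ii <- i0:min(nrow(A), i0 + bs - 1L)
    G <- A[ii, , drop = FALSE] %*% t(B)
    d2 <- outer(rowSums(A[ii, , drop = FALSE]^2), b2, "+") - 2 * G
    out[ii] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}
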
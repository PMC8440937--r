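## End-to-end parameterization of a tubular surface mesh: centerline
## extraction, B-spline fit, polar projection of the wall, wall-model fit,
## and reconstruction of the surface from the model:
##   x(s, theta) = alpha(s) + rho(s, theta) (cos(theta) v1(s) + sin(theta) v2(s)).

#' Extract the centerline polyline of a tubular mesh
#'
#' Orders the mesh along the tube by geodesic (surface graph) distance from
#' the valve end, bins vertices into cross-section bands and takes band
#' centroids, then refines the band assignment by projecting every vertex
#' onto a provisional spline so that sections are perpendicular to the tube
#' axis. The valve end is taken as the vertex closest to the origin
#' (canonical orientation).
#'
#' @param mesh a single-component tube-like `surface_mesh`.
#' @param n_bands number of cross-section bands (default scales with mesh
#'   resolution).
#' @return An ordered `n x 3` matrix of centerline points, valve end first.
#' @export
extract_centerline <- function(mesh, n_bands = NULL) {
  comp <- mesh_components(mesh)
  if (comp$no > 1L)
    stopf("mesh has %d connected components; expected a single tube", comp$no)
  v <- mesh$vertices
  n_bands <- n_bands %||% max(24L, min(64L, floor(nrow(v) / 30)))
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  w <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  src <- which.min(rowSums(v^2))
  d1 <- as.numeric(igraph::distances(g, v = src, weights = w))
  if (any(!is.finite(d1))) stopf("mesh graph is not connected")
  ## two-ended geodesic fraction: normalizing by the path length through
  ## each vertex makes the bands perpendicular-ish to the tube even where
  ## the inner and outer sides of the arch have different path lengths
  far <- which.max(d1)
  d2 <- as.numeric(igraph::distances(g, v = far, weights = w))
  f <- d1 / (d1 + d2)
  bands <- pmin(pmax(1L, as.integer(ceiling(f * n_bands))), n_bands)
  bands[f <= 0] <- 1L
  cnt <- as.numeric(table(factor(bands, levels = sort(unique(bands)))))
  ctr <- rowsum(v, bands) / cnt
  poly <- ctr[order(rowsum(f, bands) / cnt), , drop = FALSE]
  ## refinement: project every vertex onto a provisional spline and, at
  ## regular stations, estimate the section center by an algebraic circle
  ## fit of the points near the station's normal plane. The fitted center
  ## is insensitive to uneven angular coverage, which defeats the biases
  ## that plain (weighted) centroids pick up from partial vertex rings.
  prev_resid <- Inf
  prev_poly <- poly
  for (it in 1:4) {
    cl <- fit_centerline(poly, n_ctrl = min(10L, nrow(poly) - 4L),
                         natural_ends = TRUE)
    if (cl$residual > prev_resid) { poly <- prev_poly; break }
    prev_resid <- cl$residual; prev_poly <- poly
    pr <- project_points(cl, v)
    stations <- seq(0.015, 0.985, length.out = n_bands)
    hw_mm <- 1.2 * (cl$length %||% 1) / n_bands
    fr <- frames_at(cl, stations)
    ctrs <- t(vapply(seq_along(stations), function(j) {
      near <- which(abs(pr$s - stations[j]) < 3 * hw_mm / (cl$length %||% 1))
      if (length(near) < 8L) return(fr$origin[j, ])
      rho <- pr$rho[near]
      med <- stats::median(rho)
      near <- near[rho > 0.5 * med & rho < 1.6 * med]
      d <- sweep(v[near, , drop = FALSE], 2, fr$origin[j, ])
      u <- drop(d %*% fr$t[j, ])
      sel <- abs(u) <= hw_mm
      if (sum(sel) < 8L) return(fr$origin[j, ])
      q1 <- drop(d[sel, , drop = FALSE] %*% fr$v1[j, ])
      q2 <- drop(d[sel, , drop = FALSE] %*% fr$v2[j, ])
      ## Kasa circle fit: linear least squares for the center
      A <- cbind(2 * q1, 2 * q2, 1)
      b <- q1^2 + q2^2
      ck <- tryCatch(qr.solve(A, b), error = function(e) c(mean(q1), mean(q2), 0))
      fr$origin[j, ] + ck[1] * fr$v1[j, ] + ck[2] * fr$v2[j, ]
    }, numeric(3)))
    ## end anchors: centroids of the extreme stations (cap planes)
    anchor0 <- colMeans(v[pr$s <= 0.005, , drop = FALSE])
    anchor1 <- colMeans(v[pr$s >= 0.995, , drop = FALSE])
    if (!anyNA(anchor0)) ctrs <- rbind(anchor0, ctrs)
    if (!anyNA(anchor1)) ctrs <- rbind(ctrs, anchor1)
    poly <- ctrs
    rownames(poly) <- NULL
  }
  poly
}

#' Parameterize a tubular mesh
#'
#' Runs the full pipeline: centerline extraction, cubic B-spline centerline
#' fit, polar projection of all wall vertices and wall-model fit. Vertices
#' projecting onto the extreme ends of the centerline (s outside
#' `[0.015, 0.985]`, e.g. end-cap fans) are excluded from the wall fit.
#'
#' @param mesh a tube-like `surface_mesh`.
#' @param n_ctrl centerline control points (default 10).
#' @param n_s wall s-basis size (default 24).
#' @param mode wall theta basis, `"periodic"` (default) or `"literal"`.
#' @return An `aorta_param`: list with `centerline` (`centerline_spline`),
#'   `wall` (`wall_model`) and `meta` (fit residuals, vertex counts).
#' @export
parameterize <- function(mesh, n_ctrl = 10L, n_s = 24L,
                         mode = c("periodic", "literal")) {
  mode <- match.arg(mode)
  poly <- extract_centerline(mesh)
  cl <- fit_centerline(poly, n_ctrl = n_ctrl, natural_ends = TRUE)
  pr <- project_points(cl, mesh$vertices)
  keep <- pr$s > 0.015 & pr$s < 0.985
  ## reject local radius outliers (stray end-cap vertices that project into
  ## the interior): compare each rho with the median of its s-neighborhood
  med <- stats::ave(pr$rho, findInterval(pr$s, seq(0, 1, by = 0.04)),
                    FUN = stats::median)
  keep <- keep & pr$rho > 0.6 * med & pr$rho < 1.7 * med
  wall <- fit_wall(pr[keep, ], n_s = n_s, mode = mode,
                   domain = c(0.015, 0.985))
  structure(list(centerline = cl, wall = wall,
                 meta = list(n_vertices = nrow(mesh$vertices),
                             n_wall_samples = sum(keep),
                             centerline_residual = cl$residual,
                             wall_residual = wall$residual)),
            class = "aorta_param")
}

#' @export
print.aorta_param <- function(x, ...) {
  cat("aorta_param\n")
  print(x$centerline)
  print(x$wall)
  invisible(x)
}

#' Reconstruct a surface mesh from a parameterization
#'
#' Evaluates `x(s, theta) = alpha(s) + rho(s, theta)(cos(theta) v1 +
#' sin(theta) v2)` on a regular grid and triangulates it.
#'
#' @param param an `aorta_param`.
#' @param n_s,n_theta grid resolution (each at least 8).
#' @return A closed `surface_mesh`.
#' @export
reconstruct <- function(param, n_s = 64L, n_theta = 32L) {
  if (n_s < 8L || n_theta < 8L) stopf("grid counts must be >= 8")
  sg <- seq(0, 1, length.out = n_s)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  rho <- matrix(wall_eval(param$wall, rep(sg, each = n_theta),
                          rep(th, times = n_s)), ncol = n_theta, byrow = TRUE)
  if (any(rho <= 0)) {
    bad <- which(rho <= 0, arr.ind = TRUE)[1, ]
    stopf("non-positive wall radius at (s = %.3f, theta = %.3f)",
          sg[bad[1]], th[bad[2]])
  }
  cl <- param$centerline
  tube_mesh(as_curve_fn(cl),
            function(s, theta) wall_eval(param$wall, s, theta),
            n_axial = n_s, n_circumferential = n_theta, cap = TRUE)
}

#' Flatten a parameterization to a raw coefficient vector
#'
#' Concatenates, in a fixed documented order, the centerline control-point
#' coordinates (column-major over x, y, z) and the wall coefficient matrix
#' (row-major over the theta basis). `unflatten()` inverts the operation
#' exactly given a template carrying the basis metadata.
#'
#' @param param an `aorta_param`.
#' @param raw numeric vector produced by `flatten()`.
#' @param template an `aorta_param` providing knots/basis metadata.
#' @return `flatten()`: a numeric vector; `unflatten()`: an `aorta_param`.
#' @export
flatten <- function(param) {
  c(as.vector(param$centerline$coef), as.vector(t(param$wall$coef)))
}

#' @rdname flatten
#' @export
unflatten <- function(raw, template) {
  ncl <- length(template$centerline$coef)
  nw <- length(template$wall$coef)
  if (length(raw) != ncl + nw)
    stopf("raw vector length %d does not match template (%d)",
          length(raw), ncl + nw)
  out <- template
  out$centerline$coef <- matrix(raw[seq_len(ncl)],
                                nrow = nrow(template$centerline$coef))
  out$wall$coef <- matrix(raw[ncl + seq_len(nw)],
                          nrow = template$wall$n_s,
                          ncol = template$wall$n_theta, byrow = TRUE)
  out$meta <- list(decoded = TRUE)
  out
}

#' Round-trip surface distance of a parameterization
#'
#' Symmetric mean surface distance between a mesh and the reconstruction of
#' its parameterization, in mm.
#'
#' @param mesh the original `surface_mesh`.
#' @param param its `aorta_param` (default: computed from the mesh).
#' @param ... passed to [parameterize()].
#' @return Numeric distance in mm.
#' @export
roundtrip_distance <- function(mesh, param = NULL, ...) {
  param <- param %||% parameterize(mesh, ...)
  mesh_distance(mesh, reconstruct(param, n_s = 96L, n_theta = 48L))
}
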
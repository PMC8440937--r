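## Centerline representation: clamped cubic B-spline alpha(s), s in [0, 1],
## with s approximately normalized arc length, plus rotation-minimizing local
## frames <t, v1, v2> used for the polar wall coordinates.

cl_knots <- function(n_ctrl, degree = 3L) {
  if (n_ctrl < degree + 1L) stopf("need at least %d control points", degree + 1L)
  n_int <- n_ctrl - degree - 1L
  c(rep(0, degree + 1L),
    if (n_int > 0) seq_len(n_int) / (n_int + 1L),
    rep(1, degree + 1L))
}

cl_basis <- function(knots, s, deriv = 0L, degree = 3L) {
  s <- pmin(pmax(s, knots[1]), knots[length(knots)])
  splines::splineDesign(knots, s, ord = degree + 1L,
                        derivs = rep(deriv, length(s)))
}

#' Evaluate a centerline spline
#'
#' @param cl a `centerline_spline` as returned by [fit_centerline()].
#' @param s numeric vector of curve parameters in `[0, 1]`.
#' @param deriv derivative order (0, 1 or 2).
#' @return An `n x 3` matrix of points (mm) or derivative vectors.
#' @export
centerline_eval <- function(cl, s, deriv = 0L) {
  cl_basis(cl$knots, s, deriv, cl$degree) %*% cl$coef
}

as_curve_fn <- function(cl) {
  f <- function(s) centerline_eval(cl, s)
  attr(f, "deriv") <- function(s) centerline_eval(cl, s, 1L)
  f
}

#' Fit a cubic B-spline centerline to an ordered polyline
#'
#' Least-squares fit of a clamped cubic B-spline through an ordered sequence
#' of 3-D points, followed by reparameterization so that `s` is (approximately)
#' normalized arc length with `s = 0` at the first point (the valve end).
#'
#' @param points `n x 3` matrix of ordered polyline points (mm), valve end
#'   first.
#' @param n_ctrl number of control points (default 10, minimum 4).
#' @param natural_ends push the second derivative at both ends toward zero
#'   (soft natural boundary conditions). Appropriate when the tube ends in
#'   straight segments, as anatomical inlet/outlet trims do; it suppresses
#'   the end flare a plain least-squares spline develops on noisy centroids.
#' @return A `centerline_spline`: list with `knots`, `coef` (control points,
#'   one per row), `degree`, `n_ctrl`, `residual` (RMS fit residual in mm) and
#'   `length` (total arc length in mm).
#' @export
fit_centerline <- function(points, n_ctrl = 10L, natural_ends = FALSE) {
  points <- as.matrix(points)
  n_ctrl <- as.integer(n_ctrl)
  if (n_ctrl < 4L) stopf("n_ctrl must be at least 4")
  if (nrow(points) < n_ctrl + 4L)
    stopf("underdetermined centerline fit: %d points for %d control points",
          nrow(points), n_ctrl)
  knots <- cl_knots(n_ctrl)
  solve_fit <- function(u, pts) {
    B <- cl_basis(knots, u)
    if (natural_ends) {
      ## soft constraint rows alpha''(0) = alpha''(1) = 0, scaled so they
      ## dominate the fit residual without being hard constraints
      Bdd <- cl_basis(knots, c(0, 1), deriv = 2L)
      w <- 0.1 * sqrt(nrow(pts))
      B <- rbind(B, w * Bdd)
      pts <- rbind(pts, matrix(0, 2, 3))
    }
    qr.solve(B, pts)
  }
  ## chord-length parameterization
  seg <- sqrt(rowSums(diff(points)^2))
  u <- c(0, cumsum(seg))
  if (u[length(u)] <= 0) stopf("degenerate polyline")
  u <- u / u[length(u)]
  coef <- solve_fit(u, points)
  B <- cl_basis(knots, u)
  resid <- sqrt(mean(rowSums((B %*% coef - points)^2)))
  cl <- structure(list(knots = knots, coef = coef, degree = 3L,
                       n_ctrl = n_ctrl, residual = resid),
                  class = "centerline_spline")
  ## reparameterize to normalized arc length
  dense <- seq(0, 1, length.out = 2049)
  p <- centerline_eval(cl, dense)
  al <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  total <- al[length(al)]
  s_tgt <- seq(0, 1, length.out = max(8L * n_ctrl, 257L))
  u_of_s <- stats::approx(al / total, dense, xout = s_tgt, ties = "ordered")$y
  q <- centerline_eval(cl, u_of_s)
  coef2 <- solve_fit(s_tgt, q)
  structure(list(knots = knots, coef = coef2, degree = 3L, n_ctrl = n_ctrl,
                 residual = resid, length = total),
            class = "centerline_spline")
}

#' @export
print.centerline_spline <- function(x, ...) {
  cat(sprintf("centerline_spline: cubic B-spline, %d control points, arc length %.1f mm, fit RMS %.3g mm\n",
              x$n_ctrl, x$length %||% NA_real_, x$residual))
  invisible(x)
}

## Rotation-minimizing frames along a curve by the double-reflection method.
## `curve` maps s -> n x 3 points; an analytic derivative may be attached as
## attr(curve, "deriv"). Frames are propagated from s = 0 with the fixed
## convention v1(0) = x-axis orthogonalized against t(0) (y-axis fallback).
rmf_along <- function(curve, s, n_grid = 1025L) {
  ## propagate on a fixed dyadic grid, then take one double-reflection step
  ## from the nearest lower grid node to each query; frames are therefore
  ## identical no matter which other queries accompany them
  grid <- seq(0, 1, length.out = n_grid)
  dfn <- attr(curve, "deriv")
  tangent <- function(u) {
    if (is.null(dfn)) {
      h <- 1e-6
      Tm <- (curve(pmin(u + h, 1)) - curve(pmax(u - h, 0))) /
        (pmin(u + h, 1) - pmax(u - h, 0))
    } else Tm <- dfn(u)
    tn <- sqrt(rowSums(Tm^2))
    if (any(tn < 1e-12)) stopf("zero tangent on centerline")
    Tm / tn
  }
  P <- curve(grid)
  Tm <- tangent(grid)
  n <- length(grid)
  V1 <- matrix(0, n, 3)
  t0 <- Tm[1, ]
  v <- c(1, 0, 0) - sum(c(1, 0, 0) * t0) * t0
  if (sqrt(sum(v^2)) < 1e-6) v <- c(0, 1, 0) - sum(c(0, 1, 0) * t0) * t0
  V1[1, ] <- unit(v)
  dr_step <- function(p0, t0v, v0, p1, t1v) {
    c1 <- p1 - p0
    c1n <- sum(c1^2)
    if (c1n < 1e-28) return(unit(v0 - sum(v0 * t1v) * t1v))
    vL <- v0 - (2 / c1n) * sum(c1 * v0) * c1
    tL <- t0v - (2 / c1n) * sum(c1 * t0v) * c1
    c2 <- t1v - tL
    c2n <- sum(c2^2)
    out <- if (c2n < 1e-28) vL else vL - (2 / c2n) * sum(c2 * vL) * c2
    unit(out - sum(out * t1v) * t1v)
  }
  for (i in seq_len(n - 1L))
    V1[i + 1L, ] <- dr_step(P[i, ], Tm[i, ], V1[i, ], P[i + 1L, ], Tm[i + 1L, ])
  ## queries
  sq <- pmin(pmax(s, 0), 1)
  Pq <- curve(sq)
  Tq <- tangent(sq)
  iq <- pmin(pmax(findInterval(sq, grid), 1L), n)
  V1q <- matrix(0, length(sq), 3)
  for (k in seq_along(sq)) {
    i <- iq[k]
    V1q[k, ] <- dr_step(P[i, ], Tm[i, ], V1[i, ], Pq[k, ], Tq[k, ])
  }
  V2q <- cbind(Tq[, 2] * V1q[, 3] - Tq[, 3] * V1q[, 2],
               Tq[, 3] * V1q[, 1] - Tq[, 1] * V1q[, 3],
               Tq[, 1] * V1q[, 2] - Tq[, 2] * V1q[, 1])
  list(s = s, origin = Pq, t = Tq, v1 = V1q, v2 = V2q)
}

#' Local frame on a centerline
#'
#' Returns the local orthonormal frame `<t, v1, v2>` at parameter `s`:
#' the unit tangent plus two normal directions forming a right-handed triad,
#' with `v1`/`v2` obtained by propagating a rotation-minimizing frame from
#' `s = 0` (double-reflection method), which avoids the flips of Frenet frames
#' at curvature zeros.
#'
#' @param cl a `centerline_spline`.
#' @param s curve parameter in `[0, 1]` (scalar).
#' @return A list with `origin`, `t`, `v1`, `v2` (each a 3-vector).
#' @export
frame_at <- function(cl, s) {
  if (s < 0 || s > 1) stopf("s must be in [0, 1]")
  fr <- rmf_along(as_curve_fn(cl), s)
  list(origin = fr$origin[1, ], t = fr$t[1, ], v1 = fr$v1[1, ], v2 = fr$v2[1, ])
}

frames_at <- function(cl, s) rmf_along(as_curve_fn(cl), s)

#' Project a point into centerline polar coordinates
#'
#' Finds the closest point `alpha(s)` on the centerline (dense-sample
#' bracketing over 512 stations followed by local refinement to tolerance
#' 1e-8 in `s`), then expresses the offset in the local frame as polar
#' coordinates `(theta, rho)`.
#'
#' @param cl a `centerline_spline`.
#' @param x a 3-vector (mm).
#' @return A list with `s`, `theta` in `[0, 2*pi)`, `rho` (mm) and logical
#'   `ambiguous` (several equally close stations; the smallest `s` is chosen).
#' @export
project_point <- function(cl, x) {
  x <- as.numeric(x)
  grid <- seq(0, 1, length.out = 512L)
  P <- centerline_eval(cl, grid)
  d2 <- rowSums((P - matrix(x, nrow(P), 3, byrow = TRUE))^2)
  locmin <- which(d2 <= c(Inf, d2[-length(d2)]) & d2 <= c(d2[-1], Inf))
  near <- locmin[d2[locmin] <= min(d2) * (1 + 1e-9) + 1e-12]
  ambiguous <- length(near) > 1L
  i <- min(near)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  f <- function(s) sum((x - centerline_eval(cl, s)[1, ])^2)
  s <- if (hi > lo) stats::optimize(f, c(lo, hi), tol = 1e-10)$minimum else grid[i]
  if (f(grid[i]) < f(s)) s <- grid[i]
  ## Newton polish on the orthogonality condition (x - alpha(s)) . alpha'(s)
  ## = 0: optimize() stalls near sqrt(machine eps) in s, which leaves a
  ## tangential residual of order |alpha'| * 1e-8 mm in the polar split
  if (s > 0 && s < 1) {
    for (it in 1:3) {
      a0 <- centerline_eval(cl, s)[1, ]
      a1v <- centerline_eval(cl, s, 1L)[1, ]
      a2v <- centerline_eval(cl, s, 2L)[1, ]
      g <- sum((x - a0) * a1v)
      gp <- -sum(a1v^2) + sum((x - a0) * a2v)
      if (abs(gp) < 1e-300) break
      step <- g / gp
      s_new <- min(max(s - step, 0), 1)
      if (!is.finite(s_new) || abs(s_new - s) > 2 / 512) break
      s <- s_new
      if (abs(step) < 1e-14) break
    }
  }
  fr <- frame_at(cl, s)
  d <- x - fr$origin
  a1 <- sum(d * fr$v1); a2 <- sum(d * fr$v2)
  rho <- sqrt(a1^2 + a2^2)
  theta <- if (rho < 1e-12) 0 else atan2(a2, a1) %% (2 * pi)
  list(s = s, theta = theta, rho = rho, ambiguous = ambiguous)
}

## Vectorized projection used by parameterize(): grid argmin + one parabolic
## refinement per point, frames taken from a shared dense RMF grid with a
## single double-reflection step to the refined s.
project_points <- function(cl, X, n_grid = 512L) {
  X <- as.matrix(X)
  grid <- seq(0, 1, length.out = n_grid)
  fr <- frames_at(cl, grid)
  P <- fr$origin
  x2 <- rowSums(X^2)
  p2 <- rowSums(P^2)
  d2 <- outer(x2, p2, "+") - 2 * (X %*% t(P))
  i <- max.col(-d2, ties.method = "first")
  h <- grid[2] - grid[1]
  im <- pmax(i - 1L, 1L); ip <- pmin(i + 1L, n_grid)
  n <- nrow(X)
  dm <- d2[cbind(seq_len(n), im)]; d0 <- d2[cbind(seq_len(n), i)]
  dp <- d2[cbind(seq_len(n), ip)]
  denom <- dm - 2 * d0 + dp
  delta <- ifelse(abs(denom) > 1e-300, 0.5 * (dm - dp) / denom, 0)
  delta[i == 1L | i == n_grid] <- 0
  delta <- pmin(pmax(delta, -1), 1)
  s <- pmin(pmax(grid[i] + delta * h, 0), 1)
  ## frame at refined s: one double-reflection step from the grid node
  O <- centerline_eval(cl, s)
  Tm <- centerline_eval(cl, s, 1L)
  Tm <- Tm / sqrt(rowSums(Tm^2))
  V1g <- fr$v1[i, , drop = FALSE]
  Tg <- fr$t[i, , drop = FALSE]
  Pg <- P[i, , drop = FALSE]
  C1 <- O - Pg
  c1n <- rowSums(C1^2)
  dotv <- rowSums(C1 * V1g); dott <- rowSums(C1 * Tg)
  vL <- V1g - 2 * (dotv / pmax(c1n, 1e-300)) * C1
  tL <- Tg - 2 * (dott / pmax(c1n, 1e-300)) * C1
  small <- c1n < 1e-24
  vL[small, ] <- V1g[small, ]; tL[small, ] <- Tg[small, ]
  C2 <- Tm - tL
  c2n <- rowSums(C2^2)
  V1 <- vL - 2 * (rowSums(C2 * vL) / pmax(c2n, 1e-300)) * C2
  V1[c2n < 1e-24, ] <- vL[c2n < 1e-24, ]
  V1 <- V1 - rowSums(V1 * Tm) * Tm
  V1 <- V1 / sqrt(rowSums(V1^2))
  V2 <- cbind(Tm[, 2] * V1[, 3] - Tm[, 3] * V1[, 2],
              Tm[, 3] * V1[, 1] - Tm[, 1] * V1[, 3],
              Tm[, 1] * V1[, 2] - Tm[, 2] * V1[, 1])
  D <- X - O
  a1 <- rowSums(D * V1); a2 <- rowSums(D * V2)
  rho <- sqrt(a1^2 + a2^2)
  theta <- ifelse(rho < 1e-12, 0, atan2(a2, a1) %% (2 * pi))
  data.frame(s = s, theta = theta, rho = rho)
}
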
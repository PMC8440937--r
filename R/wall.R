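## Wall-radius model rho(s, theta): tensor-product least-squares fit of the
## polar wall samples. The s-basis is a clamped cubic B-spline with `n_s`
## coefficients (n_s = 4 degenerates to a plain cubic polynomial in s); the
## theta-basis is either a periodic trigonometric set {1, cos, sin, cos2,
## sin2, cos3, sin3} (default, continuous across the seam) or literal cubic
## monomials {1, theta, theta^2, theta^3} for fidelity to a plain bivariate
## cubic.

theta_basis <- function(theta, mode) {
  if (mode == "periodic") {
    cbind(1, cos(theta), sin(theta), cos(2 * theta), sin(2 * theta),
          cos(3 * theta), sin(3 * theta))
  } else {
    cbind(1, theta, theta^2, theta^3)
  }
}

s_wall_basis <- function(knots, s) cl_basis(knots, s)

wall_design <- function(knots, mode, s, theta) {
  Bs <- s_wall_basis(knots, s)
  Bt <- theta_basis(theta, mode)
  ns <- ncol(Bs); nt <- ncol(Bt)
  D <- matrix(0, length(s), ns * nt)
  for (a in seq_len(ns))
    D[, (a - 1L) * nt + seq_len(nt)] <- Bs[, a] * Bt
  D
}

#' Fit the wall-radius model
#'
#' Least-squares fit of `rho` as a smooth function of `(s, theta)` from polar
#' wall samples.
#'
#' @param samples data frame (or list) with numeric `s`, `theta`, `rho`.
#' @param n_s number of s-basis coefficients (clamped cubic B-spline;
#'   `n_s = 4` gives a plain cubic polynomial in `s`). Default 24, enough to
#'   resolve the sinus bulge.
#' @param mode theta basis: `"periodic"` (default) or `"literal"` cubic
#'   monomials. In literal mode `rho(s, 0)` and `rho(s, 2*pi)` generally
#'   differ; the seam gap is reported in the returned object.
#' @param domain s-interval actually covered by the samples; outside it the
#'   model evaluates at the clamped boundary value (constant extension), so
#'   end-cap gaps in the data cannot produce wild extrapolation.
#' @param smooth_lambda weight of a second-difference penalty on the
#'   s-coefficients (0 disables it); exactly zero for any radius field that
#'   is linear in `s`, so constant-radius recovery stays exact.
#' @return A `wall_model`: list with `knots`, `mode`, `n_s`, `coef`
#'   (`n_s x n_theta` matrix), `residual` (RMS, mm) and `seam_gap` (mm).
#' @export
fit_wall <- function(samples, n_s = 24L, mode = c("periodic", "literal"),
                     domain = c(0, 1), smooth_lambda = 0.1) {
  mode <- match.arg(mode)
  s <- samples$s; theta <- samples$theta; rho <- samples$rho
  knots <- domain[1] + cl_knots(as.integer(n_s)) * (domain[2] - domain[1])
  nt <- if (mode == "periodic") 7L else 4L
  ncoef <- as.integer(n_s) * nt
  if (length(rho) <= ncoef)
    stopf("wall fit needs more samples (%d) than coefficients (%d)",
          length(rho), ncoef)
  D <- wall_design(knots, mode, s, theta)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stopf("rank-deficient wall fit (rank %d < %d); sample coverage of (s, theta) is insufficient",
          qrD$rank, ncol(D))
  ## light second-difference penalty on the s-coefficients: stabilizes knot
  ## spans that are thinly covered near the tube ends. Higher theta
  ## harmonics carry the least data support and cause the end flare, so they
  ## are penalized more; the mean-radius term (which carries the sinus
  ## bulge) is penalized least.
  ns <- as.integer(n_s)
  if (smooth_lambda > 0 && ns >= 3L) {
    lam_b <- smooth_lambda * (if (mode == "periodic")
      c(1, 3, 3, 8, 8, 25, 25) else rep(1, nt))
    P <- matrix(0, (ns - 2L) * nt, ns * nt)
    r <- 0L
    for (a in 2:(ns - 1L)) for (b in seq_len(nt)) {
      r <- r + 1L
      P[r, (a - 2L) * nt + b] <- lam_b[b]
      P[r, (a - 1L) * nt + b] <- -2 * lam_b[b]
      P[r, a * nt + b] <- lam_b[b]
    }
    cf <- qr.coef(qr(rbind(D, P)), c(rho, numeric(nrow(P))))
  } else {
    cf <- qr.coef(qrD, rho)
  }
  resid <- sqrt(mean((D %*% cf - rho)^2))
  w <- structure(list(knots = knots, mode = mode, n_s = as.integer(n_s),
                      n_theta = nt,
                      coef = matrix(cf, nrow = n_s, ncol = nt, byrow = TRUE),
                      residual = resid),
                 class = "wall_model")
  sg <- seq(0, 1, length.out = 33)
  w$seam_gap <- max(abs(wall_eval(w, sg, rep(0, 33)) -
                        wall_eval(w, sg, rep(2 * pi, 33))))
  w
}

#' Evaluate the wall-radius model
#'
#' @param wall a `wall_model`.
#' @param s,theta numeric vectors (recycled to common length).
#' @return Vector of radii `rho(s, theta)` in mm.
#' @export
wall_eval <- function(wall, s, theta) {
  n <- max(length(s), length(theta))
  s <- rep_len(s, n); theta <- rep_len(theta, n)
  drop(wall_design(wall$knots, wall$mode, s, theta) %*% as.vector(t(wall$coef)))
}

#' @export
print.wall_model <- function(x, ...) {
  cat(sprintf("wall_model: %s theta-basis, %d x %d coefficients, RMS residual %.3g mm, seam gap %.3g mm\n",
              x$mode, x$n_s, x$n_theta, x$residual, x$seam_gap))
  invisible(x)
}
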
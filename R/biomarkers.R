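## The 11 anatomical biomarkers of a thoracic aorta parameterization:
## radii at five landmarks (SoV, PA, MA, PT, PD), centerline length to PD
## (LPD), mean arch curvature (k), arch height (h) and width (w), the ratio
## h/w, and tortuosity tor = 1 - w/LPD. Landmark radii are always the
## semi-major axis of the best-fitting ellipse of the cross-section.

BIOMARKER_NAMES <- c("SoV", "PA", "MA", "PT", "PD", "LPD", "k", "h", "w",
                     "h_over_w", "tor")

#' Fit an ellipse to planar points
#'
#' Direct least-squares conic fit with the ellipse constraint
#' (Halir-Flusser formulation of the Fitzgibbon method), falling back to the
#' second-moment ellipse when the conic system is degenerate.
#'
#' @param xy `n x 2` matrix of planar points (mm), `n >= 6`.
#' @return List with `center` (2-vector), `semi_major`, `semi_minor` (mm) and
#'   `angle` (radians).
#' @export
fit_ellipse <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 6L) stopf("ellipse fit needs at least 6 points")
  x <- xy[, 1] - mean(xy[, 1]); y <- xy[, 2] - mean(xy[, 2])
  sc <- max(stats::sd(x), stats::sd(y), 1e-12)
  x <- x / sc; y <- y / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  conic <- tryCatch({
    T1 <- -solve(S3, t(S2))
    M <- S1 + S2 %*% T1
    M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
    ev <- eigen(M)
    V <- Re(ev$vectors)
    cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
    j <- which(cond > 0)
    if (length(j) == 0) stop("no ellipse solution")
    a1 <- V[, j[1]]
    c(a1, as.numeric(T1 %*% a1))
  }, error = function(e) NULL)
  if (is.null(conic)) {
    ## second-moment fallback: principal axes of the point covariance
    C <- stats::cov(cbind(x, y))
    ev <- eigen(C, symmetric = TRUE)
    ax <- sqrt(2 * ev$values) * sc
    return(list(center = c(mean(xy[, 1]), mean(xy[, 2])),
                semi_major = ax[1], semi_minor = ax[2],
                angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1])))
  }
  A <- conic[1]; B <- conic[2]; C <- conic[3]
  D <- conic[4]; E <- conic[5]; F0 <- conic[6]
  den <- 4 * A * C - B^2
  if (den <= 0) stopf("degenerate ellipse fit")
  x0 <- (B * E - 2 * C * D) / den
  y0 <- (B * D - 2 * A * E) / den
  Fc <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F0
  Mm <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  lam <- eigen(Mm, symmetric = TRUE)$values
  ax2 <- -Fc / lam
  if (any(ax2 <= 0)) stopf("degenerate ellipse fit")
  ax <- sqrt(ax2) * sc
  ang <- 0.5 * atan2(B, A - C)
  list(center = c(x0 * sc + mean(xy[, 1]), y0 * sc + mean(xy[, 2])),
       semi_major = max(ax), semi_minor = min(ax), angle = ang)
}

#' Cross-section radius at a station
#'
#' Samples the wall at `n_theta` angles in the local frame plane at `s`, fits
#' an ellipse and returns the semi-major axis.
#'
#' @param param an `aorta_param`.
#' @param s station in `[0, 1]`.
#' @param n_theta number of sampled angles (>= 64 recommended).
#' @return Semi-major axis in mm.
#' @export
section_radius <- function(param, s, n_theta = 64L) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  rho <- wall_eval(param$wall, rep(s, n_theta), th)
  if (any(rho <= 0)) stopf("non-positive wall radius at s = %.3f", s)
  fit_ellipse(cbind(rho * cos(th), rho * sin(th)))$semi_major
}

#' Centerline arc length between two stations
#'
#' Adaptive quadrature of the parametric speed `|alpha'(s)|`.
#'
#' @param cl a `centerline_spline`.
#' @param s0,s1 stations with `s0 < s1`.
#' @return Length in mm.
#' @export
centerline_length <- function(cl, s0 = 0, s1 = 1) {
  if (s0 >= s1) stopf("need s0 < s1")
  speed <- function(s) sqrt(rowSums(centerline_eval(cl, s, 1L)^2))
  stats::integrate(speed, s0, s1, rel.tol = 1e-8, subdivisions = 400L)$value
}

#' Arc-length-weighted mean curvature of the centerline
#'
#' Mean of `kappa(s) = |alpha' x alpha''| / |alpha'|^3` weighted by arc
#' length over `[s0, s1]`.
#'
#' @inheritParams centerline_length
#' @return Mean curvature in 1/mm.
#' @export
mean_curvature <- function(cl, s0, s1, n_grid = 2001L) {
  if (s0 >= s1) stopf("need s0 < s1")
  ## composite Simpson on a fine fixed grid: |alpha' x alpha''| has kinks
  ## wherever the curvature of a fitted spline touches zero, which defeats
  ## adaptive quadrature; the fixed rule is robust and accurate to ~1e-8
  ## for the spline curves used here
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L
  s <- seq(s0, s1, length.out = n_grid)
  d1 <- centerline_eval(cl, s, 1L)
  d2 <- centerline_eval(cl, s, 2L)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  sp <- sqrt(rowSums(d1^2))
  f_num <- sqrt(rowSums(cr^2)) / sp^2
  f_den <- sp
  wts <- c(1, rep(c(4, 2), (n_grid - 3L) / 2L), 4, 1)
  num <- sum(wts * f_num)
  den <- sum(wts * f_den)
  num / den
}

#' Locate the anatomical landmarks
#'
#' Finds the five landmark stations: PT at the interior maximum of centerline
#' height (z); SoV at the maximum of the mean wall radius over the root
#' region (first 15% of `s`, falling back to `s = 0.04` when no bulge is
#' detected); PA and PD fixed ascending fractions; PD located past the arch
#' at the height of PA by bisection.
#'
#' @param param an `aorta_param`.
#' @param s_pa,s_ma default stations for the sinotubular and mid-ascending
#'   landmarks.
#' @param s_sov_default fallback SoV station.
#' @return Named list with `s_SoV`, `s_PA`, `s_MA`, `s_PT`, `s_PD`.
#' @export
locate_landmarks <- function(param, s_pa = 0.10, s_ma = 0.20,
                             s_sov_default = 0.04) {
  cl <- param$centerline
  zfun <- function(s) centerline_eval(cl, s)[, 3]
  sg <- seq(0, 1, length.out = 513)
  z <- zfun(sg)
  i <- which.max(z)
  if (i <= 2L || i >= length(sg) - 1L)
    stopf("no interior height maximum: not an arch-shaped tube")
  s_pt <- stats::optimize(function(s) zfun(s), c(sg[i - 1L], sg[i + 1L]),
                          maximum = TRUE, tol = 1e-8)$maximum
  ## SoV: bulge detection on the mean wall radius over the root region
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  sroot <- seq(0.005, 0.15, length.out = 60)
  mrho <- vapply(sroot, function(s) mean(wall_eval(param$wall, rep(s, 32), th)),
                 numeric(1))
  j <- which.max(mrho)
  s_sov <- if (j > 1L && j < length(sroot) &&
               mrho[j] > stats::median(mrho) * 1.01) sroot[j] else s_sov_default
  s_sov <- min(s_sov, s_pa - 0.005)
  ## PD: station past the arch at the height of PA
  z_pa <- zfun(s_pa)
  f <- function(s) zfun(s) - z_pa
  if (f(1) > 0)
    stopf("descending limb does not reach the height of PA")
  s_pd <- stats::uniroot(f, c(s_pt, 1), tol = 1e-9)$root
  if (!(s_sov < s_pa && s_pa < s_ma && s_ma < s_pt && s_pt < s_pd))
    stopf("landmark ordering violated")
  list(s_SoV = s_sov, s_PA = s_pa, s_MA = s_ma, s_PT = s_pt, s_PD = s_pd)
}

#' Compute the 11 anatomical biomarkers
#'
#' Radii (semi-major axis of the best-fit cross-section ellipse) at the five
#' landmarks, centerline length from the valve to PD, arc-length-weighted
#' mean curvature from PA to PD, arch height `h` (height of PT above PA),
#' arch width `w` (distance PA to PD), `h/w`, and tortuosity
#' `tor = 1 - w / LPD`.
#'
#' @param param an `aorta_param`.
#' @param landmarks optional precomputed [locate_landmarks()] result.
#' @return A named numeric vector of class `biomarker_set` with elements
#'   `SoV, PA, MA, PT, PD, LPD, k, h, w, h_over_w, tor`.
#' @export
compute_biomarkers <- function(param, landmarks = NULL) {
  lm <- landmarks %||% locate_landmarks(param)
  cl <- param$centerline
  radii <- vapply(c(lm$s_SoV, lm$s_PA, lm$s_MA, lm$s_PT, lm$s_PD),
                  function(s) section_radius(param, s), numeric(1))
  lpd <- centerline_length(cl, 0, lm$s_PD)
  k <- mean_curvature(cl, lm$s_PA, lm$s_PD)
  p_pa <- centerline_eval(cl, lm$s_PA)[1, ]
  p_pd <- centerline_eval(cl, lm$s_PD)[1, ]
  p_pt <- centerline_eval(cl, lm$s_PT)[1, ]
  h <- p_pt[3] - p_pa[3]
  w <- sqrt(sum((p_pa - p_pd)^2))
  if (w > lpd) stopf("invalid geometry: chord exceeds path length")
  b <- c(radii, lpd, k, h, w, h / w, 1 - w / lpd)
  names(b) <- BIOMARKER_NAMES
  structure(b, class = c("biomarker_set", "numeric"), landmarks = lm)
}

#' @export
print.biomarker_set <- function(x, ...) {
  v <- unclass(x); attributes(v) <- list(names = names(x))
  print(round(v, 3))
  invisible(x)
}

#' Biomarker table of a set of parameterizations
#'
#' @param params list of `aorta_param` objects.
#' @return Data frame, one row per anatomy, columns the 11 biomarkers.
#' @export
biomarker_table <- function(params) {
  rows <- lapply(params, function(p) as.numeric(compute_biomarkers(p)))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- BIOMARKER_NAMES
  out
}

#' Write a biomarker table as CSV
#'
#' Uses the conventional column labels (`h/w` for the ratio column).
#'
#' @param table data frame from [biomarker_table()].
#' @param path output CSV path.
#' @export
write_biomarker_csv <- function(table, path) {
  out <- table
  names(out)[names(out) == "h_over_w"] <- "h/w"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
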
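## Procedural generator of arch-shaped aorta-like tubes with known ground
## truth, standing in for a clinical imaging cohort. Canonical orientation:
## valve end at the origin, height along +z, arch in the x-z plane.

#' Shape parameters of a synthetic aorta
#'
#' Collects the geometric parameters of the procedural aorta generator and
#' validates their ranges. The centerline is a straight ascending segment, a
#' semicircular arch of radius `arch_radius` in the x-z plane and a straight
#' descending segment, blended C1. The wall radius is a smooth baseline
#' profile through the valve (`r_valve`), sinotubular (`r_stj`),
#' mid-ascending (`r_ma`), arch-top (`r_arch`) and descending (`r_desc`)
#' radii, plus a compact sinus-of-Valsalva bulge of height `sov_amplitude`
#' centered at arc-length fraction `sov_center` with extent `sov_width`.
#' Cross-sections are made elliptical by a `cos(2*theta)` modulation of
#' relative amplitude `ovality`.
#'
#' @param arch_radius arch (semicircle) radius, mm.
#' @param ascending_length,descending_length straight segment lengths, mm.
#' @param r_valve,r_stj,r_ma,r_arch,r_desc wall radii at the control
#'   stations, mm.
#' @param sov_amplitude sinus bulge height above the baseline, mm.
#' @param sov_center,sov_width bulge center and extent as fractions of
#'   normalized arc length (`0 < sov_center < sov_width < 0.3`).
#' @param ovality relative semi-axis difference of the cross-section ellipse,
#'   in `[0, 0.3]`; the semi-major axis is `rho * (1 + ovality)`.
#' @param surface_noise radial Gaussian noise, mm.
#' @param n_axial,n_circumferential mesh resolution (at least 16 each).
#' @return A validated list of class `aorta_shape_params`.
#' @export
aorta_shape_params <- function(arch_radius = 35, ascending_length = 75,
                               descending_length = 75,
                               r_valve = 15.3, sov_amplitude = 2.5,
                               sov_center = 0.05, sov_width = 0.09,
                               r_stj = 14.8, r_ma = 17.3, r_arch = 13.4,
                               r_desc = 12.0, ovality = 0.05,
                               surface_noise = 0, n_axial = 48,
                               n_circumferential = 32) {
  p <- list(arch_radius = arch_radius, ascending_length = ascending_length,
            descending_length = descending_length, r_valve = r_valve,
            sov_amplitude = sov_amplitude, sov_center = sov_center,
            sov_width = sov_width, r_stj = r_stj, r_ma = r_ma,
            r_arch = r_arch, r_desc = r_desc, ovality = ovality,
            surface_noise = surface_noise, n_axial = as.integer(n_axial),
            n_circumferential = as.integer(n_circumferential))
  radii <- c(p$arch_radius, p$ascending_length, p$descending_length,
             p$r_valve, p$r_stj, p$r_ma, p$r_arch, p$r_desc)
  if (any(!is.finite(unlist(p[1:13]))) || any(radii <= 0))
    stopf("all lengths and radii must be positive")
  if (p$sov_amplitude < 0) stopf("sov_amplitude must be >= 0")
  if (!(p$sov_center > 0 && p$sov_center < p$sov_width && p$sov_width < 0.3))
    stopf("need 0 < sov_center < sov_width < 0.3")
  if (p$ovality < 0 || p$ovality > 0.3) stopf("ovality must be in [0, 0.3]")
  if (p$n_axial < 16L || p$n_circumferential < 16L)
    stopf("mesh resolution counts must be >= 16")
  structure(p, class = "aorta_shape_params")
}

## True centerline as a function of normalized arc length s, with analytic
## derivative (w.r.t. s) attached. The curve is a planar arch: straight
## ascending segment, semicircular arch of radius R, straight descending
## segment, with curvature-continuous (smoothstep) transitions of half-width
## `blend` mm at the two junctions. The transitions are symmetric, so the
## total turning stays exactly pi and the mean curvature between two
## stations bracketing the arch is pi / arc-length, while the curve is C2
## (real vessels have no curvature jumps, and a C2 truth is representable
## by the cubic-spline fits used downstream).
aorta_centerline_fn <- function(params, blend = 12) {
  La <- params$ascending_length; Ld <- params$descending_length
  R <- params$arch_radius
  L <- La + pi * R + Ld
  blend <- min(blend, 0.45 * La, 0.45 * Ld, 0.45 * pi * R)
  smoothstep <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    3 * u^2 - 2 * u^3
  }
  kappa <- function(l) {
    (smoothstep((l - (La - blend)) / (2 * blend)) -
       smoothstep((l - (La + pi * R - blend)) / (2 * blend))) / R
  }
  lg <- seq(0, L, length.out = 4097)
  dl <- lg[2] - lg[1]
  kv <- kappa(lg)
  phi <- c(0, cumsum((kv[-1] + kv[-length(kv)]) / 2 * dl))
  sx <- sin(phi); cz <- cos(phi)
  xg <- c(0, cumsum((sx[-1] + sx[-length(sx)]) / 2 * dl))
  zg <- c(0, cumsum((cz[-1] + cz[-length(cz)]) / 2 * dl))
  xf <- stats::splinefun(lg, xg, method = "natural")
  zf <- stats::splinefun(lg, zg, method = "natural")
  pf <- stats::approxfun(lg, phi, rule = 2)
  f <- function(s) {
    l <- pmin(pmax(s, 0), 1) * L
    cbind(xf(l), 0, zf(l))
  }
  attr(f, "deriv") <- function(s) {
    l <- pmin(pmax(s, 0), 1) * L
    p <- pf(l)
    cbind(L * sin(p), 0, L * cos(p))
  }
  attr(f, "length") <- L
  f
}

## True baseline wall radius profile r(s) (without ovality), bulge included.
aorta_radius_fn <- function(params) {
  La <- params$ascending_length; R <- params$arch_radius
  L <- La + pi * R + params$descending_length
  s_top <- (La + pi * R / 2) / L
  base <- stats::splinefun(
    x = c(0, 0.10, 0.20, s_top, 0.80, 1),
    y = c(params$r_valve, params$r_stj, params$r_ma, params$r_arch,
          params$r_desc, params$r_desc),
    method = "natural")
  A <- params$sov_amplitude; ctr <- params$sov_center; w <- params$sov_width
  function(s) {
    r <- base(s)
    if (A > 0) {
      u <- (s - ctr) / w
      bump <- ifelse(abs(u) <= 0.5, cos(pi * u)^2, 0)
      r <- r + A * bump
    }
    r
  }
}

## Ground-truth phenotype from the generator parameters: compares the sinus
## peak radius with the radii at the sinotubular (s = 0.10) and mid-ascending
## (s = 0.20) stations using the aortic-root class rules.
true_phenotype <- function(params) {
  rf <- aorta_radius_fn(params)
  ## sinus peak radius: maximum over the aortic root, i.e. strictly below
  ## the sinotubular station at s = 0.10 (the rise toward the mid-ascending
  ## dilation beyond the root must not masquerade as the sinus bulge)
  s_root <- seq(0, 0.095, length.out = 191)
  sov <- max(rf(s_root))
  classify_phenotype(c(SoV = sov, PA = rf(0.10), MA = rf(0.20)))
}

#' Generate a synthetic aorta surface mesh
#'
#' Builds a closed triangulated arch-shaped tube from [aorta_shape_params()]
#' in the canonical orientation (valve end at the origin, height along +z,
#' arch in the x-z plane). The true centerline and true radius profile are
#' attached so that downstream computations can be checked against ground
#' truth.
#'
#' @param params an `aorta_shape_params` object.
#' @param seed optional integer seed for the surface-noise draw.
#' @return A `surface_mesh` with attributes `params`, `centerline` (function
#'   of `s` with analytic derivative), `radius` (function `(s, theta)`,
#'   ovality included), `baseline_radius` (function of `s`), `length` (mm)
#'   and `phenotype`.
#' @export
generate_aorta <- function(params, seed = NULL) {
  if (!inherits(params, "aorta_shape_params"))
    params <- do.call(aorta_shape_params, as.list(params))
  cfun <- aorta_centerline_fn(params)
  rbase <- aorta_radius_fn(params)
  ov <- params$ovality
  rfun <- function(s, theta) rbase(s) * (1 + ov * cos(2 * theta))
  m <- with_seed(seed, tube_mesh(cfun, rfun,
                                 n_axial = params$n_axial,
                                 n_circumferential = params$n_circumferential,
                                 cap = TRUE, noise_sd = params$surface_noise))
  attr(m, "params") <- params
  attr(m, "centerline") <- cfun
  attr(m, "radius") <- rfun
  attr(m, "baseline_radius") <- rbase
  attr(m, "length") <- attr(cfun, "length")
  attr(m, "phenotype") <- true_phenotype(params)
  m
}

#' Population specification for the synthetic generator
#'
#' Describes per-parameter sampling distributions and the target mixture of
#' the three aortic-root phenotypes. The defaults emulate an elderly clinical
#' cohort with ascending aortic dilation: biomarker means and spreads in the
#' regime of published sample statistics (arch width about 70 mm, centerline
#' length to the diaphragm level about 235 mm, root radii 12-18 mm), with
#' phenotype frequencies `N:A:E = 0.115 : 0.535 : 0.35`.
#'
#' @param distributions named list; each element is `list(dist, location,
#'   scale)` with `dist` one of `"normal"`, `"uniform"` (location = lower,
#'   scale = width) or `"fixed"`.
#' @param phenotype_mixture numeric weights for phenotypes N, A, E (sum 1).
#' @param seed integer seed.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(distributions = NULL,
                            phenotype_mixture = c(N = 0.115, A = 0.535, E = 0.35),
                            seed = 1L) {
  defaults <- list(
    arch_radius       = list(dist = "normal", location = 35,   scale = 4.5),
    ascending_length  = list(dist = "normal", location = 75,   scale = 7),
    descending_length = list(dist = "normal", location = 75,   scale = 7),
    r_valve           = list(dist = "normal", location = 14.2, scale = 1.6),
    sov_amplitude     = list(dist = "normal", location = 2.0,  scale = 1.2),
    sov_center        = list(dist = "fixed",  location = 0.05, scale = 0),
    sov_width         = list(dist = "fixed",  location = 0.09, scale = 0),
    r_stj             = list(dist = "normal", location = 14.8, scale = 1.4),
    r_ma              = list(dist = "normal", location = 17.3, scale = 1.8),
    r_arch            = list(dist = "normal", location = 13.4, scale = 1.5),
    r_desc            = list(dist = "normal", location = 12.0, scale = 1.1),
    ovality           = list(dist = "uniform", location = 0,   scale = 0.08),
    surface_noise     = list(dist = "fixed",  location = 0,    scale = 0))
  if (!is.null(distributions)) defaults[names(distributions)] <- distributions
  w <- as.numeric(phenotype_mixture)
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stopf("phenotype_mixture must be three nonnegative weights summing to 1")
  structure(list(distributions = defaults,
                 phenotype_mixture = stats::setNames(w, c("N", "A", "E")),
                 seed = as.integer(seed)),
            class = "population_spec")
}

draw_params_once <- function(dists) {
  vals <- lapply(dists, function(d) {
    switch(d$dist,
           normal  = stats::rnorm(1, d$location, d$scale),
           uniform = stats::runif(1, d$location, d$location + d$scale),
           fixed   = d$location,
           stopf("unknown distribution '%s'", d$dist))
  })
  vals
}

#' Sample a synthetic aorta population
#'
#' Draws `n` anatomies from a [population_spec()]. For each draw a phenotype
#' label is first sampled from the mixture; shape parameters are then
#' rejection-sampled from the per-parameter distributions until the
#' ground-truth phenotype matches the label, so labels follow the requested
#' mixture exactly in expectation while parameter draws stay within the
#' population's conditional distributions.
#'
#' @param spec a `population_spec`.
#' @param n number of anatomies (>= 1).
#' @param mesh generate surface meshes (default `TRUE`); with `FALSE` only
#'   parameters and labels are returned (fast).
#' @return A list with elements `meshes` (list of `surface_mesh` or `NULL`),
#'   `params` (list of `aorta_shape_params`) and `phenotype` (factor with
#'   levels N, A, E).
#' @export
sample_population <- function(spec, n, mesh = TRUE) {
  if (!inherits(spec, "population_spec")) stopf("spec must be a population_spec")
  n <- as.integer(n)
  if (n < 1L) stopf("n must be >= 1")
  with_seed(spec$seed, {
    labels <- sample(c("N", "A", "E"), n, replace = TRUE,
                     prob = spec$phenotype_mixture)
    params <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (tries in seq_len(5000L)) {
        v <- draw_params_once(spec$distributions)
        v$sov_amplitude <- abs(v$sov_amplitude)
        v$ovality <- min(max(v$ovality, 0), 0.3)
        p <- try(do.call(aorta_shape_params, v), silent = TRUE)
        if (inherits(p, "try-error")) next
        if (as.character(true_phenotype(p)) == labels[i]) { ok <- TRUE; break }
      }
      if (!ok) stopf("could not realize phenotype %s from the population spec",
                     labels[i])
      params[[i]] <- p
    }
    meshes <- if (mesh) {
      lapply(params, function(p) generate_aorta(p, seed = NULL))
    } else NULL
    list(meshes = meshes, params = params,
         phenotype = factor(labels, levels = c("N", "A", "E")))
  })
}

#' Write a sampled population to disk
#'
#' Writes each mesh as ASCII STL or PLY together with a JSON sidecar holding
#' the true shape parameters and phenotype.
#'
#' @param pop result of [sample_population()] (with meshes).
#' @param dir output directory (created if missing).
#' @param format `"stl"` or `"ply"`.
#' @return The output directory, invisibly.
#' @export
write_population <- function(pop, dir, format = c("stl", "ply")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(pop$params)) {
    stem <- file.path(dir, sprintf("aorta_%03d", i))
    if (!is.null(pop$meshes)) write_mesh(pop$meshes[[i]], paste0(stem, ".", format))
    meta <- c(unclass(pop$params[[i]]),
              list(phenotype = as.character(pop$phenotype[i])))
    jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}
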
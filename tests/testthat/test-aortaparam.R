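test_that("centerline extraction recovers the axis of a cylinder", {
  poly <- extract_centerline(fixture_cylinder())
  expect_lt(max(sqrt(rowSums(poly[, 1:2]^2))), 0.1)
})

test_that("centerline extraction rejects disjoint topology", {
  f1 <- function(s) cbind(0, 0, s * 50)
  f2 <- function(s) cbind(200, 0, s * 50)
  m1 <- tube_mesh(f1, function(s, th) rep(5, length(s)), 20, 16)
  m2 <- tube_mesh(f2, function(s, th) rep(5, length(s)), 20, 16)
  both <- surface_mesh(rbind(m1$vertices, m2$vertices),
                       rbind(m1$faces, m2$faces + nrow(m1$vertices)))
  expect_error(extract_centerline(both), "components")
})

test_that("extracted centerline of a synthetic arch stays close to the truth", {
  fx <- fixture_aorta()
  poly <- extract_centerline(fx$mesh)
  truth <- attr(fx$mesh, "centerline")(seq(0, 1, length.out = 4001))
  d <- aortacohort:::nn_dist(poly, truth)
  ## every extracted point lies within 1 mm of the true centerline except
  ## for a handful of stations at the arch transitions
  expect_lt(stats::median(d), 0.5)
  expect_lt(stats::quantile(d, 0.9), 1.0)
})

test_that("fit_centerline handles straight, circular and noisy inputs", {
  ## straight segment: residual ~ 0 and the spline is the segment
  pts <- cbind(0, 0, seq(0, 80, length.out = 30))
  cl <- fit_centerline(pts, 6)
  expect_lt(cl$residual, 1e-9)
  p <- centerline_eval(cl, seq(0, 1, length.out = 17))
  expect_lt(max(abs(p[, 1:2])), 1e-9)
  expect_equal(cl$length, 80, tolerance = 1e-6)

  ## quarter-circle arc: radial error below 0.1% of the radius
  R <- 50
  th <- seq(0, pi / 2, length.out = 60)
  arc <- cbind(R * cos(th), R * sin(th), 0)
  cla <- fit_centerline(arc, 10)
  pa <- centerline_eval(cla, seq(0.02, 0.98, length.out = 200))
  expect_lt(max(abs(sqrt(rowSums(pa[, 1:2]^2)) - R)), 0.001 * R)

  ## noisy arc: the regression residual reflects the noise scale
  noisy <- arc + withr::with_seed(4, matrix(rnorm(length(arc), sd = 0.5),
                                            ncol = 3))
  cln <- fit_centerline(noisy, 10)
  expect_gt(cln$residual, 0.5 * sqrt(3) * 0.55)  # 3-D rms of sd-0.5 noise ~ 0.87
  expect_lt(cln$residual, 0.5 * sqrt(3) * 1.45)

  expect_error(fit_centerline(arc[1:8, ], 10), "nderdetermined")
  expect_error(fit_centerline(arc, 3), "at least 4")
})

test_that("local frames are orthonormal, rotation-minimizing and continuous", {
  ## straight line: constant frame
  line <- cbind(0, 0, seq(0, 100, length.out = 30))
  cl <- fit_centerline(line, 6)
  for (s in c(0, 0.3, 0.9)) {
    fr <- frame_at(cl, s)
    expect_equal(fr$v1, c(1, 0, 0), tolerance = 1e-9)
    expect_equal(fr$v2, c(0, 1, 0), tolerance = 1e-9)
  }

  ## planar arc: v1 stays in the arc plane, v2 orthogonal to it
  R <- 40
  th <- seq(0, 2, length.out = 50)
  arc <- cbind(R * sin(th), 0, -R * cos(th))
  cla <- fit_centerline(arc, 10)
  for (s in seq(0.05, 0.95, length.out = 7)) {
    fr <- frame_at(cla, s)
    expect_lt(abs(fr$v1[2]), 1e-6)
    expect_gt(abs(fr$v2[2]), 1 - 1e-6)
    expect_lt(abs(sum(fr$t * fr$v1)), 1e-10)
    expect_lt(abs(sum(fr$t * fr$v2)), 1e-10)
    expect_lt(abs(sum(fr$v1 * fr$v2)), 1e-10)
    expect_equal(aortacohort:::pracma_cross(fr$t, fr$v1), fr$v2,
                 tolerance = 1e-9)
  }

  ## continuity: v1 angular jump between adjacent stations below 5 degrees
  cl2 <- fixture_aorta()$param$centerline
  fr <- aortacohort:::frames_at(cl2, seq(0, 1, length.out = 200))
  dots <- rowSums(fr$v1[-1, ] * fr$v1[-nrow(fr$v1), ])
  expect_gt(min(dots), cos(5 * pi / 180))
})

test_that("point projection recovers cylinder polar coordinates", {
  line <- cbind(0, 0, seq(0, 100, length.out = 30))
  cl <- fit_centerline(line, 6)
  for (phi in c(0.3, 2.0, 5.5)) {
    pp <- project_point(cl, c(12 * cos(phi), 12 * sin(phi), 37))
    expect_equal(pp$rho, 12, tolerance = 1e-6)
    expect_equal(pp$theta, phi, tolerance = 1e-6)
    expect_equal(pp$s, 0.37, tolerance = 1e-6)
  }
  on_axis <- project_point(cl, c(0, 0, 50))
  expect_equal(on_axis$rho, 0, tolerance = 1e-9)
  expect_identical(on_axis$theta, 0)
})

test_that("projection round-trips through the tube equation exactly", {
  cl <- fixture_aorta()$param$centerline
  set.seed(12)
  fr <- aortacohort:::frames_at(cl, runif(25, 0.05, 0.95))
  for (i in seq_len(25)) {
    rho0 <- runif(1, 5, 18); th0 <- runif(1, 0, 2 * pi)
    x <- fr$origin[i, ] + rho0 * (cos(th0) * fr$v1[i, ] + sin(th0) * fr$v2[i, ])
    pp <- project_point(cl, x)
    fr2 <- frame_at(cl, pp$s)
    back <- fr2$origin + pp$rho * (cos(pp$theta) * fr2$v1 +
                                     sin(pp$theta) * fr2$v2)
    expect_lt(sqrt(sum((back - x)^2)), 1e-6)
  }
})

test_that("wall fitting recovers known radius fields", {
  set.seed(3)
  n <- 900
  sm <- runif(n); th <- runif(n, 0, 2 * pi)
  ## constant radius: exact recovery, zero residual
  wc <- fit_wall(data.frame(s = sm, theta = th, rho = 7), n_s = 6)
  expect_lt(wc$residual, 1e-9)
  expect_equal(wall_eval(wc, c(0.1, 0.5, 0.9), c(0, 2, 4)), rep(7, 3),
               tolerance = 1e-9)

  ## rho = 10 + 2 cos(2 theta): periodic basis recovers the amplitude
  wp <- fit_wall(data.frame(s = sm, theta = th, rho = 10 + 2 * cos(2 * th)),
                 n_s = 6)
  expect_lt(wp$residual, 1e-8)
  expect_equal(wall_eval(wp, 0.5, 0) - wall_eval(wp, 0.5, pi / 2), 4,
               tolerance = 1e-8)

  ## literal cubic-in-theta basis is not periodic: the seam gap is reported
  wl <- fit_wall(data.frame(s = sm, theta = th, rho = 10 + cos(th)),
                 n_s = 6, mode = "literal")
  expect_gt(wl$seam_gap, 0.01)
  expect_lt(fit_wall(data.frame(s = sm, theta = th, rho = 10 + cos(th)),
                     n_s = 6)$seam_gap, 1e-9)

  expect_error(fit_wall(data.frame(s = sm[1:20], theta = th[1:20],
                                   rho = 7), n_s = 6), "samples")
})

test_that("parameterize/reconstruct round-trip meets the surface tolerance", {
  cyl <- fixture_cylinder()
  expect_lt(roundtrip_distance(cyl), 0.05)

  fx <- fixture_aorta()
  mean_radius <- mean(project_points(fx$param$centerline,
                                     fx$mesh$vertices)$rho)
  expect_lt(roundtrip_distance(fx$mesh, fx$param), 0.01 * mean_radius)
})

test_that("surface noise propagates to a comparable round-trip error", {
  p <- aorta_shape_params(surface_noise = 0.4)
  m <- generate_aorta(p, seed = 21)
  rt <- roundtrip_distance(m, parameterize(m))
  ## the fit averages noise out of the model, so the symmetric distance is
  ## of the order of the mean absolute deviation of the noise
  expect_gt(rt, 0.4 * 0.3)
  expect_lt(rt, 0.4 * 1.5)
})

test_that("reconstruction satisfies the tube equation and refines monotonically", {
  param <- fixture_aorta()$param
  n_s <- 32L; n_t <- 16L
  rec <- reconstruct(param, n_s, n_t)
  sg <- attr(rec, "s_grid")
  cl <- param$centerline
  alpha <- centerline_eval(cl, sg)
  v <- rec$vertices[seq_len(n_s * n_t), ]
  ctr <- alpha[rep(seq_len(n_s), each = n_t), ]
  rho_grid <- wall_eval(param$wall, rep(sg, each = n_t),
                        rep(seq(0, 2 * pi, length.out = n_t + 1)[-(n_t + 1)],
                            n_s))
  expect_lt(max(abs(sqrt(rowSums((v - ctr)^2)) - rho_grid)), 1e-9)

  d1 <- aortacohort:::mesh_distance(fixture_aorta()$mesh,
                                    reconstruct(param, 48, 24))
  d2 <- aortacohort:::mesh_distance(fixture_aorta()$mesh,
                                    reconstruct(param, 96, 48))
  expect_lte(d2, d1 + 1e-9)

  bad <- param
  bad$wall$coef[, 1] <- bad$wall$coef[, 1] - 50
  expect_error(reconstruct(bad), "non-positive wall radius")
})

test_that("flatten and unflatten are exact inverses", {
  param <- fixture_aorta()$param
  raw <- flatten(param)
  back <- unflatten(raw, param)
  expect_identical(back$centerline$coef, param$centerline$coef)
  expect_identical(back$wall$coef, param$wall$coef)
  expect_identical(flatten(back), raw)
  expect_error(unflatten(raw[-1], param), "length")
})

test_that("parameterizations survive a JSON round-trip", {
  param <- fixture_aorta()$param
  path <- withr::local_tempfile(fileext = ".json")
  write_param(param, path)
  back <- read_param(path)
  expect_equal(flatten(back), flatten(param), tolerance = 1e-12)
  s <- c(0.2, 0.6); th <- c(1, 4)
  expect_equal(wall_eval(back$wall, s, th), wall_eval(param$wall, s, th),
               tolerance = 1e-12)
})

test_that("mesh files round-trip through STL, PLY and OBJ", {
  m <- tube_mesh(function(s) cbind(0, 0, s * 30),
                 function(s, th) rep(4, length(s)), 16, 16)
  for (ext in c("stl", "ply", "obj")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, path)
    back <- read_mesh(path)
    expect_equal(nrow(back$faces), nrow(m$faces))
    ## same vertex set (STL deduplicates, order may differ); sort the
    ## rounded coordinates so ties below write precision cannot reorder
    canon <- function(V) {
      V <- round(V, 5)
      V[order(V[, 1], V[, 2], V[, 3]), ]
    }
    expect_equal(canon(m$vertices), canon(back$vertices), ignore_attr = TRUE)
  }
})
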
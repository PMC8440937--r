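test_that("a straight constant-radius tube is an exact cylinder", {
  cyl <- fixture_cylinder()
  ring <- cyl$vertices[seq_len(48 * 32), ]
  expect_equal(sqrt(rowSums(ring[, 1:2]^2)), rep(10, nrow(ring)),
               tolerance = 1e-12)
})

test_that("parameter validation rejects degenerate inputs", {
  expect_error(aorta_shape_params(r_valve = -1), "positive")
  expect_error(aorta_shape_params(n_axial = 8), ">= 16")
  expect_error(aorta_shape_params(sov_center = 0.2, sov_width = 0.1),
               "sov_center")
  expect_error(aorta_shape_params(ovality = 0.5), "ovality")
})

test_that("the sinus bulge raises the section semi-major axis by its amplitude", {
  p <- aorta_shape_params(sov_amplitude = 4, r_stj = 15, r_ma = 15,
                          ovality = 0)
  m <- generate_aorta(p)
  s_grid <- attr(m, "s_grid")
  rbase <- attr(m, "baseline_radius")
  section_major <- function(s_target) {
    i <- which.min(abs(s_grid - s_target))
    ring <- m$vertices[(i - 1) * 32 + 1:32, ]
    fr <- attr(m, "frames")
    d <- sweep(ring, 2, fr$origin[i, ])
    fit_ellipse(cbind(d %*% fr$v1[i, ], d %*% fr$v2[i, ]))$semi_major
  }
  s_c <- s_grid[which.min(abs(s_grid - p$sov_center))]
  measured_diff <- section_major(p$sov_center) - section_major(0.10)
  analytic_diff <- rbase(s_c) - rbase(s_grid[which.min(abs(s_grid - 0.10))])
  expect_equal(measured_diff, analytic_diff, tolerance = 1e-6)
  ## the analytic bulge height itself is close to the nominal 4 mm
  expect_gt(analytic_diff, 3)
})

test_that("ovality produces the expected ellipse axis ratio", {
  p <- aorta_shape_params(ovality = 0.2, sov_amplitude = 0)
  m <- generate_aorta(p)
  fr <- attr(m, "frames")
  for (i in c(10, 24, 40)) {
    ring <- m$vertices[(i - 1) * 32 + 1:32, ]
    d <- sweep(ring, 2, fr$origin[i, ])
    e <- fit_ellipse(cbind(d %*% fr$v1[i, ], d %*% fr$v2[i, ]))
    ## the cos(2*theta) modulation is elliptical to first order only, so
    ## the best-fit ellipse ratio sits within ~1% of (1+ov)/(1-ov)
    expect_equal(e$semi_major / e$semi_minor, 1.2 / 0.8, tolerance = 0.015)
  }
})

test_that("population sampling is reproducible and mixtures are honored", {
  spec <- population_spec(seed = 5)
  a <- sample_population(spec, 3)
  b <- sample_population(spec, 3)
  expect_identical(a$meshes[[2]]$vertices, b$meshes[[2]]$vertices)
  c2 <- sample_population(population_spec(seed = 6), 3)
  expect_false(isTRUE(all.equal(a$meshes[[1]]$vertices,
                                c2$meshes[[1]]$vertices)))
  ## degenerate mixture
  alln <- sample_population(population_spec(phenotype_mixture = c(1, 0, 0),
                                            seed = 2), 5, mesh = FALSE)
  expect_true(all(alln$phenotype == "N"))
})

test_that("phenotype label frequencies follow the requested mixture", {
  mix <- c(N = 0.115, A = 0.535, E = 0.35)
  counts <- c(N = 0, A = 0, E = 0)
  n_per <- 26
  seeds <- 101:108
  for (s in seeds) {
    pop <- sample_population(population_spec(phenotype_mixture = mix,
                                             seed = s), n_per, mesh = FALSE)
    counts <- counts + table(pop$phenotype)[names(counts)]
  }
  n_tot <- n_per * length(seeds)
  ## each frequency within 3 binomial standard errors of the mixture weight
  for (lab in names(mix)) {
    se <- sqrt(mix[lab] * (1 - mix[lab]) / n_tot)
    expect_lt(abs(counts[lab] / n_tot - mix[lab]), 3.5 * se)
  }
  ## labels match the ground-truth phenotype rule applied to the parameters
  pop <- sample_population(population_spec(seed = 31), 10, mesh = FALSE)
  relabel <- vapply(pop$params, function(p)
    as.character(aortacohort:::true_phenotype(p)), character(1))
  expect_identical(relabel, as.character(pop$phenotype))
})

test_that("biomarkers of noise-free meshes track the analytic generator profile", {
  pop <- fixture_pop()
  for (i in seq_along(pop$meshes)) {
    m <- pop$meshes[[i]]
    b <- compute_biomarkers(pop$fits[[i]])
    lm <- attr(b, "landmarks")
    rf <- attr(m, "baseline_radius")
    ov <- attr(m, "params")$ovality
    cf <- attr(m, "centerline")
    L <- attr(m, "length")
    ## oracle radius: semi-major axis of the best-fit ellipse of the exact
    ## analytic cross-section (the module's own measurement convention)
    th <- seq(0, 2 * pi, length.out = 257)[-257]
    truth_r <- vapply(c(lm$s_SoV, lm$s_PA, lm$s_MA, lm$s_PT, lm$s_PD),
                      function(s0) {
                        rho <- rf(s0) * (1 + ov * cos(2 * th))
                        fit_ellipse(cbind(rho * cos(th), rho * sin(th)))$semi_major
                      }, numeric(1))
    for (j in 1:5) expect_rel(as.numeric(b[j]), truth_r[j], 0.02)
    expect_rel(b[["LPD"]], lm$s_PD * L, 0.02)
    w_tru <- sqrt(sum((cf(lm$s_PA) - cf(lm$s_PD))^2))
    h_tru <- cf(lm$s_PT)[1, 3] - cf(lm$s_PA)[1, 3]
    tor_tru <- 1 - w_tru / (lm$s_PD * L)
    expect_rel(b[["tor"]], tor_tru, 0.02)
    ## station-alignment between the fitted and true arc-length scales
    ## leaves a slightly larger error on the arch extent measures
    expect_rel(b[["h"]], h_tru, 0.03)
    expect_rel(b[["w"]], w_tru, 0.03)
    ## mean curvature of a least-squares spline is upward-biased by
    ## curvature ringing; see the methods vignette
    expect_rel(b[["k"]], pi / ((lm$s_PD - lm$s_PA) * L), 0.15)
  }
})

test_that("population meshes and sidecar metadata round-trip through disk", {
  pop <- sample_population(population_spec(seed = 8), 2)
  dir <- withr::local_tempdir()
  write_population(pop, dir, format = "ply")
  m <- read_mesh(file.path(dir, "aorta_001.ply"))
  expect_equal(m$vertices, pop$meshes[[1]]$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "aorta_002.json"))
  expect_equal(meta$phenotype, as.character(pop$phenotype[2]))
})
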
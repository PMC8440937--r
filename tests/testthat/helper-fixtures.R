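## Shared fixtures, built once per test run and cached. Everything is
## generated in code; no stored data.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

## straight cylinder tube, radius 10, length 100
fixture_cylinder <- function() memo("cylinder", function() {
  fn <- function(s) cbind(0, 0, s * 100)
  attr(fn, "deriv") <- function(s) cbind(0, 0, rep(100, length(s)))
  tube_mesh(fn, function(s, th) rep(10, length(s)),
            n_axial = 48, n_circumferential = 32)
})

## one default synthetic aorta with its parameterization
fixture_aorta <- function() memo("aorta", function() {
  m <- generate_aorta(aorta_shape_params())
  list(mesh = m, param = parameterize(m))
})

## a small noise-free synthetic population with parameterizations
fixture_pop <- function() memo("pop", function() {
  pop <- sample_population(population_spec(seed = 42), 6)
  pop$fits <- lapply(pop$meshes, parameterize)
  pop
})

## the full-size 26-anatomy reference cohort used by the experiment tests
fixture_reference <- function() memo("reference26", function() {
  synthetic_reference(experiment_config(n_ref = 26, seed = 1))
})

## small feature-vector cloud with known structure
fixture_cloud <- function(K = 40, n = 5, seed = 99) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * n), n)
    matrix(rnorm(K * n), K) %*% A
  })
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
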
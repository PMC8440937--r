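## Feature-space sampling strategies. Every sampler is a pure function of
## (inputs, seed) and returns a K x n matrix of feature vectors with a
## `provenance` attribute.

as_cohort <- function(X, provenance, seed = NULL) {
  X <- as.matrix(X)
  attr(X, "provenance") <- provenance
  attr(X, "seed") <- seed
  X
}

#' Coordinate-wise bootstrap sampling
#'
#' Each coordinate of every generated feature vector is drawn independently
#' and uniformly from the observed values of that coordinate in the
#' reference cohort. This is the literal resampling construction; it
#' preserves marginals but destroys inter-mode correlation. Set
#' `joint = TRUE` to resample whole vectors instead.
#'
#' @param reference matrix of reference feature vectors (rows).
#' @param K number of samples (>= 1).
#' @param seed integer seed.
#' @param joint resample whole rows rather than coordinates.
#' @return A `K x n` cohort matrix, provenance `"bootstrap"`.
#' @export
bootstrap_sample <- function(reference, K, seed = NULL, joint = FALSE) {
  reference <- as.matrix(reference)
  if (nrow(reference) < 1L) stopf("reference cohort is empty")
  if (K <= 0) stopf("K must be positive")
  with_seed(seed, {
    X <- if (joint) {
      reference[sample.int(nrow(reference), K, replace = TRUE), , drop = FALSE]
    } else {
      apply(reference, 2, function(col) col[sample.int(length(col), K, replace = TRUE)])
    }
    if (K == 1L) X <- matrix(X, nrow = 1)
    as_cohort(X, "bootstrap", seed)
  })
}

#' Multivariate Gaussian sampling
#'
#' `fit_gaussian()` estimates the sample mean and sample covariance
#' (denominator K0 - 1) of the reference cohort; `gaussian_sample()` draws
#' from `N(mean, cov)` via a symmetric eigen factorization, clipping any
#' numerically negative eigenvalues at zero (flagged in attribute
#' `clipped`).
#'
#' @param reference matrix of reference feature vectors (>= 2 rows).
#' @return `fit_gaussian()`: list with `mean`, `cov`.
#' @export
fit_gaussian <- function(reference) {
  reference <- as.matrix(reference)
  if (nrow(reference) < 2L) stopf("need at least 2 reference vectors")
  list(mean = colMeans(reference), cov = stats::cov(reference))
}

#' @rdname fit_gaussian
#' @param params list with `mean` and `cov`.
#' @param K number of samples.
#' @param seed integer seed.
#' @export
gaussian_sample <- function(params, K, seed = NULL) {
  if (K <= 0) stopf("K must be positive")
  ev <- eigen(params$cov, symmetric = TRUE)
  clipped <- any(ev$values < 0)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam), length(lam))
  with_seed(seed, {
    Z <- matrix(stats::rnorm(K * length(params$mean)), K)
    X <- sweep(Z %*% t(A), 2, params$mean, "+")
    X <- as_cohort(X, "gaussian", seed)
    attr(X, "clipped") <- clipped
    X
  })
}

#' Independent uniform sampling over the observed box
#'
#' `fit_uniform()` takes the per-coordinate sample minima and maxima of the
#' reference cohort; `uniform_sample()` draws each coordinate independently
#' and uniformly on its `[lower, upper]` interval.
#'
#' @param reference matrix of reference feature vectors.
#' @return `fit_uniform()`: list with `lower`, `upper`.
#' @export
fit_uniform <- function(reference) {
  reference <- as.matrix(reference)
  list(lower = apply(reference, 2, min), upper = apply(reference, 2, max))
}

#' @rdname fit_uniform
#' @param bounds list with `lower`, `upper`.
#' @param K number of samples.
#' @param seed integer seed.
#' @export
uniform_sample <- function(bounds, K, seed = NULL) {
  if (K <= 0) stopf("K must be positive")
  if (any(bounds$lower > bounds$upper)) stopf("lower bound exceeds upper bound")
  n <- length(bounds$lower)
  with_seed(seed, {
    U <- matrix(stats::runif(K * n), K)
    X <- sweep(sweep(U, 2, bounds$upper - bounds$lower, "*"), 2,
               bounds$lower, "+")
    as_cohort(X, "uniform", seed)
  })
}

#' Draw a cohort with a named sampling strategy
#'
#' Dispatch helper used by the experiment drivers: fits the chosen sampler
#' on the reference cohort and draws `K` feature vectors.
#'
#' @param method one of `"bootstrap"`, `"gaussian"`, `"uniform"`, `"gan"`.
#' @param reference matrix of reference feature vectors.
#' @param K number of samples.
#' @param seed integer seed.
#' @param gan_epochs,gan_batch GAN training schedule (see [gan_train()]).
#' @return A cohort matrix with provenance attribute.
#' @export
draw_cohort <- function(method = c("bootstrap", "gaussian", "uniform", "gan"),
                        reference, K, seed = NULL, gan_epochs = 2000L,
                        gan_batch = 5L) {
  method <- match.arg(method)
  switch(method,
    bootstrap = bootstrap_sample(reference, K, seed),
    gaussian = gaussian_sample(fit_gaussian(reference), K, seed),
    uniform = uniform_sample(fit_uniform(reference), K, seed),
    gan = {
      model <- gan_train(reference, epochs = gan_epochs, batch = gan_batch,
                         seed = seed)
      gan_sample(model, K, seed = child_seed(seed %||% 0L, 17L))
    })
}
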
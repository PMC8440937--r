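## PCA shape space over flattened parameterizations: mean raw vector plus
## orthonormal deformation modes; anatomies are encoded as low-dimensional
## mode-coefficient feature vectors and decoded back to raw coefficients.

#' Build a PCA shape space
#'
#' Centered principal component analysis of raw coefficient vectors. Modes
#' are the right singular directions of the centered data matrix; per-mode
#' variances are `singular_value^2 / (K - 1)`. The sign of each mode is fixed
#' so that its largest-magnitude loading is positive, making the space
#' deterministic across platforms.
#'
#' @param raw_vectors matrix with one raw coefficient vector per row (or a
#'   list of equal-length vectors), `K >= 2` rows.
#' @param template optional `aorta_param` template carried along so that
#'   decoded vectors can be unflattened.
#' @return A `shape_space`: list with `mean`, `modes` (columns orthonormal),
#'   `variances` (nonincreasing), `K` and `template`.
#' @export
build_shape_space <- function(raw_vectors, template = NULL) {
  if (is.list(raw_vectors) && !is.matrix(raw_vectors)) {
    len <- lengths(raw_vectors)
    if (length(unique(len)) != 1L) stopf("raw vectors differ in length")
    raw_vectors <- do.call(rbind, raw_vectors)
  }
  X <- as.matrix(raw_vectors)
  if (nrow(X) < 2L) stopf("need at least 2 vectors")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  keep <- seq_len(min(nrow(X) - 1L, ncol(X)))
  modes <- sv$v[, keep, drop = FALSE]
  flip <- apply(modes, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  modes <- sweep(modes, 2, flip, "*")
  variances <- sv$d[keep]^2 / (nrow(X) - 1L)
  structure(list(mean = mu, modes = modes, variances = variances,
                 K = nrow(X), template = template),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cum <- cumsum(x$variances) / sum(x$variances)
  cat(sprintf("shape_space: %d training shapes, raw dimension %d, %d modes\n",
              x$K, length(x$mean), length(x$variances)))
  cat(sprintf("  modes for 95%% variance: %d\n", choose_dim(x, 0.95)))
  invisible(x)
}

#' Encode and decode feature vectors
#'
#' `encode()` projects a raw vector (mean-subtracted) onto the first `n`
#' deformation modes; `decode()` maps mode coefficients back to a raw vector
#' as mean + linear combination of modes.
#'
#' @param space a `shape_space`.
#' @param raw numeric raw vector, or a matrix with one vector per row.
#' @param n number of modes (default: all).
#' @param fv numeric feature vector (mode coefficients), or a matrix with
#'   one per row.
#' @return `encode()`: feature vector(s); `decode()`: raw vector(s). Matrix
#'   in, matrix out.
#' @export
encode <- function(space, raw, n = NULL) {
  n <- n %||% ncol(space$modes)
  if (n > ncol(space$modes))
    stopf("n = %d exceeds available modes (%d)", n, ncol(space$modes))
  mat <- is.matrix(raw)
  X <- if (mat) raw else matrix(raw, nrow = 1)
  A <- sweep(X, 2, space$mean) %*% space$modes[, seq_len(n), drop = FALSE]
  if (mat) A else drop(A)
}

#' @rdname encode
#' @export
decode <- function(space, fv) {
  mat <- is.matrix(fv)
  A <- if (mat) fv else matrix(fv, nrow = 1)
  n <- ncol(A)
  if (n > ncol(space$modes))
    stopf("feature dimension %d exceeds available modes (%d)", n,
          ncol(space$modes))
  X <- sweep(A %*% t(space$modes[, seq_len(n), drop = FALSE]), 2,
             space$mean, "+")
  if (mat) X else drop(X)
}

#' Choose the shape-space dimensionality
#'
#' Smallest number of modes whose cumulative explained-variance ratio
#' reaches `fraction` (default 0.95).
#'
#' @param space a `shape_space`.
#' @param fraction target explained-variance fraction in `(0, 1]`.
#' @return Integer number of modes.
#' @export
choose_dim <- function(space, fraction = 0.95) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  tot <- sum(space$variances)
  if (tot == 0) return(1L)
  cum <- cumsum(space$variances) / tot
  as.integer(which(cum >= fraction - 1e-12)[1])
}

#' Decode a feature vector to a parameterization
#'
#' Convenience composition of [decode()] and [unflatten()] using the
#' template stored in the shape space.
#'
#' @param space a `shape_space` built with a template.
#' @param fv a feature vector.
#' @return An `aorta_param`.
#' @export
decode_param <- function(space, fv) {
  if (is.null(space$template)) stopf("shape space has no template")
  unflatten(decode(space, fv), space$template)
}

#' Write a cohort of feature vectors as CSV
#'
#' Columns `a1..an` plus a `provenance` column.
#'
#' @param cohort matrix of feature vectors (one per row) with attribute
#'   `provenance`, as returned by the samplers.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  names(df) <- paste0("a", seq_len(ncol(cohort)))
  df$provenance <- attr(cohort, "provenance") %||% "unknown"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
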
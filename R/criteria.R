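## Acceptance criteria: per-biomarker interval rules (observed range,
## Gaussian two-sigma, unimodal Chebyshev M +/- 3B), the aortic-root
## phenotype rule, and intersections. Every criterion evaluates a
## biomarker set to 0/1.

#' Half-sample mode
#'
#' Robust mode estimator for continuous samples: recursively keeps the
#' shortest half of the sorted sample until at most three points remain.
#' Deterministic, no bandwidth choice.
#'
#' @param x numeric vector.
#' @return The mode estimate.
#' @export
half_sample_mode <- function(x) {
  x <- sort(x[is.finite(x)])
  while (length(x) > 3L) {
    n <- length(x)
    h <- ceiling(n / 2)
    widths <- x[h:n] - x[1:(n - h + 1L)]
    i <- which.min(widths)
    x <- x[i:(i + h - 1L)]
  }
  if (length(x) == 3L) {
    if (x[2] - x[1] < x[3] - x[2]) mean(x[1:2])
    else if (x[3] - x[2] < x[2] - x[1]) mean(x[2:3])
    else x[2]
  } else mean(x)
}

#' Chebyshev bound parameter for unimodal distributions
#'
#' `B = sqrt(sigma^2 + (mu - M)^2)`; for a unimodal distribution the
#' interval `M +/- 3B` contains at least 95% of the probability mass.
#'
#' @param mu mean.
#' @param M mode.
#' @param sigma standard deviation.
#' @return The bound `B`, in the units of the inputs.
#' @export
chebyshev_bound <- function(mu, M, sigma) sqrt(sigma^2 + (mu - M)^2)

#' Per-biomarker summary statistics for criterion construction
#'
#' Computes, per column of a biomarker table: sample mean and standard
#' deviation (denominator n-1), half-sample mode, the unimodal Chebyshev
#' bound `B`, and the observed minimum and maximum.
#'
#' @param table data frame of biomarkers (rows = anatomies).
#' @return A `criterion_stats` data frame with columns `mu`, `M`, `sigma`,
#'   `B`, `lower`, `upper` and one row per biomarker; constant columns are
#'   flagged in attribute `constant`.
#' @export
estimate_stats <- function(table) {
  table <- as.data.frame(table)
  if (nrow(table) < 3L) stopf("need at least 3 rows to estimate statistics")
  mu <- vapply(table, mean, numeric(1))
  sigma <- vapply(table, stats::sd, numeric(1))
  M <- vapply(table, half_sample_mode, numeric(1))
  const <- sigma == 0
  M[const] <- mu[const]
  B <- chebyshev_bound(mu, M, sigma)
  out <- data.frame(mu = mu, M = M, sigma = sigma, B = B,
                    lower = vapply(table, min, numeric(1)),
                    upper = vapply(table, max, numeric(1)),
                    row.names = names(table))
  attr(out, "constant") <- names(table)[const]
  class(out) <- c("criterion_stats", "data.frame")
  out
}

new_interval_criterion <- function(kind, intervals, stats = NULL) {
  structure(list(kind = kind, intervals = intervals, stats = stats),
            class = "acceptance_criterion")
}

#' Build interval acceptance criteria from summary statistics
#'
#' `range_criterion()` accepts an anatomy whose biomarkers all lie within
#' the observed `[min, max]` ranges; `gaussian_criterion()` uses
#' `mu +/- 2*sigma`; `chebyshev_criterion()` uses the unimodal Chebyshev
#' interval `M +/- 3B`. All interval endpoints are inclusive.
#'
#' @param stats a `criterion_stats` object from [estimate_stats()].
#' @return An `acceptance_criterion`.
#' @export
range_criterion <- function(stats) {
  new_interval_criterion("range", cbind(lower = stats$lower, upper = stats$upper) |>
                           `rownames<-`(rownames(stats)), stats)
}

#' @rdname range_criterion
#' @export
gaussian_criterion <- function(stats) {
  iv <- cbind(lower = stats$mu - 2 * stats$sigma,
              upper = stats$mu + 2 * stats$sigma)
  rownames(iv) <- rownames(stats)
  new_interval_criterion("gaussian2sigma", iv, stats)
}

#' @rdname range_criterion
#' @export
chebyshev_criterion <- function(stats) {
  iv <- cbind(lower = stats$M - 3 * stats$B, upper = stats$M + 3 * stats$B)
  rownames(iv) <- rownames(stats)
  new_interval_criterion("chebyshev3B", iv, stats)
}

#' Aortic-root phenotype classification
#'
#' The three disjoint root phenotypes from the radii at the sinuses of
#' Valsalva (SoV), the sinotubular junction (PA) and the mid-ascending aorta
#' (MA):
#' \itemize{
#'   \item N: `SoV > PA` and `SoV >= MA`
#'   \item A: `SoV > PA` and `SoV < MA`
#'   \item E: `SoV <= PA`
#' }
#'
#' @param b named numeric with elements `SoV`, `PA`, `MA` (a
#'   `biomarker_set` works).
#' @return A factor with levels `N`, `A`, `E`.
#' @export
classify_phenotype <- function(b) {
  sov <- b[["SoV"]]; pa <- b[["PA"]]; ma <- b[["MA"]]
  lab <- if (sov <= pa) "E" else if (sov >= ma) "N" else "A"
  factor(lab, levels = c("N", "A", "E"))
}

#' Phenotype acceptance criterion
#'
#' Accepts an anatomy iff its aortic-root phenotype equals `label`.
#'
#' @param label one of `"N"`, `"A"`, `"E"`.
#' @return An `acceptance_criterion`.
#' @export
phenotype_criterion <- function(label = c("N", "A", "E")) {
  label <- match.arg(label)
  structure(list(kind = "phenotype", label = label),
            class = "acceptance_criterion")
}

#' Intersection of acceptance criteria
#'
#' The intersection accepts iff every child accepts.
#'
#' @param ... `acceptance_criterion` objects.
#' @return An `acceptance_criterion` of kind `"intersection"`.
#' @export
intersect_criteria <- function(...) {
  children <- list(...)
  stopifnot(all(vapply(children, inherits, logical(1), "acceptance_criterion")))
  structure(list(kind = "intersection", children = children),
            class = "acceptance_criterion")
}

#' Evaluate an acceptance criterion
#'
#' @param criterion an `acceptance_criterion`.
#' @param b a `biomarker_set` (named numeric) or a data frame of biomarkers
#'   (one row per anatomy).
#' @return Integer 0/1, vectorized over data-frame rows.
#' @export
accept <- function(criterion, b) {
  if (is.data.frame(b)) {
    return(switch(criterion$kind,
      phenotype = {
        lab <- ifelse(b$SoV <= b$PA, "E", ifelse(b$SoV >= b$MA, "N", "A"))
        as.integer(lab == criterion$label)
      },
      intersection = {
        out <- rep(1L, nrow(b))
        for (ch in criterion$children) out <- pmin(out, accept(ch, b))
        out
      },
      {
        iv <- criterion$intervals
        nm <- rownames(iv)
        if (!all(nm %in% names(b)))
          stopf("biomarker table lacks: %s",
                paste(setdiff(nm, names(b)), collapse = ", "))
        v <- as.matrix(b[, nm, drop = FALSE])
        ok <- sweep(v, 2, iv[, "lower"], ">=") & sweep(v, 2, iv[, "upper"], "<=")
        as.integer(rowSums(ok) == length(nm))
      }))
  }
  switch(criterion$kind,
    phenotype = as.integer(as.character(classify_phenotype(b)) == criterion$label),
    intersection = {
      for (ch in criterion$children) if (accept(ch, b) == 0L) return(0L)
      1L
    },
    { # interval kinds
      iv <- criterion$intervals
      nm <- rownames(iv)
      if (!all(nm %in% names(b)))
        stopf("biomarker set lacks: %s",
              paste(setdiff(nm, names(b)), collapse = ", "))
      v <- as.numeric(b[nm])
      as.integer(all(v >= iv[, "lower"] & v <= iv[, "upper"]))
    })
}

#' @export
print.acceptance_criterion <- function(x, ...) {
  cat(sprintf("acceptance_criterion: %s\n", x$kind))
  if (!is.null(x$intervals)) {
    print(round(x$intervals, 3))
  } else if (x$kind == "phenotype") {
    cat(sprintf("  target phenotype: %s\n", x$label))
  } else if (x$kind == "intersection") {
    cat(sprintf("  %d children: %s\n", length(x$children),
                paste(vapply(x$children, `[[`, "", "kind"), collapse = " & ")))
  }
  invisible(x)
}

#' Serialize and restore criteria as JSON
#'
#' @param criterion an `acceptance_criterion`.
#' @param path JSON file path.
#' @export
write_criterion <- function(criterion, path) {
  enc <- function(cr) {
    if (cr$kind == "intersection")
      list(kind = "intersection", children = lapply(cr$children, enc))
    else if (cr$kind == "phenotype") list(kind = "phenotype", label = cr$label)
    else list(kind = cr$kind, biomarkers = rownames(cr$intervals),
              lower = cr$intervals[, "lower"], upper = cr$intervals[, "upper"])
  }
  jsonlite::write_json(enc(criterion), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_criterion
#' @export
read_criterion <- function(path) {
  dec <- function(o) {
    if (o$kind == "intersection")
      do.call(intersect_criteria, lapply(o$children, dec))
    else if (o$kind == "phenotype") phenotype_criterion(o$label)
    else {
      iv <- cbind(lower = unlist(o$lower), upper = unlist(o$upper))
      rownames(iv) <- unlist(o$biomarkers)
      new_interval_criterion(o$kind, iv)
    }
  }
  dec(jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE))
}
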
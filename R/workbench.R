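## Experiment workbench: builds a reference cohort and its shape space,
## runs the sampling strategies, evaluates acceptance criteria, and emits
## efficiency reports for the three experiment families (data-driven,
## clinically-driven, two-stage surrogate screening).

#' Experiment configuration
#'
#' Collects the sizes, seeds and options of the experiment drivers. The
#' defaults mirror the reference study design (26 reference anatomies,
#' data-driven cohorts of 3000, clinically-driven cohorts of 1000 per
#' phenotype, a bootstrap base cohort of 3000, surrogate training set of
#' 15000); all sizes scale down for quick runs.
#'
#' @param n_ref reference cohort size.
#' @param K1 generated cohort size (data-driven).
#' @param K1_phenotype generated cohort size per phenotype.
#' @param K_bootstrap size of the bootstrap base cohort used to build
#'   per-phenotype references.
#' @param n_train,n_eval surrogate training and held-out evaluation sizes.
#' @param n_modes shape-space dimensionality. The default of 16 modes
#'   matches the study design and keeps the aortic-root detail that drives
#'   the phenotype rules; `NULL` selects the smallest dimension explaining
#'   95% of the raw-coefficient variance, which on synthetic cohorts is
#'   dominated by the large centerline coefficients and can be much
#'   smaller.
#' @param samplers subset of `c("bootstrap", "gaussian", "uniform", "gan")`.
#' @param gan_epochs,gan_batch GAN training schedule.
#' @param seed master seed; all internal draws derive child seeds from it.
#' @param mww_alpha significance level of the rank-sum fidelity test.
#' @param bonferroni apply a Bonferroni correction across the 11 biomarkers.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_ref = 26L, K1 = 3000L, K1_phenotype = 1000L,
                              K_bootstrap = 3000L, n_train = 15000L,
                              n_eval = 3000L, n_modes = 16L,
                              samplers = c("bootstrap", "gaussian",
                                           "uniform", "gan"),
                              gan_epochs = 2000L, gan_batch = 5L, seed = 1L,
                              mww_alpha = 0.05, bonferroni = FALSE) {
  if (K1 < 1L || K1_phenotype < 1L) stopf("cohort sizes must be >= 1")
  samplers <- match.arg(samplers, several.ok = TRUE)
  structure(list(n_ref = as.integer(n_ref), K1 = as.integer(K1),
                 K1_phenotype = as.integer(K1_phenotype),
                 K_bootstrap = as.integer(K_bootstrap),
                 n_train = as.integer(n_train), n_eval = as.integer(n_eval),
                 n_modes = n_modes, samplers = samplers,
                 gan_epochs = as.integer(gan_epochs),
                 gan_batch = as.integer(gan_batch), seed = as.integer(seed),
                 mww_alpha = mww_alpha, bonferroni = bonferroni),
            class = "experiment_config")
}

#' Build a synthetic reference cohort and its shape space
#'
#' Samples `n_ref` anatomies from the synthetic population, parameterizes
#' each mesh, builds the PCA shape space over the flattened coefficients and
#' encodes the reference cohort.
#'
#' @param config an [experiment_config()].
#' @param population optional [population_spec()] (default built from the
#'   config seed).
#' @return A `reference_cohort`: list with `space`, `features` (reference
#'   feature vectors), `biomarkers` (reference biomarker table), `params`,
#'   `phenotype` and `n_modes`.
#' @export
synthetic_reference <- function(config = experiment_config(),
                                population = NULL) {
  population <- population %||% population_spec(seed = child_seed(config$seed, 1L))
  pop <- sample_population(population, config$n_ref)
  params <- lapply(pop$meshes, parameterize)
  raw <- do.call(rbind, lapply(params, flatten))
  space <- build_shape_space(raw, template = params[[1]])
  n_modes <- min(config$n_modes %||% choose_dim(space, 0.95),
                 ncol(space$modes))
  features <- encode(space, raw, n = n_modes)
  bio <- biomarker_table(params)
  structure(list(space = space, features = features, biomarkers = bio,
                 params = params, phenotype = pop$phenotype,
                 n_modes = as.integer(n_modes)),
            class = "reference_cohort")
}

#' @export
print.reference_cohort <- function(x, ...) {
  cat(sprintf("reference_cohort: %d anatomies, %d shape modes (phenotypes: %s)\n",
              nrow(x$features), x$n_modes,
              paste(sprintf("%s=%d", levels(x$phenotype), table(x$phenotype)),
                    collapse = " ")))
  invisible(x)
}

#' Biomarkers of a feature-vector cohort
#'
#' Decodes every feature vector through the shape space, reconstructs its
#' parameterization and computes the 11 biomarkers. Vectors whose decoded
#' geometry is invalid (non-positive wall radius, landmark failure) yield
#' `NA` rows and are flagged; the acceptance machinery counts them as
#' rejected.
#'
#' @param space a `shape_space` with template.
#' @param cohort matrix of feature vectors (rows).
#' @return List with `table` (data frame, `NA` rows for failures) and `ok`
#'   (logical vector).
#' @export
cohort_biomarkers <- function(space, cohort) {
  cohort <- as.matrix(cohort)
  n <- nrow(cohort)
  tab <- matrix(NA_real_, n, length(BIOMARKER_NAMES),
                dimnames = list(NULL, BIOMARKER_NAMES))
  ok <- logical(n)
  for (i in seq_len(n)) {
    b <- tryCatch(compute_biomarkers(unflatten(decode(space, cohort[i, ]),
                                               space$template)),
                  error = function(e) NULL)
    if (!is.null(b)) { tab[i, ] <- as.numeric(b); ok[i] <- TRUE }
  }
  list(table = as.data.frame(tab), ok = ok)
}

#' Acceptance efficiency of a cohort
#'
#' Fraction of the generated cohort accepted by a criterion (the efficiency
#' ratio `e = |{a in C1 : A(a) = 1}| / K1`). Decoding failures count as
#' rejections and are reported in the `failures` attribute.
#'
#' @param space a `shape_space` with template.
#' @param cohort matrix of feature vectors.
#' @param criterion an `acceptance_criterion`.
#' @param biomarkers optional precomputed [cohort_biomarkers()] result.
#' @return Efficiency in `[0, 1]` with attribute `failures`.
#' @export
efficiency <- function(space, cohort, criterion, biomarkers = NULL) {
  bm <- biomarkers %||% cohort_biomarkers(space, cohort)
  dec <- integer(nrow(bm$table))
  if (any(bm$ok))
    dec[bm$ok] <- accept(criterion, bm$table[bm$ok, , drop = FALSE])
  e <- mean(dec)
  attr(e, "failures") <- sum(!bm$ok)
  e
}

#' Distribution-fidelity rank-sum test
#'
#' Two-sided Mann-Whitney-Wilcoxon test per biomarker comparing a generated
#' cohort with the reference cohort; reports which biomarker distributions
#' differ at level `alpha` and the conventional "x / 11 reject H0" summary.
#'
#' @param generated,reference biomarker data frames.
#' @param alpha significance level (default 0.05).
#' @param bonferroni divide `alpha` by the number of biomarkers.
#' @return Data frame with `biomarker`, `p`, `reject`; attribute `summary`.
#' @export
mww_fidelity <- function(generated, reference, alpha = 0.05,
                         bonferroni = FALSE) {
  nm <- intersect(names(reference), names(generated))
  thr <- if (bonferroni) alpha / length(nm) else alpha
  p <- vapply(nm, function(v) {
    g <- generated[[v]]; g <- g[is.finite(g)]
    if (length(g) == 0) return(NA_real_)
    suppressWarnings(stats::wilcox.test(g, reference[[v]])$p.value)
  }, numeric(1))
  out <- data.frame(biomarker = nm, p = p, reject = !is.na(p) & p < thr)
  attr(out, "summary") <- sprintf("%d / %d reject H0", sum(out$reject),
                                  length(nm))
  out
}

sampler_cohort <- function(method, reference_features, K, config, k) {
  draw_cohort(method, reference_features, K,
              seed = child_seed(config$seed, k),
              gan_epochs = config$gan_epochs, gan_batch = config$gan_batch)
}

#' Data-driven cohort-generation experiment
#'
#' Builds (or reuses) a synthetic reference cohort, fits the three
#' data-driven acceptance criteria on its biomarkers, generates a cohort of
#' `K1` feature vectors with each sampling strategy, and reports per-sampler
#' efficiencies and the rank-sum fidelity summary.
#'
#' @param config an [experiment_config()].
#' @param reference optional precomputed [synthetic_reference()].
#' @return An `efficiency_report` with a `table` (rows = samplers; columns
#'   `Ar`, `Amu`, `AM`, `mww`), the criteria, and per-sampler biomarker
#'   tables.
#' @export
run_data_driven <- function(config = experiment_config(), reference = NULL) {
  ref <- reference %||% synthetic_reference(config)
  st <- estimate_stats(ref$biomarkers)
  crit <- list(Ar = range_criterion(st), Amu = gaussian_criterion(st),
               AM = chebyshev_criterion(st))
  rows <- list(); bios <- list(); cohorts <- list()
  for (i in seq_along(config$samplers)) {
    m <- config$samplers[i]
    cohort <- sampler_cohort(m, ref$features, config$K1, config, 100L + i)
    bm <- cohort_biomarkers(ref$space, cohort)
    e <- vapply(crit, function(cr) as.numeric(efficiency(ref$space, cohort,
                                                         cr, bm)), numeric(1))
    mww <- mww_fidelity(bm$table[bm$ok, , drop = FALSE], ref$biomarkers,
                        config$mww_alpha, config$bonferroni)
    rows[[m]] <- data.frame(method = m, Ar = e[["Ar"]], Amu = e[["Amu"]],
                            AM = e[["AM"]], mww = attr(mww, "summary"),
                            failures = attr(efficiency(ref$space, cohort,
                                                       crit$Ar, bm), "failures"))
    bios[[m]] <- bm; cohorts[[m]] <- cohort
  }
  structure(list(kind = "data-driven",
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 criteria = crit, reference = ref, biomarkers = bios,
                 cohorts = cohorts, config = config),
            class = "efficiency_report")
}

#' Clinically-driven cohort-generation experiment
#'
#' Builds a bootstrap base cohort from the reference features, splits it by
#' aortic-root phenotype into per-phenotype reference cohorts, then for each
#' target phenotype and sampler generates `K1_phenotype` vectors and
#' evaluates: the three data-driven criteria (anchored on the original
#' reference sample), the three phenotype fractions (a confusion-style
#' block whose diagonal is the clinically-driven efficiency), and the three
#' intersection criteria.
#'
#' @inheritParams run_data_driven
#' @return An `efficiency_report` whose `table` has one row per
#'   (sampler, target phenotype).
#' @export
run_clinically_driven <- function(config = experiment_config(),
                                  reference = NULL) {
  ref <- reference %||% synthetic_reference(config)
  st <- estimate_stats(ref$biomarkers)
  dd <- list(Ar = range_criterion(st), Amu = gaussian_criterion(st),
             AM = chebyshev_criterion(st))
  CB <- bootstrap_sample(ref$features, config$K_bootstrap,
                         seed = child_seed(config$seed, 2L))
  bmB <- cohort_biomarkers(ref$space, CB)
  phB <- rep(NA_character_, nrow(CB))
  okB <- bmB$ok
  phB[okB] <- ifelse(bmB$table$SoV[okB] <= bmB$table$PA[okB], "E",
                     ifelse(bmB$table$SoV[okB] >= bmB$table$MA[okB], "N", "A"))
  rows <- list()
  k <- 200L
  for (X in c("N", "A", "E")) {
    refX <- CB[!is.na(phB) & phB == X, , drop = FALSE]
    if (nrow(refX) < 2L)
      stopf("phenotype %s has %d members in the bootstrap base cohort",
            X, nrow(refX))
    for (m in config$samplers) {
      k <- k + 1L
      cohort <- sampler_cohort(m, refX, config$K1_phenotype, config, k)
      bm <- cohort_biomarkers(ref$space, cohort)
      e_dd <- vapply(dd, function(cr) as.numeric(efficiency(ref$space, cohort,
                                                            cr, bm)),
                     numeric(1))
      e_ph <- vapply(c("N", "A", "E"), function(lab) {
        as.numeric(efficiency(ref$space, cohort, phenotype_criterion(lab), bm))
      }, numeric(1))
      e_int <- vapply(names(dd), function(a) {
        as.numeric(efficiency(ref$space, cohort,
                              intersect_criteria(dd[[a]],
                                                 phenotype_criterion(X)), bm))
      }, numeric(1))
      rows[[paste(m, X)]] <- data.frame(
        method = m, phenotype = X,
        Ar = e_dd[["Ar"]], Amu = e_dd[["Amu"]], AM = e_dd[["AM"]],
        A_N = e_ph[["N"]], A_A = e_ph[["A"]], A_E = e_ph[["E"]],
        Ar_int = e_int[["Ar"]], Amu_int = e_int[["Amu"]],
        AM_int = e_int[["AM"]], failures = sum(!bm$ok))
    }
  }
  structure(list(kind = "clinically-driven",
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 criteria = dd, reference = ref,
                 base_cohort_phenotypes = table(factor(phB, c("N", "A", "E"))),
                 config = config),
            class = "efficiency_report")
}

#' Two-stage surrogate-screened generation experiment
#'
#' Trains the binary acceptance surrogate on a Gaussian-sampled cohort
#' labeled by the authoritative two-sigma criterion (whose statistics are
#' estimated on the bootstrap base cohort), evaluates it on a held-out
#' uniform-sampled cohort, and simulates the two-stage pipeline: the
#' surrogate prefilters, the true criterion is evaluated only on
#' surrogate-accepted vectors.
#'
#' @inheritParams run_data_driven
#' @return An `efficiency_report` with the confusion matrix, two-stage
#'   efficiency, false-negative rate, criterion-evaluation counts and the
#'   trained surrogate.
#' @export
run_two_stage <- function(config = experiment_config(), reference = NULL) {
  ref <- reference %||% synthetic_reference(config)
  CB <- bootstrap_sample(ref$features, config$K_bootstrap,
                         seed = child_seed(config$seed, 2L))
  bmB <- cohort_biomarkers(ref$space, CB)
  st <- estimate_stats(bmB$table[bmB$ok, , drop = FALSE])
  crit <- gaussian_criterion(st)
  ## training set: Gaussian sampling labeled by the true criterion
  train <- gaussian_sample(fit_gaussian(ref$features), config$n_train,
                           seed = child_seed(config$seed, 3L))
  bmT <- cohort_biomarkers(ref$space, train)
  yT <- integer(nrow(train))
  yT[bmT$ok] <- accept(crit, bmT$table[bmT$ok, , drop = FALSE])
  model <- train_binary_surrogate(train, yT, seed = child_seed(config$seed, 4L))
  ## held-out evaluation: uniform sampling never seen in training
  eval_cohort <- uniform_sample(fit_uniform(ref$features), config$n_eval,
                                seed = child_seed(config$seed, 5L))
  bmE <- cohort_biomarkers(ref$space, eval_cohort)
  yE <- integer(nrow(eval_cohort))
  yE[bmE$ok] <- accept(crit, bmE$table[bmE$ok, , drop = FALSE])
  cm <- evaluate_confusion(model, eval_cohort, factor(yE, levels = c(0L, 1L)))
  ts <- two_stage_efficiency(cm, "1")
  ## explicit pipeline simulation for the accounting identities
  pred <- as.integer(as.character(predict(model, eval_cohort)))
  passed <- which(pred == 1L)
  n_true_eval <- length(passed)
  accepted <- sum(yE[passed] == 1L)
  structure(list(kind = "two-stage",
                 confusion = cm, two_stage = ts,
                 pipeline = list(n_generated = nrow(eval_cohort),
                                 n_criterion_evaluations = n_true_eval,
                                 n_accepted = accepted,
                                 efficiency = accepted / max(1, n_true_eval),
                                 evaluations_saved = nrow(eval_cohort) - n_true_eval),
                 surrogate = model, criterion = crit, reference = ref,
                 config = config),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("efficiency_report (%s)\n", x$kind))
  if (!is.null(x$table)) {
    tab <- x$table
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], round, 3)
    print(tab, row.names = FALSE)
  }
  if (x$kind == "two-stage") {
    print(x$confusion)
    cat(sprintf("two-stage efficiency %.3f (FN rate %.3f); %d of %d criterion evaluations saved\n",
                x$two_stage$efficiency, x$two_stage$fn_rate,
                x$pipeline$evaluations_saved, x$pipeline$n_generated))
  }
  invisible(x)
}
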
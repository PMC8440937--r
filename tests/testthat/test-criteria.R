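## helper: synthetic biomarker-like table
random_table <- function(n, seed = 1) {
  withr::with_seed(seed, {
    as.data.frame(lapply(stats::setNames(1:11, aortacohort:::BIOMARKER_NAMES),
                         function(j) rnorm(n, mean = 10 + j, sd = j / 3)))
  })
}

test_that("the half-sample mode finds the dense part of a skewed sample", {
  set.seed(2)
  x <- rlnorm(20000, meanlog = 0, sdlog = 0.5)
  ## mode of this lognormal is exp(-sdlog^2) ~ 0.78, well below the mean
  expect_lt(abs(half_sample_mode(x) - exp(-0.25)), 0.08)
  expect_identical(half_sample_mode(c(5)), 5)
  expect_identical(half_sample_mode(c(2, 4)), 3)
})

test_that("summary statistics use the standard estimators", {
  tab <- random_table(200, seed = 9)
  st <- estimate_stats(tab)
  expect_equal(st$mu, unname(colMeans(tab)), tolerance = 1e-12)
  expect_equal(st$sigma, unname(vapply(tab, stats::sd, numeric(1))),
               tolerance = 1e-12)
  expect_equal(st$B, sqrt(st$sigma^2 + (st$mu - st$M)^2), tolerance = 1e-12)
  expect_true(all(st$B >= st$sigma - 1e-12))
  expect_true(all(st$lower <= st$upper))
  ## constant column: mode falls back to the mean, B to sigma
  tab$tor <- 0.7
  st2 <- estimate_stats(tab)
  expect_identical(attr(st2, "constant"), "tor")
  expect_equal(st2["tor", "M"], 0.7)
  expect_equal(st2["tor", "B"], 0)
  expect_error(estimate_stats(tab[1:2, ]), "at least 3")
})

test_that("the Chebyshev bound reproduces printed clinical statistics", {
  ## sample statistics published for a 26-patient thoracic aorta cohort
  expect_equal(round(chebyshev_bound(17.28, 15.19, 1.79), 2), 2.75)  # MA
  expect_equal(round(chebyshev_bound(233.69, 211.36, 25.25), 2), 33.71)  # LPD
  expect_equal(round(chebyshev_bound(15.30, 15.49, 2.12), 2), 2.13)  # SoV
  expect_equal(round(chebyshev_bound(7.42, 7.49, 0.44), 2), 0.45)  # k
})

test_that("interval criteria accept and reject as constructed", {
  tab <- random_table(50, seed = 3)
  st <- estimate_stats(tab)
  cr <- range_criterion(st)
  ## every training row is accepted (inclusive endpoints)
  expect_true(all(accept(cr, tab) == 1L))
  ## one biomarker just outside its observed range is rejected
  row <- stats::setNames(as.numeric(tab[1, ]), names(tab))
  row["MA"] <- st["MA", "upper"] + 1e-6
  expect_identical(accept(cr, row), 0L)
  ## brute-force 11-fold interval oracle agrees on random probes
  probe <- random_table(200, seed = 4)
  oracle <- vapply(seq_len(nrow(probe)), function(i) {
    v <- as.numeric(probe[i, ])
    as.integer(all(v >= st$lower & v <= st$upper))
  }, integer(1))
  expect_identical(accept(cr, probe), oracle)
})

test_that("the two-sigma and Chebyshev intervals follow their formulas", {
  st <- data.frame(mu = c(14.77, 15.30, 11.96), M = c(14.5, 15.0, 11.5),
                   sigma = c(1.40, 2.12, 1.12),
                   row.names = c("PA", "SoV", "PD"))
  st$B <- chebyshev_bound(st$mu, st$M, st$sigma)
  st$lower <- st$mu - 5; st$upper <- st$mu + 5
  g <- gaussian_criterion(st)
  expect_equal(round(g$intervals["PA", "lower"], 2), 11.97)
  expect_equal(round(g$intervals["SoV", "upper"], 2), 19.54)
  expect_equal(round(g$intervals["PD", "upper"], 2), 14.20)
  ## degenerate sigma
  st0 <- st; st0$sigma <- 0; st0$B <- chebyshev_bound(st0$mu, st0$M, 0)
  g0 <- gaussian_criterion(st0)
  expect_equal(g0$intervals[, "lower"], g0$intervals[, "upper"])
  ## Chebyshev with M = mu, sigma = 1 gives mu +/- 3
  stc <- data.frame(mu = 5, M = 5, sigma = 1, B = 1, lower = 0, upper = 10,
                    row.names = "SoV")
  cc <- chebyshev_criterion(stc)
  expect_equal(as.numeric(cc$intervals), c(2, 8))
})

test_that("the unimodal Chebyshev interval covers at least 95%", {
  set.seed(11)
  x <- rlnorm(1e5, sdlog = 0.6)
  st <- estimate_stats(data.frame(SoV = x, PA = x, MA = x,
                                  PT = x, PD = x, LPD = x, k = x, h = x,
                                  w = x, h_over_w = x, tor = x))
  lo <- st["SoV", "M"] - 3 * st["SoV", "B"]
  hi <- st["SoV", "M"] + 3 * st["SoV", "B"]
  expect_gte(mean(x >= lo & x <= hi), 0.95)
})

test_that("the two-sigma interval is nested inside the Chebyshev interval", {
  set.seed(13)
  for (rep in seq_len(1000)) {
    mu <- rnorm(1, 20, 5); sigma <- runif(1, 0.1, 4)
    M <- mu + rnorm(1, 0, sigma)  # |mu - M| unrestricted
    B <- chebyshev_bound(mu, M, sigma)
    expect_true(M - 3 * B <= mu - 2 * sigma + 1e-12)
    expect_true(M + 3 * B >= mu + 2 * sigma - 1e-12)
  }
})

test_that("phenotype rules are correct, exhaustive and exclusive", {
  expect_identical(as.character(classify_phenotype(c(SoV = 16, PA = 14, MA = 15))), "N")
  expect_identical(as.character(classify_phenotype(c(SoV = 16, PA = 14, MA = 17))), "A")
  expect_identical(as.character(classify_phenotype(c(SoV = 14, PA = 14, MA = 12))), "E")
  ## boundary: SoV equal to MA belongs to N
  expect_identical(as.character(classify_phenotype(c(SoV = 16, PA = 14, MA = 16))), "N")
  ## partition property over random triples
  set.seed(21)
  sov <- runif(1e5, 10, 25); pa <- runif(1e5, 10, 25); ma <- runif(1e5, 10, 25)
  isN <- sov > pa & sov >= ma
  isA <- sov > pa & sov < ma
  isE <- sov <= pa
  expect_true(all(isN + isA + isE == 1L))
  lab <- ifelse(sov <= pa, "E", ifelse(sov >= ma, "N", "A"))
  expect_identical(unname(ifelse(isN, "N", ifelse(isA, "A", "E"))), lab)
})

test_that("intersections behave as logical AND with the expected bounds", {
  tab <- random_table(120, seed = 6)
  st <- estimate_stats(tab)
  g <- gaussian_criterion(st)
  probe <- random_table(300, seed = 7)
  probe$SoV <- probe$SoV + rnorm(300, 0, 3)  # spread phenotypes around
  pN <- phenotype_criterion("N")
  both <- intersect_criteria(g, pN)
  a <- accept(g, probe); b <- accept(pN, probe)
  expect_identical(accept(both, probe), as.integer(a & b))
  ## order independence and idempotence
  expect_identical(accept(intersect_criteria(pN, g), probe),
                   accept(both, probe))
  expect_identical(accept(intersect_criteria(g, g), probe), a)
  ## intersection efficiency cannot exceed either factor
  expect_lte(mean(accept(both, probe)), min(mean(a), mean(b)))
  ## two-sigma acceptance implies Chebyshev acceptance on the same stats
  ch <- chebyshev_criterion(st)
  amu <- accept(g, probe); am <- accept(ch, probe)
  expect_true(all(am[amu == 1L] == 1L))
})

test_that("criteria survive JSON serialization", {
  tab <- random_table(40, seed = 8)
  st <- estimate_stats(tab)
  cr <- intersect_criteria(gaussian_criterion(st), phenotype_criterion("A"))
  path <- withr::local_tempfile(fileext = ".json")
  write_criterion(cr, path)
  back <- read_criterion(path)
  probe <- random_table(100, seed = 9)
  expect_identical(accept(back, probe), accept(cr, probe))
})
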
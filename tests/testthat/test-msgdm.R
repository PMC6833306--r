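test_that("I-spline basis satisfies the boundary and monotonicity properties", {
  for (b in list(ispline_basis(2, 3), ispline_basis(2, 4),
                 ispline_basis(3, 5))) {
    x <- seq(0, 1, length.out = 101)
    M <- ispline_transform(x, b)
    expect_equal(unname(M[1, ]), rep(0, b$n_basis))
    expect_equal(unname(M[101, ]), rep(1, b$n_basis))
    expect_true(all(apply(M, 2, function(cl) all(diff(cl) >= -1e-12))))
  }
  expect_error(ispline_transform(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("I-spline values match numerical integration of M-splines", {
  b <- ispline_basis(2, 3)
  for (x in c(0.1, 0.25, 0.5, 0.77, 0.9)) {
    expect_equal(unname(ispline_transform(x, b)[1, ]),
                 ispline_quadrature(x, b), tolerance = 1e-6)
  }
  b4 <- ispline_basis(2, 4)
  expect_equal(unname(ispline_transform(0.37, b4)[1, ]),
               ispline_quadrature(0.37, b4), tolerance = 1e-6)
})

make_records <- function(cm, order, n, seed) {
  zeta_montecarlo(cm, order, n_samples = n, seed = seed)
}

test_that("design columns are rescaled mean pairwise differences", {
  set.seed(8)
  x <- matrix(rbinom(60, 1, 0.5), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("sp", 1:10)))
  cm <- community_matrix(x)
  st <- site_table(paste0("s", 1:6), x = c(0, 1, 2, 3, 4, 5), y = rep(0, 6),
                   elevation = c(100, 200, 400, 800, 1600, 3200),
                   cov = c(3, 7, 1, 9, 5, 2))
  rec <- make_records(cm, 2, 500, 1)
  des <- build_design(cm, st, rec, c("elevation", "cov"))
  expect_true(all(des$predictors >= 0 & des$predictors <= 1))
  # hand-check one record's covariate difference before rescaling
  tuples <- as.matrix(rec$records[, c("site1", "site2")])
  raw <- abs(st$cov[tuples[, 1]] - st$cov[tuples[, 2]])
  expect_equal(des$predictors[, "cov"],
               (raw - min(raw)) / (max(raw) - min(raw)))
  # geographic distance column present and rescaled
  rawd <- abs(st$x[tuples[, 1]] - st$x[tuples[, 2]])
  expect_equal(des$predictors[, "distance"],
               (rawd - min(rawd)) / (max(rawd) - min(rawd)))
  # constant covariate dropped with a warning
  st$flat <- 5
  expect_warning(d2 <- build_design(cm, st, rec, c("cov", "flat")),
                 "constant")
  expect_false("flat" %in% colnames(d2$predictors))
})

test_that("a biotic matrix identical to the focal one predicts perfectly", {
  set.seed(12)
  cm <- random_cm(8, 20, 0.5)
  st <- site_table(rownames(cm), x = seq_len(8), y = rep(0, 8),
                   elevation = rnorm(8, 500, 100))
  rec <- make_records(cm, 2, 400, 2)
  des <- build_design(cm, st, rec, "elevation", biotic_cm = cm)
  # biotic column is the rescaled dissimilarity of the response itself
  r <- 1 - des$response
  expect_equal(des$predictors[, "biotic"],
               (r - min(r)) / (max(r) - min(r)))
})

test_that("msgdm recovers a monotone single-covariate signal", {
  set.seed(30)
  n <- 1200
  P <- cbind(signal = runif(n), noise1 = runif(n), noise2 = runif(n))
  dis <- 0.15 + 0.6 * P[, "signal"]^2 + rnorm(n, 0, 0.03)
  des <- structure(list(response = 1 - dis, predictors = P,
                        order = 2, scheme = "sorensen",
                        dropped = character(0)),
                   class = "msgdm_design")
  fit <- fit_msgdm(des)
  expect_true(all(fit$coefficients >= 0))
  expect_equal(names(which.max(fit$importance)), "signal")
  expect_gt(fit$variance_explained, 0.8)
  # fitted response monotone non-increasing in every predictor
  # (finite-difference scan along each axis, others fixed)
  b <- fit$basis
  for (j in seq_len(ncol(P))) {
    grid <- seq(0, 1, length.out = 50)
    spl <- ispline_transform(grid, b) %*% fit$coefficients[j, ]
    expect_true(all(diff(spl) >= -1e-10))
  }
})

test_that("pure-noise responses explain almost nothing", {
  set.seed(31)
  n <- 1000
  P <- cbind(a = runif(n), b = runif(n), c = runif(n))
  des <- structure(list(response = runif(n), predictors = P,
                        order = 2, scheme = "sorensen",
                        dropped = character(0)),
                   class = "msgdm_design")
  fit <- fit_msgdm(des)
  expect_lt(fit$variance_explained, 0.05)
})

test_that("variance explained ignores predictor order; duplicates share importance", {
  set.seed(32)
  n <- 800
  P <- cbind(a = runif(n), b = runif(n))
  dis <- 0.2 + 0.5 * P[, "a"] + 0.2 * P[, "b"] + rnorm(n, 0, 0.05)
  mk <- function(P) structure(list(response = 1 - dis, predictors = P,
                                   order = 2, scheme = "sorensen",
                                   dropped = character(0)),
                              class = "msgdm_design")
  f1 <- fit_msgdm(mk(P))
  f2 <- fit_msgdm(mk(P[, c("b", "a")]))
  expect_equal(f1$variance_explained, f2$variance_explained,
               tolerance = 1e-8)
  # duplicating a predictor: the pair's total importance matches the
  # single column's (non-negativity splits it between the copies)
  P3 <- cbind(P, a2 = P[, "a"])
  f3 <- suppressWarnings(fit_msgdm(mk(P3)))
  expect_equal(unname(f3$importance["a"] + f3$importance["a2"]),
               unname(f1$importance["a"]), tolerance = 0.02)
  expect_true("a" %in% f3$rank_deficient || "a2" %in% f3$rank_deficient)
})

test_that("order-2 msgdm response equals pairwise Sorensen dissimilarity", {
  set.seed(33)
  cm <- random_cm(7, 25, 0.5)
  st <- site_table(rownames(cm), x = 1:7, y = rep(0, 7),
                   elevation = rnorm(7, 300, 50))
  rec <- make_records(cm, 2, 300, 4)
  des <- build_design(cm, st, rec, "elevation")
  X <- unclass(cm)
  tuples <- as.matrix(rec$records[, c("site1", "site2")])
  sor <- vapply(seq_len(nrow(tuples)), function(k) {
    a <- X[tuples[k, 1], ]; b <- X[tuples[k, 2], ]
    2 * sum(a * b) / (sum(a) + sum(b))
  }, numeric(1))
  expect_equal(des$response, sor, tolerance = 1e-12)
})

test_that("the model suite is deterministic and shares samples across models", {
  study <- generate_crete_like(seed = 17, scale = 0.15)
  s1 <- suppressWarnings(run_model_suite(study, "PE", orders = 2:3, n_samples = 150,
                        seed = 5, covariates = c("elevation",
                                                 "temperature")))
  s2 <- suppressWarnings(run_model_suite(study, "PE", orders = 2:3, n_samples = 150,
                        seed = 5, covariates = c("elevation",
                                                 "temperature")))
  expect_identical(s1$variance_explained, s2$variance_explained)
  expect_setequal(unique(s1$variance_explained$model),
                  c("abiotic", "biotic1", "biotic2"))
  expect_error(run_model_suite(study, "NON_E", orders = 2,
                               models = c("abiotic", "biotic1")),
               "undefined")
})
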
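test_that("combined fit recovers exact log-linear and log-log declines", {
  i <- 1:12
  # pure exponential: b_exp = 0.5, b_pl = 0
  f1 <- suppressWarnings(fit_decline(10 * exp(-0.5 * i), orders = i,
                                     form = "combined"))
  expect_equal(f1$b_exp, 0.5, tolerance = 1e-10)
  expect_equal(f1$b_pl, 0, tolerance = 1e-10)
  # on noise-free data the t-test is degenerate; the honest significance
  # check lives in the noisy-decline tests below
  # pure power law: b_pl = 1.5, b_exp = 0
  f2 <- suppressWarnings(fit_decline(10 * i^(-1.5), orders = i,
                                     form = "combined"))
  expect_equal(f2$b_pl, 1.5, tolerance = 1e-10)
  expect_equal(f2$b_exp, 0, tolerance = 1e-10)
  # single-form fits recover their own generating coefficients
  expect_equal(suppressWarnings(fit_decline(10 * exp(-0.5 * i), orders = i,
                           form = "exponential"))$b_exp, 0.5,
               tolerance = 1e-10)
  expect_equal(suppressWarnings(fit_decline(10 * i^(-1.5), orders = i,
                           form = "powerlaw"))$b_pl, 1.5,
               tolerance = 1e-10)
})

test_that("fit_decline guards segments and positivity", {
  expect_error(fit_decline(c(1, 0.5, 0), orders = 1:3, form = "combined"),
               "short|positive")
  expect_error(fit_decline(c(1, 0.5, 0.2, 0), orders = 1:4,
                           form = "combined"), "shorten")
})

test_that("AIC selection separates exponential from power-law declines", {
  i <- 1:10
  set.seed(2)
  noisy_exp <- 10 * exp(-0.6 * i) * exp(rnorm(10, 0, 0.02))
  noisy_pl <- 10 * i^(-1.2) * exp(rnorm(10, 0, 0.02))
  expect_equal(select_decline_form(noisy_exp, orders = i)$chosen,
               "exponential")
  expect_equal(select_decline_form(noisy_pl, orders = i)$chosen,
               "powerlaw")
})

test_that("breakpoint is the first retention maximum; monotone has no peak", {
  ret <- stats::setNames(c(0.5, 0.7, 0.9, 0.8, 0.6), 2:6)
  bp <- find_breakpoint(ret)
  expect_equal(bp$order, 4L)
  expect_false(bp$no_peak)
  # ties: first maximum
  ret2 <- stats::setNames(c(0.5, 0.9, 0.9, 0.6), 2:5)
  expect_equal(find_breakpoint(ret2)$order, 3L)
  mono <- stats::setNames(c(0.2, 0.4, 0.6, 0.8), 2:5)
  bpm <- find_breakpoint(mono)
  expect_true(bpm$no_peak)
  expect_equal(bpm$order, 3L)
  expect_error(find_breakpoint(c(a = 0.1, b = 0.2, c = 0.3)), "4 orders")
})

test_that("piecewise fits recover the two regimes of a constructed decline", {
  # power law up to order 5, exponential beyond
  i <- 1:14
  z <- ifelse(i <= 5, 20 * i^(-1.4), 20 * 5^(-1.4) * exp(-0.7 * (i - 5)))
  set.seed(3)
  z <- z * exp(rnorm(length(z), 0, 0.01))
  dec <- structure(list(orders = i, zeta = z), class = "zeta_decline")
  ret <- retention_rate(dec)
  pw <- suppressWarnings(fit_piecewise(dec, ret))
  expect_lt(pw$rare$p_pl, 0.05)
  expect_gt(pw$rare$b_pl, 0.5)
  expect_gt(pw$widespread$p_pl, 0.05)
  # pure exponential everywhere: no segment shows a power-law term
  z2 <- 20 * exp(-0.5 * i) * exp(rnorm(length(i), 0, 0.01))
  dec2 <- structure(list(orders = i, zeta = z2), class = "zeta_decline")
  pw2 <- suppressWarnings(fit_piecewise(dec2))
  expect_gt(pw2$rare$p_pl, 0.05)
  expect_gt(pw2$widespread$p_pl, 0.05)
})

test_that("piecewise with the split at the range end reproduces one segment", {
  i <- 1:12
  set.seed(4)
  z <- 30 * exp(-0.4 * i) * exp(rnorm(12, 0, 0.02))
  dec <- structure(list(orders = i, zeta = z), class = "zeta_decline")
  single <- fit_decline(dec, segment = 1:8, form = "combined")
  # retention curve engineered to peak at order 8
  ret <- stats::setNames(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.99, 0.3, 0.2,
                           0.15, 0.1), 2:12)
  pw <- fit_piecewise(dec, ret)
  expect_equal(pw$split_order, 8L)
  expect_equal(pw$rare$b_exp, single$b_exp, tolerance = 1e-12)
  expect_equal(pw$rare$aic, single$aic, tolerance = 1e-12)
})

test_that("beta summary counts gamma, mean alpha and Whittaker beta", {
  bs <- beta_summary(toy_cm())
  expect_equal(bs$gamma, 3)
  expect_equal(bs$mean_alpha, 2)
  expect_equal(bs$whittaker_beta, 1.5)
  expect_equal(bs$n_star, 1.5)  # defaults to Whittaker, labelled
  expect_match(bs$n_star_formula, "whittaker")
  # single site and saturated matrix: beta = 1
  one <- community_matrix(matrix(c(1, 1, 0), 1, 3))
  expect_equal(beta_summary(one)$whittaker_beta, 1)
  sat <- community_matrix(matrix(1, 4, 5))
  expect_equal(beta_summary(sat)$whittaker_beta, 1)
  expect_error(beta_summary(community_matrix(matrix(0, 2, 2))), "empty")
  # pluggable alternative formula is used when supplied
  bs2 <- beta_summary(toy_cm(), n_star_fn = function(g, a, cm) g - a)
  expect_equal(bs2$n_star, 1)
})
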
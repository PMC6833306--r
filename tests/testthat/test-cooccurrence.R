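test_that("range statistics summarize occupied-site elevations", {
  x <- cbind(sp1 = c(1, 1, 1, 0), sp2 = c(0, 1, 0, 0), sp3 = c(0, 0, 0, 0))
  rownames(x) <- paste0("s", 1:4)
  cm <- community_matrix(x, c("NE", "PE", "PE"))
  st <- site_table(paste0("s", 1:4), x = 1:4, y = rep(0, 4),
                   elevation = c(100, 300, 500, 900))
  rs <- range_stats(cm, st)
  expect_equal(rs$elev_mean[1], 300)
  expect_equal(rs$elev_min[1], 100)
  expect_equal(rs$elev_max[1], 500)
  expect_equal(rs$elev_range[1], 400)
  expect_equal(rs$range_ratio, c(3 / 4, 1 / 4, 0))
  # zero-occupancy species: missing elevational stats, ratio 0
  expect_true(is.na(rs$elev_mean[3]))
  expect_true(rs$elev_min[2] == rs$elev_max[2])
})

test_that("permutation ANOVA F equals the classical closed form", {
  set.seed(50)
  vals <- c(rnorm(10, 0), rnorm(12, 0.5), rnorm(9, 1))
  grp <- rep(c("a", "b", "c"), c(10, 12, 9))
  res <- perm_anova(vals, grp, n_perm = 99, seed = 1, posthoc = FALSE)
  f_classic <- summary(stats::aov(vals ~ factor(grp)))[[1]]$`F value`[1]
  expect_equal(res$f, f_classic, tolerance = 1e-10)
})

test_that("permutation p-values behave at the extremes and under reordering", {
  set.seed(51)
  # extreme separation: minimum attainable p
  vals <- c(rnorm(8, 0, 1), rnorm(8, 20, 1))
  res <- perm_anova(vals, rep(c("a", "b"), each = 8), n_perm = 199,
                    seed = 3, posthoc = FALSE)
  expect_equal(res$p, 1 / 200)
  # within-group reordering leaves the p-value unchanged
  vals2 <- c(sample(vals[1:8]), sample(vals[9:16]))
  res2 <- perm_anova(vals2, rep(c("a", "b"), each = 8), n_perm = 199,
                     seed = 3, posthoc = FALSE)
  expect_equal(res$p, res2$p)
  # two large n_perm runs agree within Monte Carlo error
  set.seed(52)
  v <- c(rnorm(15), rnorm(15, 0.8))
  g <- rep(c("a", "b"), each = 15)
  p1 <- perm_anova(v, g, n_perm = 3999, seed = 3, posthoc = FALSE)$p
  p2 <- perm_anova(v, g, n_perm = 3999, seed = 4, posthoc = FALSE)$p
  expect_lt(abs(p1 - p2), 4 * sqrt(p1 * (1 - p1) / 4000))
})

test_that("post-hoc pairwise tests are Holm-adjusted and monotone", {
  set.seed(53)
  vals <- c(rnorm(10, 0), rnorm(10, 0.2), rnorm(10, 3))
  grp <- rep(c("a", "b", "c"), each = 10)
  res <- perm_anova(vals, grp, n_perm = 499, seed = 5)
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  ac <- res$pairwise$p_adj[res$pairwise$group1 == "a" &
                             res$pairwise$group2 == "c"]
  expect_lt(ac, 0.05)
  # a singleton group is excluded with a warning
  expect_warning(perm_anova(c(vals, 5), c(grp, "d"), n_perm = 99,
                            seed = 1, posthoc = FALSE), "excluding")
})

test_that("C-score hits its analytic extremes and the brute-force oracle", {
  # perfect checkerboard: each species in one site, none shared
  cb <- community_matrix(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(c_score(cb), 1)
  # identical distributions: 0
  ident <- community_matrix(cbind(a = c(1, 1, 0), b = c(1, 1, 0)))
  expect_equal(c_score(ident), 0)
  set.seed(60)
  for (rep in 1:20) {
    cm <- random_cm(5, 4, 0.5)
    if (sum(occupancy(cm) > 0) < 2) next
    expect_equal(c_score(cm), c_score_brute(cm), tolerance = 1e-12)
  }
  expect_error(c_score(community_matrix(matrix(c(1, 1), 2, 1))), "2 species")
})

test_that("NODF matches a direct implementation and its canonical extremes", {
  # perfectly nested: row and column fills strictly decreasing
  tri <- outer(1:4, 1:4, function(i, j) as.numeric(j <= 5 - i))
  expect_equal(nodf(community_matrix(tri)), 100)
  cb <- community_matrix(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))
  expect_equal(nodf(cb), 0)
  set.seed(61)
  for (rep in 1:30) {
    m <- matrix(rbinom(36, 1, runif(1, 0.3, 0.7)), 6, 6)
    expect_equal(unname(nodf(community_matrix(m))), nodf_brute(m),
                 tolerance = 1e-10)
  }
})

test_that("VIF screening drops collinear covariates in the right order", {
  set.seed(70)
  n <- 100
  a <- rnorm(n); b <- rnorm(n)
  st <- data.frame(site = 1:n, x = 1:n, y = 0, a = a, b = b)
  res <- vif_screen(st, c("a", "b"))
  expect_equal(res$retained, c("a", "b"))
  expect_true(all(res$vif < 1.2))
  # exact duplicate: one copy dropped first (unbounded VIF)
  st$a2 <- a
  res2 <- suppressWarnings(vif_screen(st, c("a", "a2", "b")))
  expect_equal(nrow(res2$dropped), 1L)
  expect_true(res2$dropped$covariate %in% c("a", "a2"))
  # R^2 = 0.95 construction: VIF = 20, dropped at threshold 10
  e <- rnorm(n)
  st$c <- as.vector(scale(a) * sqrt(0.95) +
                      scale(e) * sqrt(0.05))
  st$a_s <- as.vector(scale(a))
  res3 <- suppressWarnings(vif_screen(st, c("a_s", "c", "b")))
  expect_true(nrow(res3$dropped) >= 1)
  expect_gt(res3$dropped$vif[1], 10)
})
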
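test_that("landscape surfaces have the configured qualitative structure", {
  cfg <- landscape_config(grid_nx = 9, grid_ny = 9, cell_size = 2,
                          massif_centers = cbind(x = 9, y = 9,
                                                 peak_elevation_m = 1500),
                          noise_elev_sd = 0)
  st <- generate_landscape(cfg, seed = 1)
  # single central massif: elevation maximal at the centre cell
  expect_equal(which.max(st$elevation), 41L)  # (5, 5) of the 9x9 grid
  # determinism under a fixed seed
  st2 <- generate_landscape(cfg, seed = 1)
  expect_identical(st, st2)
  # with zero elevation noise the bumps are deterministic, but the other
  # covariate fields still differ between seeds
  expect_false(identical(generate_landscape(cfg, seed = 2)$temperature,
                         st$temperature))
  # default config: human pressure decreases with elevation
  std <- generate_landscape(seed = 3)
  expect_lt(cor(std$elevation, std$human_density, method = "spearman"), 0)
  expect_lt(cor(std$elevation, std$temperature), 0)
  expect_true(all(is.finite(as.matrix(std[, -1]))))
  expect_error(generate_landscape(landscape_config(grid_nx = 0)), "grid")
})

test_that("neutral assembly hits the target occupancy within sampling error", {
  st <- small_landscape()
  m <- assembly_model(100, 0.3, mode = "neutral")
  study <- assemble_community(st, list(NON_E = m), seed = 2)
  occ <- occupancy(study$cm) / nrow(study$cm)
  se <- sqrt(0.3 * 0.7 / (nrow(study$cm) * 100))
  expect_lt(abs(mean(occ) - 0.3), 3 * se)
})

test_that("mixture endpoints equal the pure niche and neutral assemblies", {
  st <- small_landscape()
  mk <- function(mode, w) assembly_model(40, 0.2, 0.1, mode, w = w,
                                         breadth = 250)
  neutral <- assemble_community(st, list(NE = mk("neutral", 0)), seed = 5)
  niche <- assemble_community(st, list(NE = mk("niche", 0)), seed = 5)
  w1 <- assemble_community(st, list(NE = mk("mixture", 1)), seed = 5)
  w0 <- assemble_community(st, list(NE = mk("mixture", 0)), seed = 5)
  expect_identical(unclass(w1$cm)[, ], unclass(neutral$cm)[, ])
  expect_identical(unclass(w0$cm)[, ], unclass(niche$cm)[, ])
  expect_false(identical(unclass(niche$cm)[, ], unclass(neutral$cm)[, ]))
})

test_that("very broad niches reduce to near-uniform occurrence probability", {
  st <- small_landscape()
  set.seed(1)
  m <- assembly_model(5, 0.3, 0, "niche", breadth = 1e9)
  P <- zetascape:::category_probabilities(st, m)
  expect_lt(max(abs(P - 0.3)), 1e-4)
})

test_that("assembly validates its parameters", {
  expect_error(assembly_model(10, 0), "occupancy")
  expect_error(assembly_model(10, 1.2), "occupancy")
  expect_error(assembly_model(10, 0.5, breadth = 0), "breadth")
  expect_error(assembly_model(-1, 0.5), "species_count")
})

test_that("neutral zeta matches the closed form S * p^i", {
  st <- small_landscape()
  study <- assemble_community(
    st, list(NON_E = assembly_model(600, 0.4, 0, "neutral")), seed = 9)
  z <- vapply(1:5, function(i) zeta_exact(study$cm, i), numeric(1))
  expected <- 600 * 0.4^(1:5)
  expect_true(all(abs(z / expected - 1) < 0.15))
})

test_that("Crete-like studies reproduce the configured marginal structure", {
  study <- generate_crete_like(seed = 31, scale = 0.1)
  expect_equal(nrow(study$cm), 160L)
  counts <- table(factor(species_category(study$cm),
                         levels = CATEGORY_LEVELS))
  expect_equal(unname(c(counts)), c(148L, 9L, 7L))
  # full-scale pools at two seeds: distinct matrices, ordered range
  # fractions NON_E > NE > PE near the targets
  s1 <- generate_crete_like(seed = 1)
  s2 <- generate_crete_like(seed = 2)
  expect_false(identical(unclass(s1$cm)[, ], unclass(s2$cm)[, ]))
  for (s in list(s1, s2)) {
    frac <- vapply(CATEGORY_LEVELS, function(l)
      mean(occupancy(subset_by_category(s$cm, l)) / 160), numeric(1))
    expect_true(frac["NON_E"] > frac["NE"] && frac["NE"] > frac["PE"])
    expect_lt(abs(frac["NON_E"] - 0.08), 0.01)
    expect_lt(abs(frac["NE"] - 0.06), 0.012)
    expect_lt(abs(frac["PE"] - 0.05), 0.012)
  }
  # ground truth records the generating models
  expect_s3_class(s1$ground_truth$PE$model, "assembly_model")
  expect_length(s1$ground_truth$PE$targets, 74L)
})

test_that("study export writes the three CSVs plus ground truth", {
  dir <- withr::local_tempdir()
  study <- generate_crete_like(seed = 3, scale = 0.05)
  write_study(study, dir)
  expect_true(all(file.exists(file.path(
    dir, c("matrix.csv", "sites.csv", "categories.csv",
           "ground_truth.json")))))
  back <- read_community(file.path(dir, "matrix.csv"),
                         file.path(dir, "categories.csv"))
  expect_identical(unclass(back)[, ], unclass(study$cm)[, ])
})
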
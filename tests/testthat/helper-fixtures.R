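# shared fixtures and independent oracles

# 3-site / 3-species toy: occupancies (1, 2, 3)
toy_cm <- function(categories = c("PE", "NE", "NON_E")) {
  x <- matrix(c(1, 0, 0,
                1, 1, 0,
                1, 1, 1), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("sp1", "sp2", "sp3")))
  community_matrix(x, categories)
}

random_cm <- function(n_sites, n_species, p = 0.3) {
  community_matrix(matrix(rbinom(n_sites * n_species, 1, p),
                          n_sites, n_species))
}

# oracle: zeta by full enumeration of site combinations
zeta_enum <- function(cm, order) {
  X <- unclass(cm)
  combos <- utils::combn(nrow(X), order)
  mean(apply(combos, 2L, function(idx)
    sum(colSums(X[idx, , drop = FALSE]) == order)))
}

# oracle: normalized C-score by explicit pair loop
c_score_brute <- function(cm) {
  X <- unclass(cm)
  X <- X[, colSums(X) > 0, drop = FALSE]
  S <- ncol(X)
  vals <- c()
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    ri <- sum(X[, i]); rj <- sum(X[, j]); sh <- sum(X[, i] * X[, j])
    vals <- c(vals, (ri - sh) * (rj - sh) / (ri * rj))
  }
  mean(vals)
}

# oracle: NODF directly from the published definition (decreasing fill,
# paired overlap), over row pairs and column pairs of the matrix as given
nodf_brute <- function(m) {
  pair_scores <- function(M) {
    n <- nrow(M)
    out <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      fi <- sum(M[i, ]); fj <- sum(M[j, ])
      out <- c(out,
               if (fj == 0 || fi <= fj) 0
               else 100 * sum(M[i, ] * M[j, ]) / fj)
    }
    out
  }
  mean(c(pair_scores(m), pair_scores(t(m))))
}

# oracle: I-spline values by numerical integration of M-splines
# (Ramsay's recursion), knots clamped on [0, 1]
mspline_value <- function(x, i, k, knots) {
  if (k == 1) {
    w <- knots[i + 1] - knots[i]
    if (w == 0) 0
    else if (knots[i] <= x && x < knots[i + 1]) 1 / w
    else if (x == 1 && knots[i] < 1 && knots[i + 1] == 1) 1 / w
    else 0
  } else {
    denom <- (k - 1) * (knots[i + k] - knots[i])
    if (denom == 0) return(0)
    k * ((x - knots[i]) * mspline_value(x, i, k - 1, knots) +
         (knots[i + k] - x) * mspline_value(x, i + 1, k - 1, knots)) / denom
  }
}

ispline_quadrature <- function(x, basis) {
  k <- basis$order
  knots <- c(rep(0, k), basis$knots, rep(1, k))
  vapply(seq_len(basis$n_basis), function(i)
    stats::integrate(Vectorize(function(t) mspline_value(t, i, k, knots)),
                     0, x, subdivisions = 400L, rel.tol = 1e-9)$value,
    numeric(1))
}

# neutral incidence matrix with constant occurrence probability
neutral_cm <- function(n_sites, n_species, p) {
  community_matrix(matrix(rbinom(n_sites * n_species, 1, p),
                          n_sites, n_species))
}

# small landscape reused by slower tests
small_landscape <- function(seed = 7) {
  generate_landscape(landscape_config(grid_nx = 8, grid_ny = 5), seed = seed)
}
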
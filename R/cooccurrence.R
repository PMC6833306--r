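#' Species-level elevational and geographic range statistics
#'
#' For each species: mean, minimum and maximum elevation of its occupied
#' sites, elevational range (max - min), and geographic range ratio
#' (occupied sites / total sites).  Zero-occupancy species get missing
#' elevational statistics and ratio 0.
#'
#' @param cm a [community_matrix()].
#' @param st `site_table` aligned to `cm` (must contain `elevation`).
#' @return A data.frame with one row per species: `species`, `category`,
#'   `occupancy`, `range_ratio`, `elev_mean`, `elev_min`, `elev_max`,
#'   `elev_range`.
#' @export
range_stats <- function(cm, st) {
  validate_study(cm, st)
  elev <- st$elevation
  X <- unclass(cm)
  occ <- occupancy(cm)
  n <- nrow(X)
  stat <- function(fn) vapply(seq_len(ncol(X)), function(j) {
    e <- elev[X[, j] == 1]
    if (!length(e)) NA_real_ else fn(e)
  }, numeric(1))
  out <- data.frame(species = colnames(X),
                    category = unname(species_category(cm)),
                    occupancy = occ,
                    range_ratio = occ / n,
                    elev_mean = stat(mean),
                    elev_min = stat(min),
                    elev_max = stat(max),
                    stringsAsFactors = FALSE)
  out$elev_range <- out$elev_max - out$elev_min
  out
}

# one-way ANOVA F statistic, closed form (groups: integer codes 1..g)
anova_f <- function(values, codes, g) {
  n <- length(values)
  gm <- mean(values)
  ns <- tabulate(codes, g)
  sums <- vapply(seq_len(g), function(k) sum(values[codes == k]), numeric(1))
  means <- sums / ns
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[codes])^2)
  (ssb / (g - 1)) / (ssw / (n - g))
}

#' Permutational one-way ANOVA with pairwise post-hoc tests
#'
#' The observed classical one-way F statistic is compared against its
#' distribution under random permutation of the group labels; the
#' p-value uses the add-one estimator `(1 + #(F* >= F)) / (1 + n_perm)`
#' so it can never be exactly zero.  Post-hoc pairwise comparisons are
#' permutation t-tests (absolute Welch-free pooled t) with Holm
#' step-down adjustment, run only when requested.  Groups with fewer
#' than 2 members are excluded with a warning.
#'
#' @param values numeric vector (e.g. a per-species statistic).
#' @param groups group labels aligned to `values`.
#' @param n_perm number of permutations (default 4999).
#' @param seed integer seed.
#' @param posthoc run pairwise post-hoc tests when the omnibus test is
#'   computed (default TRUE).
#' @return A list of class `perm_anova` with `f`, `p`, `n_perm`,
#'   `groups` (retained labels), and `pairwise` (data.frame with raw and
#'   Holm-adjusted permutation p-values), or `NULL` pairwise when
#'   `posthoc = FALSE`.
#' @export
perm_anova <- function(values, groups, n_perm = 4999L, seed = NULL,
                       posthoc = TRUE) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  tab <- table(groups)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
    tab <- table(groups)
  }
  labs <- names(tab)
  if (length(labs) < 2L)
    stop("need >= 2 groups with >= 2 members", call. = FALSE)
  codes <- match(groups, labs)
  g <- length(labs)
  if (!is.null(seed)) set.seed(seed)
  f_obs <- anova_f(values, codes, g)
  f_perm <- vapply(seq_len(n_perm), function(k)
    anova_f(values, sample(codes), g), numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)

  pairwise <- NULL
  if (posthoc) {
    pairs <- utils::combn(labs, 2L)
    praw <- apply(pairs, 2L, function(pr) {
      va <- values[groups == pr[1]]; vb <- values[groups == pr[2]]
      perm_t_p(va, vb, n_perm)
    })
    pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                           p_raw = praw,
                           p_adj = stats::p.adjust(praw, "holm"))
  }
  structure(list(f = f_obs, p = p, n_perm = n_perm, groups = labs,
                 pairwise = pairwise),
            class = "perm_anova")
}

# two-sample permutation test on |difference in means|, add-one estimator
perm_t_p <- function(a, b, n_perm) {
  x <- c(a, b); na <- length(a)
  obs <- abs(mean(a) - mean(b))
  stat <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(length(x), na)
    abs(mean(x[idx]) - mean(x[-idx]))
  }, numeric(1))
  (1 + sum(stat >= obs)) / (1 + n_perm)
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("permutational one-way ANOVA: F = %.4f, p = %.4g (%d perms)\n",
              x$f, x$p, x$n_perm))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Holm-adjusted permutation t-tests):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Mean normalized checkerboard score (C-score)
#'
#' For every species pair the checkerboard unit is
#' \eqn{(r_i - S)(r_j - S)} with \eqn{r} the occupancies and \eqn{S} the
#' number of shared sites; the normalized variant divides by
#' \eqn{r_i r_j} so each pair scores in \[0, 1\] (1 = perfect
#' segregation, 0 = identical distributions).  The reported C-score is
#' the mean over all pairs of species with occupancy > 0.
#'
#' @param cm a [community_matrix()].
#' @return Mean normalized C-score in \[0, 1\].
#' @export
c_score <- function(cm) {
  X <- unclass(cm)[, occupancy(cm) > 0L, drop = FALSE]
  S <- ncol(X)
  if (S < 2L) stop("need >= 2 species with occupancy > 0", call. = FALSE)
  r <- colSums(X)
  Sh <- crossprod(X)  # shared-site counts
  CU <- (outer(r, r, function(a, b) a) - Sh) *
        (outer(r, r, function(a, b) b) - Sh) / outer(r, r)
  mean(CU[upper.tri(CU)])
}

#' NODF nestedness metric
#'
#' Nestedness based on Overlap and Decreasing Fill, in \[0, 100\]: for
#' every ordered pair of rows (and of columns) with strictly decreasing
#' marginal totals, the paired overlap is the percentage of the poorer
#' line's presences that also occur in the richer line; pairs with equal
#' or increasing totals contribute 0.  NODF is the mean over all row and
#' column pairs.  Computed on the matrix as given (no resorting), via
#' [vegan::nestednodf()]; a perfectly nested triangular matrix scores
#' 100 and a checkerboard 0.
#'
#' @param cm a [community_matrix()] (or plain binary matrix) with at
#'   least 2 rows and 2 columns.
#' @return NODF value in \[0, 100\].
#' @export
nodf <- function(cm) {
  X <- unclass(cm)
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("need >= 2 rows and >= 2 columns", call. = FALSE)
  unname(vegan::nestednodf(X, order = FALSE, weighted = FALSE
                           )$statistic["NODF"])
}

#' Variance inflation factor screening of covariates
#'
#' Iteratively drops the covariate with the largest VIF (\eqn{1/(1-R^2)}
#' from regressing it on the remaining candidates) until all VIFs fall
#' below the threshold.  Exactly collinear covariates have unbounded VIF
#' and are removed first.
#'
#' @param st `site_table` (or data.frame) holding the candidates.
#' @param covariates character vector of candidate column names (>= 2).
#' @param threshold VIF threshold (default 10, i.e. \eqn{R^2 = 0.9}).
#' @return A list with `retained` (in input order), `dropped`
#'   (data.frame of dropped covariates with the VIF at removal) and
#'   `vif` (final VIFs of the retained set).
#' @export
vif_screen <- function(st, covariates, threshold = 10) {
  if (length(covariates) < 2L) stop("need >= 2 candidates", call. = FALSE)
  if (nrow(st) <= length(covariates))
    stop("need more sites than candidates", call. = FALSE)
  Z <- as.matrix(as.data.frame(st)[, covariates, drop = FALSE])
  current <- covariates
  log <- data.frame(covariate = character(0), vif = numeric(0))
  vifs_of <- function(set) {
    vapply(set, function(cv) {
      r2 <- summary(stats::lm(Z[, cv] ~ Z[, setdiff(set, cv), drop = FALSE]
                              ))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  repeat {
    if (length(current) < 2L) break
    v <- vifs_of(current)
    if (max(v) < threshold) break
    worst <- names(v)[which.max(v)]
    log <- rbind(log, data.frame(covariate = worst, vif = unname(max(v))))
    current <- setdiff(current, worst)
  }
  final_vif <- if (length(current) >= 2L) vifs_of(current)
               else stats::setNames(rep(1, length(current)), current)
  list(retained = covariates[covariates %in% current],
       dropped = log, vif = final_vif)
}
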
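#' Exact zeta diversity of a given order
#'
#' Zeta diversity of order \eqn{i} is the mean number of species shared by
#' \eqn{i} distinct sites, averaged over all \eqn{\binom{N}{i}} site
#' combinations.  The exact value has the hypergeometric closed form
#' \deqn{\zeta_i = \sum_s \binom{n_s}{i} / \binom{N}{i}}
#' where \eqn{n_s} is the occupancy of species \eqn{s} and \eqn{N} the
#' number of sites: a species is shared by a random \eqn{i}-combination
#' with probability \eqn{\binom{n_s}{i}/\binom{N}{i}}.  This equals full
#' enumeration at \eqn{O(S)} cost.  \eqn{\zeta_1} is mean per-site
#' richness (mean alpha-diversity).
#'
#' @param cm a [community_matrix()].
#' @param order integer zeta order \eqn{i}, `1 <= order <= nrow(cm)`.
#' @return The exact zeta value (numeric scalar).
#' @examples
#' x <- matrix(c(1, 0, 0, 1, 1, 0, 1, 1, 1), nrow = 3,
#'             dimnames = list(LETTERS[1:3], paste0("sp", 1:3)))
#' cm <- community_matrix(x)
#' zeta_exact(cm, 2)  # 4/3
#' @export
zeta_exact <- function(cm, order) {
  n <- nrow(cm)
  if (length(order) != 1L || order < 1L || order > n)
    stop("order must be a single integer in [1, ", n, "]", call. = FALSE)
  occ <- occupancy(cm)
  # lchoose is -Inf for occ < order; exp(-Inf) = 0 handles rare species
  sum(exp(lchoose(occ, order) - lchoose(n, order)))
}

#' Monte Carlo zeta diversity with per-combination records
#'
#' Estimates zeta diversity of a given order by sampling site combinations
#' uniformly at random (sites distinct within a combination; combinations
#' drawn independently, so the estimator is unbiased for [zeta_exact()]).
#' The per-combination records (site tuples, shared-species counts, and
#' normalized values) are returned so that MS-GDM can regress on them.
#'
#' @param cm a [community_matrix()].
#' @param order zeta order \eqn{i}.
#' @param n_samples number of sampled combinations (default 1e4).
#' @param seed optional integer seed for reproducibility.
#' @return A list of class `zeta_samples` with elements `order`, `zeta`
#'   (mean shared count), `sd` (spread across combinations), `sem`
#'   (standard error of the mean), `records` (a data.frame with the site
#'   indices `site1..site<i>`, `shared`, `sorensen`, `simpson`) and
#'   `n_samples`.
#' @export
zeta_montecarlo <- function(cm, order, n_samples = 10000L, seed = NULL) {
  n <- nrow(cm)
  if (order < 1L || order > n)
    stop("order must be in [1, ", n, "]", call. = FALSE)
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tuples <- sample_combinations(n, order, n_samples)
  res <- shared_counts(cm, tuples)
  records <- as.data.frame(tuples)
  names(records) <- paste0("site", seq_len(order))
  records$shared <- res$shared
  records$sorensen <- normalize_shared(res$shared, res$rich, "sorensen")
  records$simpson <- normalize_shared(res$shared, res$rich, "simpson")
  structure(list(order = order,
                 zeta = mean(res$shared),
                 sd = stats::sd(res$shared),
                 sem = stats::sd(res$shared) / sqrt(n_samples),
                 records = records,
                 n_samples = n_samples),
            class = "zeta_samples")
}

# n_samples x order matrix of site indices, each row a uniform draw of
# `order` distinct sites.  Vectorized partial Fisher-Yates across all
# samples at once: i swap steps instead of n_samples calls to sample().
sample_combinations <- function(n, order, n_samples) {
  A <- matrix(rep(seq_len(n), each = n_samples), nrow = n_samples)
  rows <- seq_len(n_samples)
  for (k in seq_len(order)) {
    j <- k + floor(stats::runif(n_samples) * (n - k + 1))
    jk <- cbind(rows, j)
    kk <- cbind(rows, k)
    tmp <- A[jk]
    A[jk] <- A[kk]
    A[kk] <- tmp
  }
  A[, seq_len(order), drop = FALSE]
}

# shared species counts and per-site richness for a batch of site tuples
shared_counts <- function(cm, tuples) {
  X <- unclass(cm)
  i <- ncol(tuples)
  acc <- X[tuples[, 1L], , drop = FALSE]
  if (i > 1L)
    for (k in 2:i) acc <- acc * X[tuples[, k], , drop = FALSE]
  rich <- matrix(site_richness(cm)[tuples], nrow = nrow(tuples))
  list(shared = rowSums(acc), rich = rich)
}

normalize_shared <- function(shared, rich, scheme) {
  denom <- switch(scheme,
                  sorensen = rowMeans(rich),
                  simpson  = apply(rich, 1L, min),
                  stop("scheme must be 'sorensen' or 'simpson'",
                       call. = FALSE))
  out <- ifelse(denom > 0, shared / denom, 0)
  as.numeric(out)
}

#' Normalize a shared-species count to the Sorensen or Simpson scale
#'
#' Sorensen: shared species divided by the mean richness of the
#' combination's sites (richness-dependent turnover); Simpson: divided by
#' the minimum richness ("true" turnover).  A combination whose sites all
#' have zero richness is defined as 0.
#'
#' @param shared shared-species count(s) of the combination(s).
#' @param richness matrix (combinations x sites) or vector of per-site
#'   richness of the combination's sites.
#' @param scheme `"sorensen"` or `"simpson"`.
#' @return Normalized value(s) in \[0, 1\].
#' @export
normalize_zeta <- function(shared, richness, scheme = c("sorensen", "simpson")) {
  scheme <- match.arg(scheme)
  if (!is.matrix(richness)) richness <- matrix(richness, nrow = 1L)
  normalize_shared(shared, richness, scheme)
}

#' Zeta decline across orders
#'
#' Computes zeta diversity for orders `1..max_order`, exactly (closed
#' form, the default) or by Monte Carlo sampling.  Normalized curves
#' report the mean of per-combination normalized values, which is what a
#' regression on per-combination records requires; under `"raw"` the exact
#' mode uses the closed form and the Monte Carlo mode the sample mean.
#'
#' @param cm a [community_matrix()].
#' @param orders integer vector of zeta orders (default
#'   `1:min(nrow(cm), 50)`).
#' @param mode `"exact"` or `"montecarlo"`.  Normalized values
#'   (`normalization != "raw"`) require per-combination richness and are
#'   only available in Monte Carlo mode except at orders 1 and 2, where
#'   exact enumeration is cheap and used automatically.
#' @param normalization `"raw"`, `"sorensen"` or `"simpson"`.
#' @param n_samples Monte Carlo combinations per order (default 1e4).
#' @param seed integer seed used in Monte Carlo mode.
#' @return An object of class `zeta_decline`: a list with `orders`,
#'   `zeta`, `sd`, `sem`, `mode`, `normalization` and (Monte Carlo mode)
#'   `samples`, a list of `zeta_samples` per order.
#' @export
zeta_decline <- function(cm, orders = NULL,
                         mode = c("exact", "montecarlo"),
                         normalization = c("raw", "sorensen", "simpson"),
                         n_samples = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  n <- nrow(cm)
  if (is.null(orders)) orders <- seq_len(min(n, 50L))
  if (any(orders < 1L) || any(orders > n))
    stop("orders must lie in [1, ", n, "]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  samples <- NULL
  if (mode == "exact" && normalization == "raw") {
    zeta <- vapply(orders, function(i) zeta_exact(cm, i), numeric(1))
    sd <- sem <- rep(NA_real_, length(orders))
  } else if (mode == "exact") {
    # exact normalized decline by full enumeration; feasible for small
    # matrices or low orders, otherwise prefer montecarlo
    vals <- lapply(orders, function(i) {
      tuples <- t(utils::combn(n, i))
      res <- shared_counts(cm, tuples)
      normalize_shared(res$shared, res$rich, normalization)
    })
    zeta <- vapply(vals, mean, numeric(1))
    sd <- vapply(vals, stats::sd, numeric(1))
    sem <- sd / sqrt(vapply(vals, length, numeric(1)))
  } else {
    samples <- lapply(orders, function(i)
      zeta_montecarlo(cm, i, n_samples = n_samples))
    if (normalization == "raw") {
      zeta <- vapply(samples, `[[`, numeric(1), "zeta")
      sd <- vapply(samples, `[[`, numeric(1), "sd")
    } else {
      zeta <- vapply(samples, function(s)
        mean(s$records[[normalization]]), numeric(1))
      sd <- vapply(samples, function(s)
        stats::sd(s$records[[normalization]]), numeric(1))
    }
    sem <- sd / sqrt(n_samples)
  }
  structure(list(orders = orders, zeta = zeta, sd = sd, sem = sem,
                 mode = mode, normalization = normalization,
                 samples = samples),
            class = "zeta_decline")
}

#' @export
print.zeta_decline <- function(x, ...) {
  cat(sprintf("zeta_decline (%s, %s), orders %d..%d\n", x$mode,
              x$normalization, min(x$orders), max(x$orders)))
  print(data.frame(order = x$orders, zeta = x$zeta, sd = x$sd),
        row.names = FALSE)
  invisible(x)
}

#' Retention rate of a zeta decline
#'
#' The retention rate is the ratio of consecutive zeta values: the
#' probability-scale proportion of shared species retained when one more
#' site is added.  We report \eqn{\zeta_i / \zeta_{i-1}} at order
#' \eqn{i} (the order of the larger combination, i.e. the ratio's
#' denominator order plus one), so values lie in \[0, 1\].  Ratios whose
#' denominator zeta is 0 are returned as `NA` rather than an error.
#'
#' @param decline a [zeta_decline()] object, or a numeric vector of zeta
#'   values at consecutive orders starting at `orders[1]`.
#' @param orders integer orders matching `decline` when it is a bare
#'   numeric vector.
#' @return A named numeric vector of retention rates indexed by order
#'   (starting at the second available order).
#' @export
retention_rate <- function(decline, orders = NULL) {
  if (inherits(decline, "zeta_decline")) {
    zeta <- decline$zeta
    orders <- decline$orders
  } else {
    zeta <- decline
    if (is.null(orders)) orders <- seq_along(zeta)
  }
  if (any(diff(orders) != 1L))
    stop("retention rate requires consecutive orders", call. = FALSE)
  num <- zeta[-1L]
  den <- zeta[-length(zeta)]
  ratio <- ifelse(den > 0, num / den, NA_real_)
  stats::setNames(ratio, orders[-1L])
}
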
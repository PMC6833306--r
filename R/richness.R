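#' Distance-based Moran eigenvector maps (dbMEM)
#'
#' Spatial eigenfunctions used as covariates to absorb spatial
#' autocorrelation.  Pairwise Euclidean distances are truncated: values
#' above the threshold (default: the longest edge of the minimum
#' spanning tree, the conventional dbMEM default) are replaced by 4x the
#' threshold; the truncated matrix is double-centred (Gower) and
#' eigendecomposed; eigenvectors with positive eigenvalue are returned
#' in decreasing-eigenvalue order.  Eigenvectors are orthonormal and
#' orthogonal to the constant vector.
#'
#' @param st a `site_table` (coordinates `x`, `y` in km).
#' @param truncation optional truncation distance; `NULL` uses the
#'   longest minimum-spanning-tree edge.
#' @return A list of class `dbmem` with `vectors` (sites x k), `values`
#'   (positive eigenvalues, decreasing) and `truncation`.
#' @export
dbmem <- function(st, truncation = NULL) {
  coords <- cbind(st$x, st$y)
  if (nrow(coords) < 3L) stop("need >= 3 sites", call. = FALSE)
  d <- stats::dist(coords)
  if (max(d) == 0) stop("all sites coincident", call. = FALSE)
  if (is.null(truncation))
    truncation <- max(vegan::spantree(d)$dist)
  D <- as.matrix(d)
  D[D > truncation] <- 4 * truncation
  A <- -0.5 * D^2
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- sqrt(.Machine$double.eps) * max(abs(e$values))
  keep <- e$values > tol
  vec <- e$vectors[, keep, drop = FALSE]
  colnames(vec) <- paste0("MEM", seq_len(ncol(vec)))
  structure(list(vectors = vec, values = e$values[keep],
                 truncation = truncation),
            class = "dbmem")
}

#' Spline-Poisson regression of site richness on covariates
#'
#' Log-link Poisson regression of per-site species richness on an
#' unpenalized cubic regression spline (3 knots) per covariate, plus
#' linear terms for the supplied spatial eigenvectors, fitted by
#' penalized iteratively reweighted least squares via [mgcv::gam()].
#' With 3 knots per spline the model is low-dimensional, so no smoothing
#' penalty is applied by default (`fx = TRUE`); set `ridge = TRUE` to
#' let mgcv estimate penalties instead.  Reports deviance explained
#' (1 - residual/null deviance), pseudo-R^2 (squared correlation of
#' observed and fitted), and a likelihood-ratio chi-square p-value per
#' covariate from dropping its smooth.
#'
#' @param richness non-negative integer vector of per-site counts.
#' @param st `site_table` holding the covariates.
#' @param covariates character vector of covariate column names.
#' @param spatial optional [dbmem()] object (or matrix of spatial
#'   eigenvectors) entered as linear terms.
#' @param knots knots per covariate spline (default 3).
#' @param ridge use penalized splines instead of fixed df.
#' @return A list of class `richness_fit` with `gam` (the mgcv fit),
#'   `deviance_explained`, `pseudo_r2`, `p_values` (per covariate),
#'   `converged`.
#' @export
fit_richness <- function(richness, st, covariates, spatial = NULL,
                         knots = 3L, ridge = FALSE) {
  if (any(richness < 0) || any(richness != round(richness)))
    stop("richness must be non-negative integers", call. = FALSE)
  dat <- as.data.frame(st)[, covariates, drop = FALSE]
  const <- vapply(dat, function(v) stats::sd(v) == 0, logical(1))
  if (any(const))
    stop("constant covariate(s): ",
         paste(covariates[const], collapse = ", "), call. = FALSE)
  dat$.richness <- richness
  sterms <- sprintf("s(%s, bs = 'cr', k = %d, fx = %s)", covariates,
                    knots, if (ridge) "FALSE" else "TRUE")
  mem_names <- character(0)
  if (!is.null(spatial)) {
    M <- if (inherits(spatial, "dbmem")) spatial$vectors else spatial
    mem_names <- colnames(M) %||% paste0("MEM", seq_len(ncol(M)))
    colnames(M) <- mem_names
    dat <- cbind(dat, as.data.frame(M))
  }
  rhs <- paste(c(sterms, mem_names), collapse = " + ")
  fml <- stats::as.formula(paste(".richness ~", rhs))
  fit <- mgcv::gam(fml, family = stats::poisson(), data = dat,
                   method = "REML")
  if (!fit$converged)
    warning("IRLS did not converge; diagnostics in $gam")
  dev_expl <- 1 - fit$deviance / fit$null.deviance
  pseudo_r2 <- stats::cor(richness, stats::fitted(fit))^2
  # likelihood-ratio test per covariate: drop its smooth, compare deviance
  p_values <- vapply(covariates, function(cv) {
    rest <- setdiff(covariates, cv)
    rhs0 <- paste(c(sprintf("s(%s, bs = 'cr', k = %d, fx = %s)", rest,
                            knots, if (ridge) "FALSE" else "TRUE"),
                    mem_names, "1"), collapse = " + ")
    fit0 <- mgcv::gam(stats::as.formula(paste(".richness ~", rhs0)),
                      family = stats::poisson(), data = dat,
                      method = "REML")
    dd <- fit0$deviance - fit$deviance
    df <- sum(fit0$edf) ; df <- abs(sum(fit$edf) - sum(fit0$edf))
    stats::pchisq(max(dd, 0), df = max(df, 1e-8), lower.tail = FALSE)
  }, numeric(1))
  structure(list(gam = fit, deviance_explained = dev_expl,
                 pseudo_r2 = pseudo_r2, p_values = p_values,
                 converged = fit$converged),
            class = "richness_fit")
}

#' @export
print.richness_fit <- function(x, ...) {
  cat(sprintf(
    "richness_fit: deviance explained %.3f, pseudo-R2 %.3f%s\n",
    x$deviance_explained, x$pseudo_r2,
    if (!x$converged) " (NOT converged)" else ""))
  if (length(x$p_values)) {
    cat("per-covariate LRT p-values:\n")
    print(signif(x$p_values, 3))
  }
  invisible(x)
}

#' Smooth relationship between richness of two species categories
#'
#' Fits one category's per-site richness as a 3-knot spline function of
#' another's under a log-link Poisson model, and inspects the fitted
#' curve for an interior maximum (a "hump": richness of one category
#' peaking at intermediate richness of the other).
#'
#' @param richness_a predictor counts (per site).
#' @param richness_b response counts (per site), aligned to
#'   `richness_a`.
#' @param knots spline knots (default 3).
#' @return A list of class `richness_relationship` with `fit` (a
#'   `richness_fit`), `curve` (data.frame `a`, `fitted` over the
#'   predictor range), `hump` (logical: interior maximum) and
#'   `hump_location`.
#' @export
richness_relationship <- function(richness_a, richness_b, knots = 3L) {
  if (stats::sd(richness_a) == 0)
    stop("constant predictor", call. = FALSE)
  st <- data.frame(site = seq_along(richness_a), x = seq_along(richness_a),
                   y = 0, a = as.numeric(richness_a))
  fit <- fit_richness(richness_b, st, "a", knots = knots)
  grid <- seq(min(richness_a), max(richness_a), length.out = 200L)
  mu <- stats::predict(fit$gam, newdata = data.frame(a = grid),
                       type = "response")
  imax <- which.max(mu)
  hump <- imax > 1L && imax < length(grid)
  structure(list(fit = fit,
                 curve = data.frame(a = grid, fitted = as.numeric(mu)),
                 hump = hump,
                 hump_location = if (hump) grid[imax] else NA_real_),
            class = "richness_relationship")
}
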
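#' Monotone I-spline basis on \[0, 1\]
#'
#' I-splines are integrated M-splines: each basis function is monotone
#' non-decreasing, 0 at `x = 0` and 1 at `x = 1`, so a non-negative
#' linear combination is itself monotone non-decreasing — the property
#' that makes them the canonical basis for generalized dissimilarity
#' modelling.  With order `k` and `n_basis` functions the basis uses
#' `n_basis - k` equally spaced internal knots on \[0, 1\].  The default
#' (order 2, 3 basis functions, one internal knot at 0.5) matches the
#' "first/second/third I-spline" reporting convention of multi-site GDM.
#'
#' @param order spline order (2 = piecewise-linear M-splines, hence
#'   piecewise-quadratic I-splines).
#' @param n_basis number of basis functions per predictor (>= order).
#' @return A list of class `ispline_basis` with `order`, `n_basis` and
#'   `knots` (the internal knots).
#' @export
ispline_basis <- function(order = 2L, n_basis = 3L) {
  if (n_basis < order) stop("n_basis must be >= order", call. = FALSE)
  n_int <- n_basis - order
  knots <- if (n_int > 0) seq(0, 1, length.out = n_int + 2L)[-c(1L, n_int + 2L)]
           else numeric(0)
  structure(list(order = as.integer(order), n_basis = as.integer(n_basis),
                 knots = knots),
            class = "ispline_basis")
}

#' Evaluate the I-spline basis
#'
#' Uses the identity between I-splines of order `k` and partial sums of
#' B-splines of order `k + 1` on the same internal knots:
#' \eqn{I_j(x) = \sum_{m > j} B_m(x)} (dropping the first B-spline),
#' evaluated with [splines::splineDesign()].
#'
#' @param x numeric vector with values in \[0, 1\].
#' @param basis an [ispline_basis()].
#' @return Matrix `length(x) x n_basis`; each column non-decreasing in
#'   `x`, equal to 0 at `x = 0` and 1 at `x = 1`.
#' @export
ispline_transform <- function(x, basis = ispline_basis()) {
  if (any(x < 0 | x > 1, na.rm = TRUE) || anyNA(x))
    stop("x must lie in [0, 1]; rescale before transforming", call. = FALSE)
  k <- basis$order + 1L  # B-spline order
  aug <- c(rep(0, k), basis$knots, rep(1, k))
  B <- splines::splineDesign(aug, x, ord = k, outer.ok = TRUE)
  # B has n_basis + 1 columns; I_j = sum of B-splines m = j+1 .. n_basis+1
  nb <- basis$n_basis
  out <- matrix(0, length(x), nb)
  for (j in seq_len(nb))
    out[, j] <- rowSums(B[, (j + 1L):(nb + 1L), drop = FALSE])
  colnames(out) <- paste0("I", seq_len(nb))
  out
}

# min-max rescale to [0, 1]; constant vectors return NULL (caller drops)
rescale01 <- function(v) {
  r <- range(v)
  if (r[2] - r[1] <= 0) return(NULL)
  (v - r[1]) / (r[2] - r[1])
}

# mean pairwise absolute difference of covariate values over each
# record's sites (tuples: records x order matrix of site indices)
mean_pairwise_diff <- function(values, tuples) {
  i <- ncol(tuples)
  V <- matrix(values[tuples], nrow = nrow(tuples))
  if (i == 1L) return(rep(0, nrow(tuples)))
  tot <- numeric(nrow(tuples))
  for (a in seq_len(i - 1L))
    for (b in (a + 1L):i)
      tot <- tot + abs(V[, a] - V[, b])
  tot / choose(i, 2)
}

mean_pairwise_dist <- function(x, y, tuples) {
  i <- ncol(tuples)
  X <- matrix(x[tuples], nrow = nrow(tuples))
  Y <- matrix(y[tuples], nrow = nrow(tuples))
  if (i == 1L) return(rep(0, nrow(tuples)))
  tot <- numeric(nrow(tuples))
  for (a in seq_len(i - 1L))
    for (b in (a + 1L):i)
      tot <- tot + sqrt((X[, a] - X[, b])^2 + (Y[, a] - Y[, b])^2)
  tot / choose(i, 2)
}

#' Build an MS-GDM regression design from sampled site combinations
#'
#' For each sampled combination of `order` sites: the response is the
#' normalized zeta of the focal matrix; each covariate is summarized as
#' the mean pairwise absolute difference among the combination's sites,
#' min-max rescaled to \[0, 1\] across records; geographic distance is
#' the mean pairwise Euclidean distance, rescaled likewise.  An optional
#' biotic predictor is `1 -` the normalized zeta of another category's
#' matrix on the identical site tuple (dissimilarity orientation),
#' rescaled to \[0, 1\].
#'
#' @param cm focal [community_matrix()].
#' @param st `site_table` aligned to `cm`.
#' @param records a `zeta_samples` object from [zeta_montecarlo()] run on
#'   `cm`, providing the site tuples and the focal normalized zeta.
#' @param covariates character vector of site-table columns to use.
#' @param biotic_cm optional `community_matrix` of another category on
#'   the same sites, added as a biotic turnover predictor.
#' @param scheme `"sorensen"` or `"simpson"`.
#' @param include_distance add the geographic-distance predictor.
#' @param summary_fn how covariate values are summarized over each
#'   combination: `"mean"` (mean pairwise |difference|) or `"max"`.
#' @return A list of class `msgdm_design` with `response` (normalized
#'   zeta similarity in \[0, 1\]), `predictors` (matrix of \[0, 1\]
#'   dissimilarity-oriented columns), `order`, `scheme`, `dropped`
#'   (constant covariates removed with a warning).
#' @export
build_design <- function(cm, st, records, covariates,
                         biotic_cm = NULL,
                         scheme = c("sorensen", "simpson"),
                         include_distance = TRUE,
                         summary_fn = c("mean", "max")) {
  scheme <- match.arg(scheme)
  summary_fn <- match.arg(summary_fn)
  validate_study(cm, st)
  order <- records$order
  tuples <- as.matrix(records$records[, paste0("site", seq_len(order)),
                                      drop = FALSE])
  response <- records$records[[scheme]]

  cols <- list(); dropped <- character(0)
  for (cv in covariates) {
    v <- st[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not in site table",
                         call. = FALSE)
    d <- if (summary_fn == "mean") mean_pairwise_diff(v, tuples)
         else max_pairwise_diff(v, tuples)
    r <- rescale01(d)
    if (is.null(r)) {
      warning("covariate '", cv, "' constant across records; dropped")
      dropped <- c(dropped, cv)
    } else cols[[cv]] <- r
  }
  if (include_distance) {
    d <- mean_pairwise_dist(st$x, st$y, tuples)
    r <- rescale01(d)
    if (is.null(r)) {
      warning("distance constant across records; dropped")
      dropped <- c(dropped, "distance")
    } else cols[["distance"]] <- r
  }
  if (!is.null(biotic_cm)) {
    res <- shared_counts(biotic_cm, tuples)
    bz <- normalize_shared(res$shared, res$rich, scheme)
    r <- rescale01(1 - bz)
    if (is.null(r)) {
      warning("biotic predictor constant across records; dropped")
      dropped <- c(dropped, "biotic")
    } else cols[["biotic"]] <- r
  }
  if (!length(cols)) stop("no usable predictors", call. = FALSE)
  structure(list(response = response,
                 predictors = do.call(cbind, cols),
                 order = order, scheme = scheme, dropped = dropped),
            class = "msgdm_design")
}

#' Construct an MS-GDM design from ready-made columns
#'
#' Low-level constructor for [fit_msgdm()] when the response and the
#' \[0, 1\] predictor columns are already in hand (e.g. simulation
#' studies); [build_design()] is the high-level route from community
#' data.
#'
#' @param response numeric vector of normalized zeta similarities in
#'   \[0, 1\].
#' @param predictors numeric matrix with named columns in \[0, 1\],
#'   dissimilarity-oriented.
#' @param order the zeta order the rows represent.
#' @param scheme `"sorensen"` or `"simpson"`.
#' @return An `msgdm_design`.
#' @export
msgdm_design <- function(response, predictors, order = 2L,
                         scheme = c("sorensen", "simpson")) {
  scheme <- match.arg(scheme)
  predictors <- as.matrix(predictors)
  if (length(response) != nrow(predictors))
    stop("response and predictors disagree in length", call. = FALSE)
  if (anyNA(response) || anyNA(predictors))
    stop("missing values in design", call. = FALSE)
  if (any(predictors < 0 | predictors > 1))
    stop("predictor columns must lie in [0, 1]", call. = FALSE)
  if (is.null(colnames(predictors)))
    colnames(predictors) <- paste0("p", seq_len(ncol(predictors)))
  structure(list(response = as.numeric(response), predictors = predictors,
                 order = as.integer(order), scheme = scheme,
                 dropped = character(0)),
            class = "msgdm_design")
}

max_pairwise_diff <- function(values, tuples) {
  V <- matrix(values[tuples], nrow = nrow(tuples))
  apply(V, 1L, max) - apply(V, 1L, min)
}

#' Fit a multi-site generalized dissimilarity model
#'
#' Regresses compositional dissimilarity (`1 -` normalized zeta) on
#' I-spline-transformed predictor dissimilarities with all spline
#' coefficients constrained non-negative (Lawson-Hanson non-negative
#' least squares; the intercept is unconstrained).  Non-negativity plus
#' the monotone I-spline basis guarantees the fitted dissimilarity
#' surface is monotone non-decreasing in every predictor.  Variance
#' explained is the squared Pearson correlation between observed and
#' predicted response; per-predictor importance is the maximum value of
#' its fitted spline, i.e. the sum of its coefficients (each I-spline
#' reaches 1 at `x = 1`).
#'
#' @param design an [build_design()] result.
#' @param basis an [ispline_basis()].
#' @return An object of class `msgdm_fit`: list with `coefficients`
#'   (matrix predictors x basis), `intercept`, `importance`,
#'   `variance_explained`, `predicted` (on the response/similarity
#'   scale), `rank_deficient` (names of predictors flagged when the
#'   design is rank deficient), `order`, `scheme`, `basis`.
#' @export
fit_msgdm <- function(design, basis = ispline_basis()) {
  P <- design$predictors
  npred <- ncol(P)
  nb <- basis$n_basis
  n <- nrow(P)
  if (n < 10 * (npred * nb + 1))
    warning("fewer than 10 records per coefficient; fit may be unstable")
  X <- matrix(0, n, npred * nb)
  for (j in seq_len(npred))
    X[, (j - 1L) * nb + seq_len(nb)] <- ispline_transform(P[, j], basis)
  colnames(X) <- as.vector(outer(paste0("I", seq_len(nb)),
                                 colnames(P),
                                 function(i, p) paste(p, i, sep = ".")))
  y <- 1 - design$response  # dissimilarity orientation
  # unconstrained intercept via a +/- column pair inside NNLS
  C <- cbind(`(int+)` = 1, `(int-)` = -1, X)
  sol <- pracma::lsqnonneg(C, y)
  beta <- sol$x
  intercept <- beta[1L] - beta[2L]
  coefs <- matrix(beta[-(1:2)], nrow = npred, byrow = TRUE,
                  dimnames = list(colnames(P), paste0("I", seq_len(nb))))
  pred_dis <- as.vector(C %*% beta)
  ve <- if (stats::sd(pred_dis) > 0 && stats::sd(y) > 0)
    stats::cor(y, pred_dis)^2 else 0
  qrX <- qr(X)
  rank_def <- character(0)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    rank_def <- unique(colnames(P)[ceiling(bad / nb)])
  }
  structure(list(coefficients = coefs, intercept = intercept,
                 importance = rowSums(coefs),
                 variance_explained = ve,
                 predicted = 1 - pred_dis,
                 rank_deficient = rank_def,
                 order = design$order, scheme = design$scheme,
                 basis = basis),
            class = "msgdm_fit")
}

#' @export
print.msgdm_fit <- function(x, ...) {
  cat(sprintf("msgdm_fit (order %d, %s): variance explained %.3f\n",
              x$order, x$scheme, x$variance_explained))
  cat("importance (max spline value):\n")
  print(round(sort(x$importance, decreasing = TRUE), 4))
  if (length(x$rank_deficient))
    cat("rank-deficient predictors:",
        paste(x$rank_deficient, collapse = ", "), "\n")
  invisible(x)
}

#' Run the abiotic and biotic MS-GDM model suite over zeta orders
#'
#' For each order: samples one set of site combinations on the focal
#' category and fits (a) the abiotic model (environmental covariates +
#' distance), (b) biotic model I adding the non-endemic (`NON_E`) zeta
#' on the identical combinations, and (c) biotic model II adding the
#' other endemic category's zeta.  Sharing the combination sample across
#' models makes variance-explained comparisons paired.
#'
#' @param study a `synthetic_study`, or a list with elements `cm` and
#'   `site_table`.
#' @param focal_category focal category (`"NE"` or `"PE"`; `"NON_E"` is
#'   allowed for the abiotic model only — biotic model I is undefined
#'   for the non-endemics themselves).
#' @param orders zeta orders to fit (default `2:8`).
#' @param scheme `"sorensen"` or `"simpson"`.
#' @param covariates site-table columns (default: all covariates except
#'   coordinates, VIF-screening left to the caller).
#' @param models subset of `c("abiotic", "biotic1", "biotic2")`.
#' @param n_samples combinations sampled per order (default 1000).
#' @param seed integer seed.
#' @param basis an [ispline_basis()].
#' @return A list of class `msgdm_suite`: per-order list of fits per
#'   model, plus a `variance_explained` data.frame (order x model).
#' @export
run_model_suite <- function(study, focal_category, orders = 2:8,
                            scheme = c("sorensen", "simpson"),
                            covariates = NULL,
                            models = c("abiotic", "biotic1", "biotic2"),
                            n_samples = 1000L, seed = 1L,
                            basis = ispline_basis()) {
  scheme <- match.arg(scheme)
  models <- match.arg(models, several.ok = TRUE)
  cm <- study$cm; st <- study$site_table
  if (focal_category == "NON_E" && any(models != "abiotic"))
    stop("biotic models are undefined for focal category NON_E",
         call. = FALSE)
  focal <- subset_by_category(cm, focal_category)
  if (is.null(covariates))
    covariates <- setdiff(covariate_names(st), "site")
  other_endemic <- setdiff(c("NE", "PE"), focal_category)
  set.seed(seed)
  fits <- list()
  for (i in orders) {
    rec <- zeta_montecarlo(focal, i, n_samples = n_samples)
    per <- list()
    if ("abiotic" %in% models)
      per$abiotic <- fit_msgdm(
        build_design(focal, st, rec, covariates, scheme = scheme), basis)
    if ("biotic1" %in% models)
      per$biotic1 <- fit_msgdm(
        build_design(focal, st, rec, covariates,
                     biotic_cm = subset_by_category(cm, "NON_E"),
                     scheme = scheme), basis)
    if ("biotic2" %in% models && length(other_endemic))
      per$biotic2 <- fit_msgdm(
        build_design(focal, st, rec, covariates,
                     biotic_cm = subset_by_category(cm, other_endemic),
                     scheme = scheme), basis)
    fits[[as.character(i)]] <- per
  }
  ve <- do.call(rbind, lapply(names(fits), function(i) {
    data.frame(order = as.integer(i),
               model = names(fits[[i]]),
               variance_explained = vapply(fits[[i]],
                 `[[`, numeric(1), "variance_explained"),
               row.names = NULL)
  }))
  structure(list(fits = fits, variance_explained = ve,
                 focal_category = focal_category, scheme = scheme,
                 orders = orders, seed = seed),
            class = "msgdm_suite")
}

#' @export
print.msgdm_suite <- function(x, ...) {
  cat(sprintf("msgdm_suite: focal %s, %s index\n", x$focal_category,
              x$scheme))
  print(stats::reshape(x$variance_explained, direction = "wide",
                       idvar = "order", timevar = "model"),
        row.names = FALSE)
  invisible(x)
}
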
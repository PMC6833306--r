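#' Fit a parametric form to a zeta decline
#'
#' Declines of zeta diversity with order are classically summarized by a
#' negative exponential (\eqn{\zeta_i \propto e^{-b_{exp} i}}, equal
#' per-site occurrence chance, i.e. stochastic assembly) or a power law
#' (\eqn{\zeta_i \propto i^{-b_{pl}}}, site-specific occurrence chance,
#' i.e. niche assembly).  Fits are ordinary least squares on
#' \eqn{\log\zeta_i}: the exponential form regresses on \eqn{i}, the
#' power law on \eqn{\log i}, and the combined form on both
#' (\eqn{\log\zeta_i = a - b_{exp} i - b_{pl}\log i}).  Log-scale OLS is
#' standard practice for these forms and stabilizes the combined model.
#' Coefficients are reported with two-sided t-test p-values and are not
#' constrained to be non-negative; a negative fitted coefficient is
#' reported with its p-value.
#'
#' @param decline a [zeta_decline()] object or a numeric vector of zeta
#'   values (with `orders` supplied).
#' @param segment integer vector of orders to fit over (default: all
#'   available orders).
#' @param form `"exponential"`, `"powerlaw"` or `"combined"`.
#' @param orders orders matching `decline` when it is a bare vector.
#' @return An object of class `decline_fit`: list with `form`, `segment`,
#'   `intercept`, `b_exp`, `b_pl` (NA where not in the model), `p_exp`,
#'   `p_pl`, `aic`, `lm` (the underlying fit) and `fitted` (fitted zeta on
#'   the raw scale).
#' @export
fit_decline <- function(decline, segment = NULL,
                        form = c("combined", "exponential", "powerlaw"),
                        orders = NULL) {
  form <- match.arg(form)
  if (inherits(decline, "zeta_decline")) {
    zeta <- decline$zeta
    orders <- decline$orders
  } else {
    zeta <- decline
    if (is.null(orders)) orders <- seq_along(zeta)
  }
  if (is.null(segment)) segment <- orders
  keep <- orders %in% segment
  i <- orders[keep]
  z <- zeta[keep]
  ncoef <- switch(form, combined = 3L, 2L)
  if (length(i) < ncoef + 1L)
    stop("segment too short: need at least ", ncoef + 1L, " orders",
         call. = FALSE)
  if (any(z <= 0))
    stop("zero or negative zeta in segment; shorten the segment to orders ",
         "with positive zeta", call. = FALSE)
  dat <- data.frame(logz = log(z), i = i, logi = log(i))
  fml <- switch(form,
                exponential = logz ~ i,
                powerlaw    = logz ~ logi,
                combined    = logz ~ i + logi)
  fit <- stats::lm(fml, data = dat)
  cf <- summary(fit)$coefficients
  get <- function(term, col) if (term %in% rownames(cf)) cf[term, col] else NA_real_
  structure(list(form = form, segment = i,
                 intercept = cf["(Intercept)", 1L],
                 b_exp = -get("i", 1L), p_exp = get("i", 4L),
                 b_pl = -get("logi", 1L), p_pl = get("logi", 4L),
                 se_exp = get("i", 2L), se_pl = get("logi", 2L),
                 aic = stats::AIC(fit),
                 lm = fit,
                 fitted = exp(stats::fitted(fit))),
            class = "decline_fit")
}

#' @export
print.decline_fit <- function(x, ...) {
  cat(sprintf("decline_fit [%s] over orders %d..%d\n", x$form,
              min(x$segment), max(x$segment)))
  cat(sprintf("  b_exp = %.4f (p = %.3g)   b_pl = %.4f (p = %.3g)   AIC = %.2f\n",
              x$b_exp, x$p_exp, x$b_pl, x$p_pl, x$aic))
  invisible(x)
}

#' Select the decline form (exponential vs power law) by AIC
#'
#' Compares the two two-parameter hypotheses about the decline — equal
#' per-site occurrence chance (exponential) versus site-specific chance
#' (power law) — by AIC of the log-scale fits.  The three-parameter
#' combined model nests both and is used for coefficient reporting (see
#' [fit_decline()] and [fit_piecewise()]), not for form selection: with
#' the short order ranges typical of decline curves its extra parameter
#' makes AIC comparisons against the two-parameter forms unstable, while
#' the exponential-vs-power-law contrast is the process diagnosis of
#' interest.
#'
#' @inheritParams fit_decline
#' @return A list with `chosen` (`"exponential"` or `"powerlaw"`), `fits`
#'   (both `decline_fit`s) and `delta_aic` (AIC(powerlaw) -
#'   AIC(exponential); negative favours the power law).
#' @export
select_decline_form <- function(decline, segment = NULL, orders = NULL) {
  fe <- fit_decline(decline, segment, "exponential", orders)
  fp <- fit_decline(decline, segment, "powerlaw", orders)
  chosen <- if (fe$aic <= fp$aic) "exponential" else "powerlaw"
  list(chosen = chosen, fits = list(exponential = fe, powerlaw = fp),
       delta_aic = fp$aic - fe$aic)
}

#' Locate the retention-rate breakpoint between rare and widespread species
#'
#' Low zeta orders (the increasing limb of the retention-rate curve)
#' reflect rare species; higher orders (the decreasing limb) reflect
#' widespread species.  The breakpoint is the order at the retention-rate
#' maximum, taking the first (lowest-order) maximum under ties.  If the
#' retention curve is monotone there is no peak: the midpoint of the
#' range is returned with `no_peak = TRUE`.
#'
#' @param retention named numeric vector from [retention_rate()] (names =
#'   orders) over at least 4 consecutive orders.
#' @return A list of class `breakpoint` with `order`, `no_peak`, and
#'   `rule` (a tag describing the selection rule).
#' @export
find_breakpoint <- function(retention) {
  retention <- retention[!is.na(retention)]
  if (length(retention) < 4L)
    stop("retention must be defined on at least 4 orders", call. = FALSE)
  ords <- as.integer(names(retention))
  if (is.null(names(retention)) || anyNA(ords))
    ords <- seq_along(retention) + 1L
  mono <- all(diff(retention) >= 0) || all(diff(retention) <= 0)
  if (mono) {
    b <- ords[ceiling(length(ords) / 2)]
    return(structure(list(order = b, no_peak = TRUE, rule = "midpoint"),
                     class = "breakpoint"))
  }
  b <- ords[which.max(retention)]  # which.max takes the first maximum
  structure(list(order = b, no_peak = FALSE, rule = "first-maximum"),
            class = "breakpoint")
}

#' @export
print.breakpoint <- function(x, ...) {
  cat(sprintf("breakpoint at order %d (%s%s)\n", x$order, x$rule,
              if (x$no_peak) ", no peak" else ""))
  invisible(x)
}

#' Piece-wise decline fits around the retention-rate breakpoint
#'
#' Splits the decline at the retention-rate breakpoint into a "rare"
#' segment (orders <= b) and a "widespread" segment (orders > b) and fits
#' the combined exponential + power-law form on each, mirroring the
#' rare-vs-widespread coefficient reporting of multi-site turnover
#' studies.  If a segment is too short for the combined model it is
#' widened by moving the split (with a warning) until both segments
#' support the fit.
#'
#' @param decline a [zeta_decline()] object.
#' @param retention optional retention-rate vector; computed from
#'   `decline` when omitted.
#' @param form model form per segment (default `"combined"`).
#' @return A list of class `piecewise_fit` with `rare`, `widespread`
#'   (both `decline_fit`s) and `breakpoint`.
#' @export
fit_piecewise <- function(decline, retention = NULL, form = "combined") {
  if (is.null(retention)) retention <- retention_rate(decline)
  bp <- find_breakpoint(retention)
  orders <- decline$orders
  ncoef <- if (form == "combined") 3L else 2L
  b <- bp$order
  # each segment needs ncoef + 1 points; shift the split if needed
  lo <- min(orders)
  hi <- max(orders)
  b_min <- lo + ncoef
  b_max <- hi - ncoef - 1L
  if (b_min > b_max)
    stop("decline too short for piece-wise fitting", call. = FALSE)
  if (b < b_min || b > b_max) {
    b_new <- min(max(b, b_min), b_max)
    warning(sprintf(
      "segment too short at breakpoint %d; widened to split at %d", b, b_new))
    b <- b_new
  }
  rare <- fit_decline(decline, segment = orders[orders <= b], form = form)
  widespread <- fit_decline(decline, segment = orders[orders > b], form = form)
  structure(list(rare = rare, widespread = widespread, breakpoint = bp,
                 split_order = b),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  print(x$breakpoint)
  cat("rare segment: "); print(x$rare)
  cat("widespread segment: "); print(x$widespread)
  invisible(x)
}

#' Classical multi-site diversity summary
#'
#' Gamma-diversity (number of species with occupancy >= 1), mean
#' alpha-diversity (mean per-site richness), and Whittaker's
#' beta-diversity (gamma / mean alpha).  A multiplicative beta index
#' under a user-configurable formula can be supplied through `n_star_fn`;
#' when none is given the Whittaker value is reported again under the
#' label `n_star` so downstream tables always carry the column, with the
#' `n_star_formula` field recording which formula was used.
#'
#' @param cm a [community_matrix()].
#' @param n_star_fn optional function `(gamma, mean_alpha, cm) -> numeric`
#'   implementing an alternative multiplicative beta index.
#' @return A list with `gamma`, `mean_alpha`, `whittaker_beta`, `n_star`
#'   and `n_star_formula`.
#' @export
beta_summary <- function(cm, n_star_fn = NULL) {
  occ <- occupancy(cm)
  if (all(occ == 0)) stop("all-empty community matrix", call. = FALSE)
  gamma <- sum(occ >= 1L)
  mean_alpha <- mean(site_richness(cm))
  whittaker <- gamma / mean_alpha
  if (is.null(n_star_fn)) {
    n_star <- whittaker
    formula_tag <- "whittaker (default)"
  } else {
    n_star <- n_star_fn(gamma, mean_alpha, cm)
    formula_tag <- "user-supplied"
  }
  list(gamma = gamma, mean_alpha = mean_alpha, whittaker_beta = whittaker,
       n_star = n_star, n_star_formula = formula_tag)
}
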
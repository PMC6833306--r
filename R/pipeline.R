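#' Default run configuration
#'
#' A `run_config` captures every knob of the full workflow so that a run
#' is reproducible from the config alone: generator settings (or input
#' paths), categories, zeta orders, sampling sizes, explicit seeds (no
#' wall-clock seeding), the normalization scheme, the MS-GDM model list
#' and the output directory.
#'
#' @param input optional list with `matrix`, `sites`, `categories` CSV
#'   paths; `NULL` generates a synthetic study instead.
#' @param seed master integer seed.
#' @param scale synthetic species-count scale factor.
#' @param w synthetic mixture weight on the neutral component.
#' @param categories categories to analyse.
#' @param orders zeta orders for declines.
#' @param msgdm_orders zeta orders for the MS-GDM suite.
#' @param n_samples Monte Carlo combinations per order for declines when
#'   sampling is needed.
#' @param msgdm_samples combinations per order for MS-GDM.
#' @param scheme `"sorensen"` or `"simpson"`.
#' @param models MS-GDM models to run.
#' @param n_perm permutations for the range-statistic tests.
#' @param out_dir output directory (`NULL`: no files written).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, seed = 1L, scale = 1, w = 0.5,
                       categories = CATEGORY_LEVELS,
                       orders = 1:15, msgdm_orders = 2:6,
                       n_samples = 10000L, msgdm_samples = 1000L,
                       scheme = "sorensen",
                       models = c("abiotic", "biotic1", "biotic2"),
                       n_perm = 999L, out_dir = NULL) {
  if (any(orders < 1L)) stop("orders must be >= 1", call. = FALSE)
  structure(list(input = input, seed = as.integer(seed), scale = scale,
                 w = w, categories = categories, orders = orders,
                 msgdm_orders = msgdm_orders, n_samples = n_samples,
                 msgdm_samples = msgdm_samples, scheme = scheme,
                 models = models, n_perm = n_perm, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys override [run_config()] defaults.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- run_config()
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  cfg
}

# polynomial rolling hash (two streams, moduli < 2^25 so the arithmetic
# stays exact in doubles); small stable config fingerprint
fnv1a32 <- function(s) {
  h1 <- 17; h2 <- 89
  for (b in utf8ToInt(s)) {
    h1 <- (h1 * 31 + b) %% 33554393
    h2 <- (h2 * 37 + b) %% 33554467
  }
  sprintf("%07x%07x", h1, h2)
}

config_hash <- function(cfg) {
  fnv1a32(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                           null = "null"))
}

#' Run the full multi-site turnover workflow
#'
#' Executes, in order: data generation (or ingestion), covariate VIF
#' screening, per-category diversity summaries and range statistics with
#' permutational tests, co-occurrence indices, spatially corrected
#' richness models, zeta declines with retention rates and piece-wise
#' decline fits, and the MS-GDM model suite for the endemic categories.
#' Every numeric output is fully determined by the config and its seed.
#' When `out_dir` is set, per-stage CSV/JSON artifacts and a single
#' `summary.json` (carrying the seed and a config hash) are written;
#' stage timings and warnings are logged to the console.
#'
#' @param cfg a [run_config()] (or path to a YAML config file).
#' @param quiet suppress stage logging.
#' @return A list of class `study_report` — the summary structure that
#'   is also serialized to JSON.
#' @export
run_study <- function(cfg = run_config(), quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  t0 <- proc.time()[["elapsed"]]
  log <- function(...) if (!quiet)
    message(sprintf("[%7.2fs] ", proc.time()[["elapsed"]] - t0), ...)

  log("stage: data")
  if (is.null(cfg$input)) {
    study <- generate_crete_like(seed = cfg$seed, scale = cfg$scale,
                                 w = cfg$w)
  } else {
    cm <- read_community(cfg$input$matrix, cfg$input$categories)
    st <- read_site_table(cfg$input$sites)
    study <- list(cm = cm, site_table = st, ground_truth = NULL,
                  seed = cfg$seed)
  }
  validate_study(study$cm, study$site_table)
  cats <- intersect(cfg$categories,
                    unique(species_category(study$cm)))

  log("stage: covariate screening")
  covs <- setdiff(covariate_names(study$site_table), "site")
  screen <- vif_screen(study$site_table, covs)

  log("stage: range statistics and co-occurrence")
  rs <- range_stats(study$cm, study$site_table)
  range_test <- perm_anova(rs$range_ratio, rs$category,
                           n_perm = cfg$n_perm, seed = cfg$seed)
  cooc <- lapply(stats::setNames(cats, cats), function(lab) {
    sub <- subset_by_category(study$cm, lab)
    list(c_score = c_score(sub), nodf = nodf(sub))
  })

  log("stage: richness models")
  mem <- dbmem(study$site_table)
  richness <- lapply(stats::setNames(cats, cats), function(lab) {
    sub <- subset_by_category(study$cm, lab)
    fit <- fit_richness(site_richness(sub), study$site_table,
                        screen$retained, spatial = mem)
    list(deviance_explained = fit$deviance_explained,
         pseudo_r2 = fit$pseudo_r2,
         p_values = as.list(fit$p_values))
  })

  log("stage: zeta declines and fits")
  declines <- list(); turnover <- list()
  for (lab in cats) {
    sub <- subset_by_category(study$cm, lab)
    dec <- zeta_decline(sub, orders = cfg$orders)
    ret <- retention_rate(dec)
    pw <- tryCatch(fit_piecewise(dec), error = function(e) NULL)
    form <- select_decline_form(dec)
    declines[[lab]] <- dec
    turnover[[lab]] <- list(
      beta = beta_summary(sub),
      zeta = as.list(stats::setNames(dec$zeta, dec$orders)),
      retention = as.list(ret),
      chosen_form = form$chosen,
      delta_aic = form$delta_aic,
      breakpoint = if (!is.null(pw)) pw$breakpoint$order else NA,
      rare_fit = if (!is.null(pw)) decline_fit_row(pw$rare) else NULL,
      widespread_fit = if (!is.null(pw)) decline_fit_row(pw$widespread)
                       else NULL)
  }

  log("stage: MS-GDM suite")
  msgdm <- list()
  for (lab in intersect(c("NE", "PE"), cats)) {
    suite <- run_model_suite(study, lab, orders = cfg$msgdm_orders,
                             scheme = cfg$scheme,
                             covariates = screen$retained,
                             models = cfg$models,
                             n_samples = cfg$msgdm_samples,
                             seed = cfg$seed)
    msgdm[[lab]] <- suite
  }

  report <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    categories = cats,
    covariates_retained = screen$retained,
    covariates_dropped = screen$dropped$covariate,
    range_test = list(f = range_test$f, p = range_test$p,
                      pairwise = range_test$pairwise),
    cooccurrence = cooc,
    richness = richness,
    turnover = turnover,
    msgdm_variance_explained = lapply(msgdm, `[[`, "variance_explained"))
  class(report) <- "study_report"

  if (!is.null(cfg$out_dir)) {
    log("stage: write artifacts to ", cfg$out_dir)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(cfg$input))
      write_study(study, file.path(cfg$out_dir, "data"))
    for (lab in names(declines))
      utils::write.csv(
        data.frame(order = declines[[lab]]$orders,
                   zeta = declines[[lab]]$zeta),
        file.path(cfg$out_dir, paste0("decline_", lab, ".csv")),
        row.names = FALSE)
    for (lab in names(msgdm))
      utils::write.csv(msgdm[[lab]]$variance_explained,
                       file.path(cfg$out_dir,
                                 paste0("msgdm_ve_", lab, ".csv")),
                       row.names = FALSE)
    utils::write.csv(rs, file.path(cfg$out_dir, "range_stats.csv"),
                     row.names = FALSE)
    write_summary_json(report, file.path(cfg$out_dir, "summary.json"))
  }
  log("done")
  report
}

decline_fit_row <- function(f) {
  list(b_exp = f$b_exp, p_exp = f$p_exp, b_pl = f$b_pl, p_pl = f$p_pl,
       aic = f$aic, orders = range(f$segment))
}

# serialize with a light schema check: required top-level keys present
write_summary_json <- function(report, path) {
  need <- c("schema_version", "seed", "config_hash", "categories",
            "turnover")
  missing <- setdiff(need, names(report))
  if (length(missing))
    stop("summary schema invalid; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report (seed ", x$seed, ", config ", x$config_hash, ")\n",
      sep = "")
  for (lab in names(x$turnover)) {
    tv <- x$turnover[[lab]]
    cat(sprintf(
      "  %-6s gamma %5d  mean alpha %8.2f  Whittaker beta %6.2f  form %s\n",
      lab, tv$beta$gamma, tv$beta$mean_alpha, tv$beta$whittaker_beta,
      tv$chosen_form))
  }
  invisible(x)
}
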
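#' @keywords internal
"_PACKAGE"

#' Species category labels
#'
#' The closed set of species categories used throughout the package:
#' non-endemics (`"NON_E"`), single-island neo-endemics (`"NE"`) and
#' single-island palaeo-endemics (`"PE"`).
#'
#' @export
CATEGORY_LEVELS <- c("NON_E", "NE", "PE")

#' Construct a community matrix
#'
#' A `community_matrix` bundles a binary site-by-species incidence matrix
#' with a category label per species.  It is the substrate of every
#' statistic in the package.
#'
#' @param incidence numeric or logical matrix, sites in rows and species in
#'   columns, entries 0/1 (1 = recorded present).  Row and column names are
#'   the site and species identifiers.
#' @param category character vector of species categories, one per column
#'   of `incidence`, each an element of [CATEGORY_LEVELS]; optionally named
#'   by species.  May be `NULL` to label every species `"NON_E"`.
#' @return An object of class `community_matrix`: the binary incidence
#'   matrix with attributes `category` (named character vector) and
#'   `zero_occupancy` (logical vector flagging species recorded in no
#'   site).  Zero-occupancy species are retained: they keep gamma-diversity
#'   counts aligned with the input checklist and contribute nothing to any
#'   shared-species count.
#' @examples
#' x <- matrix(c(1, 0, 0, 1, 1, 0, 1, 1, 1), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("sp1", "sp2", "sp3")))
#' cm <- community_matrix(x, c("PE", "NE", "NON_E"))
#' occupancy(cm)
#' @export
community_matrix <- function(incidence, category = NULL) {
  if (!is.matrix(incidence))
    incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "double"
  bad <- which(!(incidence %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(incidence)) + 1
    j <- ((bad[1] - 1) %/% nrow(incidence)) + 1
    stop(sprintf(
      "incidence must be binary; cell (%s, %s) is %s",
      rownames(incidence)[i] %||% i, colnames(incidence)[j] %||% j,
      format(incidence[i, j])), call. = FALSE)
  }
  if (is.null(dimnames(incidence)))
    dimnames(incidence) <- list(NULL, NULL)
  if (is.null(rownames(incidence)))
    rownames(incidence) <- paste0("site", seq_len(nrow(incidence)))
  if (is.null(colnames(incidence)) && ncol(incidence) > 0)
    colnames(incidence) <- paste0("sp", seq_len(ncol(incidence)))
  if (anyDuplicated(rownames(incidence)))
    stop("duplicate site identifiers", call. = FALSE)
  if (anyDuplicated(colnames(incidence)))
    stop("duplicate species identifiers", call. = FALSE)
  if (is.null(category))
    category <- rep("NON_E", ncol(incidence))
  if (ncol(incidence) == 0L) {
    category <- stats::setNames(character(0), character(0))
  } else if (!is.null(names(category))) {
    missing <- setdiff(colnames(incidence), names(category))
    if (length(missing))
      stop("species missing a category: ",
           paste(missing, collapse = ", "), call. = FALSE)
    category <- category[colnames(incidence)]
  } else {
    if (length(category) != ncol(incidence))
      stop("category must have one entry per species", call. = FALSE)
    names(category) <- colnames(incidence)
  }
  unknown <- setdiff(unique(category), CATEGORY_LEVELS)
  if (length(unknown))
    stop("unknown category label(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(CATEGORY_LEVELS, collapse = ", "),
         call. = FALSE)
  structure(incidence,
            category = category,
            zero_occupancy = colSums(incidence) == 0,
            class = c("community_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d sites x %d species\n", nrow(x), ncol(x)))
  tab <- table(factor(attr(x, "category"), levels = CATEGORY_LEVELS))
  cat("categories:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  nz <- sum(attr(x, "zero_occupancy"))
  if (nz) cat(nz, "species with zero occupancy (flagged, retained)\n")
  invisible(x)
}

#' @rdname community_matrix
#' @param cm a `community_matrix`.
#' @export
species_category <- function(cm) attr(cm, "category")

#' Read a community matrix and its category map from CSV
#'
#' The incidence file is comma-delimited UTF-8 with a site-id first column
#' and one 0/1 column per species (header row of species ids).  The
#' categories file maps species to labels with columns `species` and
#' `category`.  Row and column order are preserved from file.
#'
#' @param matrix_path path to the incidence CSV.
#' @param categories_path path to the species-category CSV; `NULL` labels
#'   all species `"NON_E"`.
#' @return A validated [community_matrix()].
#' @export
read_community <- function(matrix_path, categories_path = NULL) {
  raw <- utils::read.csv(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  sites <- as.character(raw[[1]])
  inc <- as.matrix(raw[, -1, drop = FALSE])
  rownames(inc) <- sites
  category <- NULL
  if (!is.null(categories_path)) {
    map <- utils::read.csv(categories_path, stringsAsFactors = FALSE)
    if (!all(c("species", "category") %in% names(map)))
      stop("categories file needs columns 'species' and 'category'",
           call. = FALSE)
    category <- stats::setNames(map$category, map$species)
  }
  community_matrix(inc, category)
}

#' Write a community matrix (and its category map) to CSV
#'
#' Inverse of [read_community()]: a read-write-read round trip reproduces
#' the incidence matrix exactly.
#'
#' @param cm a `community_matrix`.
#' @param matrix_path output path for the incidence CSV.
#' @param categories_path optional output path for the category map CSV.
#' @return `cm`, invisibly.
#' @export
write_community <- function(cm, matrix_path, categories_path = NULL) {
  df <- data.frame(site = rownames(cm), unclass(cm)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, matrix_path, row.names = FALSE, quote = FALSE)
  if (!is.null(categories_path)) {
    utils::write.csv(
      data.frame(species = colnames(cm), category = species_category(cm)),
      categories_path, row.names = FALSE, quote = FALSE)
  }
  invisible(cm)
}

#' Restrict a community matrix to one species category
#'
#' Downstream statistics are computed separately per category; this keeps
#' the site list unchanged (sites may become empty of species).
#'
#' @param cm a `community_matrix`.
#' @param label a single category in [CATEGORY_LEVELS].
#' @return A `community_matrix` containing only species of that category.
#' @export
subset_by_category <- function(cm, label) {
  if (length(label) != 1L || !label %in% CATEGORY_LEVELS)
    stop("unknown category label: ", label, call. = FALSE)
  keep <- species_category(cm) == label
  community_matrix(unclass(cm)[, keep, drop = FALSE],
                   species_category(cm)[keep])
}

#' Per-species occupancy (number of occupied sites)
#'
#' @param cm a `community_matrix`.
#' @return Integer vector of per-species site counts, in species order.
#' @export
occupancy <- function(cm) {
  counts <- colSums(unclass(cm))
  storage.mode(counts) <- "integer"
  counts
}

#' Per-site species richness
#'
#' @param cm a `community_matrix`.
#' @return Integer vector of per-site richness, in site order.
#' @export
site_richness <- function(cm) {
  r <- rowSums(unclass(cm))
  storage.mode(r) <- "integer"
  r
}

#' Construct a site attribute table
#'
#' One row per site, aligned to a community matrix: planar coordinates
#' (km), elevation (m) and any number of named numeric covariate columns
#' (bioclimatic, human-pressure, ...).  Any geographic projection is the
#' caller's responsibility; coordinates are treated as planar.
#'
#' @param site character vector of site identifiers.
#' @param x,y planar coordinates in km.
#' @param elevation elevation in m.
#' @param ... further named numeric covariate columns.
#' @return A `data.frame` with class `site_table`.
#' @export
site_table <- function(site, x, y, elevation, ...) {
  st <- data.frame(site = as.character(site), x = x, y = y,
                   elevation = elevation, ..., stringsAsFactors = FALSE)
  validate_site_table(st)
}

validate_site_table <- function(st) {
  if (anyDuplicated(st$site))
    stop("duplicate site identifiers in site table", call. = FALSE)
  if (anyDuplicated(st[, c("x", "y")]))
    stop("duplicate site coordinates", call. = FALSE)
  num <- vapply(st, is.numeric, logical(1))
  if (any(!vapply(st[num], function(v) all(is.finite(v)), logical(1))))
    stop("non-finite values in site table", call. = FALSE)
  class(st) <- c("site_table", "data.frame")
  st
}

#' Read a site table from CSV
#'
#' @param path CSV with columns `site`, `x`, `y`, `elevation` and any
#'   further numeric covariates.
#' @return A validated `site_table`.
#' @export
read_site_table <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "x", "y", "elevation")
  if (!all(need %in% names(st)))
    stop("site table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  st$site <- as.character(st$site)
  validate_site_table(st)
}

#' Write a site table to CSV
#' @param st a `site_table`.
#' @param path output path.
#' @return `st`, invisibly.
#' @export
write_site_table <- function(st, path) {
  utils::write.csv(st, path, row.names = FALSE, quote = FALSE)
  invisible(st)
}

#' Check that a community matrix and a site table describe the same sites
#'
#' @param cm a `community_matrix`.
#' @param st a `site_table`.
#' @return `TRUE` invisibly, or an error naming the mismatch.
#' @export
validate_study <- function(cm, st) {
  if (!identical(rownames(cm), st$site))
    stop("site identifiers of the community matrix and site table differ ",
         "or are ordered differently", call. = FALSE)
  invisible(TRUE)
}

covariate_names <- function(st) {
  setdiff(names(st), c("site", "x", "y"))
}
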
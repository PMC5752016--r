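# Expression catalogs (one category per gene) and per-category percentage
# distributions: the all-genes background and the query-specific distribution
# of expression maxima (DEM).

#' Construct an expression catalog
#'
#' Each gene carries exactly one expression category (for the circadian case
#' the six 4-hour Zeitgeber-time bins); the ordered category list is kept as
#' factor levels.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param category Character/factor vector of category labels.
#' @param categories Ordered vector of all category labels. Defaults to the
#'   distinct values of `category` in order of first appearance.
#' @return A tibble of class `expression_catalog` with columns `gene_id` and
#'   `category` (factor with the full ordered level set).
#' @export
expression_catalog <- function(gene_id, category, categories = NULL) {
  gene_id <- as.character(gene_id)
  category <- as.character(category)
  stopifnot(length(gene_id) == length(category))
  if (anyDuplicated(gene_id)) stop("each gene may appear in exactly one category")
  if (is.null(categories)) categories <- unique(category)
  if (!all(category %in% categories)) {
    stop("every assigned category must be in the ordered category list")
  }
  out <- tibble::tibble(gene_id = gene_id,
                        category = factor(category, levels = categories))
  class(out) <- c("expression_catalog", class(out))
  out
}

#' Category labels of a catalog
#' @param catalog An [expression_catalog()].
#' @return Character vector of ordered category labels.
#' @export
catalog_categories <- function(catalog) levels(catalog$category)

#' Read a gene-to-category table from TSV
#'
#' Expects columns `gene_id` and `category` (header required). The category
#' order is the order of first appearance unless `categories` is given.
#'
#' @param path Path to a tab-separated file.
#' @param categories Optional ordered category labels.
#' @return An [expression_catalog()].
#' @export
read_catalog <- function(path, categories = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "category") %in% names(df))) {
    stop("catalog TSV must have columns 'gene_id' and 'category'")
  }
  expression_catalog(df$gene_id, df$category, categories = categories)
}

#' Write a catalog to TSV
#' @param catalog An [expression_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(
    data.frame(gene_id = catalog$gene_id, category = as.character(catalog$category)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Categorize genes by their maximum expression
#'
#' Assigns each gene of a gene-by-condition expression matrix to the category
#' containing its maximum-expression condition. Ties are broken by the
#' earliest category in the ordered list (tied genes are reported in a
#' message); genes with all-missing values are excluded with a warning.
#'
#' @param expr A data frame or matrix: one row per gene. If a data frame with
#'   a `gene_id` column, that column supplies ids; otherwise row names are
#'   used.
#' @param condition_map Named character vector mapping every expression column
#'   (condition) to a category label.
#' @param categories Ordered category labels; defaults to unique map values in
#'   order of first appearance.
#' @return An [expression_catalog()].
#' @export
categorize_by_max <- function(expr, condition_map, categories = NULL) {
  if (is.data.frame(expr) && "gene_id" %in% names(expr)) {
    ids <- as.character(expr$gene_id)
    mat <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  } else {
    mat <- as.matrix(expr)
    ids <- rownames(mat)
    if (is.null(ids)) stop("expression matrix needs gene ids (column 'gene_id' or row names)")
  }
  if (!all(colnames(mat) %in% names(condition_map))) {
    miss <- setdiff(colnames(mat), names(condition_map))
    stop(sprintf("conditions without a category mapping: %s", paste(miss, collapse = ", ")))
  }
  if (is.null(categories)) categories <- unique(unname(condition_map))
  cat_of_col <- factor(condition_map[colnames(mat)], levels = categories)

  all_na <- apply(mat, 1L, function(r) all(is.na(r)))
  if (any(all_na)) {
    warning(sprintf("%d gene(s) with all-missing expression excluded", sum(all_na)))
    mat <- mat[!all_na, , drop = FALSE]
    ids <- ids[!all_na]
  }
  # per gene: best value per category, then earliest category attaining the max
  assign_one <- function(r) {
    best <- tapply(r, cat_of_col, max, na.rm = TRUE)
    best[!is.finite(best)] <- -Inf
    m <- max(best)
    hit <- which(best == m)
    list(cat = names(best)[hit[1]], tie = length(hit) > 1L)
  }
  res <- apply(mat, 1L, assign_one)
  cats <- vapply(res, `[[`, character(1), "cat")
  ties <- vapply(res, `[[`, logical(1), "tie")
  if (any(ties)) {
    message(sprintf("%d gene(s) with tied maxima assigned to the earliest category", sum(ties)))
  }
  expression_catalog(ids, cats, categories = categories)
}

#' Background distribution of expression maxima
#'
#' Percentage of all cataloged genes per category.
#'
#' @param catalog An [expression_catalog()].
#' @return A tibble with columns `category`, `n`, `pct` (`pct` sums to 100).
#' @export
background_distribution <- function(catalog) {
  if (nrow(catalog) == 0L) stop("catalog is empty")
  counts <- table(catalog$category)
  tibble::tibble(category = names(counts),
                 n = as.integer(counts),
                 pct = 100 * as.integer(counts) / nrow(catalog))
}

#' Distribution of expression maxima (DEM) of a gene set
#'
#' Per-category percentage of the genes in `gene_set` that are present in the
#' catalog. Genes absent from the catalog are dropped (their count is
#' reported in attribute `n_dropped`); an empty intersection yields an
#' undefined DEM (`pct` all `NA`, attribute `n_genes = 0`), not zeros.
#'
#' @param gene_set Character vector of gene ids.
#' @param catalog An [expression_catalog()].
#' @return A tibble `category`, `n`, `pct` with attributes `n_genes` (genes
#'   used) and `n_dropped` (genes absent from the catalog).
#' @export
dem <- function(gene_set, catalog) {
  gene_set <- unique(as.character(gene_set))
  in_cat <- gene_set %in% catalog$gene_id
  used <- gene_set[in_cat]
  cats <- levels(catalog$category)
  if (length(used) == 0L) {
    out <- tibble::tibble(category = cats, n = 0L, pct = NA_real_)
  } else {
    counts <- table(factor(catalog$category[match(used, catalog$gene_id)], levels = cats))
    out <- tibble::tibble(category = cats, n = as.integer(counts),
                          pct = 100 * as.integer(counts) / length(used))
  }
  attr(out, "n_genes") <- length(used)
  attr(out, "n_dropped") <- sum(!in_cat)
  out
}

# Fast internal DEM: integer category codes (1..K) of a gene-index set.
dem_pct <- function(cat_codes, n_cat) {
  100 * tabulate(cat_codes, nbins = n_cat) / length(cat_codes)
}
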
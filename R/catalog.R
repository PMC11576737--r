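INHERITANCE_CODES <- c("AD", "AR", "SD", "XL")
GENE_CATEGORIES <- c("cancer", "cardiovascular", "miscellaneous")

#' Read an actionable-gene catalog
#'
#' The catalog lists the genes screened for secondary findings, one row per
#' gene, with its inheritance mode (`AD` autosomal dominant, `AR` autosomal
#' recessive, `SD` semidominant, `XL` X-linked), its disease category
#' (`cancer`, `cardiovascular`, `miscellaneous`), the associated condition,
#' a list-version tag, and a `lof_gene` flag marking genes where loss of
#' function is an established disease mechanism (data used by the LP1 rule).
#'
#' @param path TSV with columns `symbol`, `inheritance`, `category`,
#'   `phenotype`, `sf_version` and optionally `lof_gene` (defaults to TRUE).
#' @param expect_n If non-NULL, error unless the catalog has exactly this
#'   many genes (the SF v3.1 list has 78).
#' @return data.frame with one row per gene.
#' @export
read_gene_catalog <- function(path, expect_n = NULL) {
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("symbol", "inheritance", "category", "phenotype", "sf_version")
  missing_cols <- setdiff(needed, names(cat_df))
  if (length(missing_cols) > 0)
    stopf("gene catalog is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cat_df$symbol))
    stopf("gene catalog has duplicate symbol(s): %s",
          paste(unique(cat_df$symbol[duplicated(cat_df$symbol)]), collapse = ", "))
  bad_inh <- setdiff(unique(cat_df$inheritance), INHERITANCE_CODES)
  if (length(bad_inh) > 0)
    stopf("unknown inheritance code(s): %s", paste(bad_inh, collapse = ", "))
  bad_cat <- setdiff(unique(cat_df$category), GENE_CATEGORIES)
  if (length(bad_cat) > 0)
    stopf("unknown disease category(s): %s", paste(bad_cat, collapse = ", "))
  cat_df$lof_gene <- if ("lof_gene" %in% names(cat_df)) {
    as.logical(cat_df$lof_gene)
  } else TRUE
  if (anyNA(cat_df$lof_gene)) stopf("lof_gene column must be TRUE/FALSE")
  if (!is.null(expect_n) && nrow(cat_df) != expect_n)
    stopf("expected %d catalog genes, found %d", expect_n, nrow(cat_df))
  cat_df[c(needed, "lof_gene")]
}

#' The bundled ACMG SF v3.1 actionable-gene catalog
#'
#' Returns the 78-gene secondary-findings catalog shipped with the package,
#' transcribed from the published v3.1 recommendation. Inheritance and
#' category codes follow the published table (LDLR is semidominant).
#'
#' @return data.frame as from [read_gene_catalog()], 78 rows.
#' @export
acmg_sf_catalog <- function() {
  read_gene_catalog(
    system.file("extdata", "acmg_sf_v3.1_catalog.tsv", package = "sftriage",
                mustWork = TRUE),
    expect_n = 78L)
}

#' Read a gene region map
#'
#' Maps each catalog gene to a genomic interval used to trim the cohort VCF.
#' Coordinates are 1-based and fully closed on both ends (VCF convention,
#' not BED half-open).
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `symbol`.
#' @param catalog Optional catalog data.frame; if given, every catalog gene
#'   must be covered by the map.
#' @return data.frame with one row per gene interval.
#' @export
read_region_map <- function(path, catalog = NULL) {
  rm_df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chrom", "start", "end", "symbol")
  missing_cols <- setdiff(needed, names(rm_df))
  if (length(missing_cols) > 0)
    stopf("region map is missing column(s): %s", paste(missing_cols, collapse = ", "))
  rm_df$start <- as.integer(rm_df$start)
  rm_df$end <- as.integer(rm_df$end)
  if (any(rm_df$end < rm_df$start)) stopf("region map has end < start")
  if (!is.null(catalog)) {
    uncovered <- setdiff(catalog$symbol, rm_df$symbol)
    if (length(uncovered) > 0)
      stopf("region map does not cover catalog gene(s): %s",
            paste(uncovered, collapse = ", "))
  }
  rm_df[needed]
}
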
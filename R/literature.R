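#' Count distinct disease associations per gene
#'
#' Counts distinct disease IDs per gene in a gene-disease association table.
#' The `"curated"` tier counts only rows from curated sources; `"all"` counts
#' every row (curated plus text-mined), so curated counts never exceed the
#' all-tier counts.
#'
#' @param assoc_table Data frame with columns `gene_col`, `disease_col`,
#'   `tier_col`; the tier column labels each row `"curated"` or
#'   `"text_mining"`.
#' @param tier `"curated"` or `"all"`.
#' @param gene_col,disease_col,tier_col Column names.
#' @return Tibble `entrez_id`, `n_diseases` for genes with at least one
#'   qualifying row.
#' @export
count_disease_associations <- function(assoc_table, tier = c("curated", "all"),
                                       gene_col = "entrez_id",
                                       disease_col = "disease_id",
                                       tier_col = "source_tier") {
  tier <- match.arg(tier)
  stopifnot(all(c(gene_col, disease_col, tier_col) %in% names(assoc_table)))
  tab <- tibble::tibble(
    entrez_id = as.integer(assoc_table[[gene_col]]),
    disease_id = as.character(assoc_table[[disease_col]]),
    source_tier = as.character(assoc_table[[tier_col]])
  )
  bad <- setdiff(unique(tab$source_tier), c("curated", "text_mining"))
  if (length(bad) > 0) {
    stop("unknown source tier label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (tier == "curated") tab <- tab[tab$source_tier == "curated", , drop = FALSE]
  tab |>
    dplyr::distinct(.data$entrez_id, .data$disease_id) |>
    dplyr::count(.data$entrez_id, name = "n_diseases")
}

#' Count GeneRIF entries per gene, highlighting well-covered genes
#'
#' Each row of the table is one functional statement (RIF); the count per
#' gene is the number of rows. Genes reaching `threshold` entries (10 by
#' default) are highlighted.
#'
#' @param rif_table Data frame with a gene column (one row per RIF).
#' @param threshold Highlight bar, default 10.
#' @param gene_col Gene column name.
#' @return Tibble `entrez_id`, `n_generifs`, `highlighted`.
#' @export
count_generifs <- function(rif_table, threshold = 10, gene_col = "entrez_id") {
  stopifnot(gene_col %in% names(rif_table), threshold >= 1)
  tibble::tibble(entrez_id = as.integer(rif_table[[gene_col]])) |>
    dplyr::count(.data$entrez_id, name = "n_generifs") |>
    dplyr::mutate(highlighted = .data$n_generifs >= threshold)
}

#' Count distinct publications per gene
#'
#' Duplicate (gene, PMID) pairs count once; a publication mentioning several
#' genes increments each of them independently.
#'
#' @param gene2pub_table Data frame with gene and PMID columns.
#' @param gene_col,pmid_col Column names.
#' @return Tibble `entrez_id`, `n_publications`.
#' @export
count_publications <- function(gene2pub_table, gene_col = "entrez_id",
                               pmid_col = "pmid") {
  stopifnot(all(c(gene_col, pmid_col) %in% names(gene2pub_table)))
  tibble::tibble(
    entrez_id = as.integer(gene2pub_table[[gene_col]]),
    pmid = as.character(gene2pub_table[[pmid_col]])
  ) |>
    dplyr::distinct() |>
    dplyr::count(.data$entrez_id, name = "n_publications")
}
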
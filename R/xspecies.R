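#' Map human genes to rat orthologs
#'
#' One-to-many orthologs are kept and flagged rather than dropped, so module
#' hits through any rat copy remain visible downstream.
#'
#' @param human_genes Vector of human Entrez IDs.
#' @param ortholog_table Data frame with human and rat gene columns.
#' @param human_col,rat_col Column names.
#' @return A list of class `ortholog_mapping`: `mapping` (tibble
#'   `human_entrez`, `rat_gene`, `multi` flag), `rat_genes` (unique rat IDs),
#'   `n_mapped` (human genes with >= 1 ortholog), `unmapped` (human IDs
#'   without one), `n_unmapped`.
#' @export
map_orthologs <- function(human_genes, ortholog_table,
                          human_col = "human_entrez", rat_col = "rat_gene") {
  stopifnot(all(c(human_col, rat_col) %in% names(ortholog_table)))
  human_genes <- unique(as.integer(human_genes))
  tab <- tibble::tibble(
    human_entrez = as.integer(ortholog_table[[human_col]]),
    rat_gene = as.character(ortholog_table[[rat_col]])
  ) |>
    dplyr::distinct() |>
    dplyr::filter(.data$human_entrez %in% human_genes)
  tab <- tab |>
    dplyr::add_count(.data$human_entrez, name = "n_orth") |>
    dplyr::mutate(multi = .data$n_orth > 1) |>
    dplyr::select(-"n_orth")
  unmapped <- setdiff(human_genes, tab$human_entrez)
  structure(
    list(mapping = tab, rat_genes = sort(unique(tab$rat_gene)),
         n_mapped = length(unique(tab$human_entrez)),
         unmapped = sort(unmapped), n_unmapped = length(unmapped)),
    class = "ortholog_mapping"
  )
}

#' @export
print.ortholog_mapping <- function(x, ...) {
  cat("<ortholog_mapping> ", x$n_mapped, " human genes mapped to ",
      length(x$rat_genes), " rat genes (", x$n_unmapped, " unmapped)\n",
      sep = "")
  invisible(x)
}

#' Assign rat genes to co-expression modules
#'
#' @param rat_genes Vector of rat gene IDs.
#' @param module_table Data frame with rat-gene and module-ID columns
#'   (soft assignment allowed: a gene may appear with several modules).
#' @param rat_col,module_col Column names.
#' @return A list of class `module_assignment`: `assignments` (tibble
#'   `rat_gene`, `modules` list-column), `n_in_module` (genes in >= 1
#'   module), `outside` (genes in none).
#' @export
assign_modules <- function(rat_genes, module_table,
                           rat_col = "rat_gene", module_col = "module_id") {
  stopifnot(all(c(rat_col, module_col) %in% names(module_table)))
  rat_genes <- unique(as.character(rat_genes))
  tab <- tibble::tibble(
    rat_gene = as.character(module_table[[rat_col]]),
    module_id = as.character(module_table[[module_col]])
  ) |>
    dplyr::distinct() |>
    dplyr::filter(.data$rat_gene %in% rat_genes)
  per_gene <- tab |>
    dplyr::group_by(.data$rat_gene) |>
    dplyr::summarise(modules = list(sort(.data$module_id)), .groups = "drop")
  outside <- setdiff(rat_genes, per_gene$rat_gene)
  assignments <- dplyr::bind_rows(
    per_gene,
    tibble::tibble(rat_gene = outside,
                   modules = rep(list(character(0)), length(outside)))
  ) |>
    dplyr::arrange(.data$rat_gene)
  structure(
    list(assignments = assignments,
         n_in_module = nrow(per_gene),
         outside = sort(outside)),
    class = "module_assignment"
  )
}

#' Module-pathology report for dark-gene orthologs
#'
#' Joins module assignments with module-level pathology and GO-BP context and
#' keeps only modules carrying at least one pathology label. Modules without
#' any GO-BP label are shown with a placeholder token.
#'
#' @param assignment A [assign_modules()] result.
#' @param module_annotation Data frame with `module_col`, `pathology_col`
#'   and `gobp_col` columns (one row per module; multiple labels joined with
#'   `"; "` or empty).
#' @param module_col,pathology_col,gobp_col Column names.
#' @param placeholder Token rendered for an empty GO-BP field.
#' @return Tibble `module_id`, `rat_gene`, `pathology`, `go_bp`, one row per
#'   (module, gene) with the gene assigned to that module.
#' @export
pathology_report <- function(assignment, module_annotation,
                             module_col = "module_id",
                             pathology_col = "pathology",
                             gobp_col = "go_bp", placeholder = "-") {
  stopifnot(inherits(assignment, "module_assignment"),
            all(c(module_col, pathology_col, gobp_col) %in% names(module_annotation)))
  ann <- tibble::tibble(
    module_id = as.character(module_annotation[[module_col]]),
    pathology = trimws(as.character(module_annotation[[pathology_col]])),
    go_bp = trimws(as.character(module_annotation[[gobp_col]]))
  )
  ann$pathology[is.na(ann$pathology)] <- ""
  ann$go_bp[is.na(ann$go_bp)] <- ""
  ann <- ann[ann$pathology != "", , drop = FALSE]

  long <- assignment$assignments |>
    tidyr::unnest_longer("modules", values_to = "module_id") |>
    dplyr::mutate(module_id = as.character(.data$module_id)) |>
    dplyr::select("module_id", "rat_gene")
  out <- dplyr::inner_join(long, ann, by = "module_id") |>
    dplyr::mutate(go_bp = ifelse(.data$go_bp == "", placeholder, .data$go_bp)) |>
    dplyr::arrange(.data$module_id, .data$rat_gene)
  out
}
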
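#' Default evidence-source order
#'
#' The fixed ordered list of binary evidence sources combined into the
#' per-gene score: presence in each of four interactome snapshots, curated
#' and all-tier disease associations, GeneRIF and publication hits, regulon
#' and pathway-signature membership, rat-ortholog existence and
#' co-expression-module membership.
#'
#' @return Character vector of source names.
#' @export
evidence_sources <- function() {
  c("PIN_BIANA", "PIN_HIPPIE", "PIN_INBIOMAP", "PIN_INTACT",
    "DISEASE_CURATED", "DISEASE_ALL", "GENERIF", "PUBTATOR",
    "REGULON", "SIGNATURE", "RAT_ORTHOLOG", "WGCNA_MODULE")
}

flag_from_ids <- function(genes, ids) genes %in% as.integer(ids)

#' Assemble the per-gene binary evidence matrix
#'
#' Builds one logical column per evidence source over the supplied dark-gene
#' set: `PIN_*` flags are degree >= 1 in the corresponding snapshot;
#' `DISEASE_*`, `GENERIF` and `PUBTATOR` flags are count >= 1; `REGULON` /
#' `SIGNATURE` flags mark genes covered by at least one mapped regulator in
#' at least one compound; `RAT_ORTHOLOG` marks genes with a rat ortholog and
#' `WGCNA_MODULE` genes whose ortholog sits in at least one module. Absent
#' evidence is `FALSE`. Upstream tables mentioning genes outside `genes` are
#' an error (the inputs must be computed over the same dark-gene set).
#'
#' @param genes Vector of (dark) Entrez IDs — the row universe.
#' @param degree_table A [degree_profile()] result whose snapshot names map
#'   onto the `PIN_*` sources via `pin_map`.
#' @param disease_curated,disease_all,generif_counts,publication_counts
#'   Count tibbles from the literature module (or `NULL`).
#' @param regulon_mappings,signature_mappings [map_regulators()] results (or
#'   `NULL`).
#' @param ortholog_mapping A [map_orthologs()] result (or `NULL`).
#' @param module_assignment A [assign_modules()] result (or `NULL`); module
#'   membership is pulled back to human genes through `ortholog_mapping`.
#' @param pin_map Named character vector: snapshot name -> `PIN_*` source
#'   name. Defaults to matching on upper-cased snapshot names.
#' @param sources Ordered source list, default [evidence_sources()].
#' @return A tibble of class `evidence_matrix`: `entrez_id` plus one logical
#'   column per source, in the order of `sources`.
#' @export
build_evidence_matrix <- function(genes,
                                  degree_table = NULL,
                                  disease_curated = NULL, disease_all = NULL,
                                  generif_counts = NULL,
                                  publication_counts = NULL,
                                  regulon_mappings = NULL,
                                  signature_mappings = NULL,
                                  ortholog_mapping = NULL,
                                  module_assignment = NULL,
                                  pin_map = NULL,
                                  sources = evidence_sources()) {
  genes <- unique(as.integer(genes))
  check_subset <- function(ids, what) {
    extra <- setdiff(unique(as.integer(ids)), genes)
    if (length(extra) > 0) {
      stop("gene-set mismatch: ", what, " mentions ", length(extra),
           " gene(s) outside the evidence universe: ",
           paste(utils::head(extra, 10), collapse = ", "),
           if (length(extra) > 10) ", ...", call. = FALSE)
    }
  }

  out <- tibble::tibble(entrez_id = genes)
  for (s in sources) out[[s]] <- FALSE

  if (!is.null(degree_table) && nrow(degree_table) > 0) {
    check_subset(degree_table$entrez_id, "degree table")
    snaps <- unique(degree_table$snapshot)
    if (is.null(pin_map)) {
      pin_map <- stats::setNames(paste0("PIN_", toupper(snaps)), snaps)
    }
    for (sn in snaps) {
      src <- unname(pin_map[[sn]])
      if (is.null(src) || !src %in% sources) next
      ids <- degree_table$entrez_id[degree_table$snapshot == sn &
                                      degree_table$degree >= 1]
      out[[src]] <- flag_from_ids(genes, ids)
    }
  }

  count_flag <- function(tab, src, count_col) {
    if (is.null(tab) || !src %in% sources) return()
    check_subset(tab$entrez_id, src)
    out[[src]] <<- flag_from_ids(genes, tab$entrez_id[tab[[count_col]] >= 1])
  }
  count_flag(disease_curated, "DISEASE_CURATED", "n_diseases")
  count_flag(disease_all, "DISEASE_ALL", "n_diseases")
  count_flag(generif_counts, "GENERIF", "n_generifs")
  count_flag(publication_counts, "PUBTATOR", "n_publications")

  mapping_flag <- function(mp, src) {
    if (is.null(mp) || !src %in% sources) return()
    ids <- unique(as.integer(unlist(mp$mapped_genes)))
    check_subset(ids, src)
    out[[src]] <<- flag_from_ids(genes, ids)
  }
  mapping_flag(regulon_mappings, "REGULON")
  mapping_flag(signature_mappings, "SIGNATURE")

  if (!is.null(ortholog_mapping) && "RAT_ORTHOLOG" %in% sources) {
    check_subset(ortholog_mapping$mapping$human_entrez, "ortholog mapping")
    out$RAT_ORTHOLOG <- flag_from_ids(genes, ortholog_mapping$mapping$human_entrez)
    if (!is.null(module_assignment) && "WGCNA_MODULE" %in% sources) {
      in_mod <- module_assignment$assignments$rat_gene[
        lengths(module_assignment$assignments$modules) > 0]
      humans <- ortholog_mapping$mapping$human_entrez[
        ortholog_mapping$mapping$rat_gene %in% in_mod]
      out$WGCNA_MODULE <- flag_from_ids(genes, humans)
    }
  }

  attr(out, "sources") <- sources
  class(out) <- c("evidence_matrix", class(out))
  out
}

#' Score and tier genes from the evidence matrix
#'
#' The score S of a gene is the number of `TRUE` evidence flags. Tiers follow
#' the published convention: `high` for S >= 8, `moderate` for 4 <= S < 8,
#' `none` for S = 0, `low` otherwise; both cutoffs are configurable.
#'
#' @param matrix An [build_evidence_matrix()] result.
#' @param high_cutoff,moderate_cutoff Tier thresholds (defaults 8 and 4).
#' @return A tibble of class `evidence_summary`: `entrez_id`, `score`,
#'   `tier` (ordered factor none < low < moderate < high).
#' @export
score_and_tier <- function(matrix, high_cutoff = 8, moderate_cutoff = 4) {
  stopifnot(inherits(matrix, "evidence_matrix"),
            high_cutoff > moderate_cutoff, moderate_cutoff > 0)
  sources <- attr(matrix, "sources")
  s <- as.integer(rowSums(as.matrix(matrix[, sources, drop = FALSE])))
  tier <- dplyr::case_when(
    s >= high_cutoff ~ "high",
    s >= moderate_cutoff ~ "moderate",
    s == 0 ~ "none",
    TRUE ~ "low"
  )
  out <- tibble::tibble(
    entrez_id = matrix$entrez_id, score = s,
    tier = factor(tier, levels = c("none", "low", "moderate", "high"),
                  ordered = TRUE)
  )
  class(out) <- c("evidence_summary", class(out))
  out
}

#' @export
glance.evidence_summary <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_with_evidence = sum(x$score >= 1),
    n_high = sum(x$tier == "high"),
    n_moderate = sum(x$tier == "moderate"),
    mean_score = mean(x$score)
  )
}

#' DILI-group exclusivity flags
#'
#' For each gene appearing as a DEG anywhere, flags whether its modulation is
#' exclusive to the most-DILI group: `most_dili_exclusive` requires being a
#' DEG in at least one most-DILI compound and in zero no-DILI compounds;
#' `deg_in_4of5_dili` additionally requires at least `min_dili` (default 4)
#' most-DILI compounds, so it implies the first flag.
#'
#' @param deg_tables Named list of per-compound DEG tables (tibbles with
#'   `entrez_id`, `is_deg`).
#' @param groups Named character vector compound -> group; groups must be
#'   `"most_dili"` and `"no_dili"`.
#' @param min_dili Minimum most-DILI compounds for the stronger flag.
#' @return Tibble `entrez_id`, `n_most_dili`, `n_no_dili`,
#'   `most_dili_exclusive`, `deg_in_4of5_dili`.
#' @export
exclusivity_flags <- function(deg_tables, groups, min_dili = 4) {
  miss <- setdiff(names(groups), names(deg_tables))
  if (length(miss) > 0) {
    stop("missing DEG table(s) for compound(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss2 <- setdiff(names(deg_tables), names(groups))
  if (length(miss2) > 0) {
    stop("compound(s) without group label: ", paste(miss2, collapse = ", "),
         call. = FALSE)
  }
  long <- purrr::imap_dfr(deg_tables, function(tab, cmp) {
    tibble::tibble(entrez_id = tab$entrez_id[tab$is_deg],
                   group = unname(groups[[cmp]]))
  })
  long |>
    dplyr::count(.data$entrez_id, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (!"most_dili" %in% names(d)) d$most_dili <- 0L
      if (!"no_dili" %in% names(d)) d$no_dili <- 0L
      d
    })() |>
    dplyr::transmute(
      entrez_id = .data$entrez_id,
      n_most_dili = .data$most_dili,
      n_no_dili = .data$no_dili,
      most_dili_exclusive = .data$most_dili >= 1 & .data$no_dili == 0,
      deg_in_4of5_dili = .data$most_dili >= min_dili & .data$no_dili == 0
    ) |>
    dplyr::arrange(.data$entrez_id)
}

#' Fraction of genes with any supporting evidence
#'
#' @param matrix An [build_evidence_matrix()] result.
#' @return A tibble with `n_total`, `n_with_evidence`, `fraction` (raw,
#'   percent scale), `pct_floor` (the display convention used when reporting
#'   "76%" for 701/916) and `pct_round`.
#' @export
coverage_fraction <- function(matrix) {
  stopifnot(inherits(matrix, "evidence_matrix"))
  if (nrow(matrix) == 0) stop("empty evidence matrix", call. = FALSE)
  sources <- attr(matrix, "sources")
  s <- rowSums(as.matrix(matrix[, sources, drop = FALSE]))
  frac <- 100 * sum(s >= 1) / nrow(matrix)
  tibble::tibble(
    n_total = nrow(matrix), n_with_evidence = sum(s >= 1),
    fraction = frac, pct_floor = floor(frac), pct_round = round_half_up(frac)
  )
}
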
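#' Construct an annotation resource
#'
#' A resource is a named set of Entrez IDs considered "annotated" by one
#' biological-process/pathway database after its filter (GO BP aspect filter,
#' Pathway Commons pathway-annotation filter, OmniPath PPI-only-source
#' filter, ...). Provenance records where the set came from.
#'
#' @param name Resource name, e.g. `"GO_BP"`, `"Reactome"`, `"MSigDB"`,
#'   `"PathwayCommons"`, `"OmniPath"`, or any user-defined label.
#' @param genes Vector of Entrez IDs (coerced to integer, deduplicated).
#' @param provenance Free-text provenance (source file, filter log).
#' @return A list of class `gene_set_resource`.
#' @export
gene_set_resource <- function(name, genes, provenance = "") {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  genes <- sort(unique(as.integer(genes)))
  genes <- genes[!is.na(genes)]
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "gene_set_resource")
}

#' @export
print.gene_set_resource <- function(x, ...) {
  cat("<gene_set_resource> ", x$name, ": ", length(x$genes),
      " annotated genes\n", sep = "")
  invisible(x)
}

#' Parse a GMT gene-set file into an annotation resource
#'
#' GMT lines carry a set name, a description, and member tokens, tab
#' separated. Members are resolved to Entrez IDs through the catalog's
#' mapping cascade when a catalog is supplied; otherwise they must already be
#' Entrez IDs. Lines with fewer than three fields are skipped with a warning;
#' unmapped member tokens are counted in a warning.
#'
#' @param path Path to a GMT file.
#' @param name Resource name (e.g. `"MSigDB"` or `"Reactome"`).
#' @param catalog Optional [gene_catalog()] for symbol resolution.
#' @return A `gene_set_resource` whose genes are the union of all set members.
#' @export
parse_gmt <- function(path, name = "MSigDB", catalog = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    warning(sum(short), " GMT line(s) with < 3 fields skipped", call. = FALSE)
    fields <- fields[!short]
  }
  tokens <- unique(unlist(lapply(fields, function(f) f[-(1:2)])))
  tokens <- tokens[nzchar(trimws(tokens))]
  genes <- resolve_tokens(tokens, catalog, context = paste0("GMT ", basename(path)))
  gene_set_resource(name, genes, provenance = paste0("gmt:", path))
}

resolve_tokens <- function(tokens, catalog, context = "") {
  if (length(tokens) == 0) return(integer(0))
  if (is.null(catalog)) {
    ids <- suppressWarnings(as.integer(tokens))
    if (anyNA(ids)) {
      warning(sum(is.na(ids)), " non-Entrez token(s) dropped in ", context,
              call. = FALSE)
    }
    return(ids[!is.na(ids)])
  }
  mp <- map_to_entrez(tokens, catalog)
  n_lost <- sum(mp$status != "mapped")
  if (n_lost > 0) {
    warning(n_lost, " token(s) unmapped/ambiguous in ", context, call. = FALSE)
  }
  mapped_ids(mp)
}

#' Parse GO annotations, keeping one aspect
#'
#' Only rows of the biological-process aspect (code `"P"`) contribute by
#' default; molecular-function (`"F"`) and cellular-component (`"C"`) rows are
#' dropped. Rows with an unknown aspect code are skipped with a warning.
#'
#' @param go_table Data frame (or path to a headered TSV) with gene, GO term
#'   and aspect columns.
#' @param aspect_filter Aspect code(s) to keep. Default `"P"`.
#' @param gene_col,aspect_col Column names.
#' @param exclude_evidence Optional character vector of evidence codes to
#'   drop (requires an `evidence_col` column); default empty, i.e. all rows
#'   including electronic annotations are kept.
#' @param evidence_col Evidence-code column name.
#' @param catalog Optional [gene_catalog()] when the gene column holds symbols.
#' @return A `gene_set_resource` named `"GO_BP"` (or `GO_<aspects>` otherwise).
#' @export
parse_go_annotations <- function(go_table, aspect_filter = "P",
                                 gene_col = "gene_id", aspect_col = "aspect",
                                 exclude_evidence = character(0),
                                 evidence_col = "evidence", catalog = NULL) {
  if (is.character(go_table) && length(go_table) == 1) {
    go_table <- readr::read_tsv(go_table, show_col_types = FALSE, progress = FALSE)
  }
  stopifnot(all(c(gene_col, aspect_col) %in% names(go_table)))
  aspect <- as.character(go_table[[aspect_col]])
  unknown <- !aspect %in% c("P", "F", "C")
  if (any(unknown)) {
    warning(sum(unknown), " GO row(s) with unknown aspect code skipped",
            call. = FALSE)
  }
  keep <- aspect %in% aspect_filter
  if (length(exclude_evidence) > 0 && evidence_col %in% names(go_table)) {
    keep <- keep & !go_table[[evidence_col]] %in% exclude_evidence
  }
  genes <- resolve_tokens(as.character(go_table[[gene_col]][keep]), catalog,
                          context = "GO annotations")
  name <- if (identical(aspect_filter, "P")) "GO_BP" else
    paste0("GO_", paste(aspect_filter, collapse = ""))
  gene_set_resource(name, genes, provenance = paste0(
    "go aspect=", paste(aspect_filter, collapse = ",")))
}

#' Parse Pathway Commons interactions, requiring pathway annotation
#'
#' Rows whose pathway field is empty (after whitespace stripping) do not
#' contribute; a gene appearing only in such rows is excluded from the
#' resource. Rows missing a participant are skipped with a warning.
#'
#' @param pc_table Data frame (or path to a headered TSV) of interactions.
#' @param a_col,b_col,pathway_col Column names for the two participants and
#'   the (possibly empty) pathway-annotation field.
#' @param catalog Optional [gene_catalog()] when participants are symbols.
#' @return A `gene_set_resource` named `"PathwayCommons"`.
#' @export
parse_pathway_commons <- function(pc_table, a_col = "gene_a", b_col = "gene_b",
                                  pathway_col = "pathway", catalog = NULL) {
  if (is.character(pc_table) && length(pc_table) == 1) {
    pc_table <- readr::read_tsv(pc_table, show_col_types = FALSE, progress = FALSE)
  }
  stopifnot(all(c(a_col, b_col, pathway_col) %in% names(pc_table)))
  a <- trimws(as.character(pc_table[[a_col]]))
  b <- trimws(as.character(pc_table[[b_col]]))
  pw <- trimws(as.character(pc_table[[pathway_col]]))
  pw[is.na(pw)] <- ""
  bad <- is.na(a) | a == "" | is.na(b) | b == ""
  if (any(bad)) {
    warning(sum(bad), " Pathway Commons row(s) missing a participant skipped",
            call. = FALSE)
  }
  keep <- !bad & pw != ""
  genes <- resolve_tokens(unique(c(a[keep], b[keep])), catalog,
                          context = "Pathway Commons")
  gene_set_resource("PathwayCommons", genes,
                    provenance = "pathway-annotation filter applied")
}

#' Parse OmniPath interactions, dropping PPI-only-supported rows
#'
#' Rows whose source-database set is a subset of the pure protein-protein
#' interaction databases (`ppi_sources`; BioGRID, HPRD and IntAct by default)
#' are dropped — they carry no pathway-level support. Rows with an empty
#' source list are treated as PPI-only and dropped with a warning.
#'
#' @param op_table Data frame (or path to a headered TSV) of interactions.
#' @param a_col,b_col,sources_col Column names; `sources_col` holds a
#'   `;`-delimited database list.
#' @param ppi_sources Databases counting as PPI-only support.
#' @param catalog Optional [gene_catalog()].
#' @return A `gene_set_resource` named `"OmniPath"`.
#' @export
parse_omnipath <- function(op_table, a_col = "gene_a", b_col = "gene_b",
                           sources_col = "sources",
                           ppi_sources = c("BioGRID", "HPRD", "IntAct"),
                           catalog = NULL) {
  if (is.character(op_table) && length(op_table) == 1) {
    op_table <- readr::read_tsv(op_table, show_col_types = FALSE, progress = FALSE)
  }
  stopifnot(all(c(a_col, b_col, sources_col) %in% names(op_table)))
  src <- strsplit(as.character(op_table[[sources_col]]), ";", fixed = TRUE)
  src <- lapply(src, function(s) trimws(s[nzchar(trimws(s))]))
  empty <- lengths(src) == 0 | is.na(op_table[[sources_col]])
  if (any(empty)) {
    warning(sum(empty),
            " OmniPath row(s) with empty source list treated as PPI-only and dropped",
            call. = FALSE)
  }
  ppi_only <- vapply(src, function(s) length(s) > 0 && all(s %in% ppi_sources),
                     logical(1))
  keep <- !empty & !ppi_only
  genes <- resolve_tokens(
    unique(c(as.character(op_table[[a_col]][keep]),
             as.character(op_table[[b_col]][keep]))),
    catalog, context = "OmniPath")
  gene_set_resource("OmniPath", genes,
                    provenance = paste0("dropped rows supported only by: ",
                                        paste(ppi_sources, collapse = ",")))
}

#' Assemble resources into an annotation universe
#'
#' @param resources List of `gene_set_resource` objects with unique names.
#' @return A list of class `annotation_universe` with `resources` and the
#'   recomputed `union_annotated` set.
#' @export
annotation_universe <- function(resources) {
  stopifnot(length(resources) >= 1,
            all(vapply(resources, inherits, logical(1), "gene_set_resource")))
  nm <- vapply(resources, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate resource names in universe: ",
         paste(nm[duplicated(nm)], collapse = ", "), call. = FALSE)
  }
  names(resources) <- nm
  structure(
    list(resources = resources,
         union_annotated = sort(unique(unlist(lapply(resources, `[[`, "genes"))))),
    class = "annotation_universe"
  )
}

#' @export
print.annotation_universe <- function(x, ...) {
  cat("<annotation_universe> ", length(x$resources), " resources, ",
      length(x$union_annotated), " annotated genes\n", sep = "")
  for (r in x$resources) cat("  ", r$name, ": ", length(r$genes), "\n", sep = "")
  invisible(x)
}

#' Tag dark genes: absent from every annotation resource
#'
#' A gene is dark exactly when it appears in none of the universe's
#' resources. Genes unknown to every resource are simply dark.
#'
#' @param genes Vector of Entrez IDs to classify (e.g. the DEG union).
#' @param universe An [annotation_universe()].
#' @return A tibble of class `darkness_calls` with `entrez_id`, `dark`,
#'   `present_in` (list-column of resource names) and `n_resources`.
#' @export
classify_darkness <- function(genes, universe) {
  stopifnot(inherits(universe, "annotation_universe"))
  genes <- unique(as.integer(genes))
  present <- purrr::map(universe$resources, ~ genes %in% .x$genes)
  pm <- do.call(cbind, present)   # genes x resources logical
  res_names <- names(universe$resources)
  present_in <- apply(pm, 1, function(row) res_names[row], simplify = FALSE)
  out <- tibble::tibble(
    entrez_id = genes,
    dark = rowSums(pm) == 0,
    present_in = present_in,
    n_resources = as.integer(rowSums(pm))
  )
  class(out) <- c("darkness_calls", class(out))
  out
}

#' @export
glance.darkness_calls <- function(x, ...) {
  tibble::tibble(n_input = nrow(x), n_dark = sum(x$dark),
                 dark_fraction = 100 * sum(x$dark) / nrow(x))
}

# round half up at 0 decimals (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Dark-gene coverage report
#'
#' Summarizes the dark fraction of a gene set and, optionally, of the full
#' array background. Because published percentages mix display conventions,
#' both round-half-up and floor display variants accompany the raw fraction.
#'
#' @param calls A [classify_darkness()] result for the genes of interest.
#' @param background_calls Optional second result for the array background.
#' @return A tibble with one row per universe (`which` = `"input"` /
#'   `"background"`): `n_input`, `n_dark`, `dark_fraction` (percent, raw),
#'   `pct_round` (round half up) and `pct_floor`.
#' @export
coverage_report <- function(calls, background_calls = NULL) {
  if (nrow(calls) == 0) stop("empty darkness-call table", call. = FALSE)
  one <- function(x, label) {
    frac <- 100 * sum(x$dark) / nrow(x)
    tibble::tibble(which = label, n_input = nrow(x), n_dark = sum(x$dark),
                   dark_fraction = frac,
                   pct_round = round_half_up(frac), pct_floor = floor(frac))
  }
  out <- one(calls, "input")
  if (!is.null(background_calls)) {
    if (nrow(background_calls) == 0) stop("empty background-call table", call. = FALSE)
    out <- dplyr::bind_rows(out, one(background_calls, "background"))
  }
  out
}

#' Tally dark genes by biotype
#'
#' Cross-tabulates dark genes against the catalog's biotype vocabulary.
#' Genes with biotype `"unknown"` are reported in a separate `uncategorized`
#' row and excluded from the categorized `Total` row, mirroring how published
#' dark-gene tables categorize only the subset with a known gene type.
#'
#' @param dark_calls A [classify_darkness()] result (only rows with
#'   `dark == TRUE` are tallied) or a vector of dark Entrez IDs.
#' @param catalog A [gene_catalog()] supplying biotypes.
#' @param group_membership Optional named list of Entrez ID vectors (e.g.
#'   `list(most_dili = ..., no_dili = ...)`); a gene dark in several groups is
#'   counted once per group column and once in the combined column.
#' @return A tibble with a `biotype` column, one count column per group, and
#'   an `all_dark` column; the last rows are `Total` (categorized genes) and
#'   `uncategorized`.
#' @export
tally_biotypes <- function(dark_calls, catalog, group_membership = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  dark_genes <- if (is.data.frame(dark_calls)) {
    dark_calls$entrez_id[dark_calls$dark]
  } else {
    as.integer(dark_calls)
  }
  dark_genes <- unique(dark_genes)

  bt_of <- function(ids) {
    bt <- catalog$records$biotype[match(ids, catalog$records$entrez_id)]
    bt[is.na(bt)] <- "unknown"
    bt
  }
  vocab <- setdiff(biotype_vocabulary(), "unknown")
  count_col <- function(ids) {
    bt <- bt_of(ids)
    counts <- table(factor(bt[bt != "unknown"], levels = vocab))
    c(as.integer(counts), sum(as.integer(counts)), sum(bt == "unknown"))
  }

  cols <- list(all_dark = count_col(dark_genes))
  if (!is.null(group_membership)) {
    grp <- purrr::map(group_membership, ~ count_col(intersect(dark_genes, as.integer(.x))))
    cols <- c(grp, cols)
  }
  out <- tibble::tibble(biotype = c(vocab, "Total", "uncategorized"))
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  out
}
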
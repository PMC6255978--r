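#' Build a gene catalog keyed by Entrez ID
#'
#' Harmonizes a gene-identity table (NCBI `gene_info`-style) into a catalog
#' used throughout the package to resolve symbols, synonyms and UniProt
#' accessions to Entrez gene identifiers. One record is kept per distinct
#' Entrez ID; duplicated IDs keep the first row seen and raise a warning.
#'
#' @param gene_info A data frame with one row per gene. Column names are
#'   configurable; defaults follow the NCBI `gene_info` convention.
#' @param biotype_table Optional data frame mapping Entrez IDs to Ensembl-style
#'   biotypes (columns named by `entrez_col` and `biotype_col`). Genes absent
#'   from it (or when it is `NULL`) get biotype `"unknown"`.
#' @param entrez_col,symbol_col,synonyms_col,uniprot_col,biotype_col Column
#'   names in `gene_info` (and `biotype_table`). `synonyms_col` and
#'   `uniprot_col` hold pipe- or comma-delimited token lists; `"-"` and empty
#'   strings mean none.
#' @return An object of class `gene_catalog`: a list with `records` (a tibble
#'   with `entrez_id`, `symbol`, `synonyms` and `uniprot_ids` list-columns,
#'   `biotype`), plus `symbol_index` and `uniprot_index` lookup tibbles,
#'   rebuilt deterministically from `records`.
#' @examples
#' gi <- tibble::tibble(GeneID = 1:3, Symbol = c("TP53", "EGFR", "MALAT1"),
#'                      Synonyms = c("P53|LFS1", "-", "-"))
#' cat3 <- gene_catalog(gi)
#' nrow(cat3$records)
#' @seealso [map_to_entrez()]
#' @export
gene_catalog <- function(gene_info, biotype_table = NULL,
                         entrez_col = "GeneID", symbol_col = "Symbol",
                         synonyms_col = "Synonyms", uniprot_col = "UniProt",
                         biotype_col = "biotype") {
  stopifnot(is.data.frame(gene_info))
  for (col in c(entrez_col, symbol_col)) {
    if (!col %in% names(gene_info)) {
      stop("gene_info lacks required column '", col, "'", call. = FALSE)
    }
  }

  rec <- tibble::tibble(
    entrez_id = suppressWarnings(as.integer(gene_info[[entrez_col]])),
    symbol    = as.character(gene_info[[symbol_col]]),
    synonyms  = split_tokens(pull_or_empty(gene_info, synonyms_col)),
    uniprot_ids = split_tokens(pull_or_empty(gene_info, uniprot_col)),
    biotype   = if (biotype_col %in% names(gene_info)) {
      normalize_biotype(as.character(gene_info[[biotype_col]]))
    } else {
      "unknown"
    }
  )

  bad <- is.na(rec$entrez_id) | rec$entrez_id <= 0 |
    is.na(rec$symbol) | rec$symbol == ""
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) skipped while loading gene catalog",
            call. = FALSE)
    rec <- rec[!bad, , drop = FALSE]
  }
  dup <- duplicated(rec$entrez_id)
  if (any(dup)) {
    warning(sum(dup), " duplicated Entrez ID row(s) dropped (first kept)",
            call. = FALSE)
    rec <- rec[!dup, , drop = FALSE]
  }

  if (!is.null(biotype_table)) {
    if (!all(c(entrez_col, biotype_col) %in% names(biotype_table))) {
      stop("biotype_table needs columns '", entrez_col, "' and '",
           biotype_col, "'", call. = FALSE)
    }
    bt <- tibble::tibble(
      entrez_id = as.integer(biotype_table[[entrez_col]]),
      bt = normalize_biotype(as.character(biotype_table[[biotype_col]]))
    )
    bt <- bt[!duplicated(bt$entrez_id), ]
    idx <- match(rec$entrez_id, bt$entrez_id)
    rec$biotype[!is.na(idx)] <- bt$bt[idx[!is.na(idx)]]
  }

  structure(
    list(
      records = rec,
      symbol_index = build_symbol_index(rec),
      uniprot_index = build_uniprot_index(rec)
    ),
    class = "gene_catalog"
  )
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("<gene_catalog> ", nrow(x$records), " genes, ",
      nrow(x$symbol_index), " symbol/synonym tokens, ",
      nrow(x$uniprot_index), " UniProt tokens\n", sep = "")
  invisible(x)
}

#' Read an NCBI gene_info-style TSV into a gene catalog
#'
#' @param path Path to a tab-separated file with a header row.
#' @inheritParams gene_catalog
#' @inheritDotParams gene_catalog
#' @return A `gene_catalog`.
#' @export
read_gene_info <- function(path, biotype_table = NULL, ...) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  gene_catalog(tab, biotype_table = biotype_table, ...)
}

# closed biotype vocabulary; pseudogene subtypes collapse to "pseudogene"
biotype_vocabulary <- function() {
  c("protein_coding", "antisense", "lincRNA", "processed_transcript",
    "pseudogene", "snoRNA", "sense_intronic", "sense_overlapping",
    "miRNA", "TEC", "unknown")
}

normalize_biotype <- function(x) {
  x <- trimws(x)
  x[is.na(x) | x == ""] <- "unknown"
  x[grepl("pseudogene", x, ignore.case = TRUE)] <- "pseudogene"
  x[!x %in% biotype_vocabulary()] <- "unknown"
  x
}

pull_or_empty <- function(df, col) {
  if (col %in% names(df)) as.character(df[[col]]) else rep("", nrow(df))
}

split_tokens <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "" || s == "-") return(character(0))
    toks <- unlist(strsplit(s, "[|,]"))
    toks <- trimws(toks)
    unique(toks[toks != "" & toks != "-"])
  })
}

build_symbol_index <- function(rec) {
  primary <- tibble::tibble(
    token = toupper(rec$symbol), entrez_id = rec$entrez_id, kind = "primary"
  )
  syn <- tibble::tibble(
    token = toupper(unlist(rec$synonyms, use.names = FALSE)),
    entrez_id = rep(rec$entrez_id, lengths(rec$synonyms)),
    kind = "synonym"
  )
  dplyr::distinct(dplyr::bind_rows(primary, syn))
}

build_uniprot_index <- function(rec) {
  dplyr::distinct(tibble::tibble(
    token = toupper(unlist(rec$uniprot_ids, use.names = FALSE)),
    entrez_id = rep(rec$entrez_id, lengths(rec$uniprot_ids))
  ))
}

#' Map symbols or UniProt accessions to Entrez IDs
#'
#' Resolves each input token through a fixed three-step cascade:
#' primary-symbol match, then synonym match, then UniProt-accession match.
#' Matching is case-insensitive. A token whose winning step yields more than
#' one candidate Entrez ID is reported as ambiguous rather than resolved — a
#' silent mis-mapping would corrupt downstream darkness calls. Tokens that
#' already are Entrez IDs present in the catalog map to themselves, so the
#' mapping is idempotent on its own output.
#'
#' @param tokens Character vector of gene symbols, synonyms, UniProt
#'   accessions, or Entrez IDs (as strings or integers).
#' @param catalog A [gene_catalog()].
#' @return A tibble of class `mapping_result` with one row per distinct input
#'   token: `token`, `entrez_id` (`NA` unless mapped), `status` in
#'   `{"mapped", "unmapped", "ambiguous"}`, and `step` naming the cascade step
#'   that resolved the token. The three statuses partition the tokens.
#' @examples
#' gi <- tibble::tibble(GeneID = 1:2, Symbol = c("A1", "B1"),
#'                      Synonyms = c("ALT1", "-"))
#' map_to_entrez(c("A1", "alt1", "nope"), gene_catalog(gi))
#' @export
map_to_entrez <- function(tokens, catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  tokens <- unique(as.character(tokens))
  up <- toupper(trimws(tokens))

  sym <- catalog$symbol_index
  uni <- catalog$uniprot_index
  known_ids <- catalog$records$entrez_id

  resolve_one <- function(token_up) {
    if (is.na(token_up) || token_up == "") {
      return(list(id = NA_integer_, status = "unmapped", step = NA_character_))
    }
    # Entrez IDs pass through unchanged (idempotence)
    if (grepl("^[0-9]+$", token_up)) {
      id <- as.integer(token_up)
      if (id %in% known_ids) {
        return(list(id = id, status = "mapped", step = "entrez"))
      }
    }
    for (step in c("primary", "synonym")) {
      hits <- unique(sym$entrez_id[sym$token == token_up & sym$kind == step])
      if (length(hits) == 1L) return(list(id = hits, status = "mapped", step = step))
      if (length(hits) > 1L) return(list(id = NA_integer_, status = "ambiguous", step = step))
    }
    hits <- unique(uni$entrez_id[uni$token == token_up])
    if (length(hits) == 1L) return(list(id = hits, status = "mapped", step = "uniprot"))
    if (length(hits) > 1L) return(list(id = NA_integer_, status = "ambiguous", step = "uniprot"))
    list(id = NA_integer_, status = "unmapped", step = NA_character_)
  }

  res <- purrr::map(up, resolve_one)
  out <- tibble::tibble(
    token = tokens,
    entrez_id = purrr::map_int(res, "id"),
    status = purrr::map_chr(res, "status"),
    step = purrr::map_chr(res, "step")
  )
  class(out) <- c("mapping_result", class(out))
  out
}

#' Extract the successfully mapped Entrez IDs from a mapping result
#' @param mapping A `mapping_result` tibble from [map_to_entrez()].
#' @return Integer vector of unique Entrez IDs.
#' @export
mapped_ids <- function(mapping) {
  unique(mapping$entrez_id[mapping$status == "mapped"])
}
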
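#' Write a synthetic world to disk as plain-text fixture files
#'
#' Emits every input of the pipeline in its standard carrier format: the gene
#' catalog and interaction/literature/ortholog tables as headered TSVs, the
#' Reactome- and MSigDB-style resources as GMT files, the expression matrix
#' as a genes-by-samples TSV, plus a `MANIFEST.tsv` with the MD5 hash of each
#' file. Identical world, identical bytes.
#'
#' @param world A [simulate_world()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
write_world <- function(world, outdir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tab, name) {
    readr::write_tsv(tab, file.path(outdir, name), progress = FALSE)
    name
  }
  files <- c(
    w(world$gene_info, "gene_info.tsv"),
    w(world$go_table, "go_annotations.tsv"),
    write_gmt(world$reactome_sets, file.path(outdir, "reactome.gmt")),
    write_gmt(world$msigdb_sets, file.path(outdir, "msigdb.gmt")),
    w(world$pc_table, "pathway_commons.tsv"),
    w(world$op_table, "omnipath.tsv"),
    unlist(purrr::imap(world$edge_tables, function(tab, nm) {
      w(tab, paste0("edges_", tolower(nm), ".tsv"))
    }), use.names = FALSE),
    w(world$disease_table, "disease_associations.tsv"),
    w(world$rif_table, "generifs.tsv"),
    w(world$pub_table, "gene2pubtator.tsv"),
    w(world$regulons, "regulons.tsv"),
    w(world$signatures, "signatures.tsv"),
    w(world$orthologs, "orthologs.tsv"),
    w(world$modules, "modules.tsv"),
    w(world$module_annotation, "module_annotation.tsv"),
    w(dplyr::bind_cols(
      tibble::tibble(entrez_id = rownames(world$expression$values)),
      tibble::as_tibble(world$expression$values)
    ), "expression.tsv"),
    w(world$expression$sample_meta, "sample_meta.tsv"),
    w(tibble::tibble(compound = names(world$groups),
                     group = unname(world$groups)), "groups.tsv")
  )
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files)))
  )
  readr::write_tsv(manifest, file.path(outdir, "MANIFEST.tsv"),
                   progress = FALSE)
  invisible(manifest)
}

write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(set_name, genes, description, ...) {
    paste(c(set_name, description, as.character(genes)), collapse = "\t")
  })
  readr::write_lines(lines, path)
  basename(path)
}

#' Read a GMT file into a tidy set table
#'
#' @param path Path to a GMT file (tab-separated: set name, description,
#'   member tokens).
#' @return Tibble `set_name`, `description`, `genes` (list-column of member
#'   tokens). Lines with fewer than 3 fields are skipped with a warning.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    warning(sum(short), " GMT line(s) with < 3 fields skipped", call. = FALSE)
    fields <- fields[!short]
  }
  tibble::tibble(
    set_name = vapply(fields, `[[`, character(1), 1),
    description = vapply(fields, `[[`, character(1), 2),
    genes = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Load a written world directory back into a synthetic-world object
#'
#' Reconstructs the in-memory world from the files emitted by
#' [write_world()]. Planted truth is not stored on disk, so the `truth`
#' element is `NULL`; everything the pipeline needs is restored.
#'
#' @param dir Directory written by [write_world()].
#' @return A `synthetic_world`-shaped list (without `config`/`truth`).
#' @export
load_world <- function(dir) {
  rd <- function(name, col_types = NULL) {
    readr::read_tsv(file.path(dir, name), show_col_types = FALSE,
                    progress = FALSE, col_types = col_types)
  }
  expr_tab <- rd("expression.tsv")
  values <- as.matrix(expr_tab[, -1, drop = FALSE])
  rownames(values) <- as.character(expr_tab$entrez_id)
  groups_tab <- rd("groups.tsv")
  snap_files <- list.files(dir, pattern = "^edges_.*\\.tsv$")
  edge_tables <- stats::setNames(
    lapply(snap_files, rd),
    toupper(sub("^edges_(.*)\\.tsv$", "\\1", snap_files))
  )
  structure(list(
    gene_info = rd("gene_info.tsv"),
    go_table = rd("go_annotations.tsv"),
    reactome_sets = read_gmt(file.path(dir, "reactome.gmt")),
    msigdb_sets = read_gmt(file.path(dir, "msigdb.gmt")),
    pc_table = rd("pathway_commons.tsv",
                  col_types = readr::cols(pathway = readr::col_character())),
    op_table = rd("omnipath.tsv"),
    edge_tables = edge_tables,
    disease_table = rd("disease_associations.tsv"),
    rif_table = rd("generifs.tsv"),
    pub_table = rd("gene2pubtator.tsv"),
    regulons = rd("regulons.tsv"),
    signatures = rd("signatures.tsv"),
    orthologs = rd("orthologs.tsv"),
    modules = rd("modules.tsv",
                 col_types = readr::cols(module_id = readr::col_character())),
    module_annotation = rd(
      "module_annotation.tsv",
      col_types = readr::cols(module_id = readr::col_character(),
                              pathology = readr::col_character(),
                              go_bp = readr::col_character())),
    expression = list(values = values, sample_meta = rd("sample_meta.tsv")),
    groups = stats::setNames(groups_tab$group, groups_tab$compound),
    truth = NULL
  ), class = "synthetic_world")
}
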
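#' Run the whole dark-gene pipeline on a world
#'
#' Orchestrates every stage end-to-end: per-compound DEG calling, group-wise
#' DEG unions, construction of the five-resource annotation universe,
#' darkness classification of the DEG union against the array background,
#' biotype tallies, interactome degree profiling of the dark genes,
#' literature counts, TF-regulon and pathway-signature mapping with
#' group-wise consensus and Venn regions, rat-ortholog module context, and
#' the integrated evidence matrix with scores, tiers and DILI-exclusivity
#' flags. Optionally writes the report bundle as TSV files.
#'
#' @param world A [simulate_world()] result (or [load_world()] output): the
#'   full set of input tables.
#' @param params [deg_params()] controlling the DEG gates.
#' @param empty_policy Consensus empty-set policy, see [consensus_sets()].
#' @param rank_statistic Ranking statistic for [top_connected()].
#' @param generif_threshold Highlight bar for [count_generifs()].
#' @param high_cutoff,moderate_cutoff Evidence-tier thresholds.
#' @param outdir Optional directory; when given, every report table is
#'   written as TSV plus a `run_log.txt` recording package version, seed and
#'   policies (no timestamps, so reruns are byte-identical).
#' @return A list of class `darkgene_run` with elements `deg_tables`,
#'   `deg_unions`, `universe`, `darkness`, plus a `reports` list holding the
#'   paper-shaped tables: `deg_counts`, `biotype_tally`, `coverage`,
#'   `degree_table`, `top_connected`, `literature_counts`,
#'   `regulon_overview`, `consensus_venn`, `ortholog_pathology`,
#'   `evidence_summary`.
#' @export
run_all <- function(world, params = deg_params(),
                    empty_policy = c("exclude_empty", "strict"),
                    rank_statistic = "max", generif_threshold = 10,
                    high_cutoff = 8, moderate_cutoff = 4, outdir = NULL) {
  empty_policy <- match.arg(empty_policy)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  catalog <- stage("catalog", gene_catalog(world$gene_info))
  compounds <- names(world$groups)

  deg_tables <- stage("diffexpr", {
    stats::setNames(lapply(compounds, function(cmp) {
      call_degs(world$expression$values, world$expression$sample_meta,
                cmp, params = params)
    }), compounds)
  })
  deg_unions <- stage("deg_union", union_group_degs(deg_tables, world$groups))

  universe <- stage("annotation", {
    annotation_universe(list(
      parse_go_annotations(world$go_table),
      gene_set_resource("Reactome",
                        unlist(world$reactome_sets$genes, use.names = FALSE),
                        provenance = "synthetic reactome sets"),
      gene_set_resource("MSigDB",
                        unlist(world$msigdb_sets$genes, use.names = FALSE),
                        provenance = "synthetic msigdb sets"),
      parse_pathway_commons(world$pc_table),
      parse_omnipath(world$op_table)
    ))
  })

  darkness <- stage("darkness", classify_darkness(deg_unions$all_degs, universe))
  background <- stage("background",
                      classify_darkness(catalog$records$entrez_id, universe))
  dark_genes <- darkness$entrez_id[darkness$dark]

  group_dark <- lapply(deg_unions$group_degs, intersect, y = dark_genes)
  biotype_tally <- stage("biotypes",
                         tally_biotypes(darkness, catalog,
                                        group_membership = group_dark))
  coverage <- stage("coverage", coverage_report(darkness, background))

  snapshots <- stage("interactome", {
    purrr::imap(world$edge_tables, ~ as_interactome(.x, name = .y))
  })
  degree_tab <- stage("degree", degree_profile(dark_genes, snapshots))
  presence <- presence_summary(degree_tab)
  top <- top_connected(degree_tab, k = 10, rank_statistic = rank_statistic)

  lit <- stage("literature", {
    dark_only <- function(tab) tab[as.integer(tab$entrez_id) %in% dark_genes, ,
                                   drop = FALSE]
    list(
      disease_curated = count_disease_associations(
        dark_only(world$disease_table), tier = "curated"),
      disease_all = count_disease_associations(
        dark_only(world$disease_table), tier = "all"),
      generif = count_generifs(dark_only(world$rif_table),
                               threshold = generif_threshold),
      pub = count_publications(dark_only(world$pub_table))
    )
  })
  literature_counts <- lit$disease_all |>
    dplyr::rename(n_diseases_all = "n_diseases") |>
    dplyr::full_join(dplyr::rename(lit$disease_curated,
                                   n_diseases_curated = "n_diseases"),
                     by = "entrez_id") |>
    dplyr::full_join(lit$generif, by = "entrez_id") |>
    dplyr::full_join(lit$pub, by = "entrez_id") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ tidyr::replace_na(.x, 0)),
                  highlighted = tidyr::replace_na(.data$highlighted, FALSE)) |>
    dplyr::arrange(.data$entrez_id)

  dark_by_compound <- stage("dark_by_compound", {
    stats::setNames(lapply(compounds, function(cmp) {
      intersect(deg_tables[[cmp]]$entrez_id[deg_tables[[cmp]]$is_deg],
                dark_genes)
    }), compounds)
  })
  reg_map <- stage("regulons",
                   map_regulators(dark_by_compound, world$regulons,
                                  regulator_col = "tf", target_col = "target"))
  sig_map <- stage("signatures",
                   map_regulators(dark_by_compound, world$signatures,
                                  regulator_col = "pathway",
                                  target_col = "gene"))
  group_of <- function(cmps, grp) cmps[world$groups[cmps] == grp]
  consensus <- stage("consensus", {
    out <- list()
    for (grp in unique(world$groups)) {
      cmps <- group_of(compounds, grp)
      out[[paste0("tf_", grp)]] <- consensus_sets(
        reg_map[reg_map$compound %in% cmps, ], empty_policy, group = grp)
      out[[paste0("pathway_", grp)]] <- consensus_sets(
        sig_map[sig_map$compound %in% cmps, ], empty_policy, group = grp)
    }
    out
  })
  consensus_venn <- purrr::imap_dfr(consensus, function(cr, nm) {
    dplyr::mutate(cr$venn_regions,
                  analysis = sub("_(most_dili|no_dili)$", "", nm),
                  group = cr$group, .before = 1)
  })

  orth <- stage("orthologs", map_orthologs(dark_genes, world$orthologs))
  mod_assign <- stage("modules", assign_modules(orth$rat_genes, world$modules))
  path_report <- stage("pathology",
                       pathology_report(mod_assign, world$module_annotation))

  evidence <- stage("evidence", {
    build_evidence_matrix(
      genes = dark_genes,
      degree_table = degree_tab,
      disease_curated = lit$disease_curated,
      disease_all = lit$disease_all,
      generif_counts = lit$generif,
      publication_counts = lit$pub,
      regulon_mappings = reg_map,
      signature_mappings = sig_map,
      ortholog_mapping = orth,
      module_assignment = mod_assign
    )
  })
  summary <- score_and_tier(evidence, high_cutoff = high_cutoff,
                            moderate_cutoff = moderate_cutoff)
  excl <- stage("exclusivity", exclusivity_flags(deg_tables, world$groups))
  evidence_summary <- summary |>
    dplyr::left_join(excl, by = "entrez_id") |>
    dplyr::mutate(dplyr::across(c("n_most_dili", "n_no_dili"),
                                ~ tidyr::replace_na(.x, 0L)),
                  dplyr::across(c("most_dili_exclusive", "deg_in_4of5_dili"),
                                ~ tidyr::replace_na(.x, FALSE)))
  evid_cov <- if (length(dark_genes) == 0) {
    tibble::tibble(n_total = 0L, n_with_evidence = 0L, fraction = NA_real_,
                   pct_floor = NA_real_, pct_round = NA_real_)
  } else {
    coverage_fraction(evidence)
  }

  regulon_overview <- reg_map |>
    dplyr::transmute(compound = .data$compound,
                     group = unname(world$groups[.data$compound]),
                     n_dark = .data$n_dark,
                     dark_in_regulons = .data$n_mapped,
                     mapped_tfs = .data$n_regulators) |>
    dplyr::left_join(
      dplyr::transmute(sig_map, compound = .data$compound,
                       dark_in_signatures = .data$n_mapped,
                       mapped_pathways = .data$n_regulators),
      by = "compound")

  reports <- list(
    deg_counts = deg_unions$per_compound,
    biotype_tally = biotype_tally,
    coverage = coverage,
    degree_table = tibble::as_tibble(degree_tab),
    top_connected = top,
    literature_counts = literature_counts,
    regulon_overview = regulon_overview,
    consensus_venn = consensus_venn,
    ortholog_pathology = path_report,
    evidence_summary = evidence_summary
  )

  run <- structure(list(
    deg_tables = deg_tables, deg_unions = deg_unions, universe = universe,
    darkness = darkness, background = background, dark_genes = dark_genes,
    presence = presence, consensus = consensus, evidence = evidence,
    evidence_coverage = evid_cov, ortholog_mapping = orth,
    module_assignment = mod_assign, params = params,
    policies = list(empty_policy = empty_policy,
                    rank_statistic = rank_statistic,
                    generif_threshold = generif_threshold,
                    high_cutoff = high_cutoff,
                    moderate_cutoff = moderate_cutoff),
    reports = reports
  ), class = "darkgene_run")

  if (!is.null(outdir)) write_report_bundle(run, outdir)
  run
}

#' @export
print.darkgene_run <- function(x, ...) {
  cat("<darkgene_run>\n")
  cat("  DEGs (union): ", length(x$deg_unions$all_degs),
      "; dark: ", length(x$dark_genes), "\n", sep = "")
  cat("  evidence coverage: ", x$evidence_coverage$n_with_evidence, "/",
      x$evidence_coverage$n_total, " (", x$evidence_coverage$pct_floor,
      "%)\n", sep = "")
  invisible(x)
}

#' Write a pipeline run's report bundle as TSV files
#'
#' One TSV per report table plus `run_log.txt` (package version, parameters,
#' policies; no timestamps, so identical runs give byte-identical bundles).
#'
#' @param run A [run_all()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of written file names.
#' @export
write_report_bundle <- function(run, outdir) {
  stopifnot(inherits(run, "darkgene_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  flatten_cols <- function(tab) {
    dplyr::mutate(tab, dplyr::across(
      dplyr::where(is.list),
      ~ vapply(.x, function(v) paste(v, collapse = ";"), character(1))))
  }
  files <- character(0)
  for (nm in names(run$reports)) {
    f <- paste0(nm, ".tsv")
    readr::write_tsv(flatten_cols(run$reports[[nm]]), file.path(outdir, f),
                     progress = FALSE)
    files <- c(files, f)
  }
  log_lines <- c(
    paste0("darkgenes version: ",
           as.character(utils::packageVersion("darkgenes"))),
    paste0("fc_threshold: ", run$params$fc_threshold),
    paste0("fdr_alpha: ", run$params$fdr_alpha),
    paste0("test_method: ", run$params$test_method),
    paste0("empty_policy: ", run$policies$empty_policy),
    paste0("rank_statistic: ", run$policies$rank_statistic),
    paste0("generif_threshold: ", run$policies$generif_threshold),
    paste0("tier_cutoffs: high>=", run$policies$high_cutoff,
           ", moderate>=", run$policies$moderate_cutoff)
  )
  readr::write_lines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(c(files, "run_log.txt"))
}
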
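#' Configuration for the synthetic fixture world
#'
#' Describes a complete, seeded stand-in for every input the pipeline
#' consumes: a gene catalog with biotypes, five annotation resources with a
#' planted unannotated (dark) subset, four interactome snapshots with
#' heavy-tailed degrees, literature count tables, TF-regulon and
#' pathway-signature tables with planted group-consensus regulators, an
#' ortholog map, module/pathology labels, and a log2 expression matrix with
#' planted per-compound differentially expressed genes for a 5-compound
#' most-DILI group and a 5-compound no-DILI group.
#'
#' The defaults define the study conditions the package is tested under:
#' 2,000 genes, 3 replicates per arm, log2 noise sd 0.25 and planted effects
#' of 1.2 log2 units.
#'
#' @param seed Integer seed; identical config + seed give byte-identical
#'   outputs. Every artifact draws from its own named substream, so adding a
#'   new output never perturbs existing ones.
#' @param n_genes Number of genes in the catalog.
#' @param biotype_proportions Named numeric vector over the biotype
#'   vocabulary (normalized internally).
#' @param annotation_coverage Named per-resource inclusion probability for
#'   non-planted genes; every non-planted gene is guaranteed membership in at
#'   least one resource.
#' @param n_planted_dark Number of genes planted as dark (absent from all
#'   resources).
#' @param compounds Named list with `most_dili` and `no_dili` label vectors
#'   (5 each by default).
#' @param deg_model List: `n_deg_per_compound`, `effect_size_mean` /
#'   `effect_size_sd` (log2 units), `noise_sd`, `n_replicates` per arm,
#'   `dark_deg_fraction` (share of each compound's planted DEGs drawn from
#'   the planted dark set).
#' @param interactome_model List: `snapshots` (names), `n_edges` per
#'   snapshot, `node_inclusion` probability, `tail_exponent` of the
#'   heavy-tailed endpoint weights.
#' @param regulon_model List: `n_tfs`, `targets_per_tf`,
#'   `n_consensus_per_group` planted TFs targeting dark DEGs of every
#'   compound in their group.
#' @param signature_model List: `n_pathways`, `genes_per_pathway`,
#'   `n_consensus_per_group`.
#' @param literature_model List of rates: `p_disease`, `mean_diseases`,
#'   `curated_fraction`, `p_rif`, `mean_rifs`, `p_pub`, `mean_pubs`.
#' @param ortholog_rate,multi_ortholog_rate Probability that a gene has a rat
#'   ortholog / a second one.
#' @param module_model List: `n_modules`, `p_in_module`, `p_pathology`.
#' @return A list of class `world_config`.
#' @export
world_config <- function(
    seed = 20181120,
    n_genes = 2000,
    biotype_proportions = c(
      protein_coding = 0.72, antisense = 0.06, lincRNA = 0.08,
      processed_transcript = 0.02, pseudogene = 0.05, snoRNA = 0.01,
      sense_intronic = 0.01, sense_overlapping = 0.005, miRNA = 0.005,
      TEC = 0.005, unknown = 0.035
    ),
    annotation_coverage = c(
      GO_BP = 0.70, Reactome = 0.45, MSigDB = 0.55,
      PathwayCommons = 0.65, OmniPath = 0.30
    ),
    n_planted_dark = 150,
    compounds = list(
      most_dili = c("acetaminophen", "diclofenac", "isoniazid",
                    "nimesulide", "valproic_acid"),
      no_dili = c("caffeine", "chloramphenicol", "chlorpheniramine",
                  "hydroxyzine", "theophylline")
    ),
    deg_model = list(n_deg_per_compound = 200, effect_size_mean = 1.2,
                     effect_size_sd = 0, noise_sd = 0.25, n_replicates = 3,
                     dark_deg_fraction = 0.15),
    interactome_model = list(
      snapshots = c("BIANA", "HIPPIE", "INBIOMAP", "INTACT"),
      n_edges = 4000, node_inclusion = 0.75, tail_exponent = 0.8
    ),
    regulon_model = list(n_tfs = 30, targets_per_tf = 25,
                         n_consensus_per_group = 2),
    signature_model = list(n_pathways = 12, genes_per_pathway = 40,
                           n_consensus_per_group = 1),
    literature_model = list(p_disease = 0.25, mean_diseases = 3,
                            curated_fraction = 0.3, p_rif = 0.3,
                            mean_rifs = 4, p_pub = 0.4, mean_pubs = 5),
    ortholog_rate = 0.6, multi_ortholog_rate = 0.05,
    module_model = list(n_modules = 40, p_in_module = 0.5,
                        p_pathology = 0.3)) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    biotype_proportions = biotype_proportions / sum(biotype_proportions),
    annotation_coverage = annotation_coverage,
    n_planted_dark = as.integer(n_planted_dark),
    compounds = compounds, deg_model = deg_model,
    interactome_model = interactome_model, regulon_model = regulon_model,
    signature_model = signature_model, literature_model = literature_model,
    ortholog_rate = ortholog_rate, multi_ortholog_rate = multi_ortholog_rate,
    module_model = module_model
  )
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  probs <- c(cfg$annotation_coverage, cfg$biotype_proportions,
             cfg$ortholog_rate, cfg$multi_ortholog_rate,
             cfg$module_model$p_in_module, cfg$module_model$p_pathology)
  if (any(probs < 0 | probs > 1)) {
    stop("world_config probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_planted_dark > cfg$n_genes) {
    stop("n_planted_dark exceeds n_genes", call. = FALSE)
  }
  n_deg <- cfg$deg_model$n_deg_per_compound
  if (n_deg > cfg$n_genes) stop("n_deg_per_compound exceeds n_genes", call. = FALSE)
  if (cfg$deg_model$n_replicates < 2) {
    stop("n_replicates must be >= 2 per arm", call. = FALSE)
  }
  invisible(cfg)
}

# deterministic named substreams off one base seed: adding a new artifact
# never perturbs existing ones
substream_names <- c("catalog", "annotation", "degs", "expression",
                     "interactome", "literature", "regulon", "signature",
                     "ortholog", "module")

with_substream <- function(seed, name, code) {
  k <- match(name, substream_names)
  stopifnot(!is.na(k))
  sub <- (as.double(seed) * 131 + k * 100003) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(sub))
  force(code)
}

#' Generate the synthetic fixture world
#'
#' Produces every input table the pipeline consumes, plus the planted ground
#' truth (`truth`): the dark set, per-compound planted DEG sets, planted
#' group-consensus TFs/pathways, and the dark genes whose rat ortholog sits
#' in a pathology-labelled module. Planted dark genes appear in zero
#' annotation resources by construction; every other gene appears in at
#' least one. Planted group-consensus regulators target at least one dark
#' DEG of every compound in their group, so a strict group consensus must
#' recover them.
#'
#' @param config A [world_config()].
#' @return A list of class `synthetic_world` holding the config, the input
#'   tables (`gene_info`, `go_table`, `reactome_sets`, `msigdb_sets`,
#'   `pc_table`, `op_table`, `edge_tables`, `disease_table`, `rif_table`,
#'   `pub_table`, `regulons`, `signatures`, `orthologs`, `modules`,
#'   `module_annotation`, `expression` = list(values, sample_meta),
#'   `groups`) and `truth`.
#' @examples
#' w <- simulate_world(world_config(seed = 1, n_genes = 200,
#'                                  n_planted_dark = 20,
#'                                  deg_model = list(n_deg_per_compound = 40,
#'                                    effect_size_mean = 1.2, effect_size_sd = 0,
#'                                    noise_sd = 0.25, n_replicates = 3,
#'                                    dark_deg_fraction = 0.2)))
#' length(w$truth$planted_dark)
#' @export
simulate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  validate_world_config(config)
  seed <- config$seed
  n <- config$n_genes
  genes <- seq_len(n) + 1000L   # Entrez-style positive integers

  ## --- catalog ------------------------------------------------------------
  cat_parts <- with_substream(seed, "catalog", {
    biotype <- sample(names(config$biotype_proportions), n, replace = TRUE,
                      prob = config$biotype_proportions)
    symbol <- sprintf("GENE%04d", seq_len(n))
    has_syn <- stats::runif(n) < 0.4
    synonyms <- ifelse(has_syn, sprintf("SYN%04dA|SYN%04dB",
                                        seq_len(n), seq_len(n)), "-")
    has_uni <- stats::runif(n) < 0.8
    uniprot <- ifelse(has_uni, sprintf("P%05d", seq_len(n)), "-")
    planted_dark <- sort(sample(genes, config$n_planted_dark))
    list(gene_info = tibble::tibble(
      GeneID = genes, Symbol = symbol, Synonyms = synonyms,
      UniProt = uniprot, biotype = biotype
    ), planted_dark = planted_dark)
  })
  gene_info <- cat_parts$gene_info
  planted_dark <- cat_parts$planted_dark
  annotated_pool <- setdiff(genes, planted_dark)

  ## --- annotation resources -----------------------------------------------
  ann <- with_substream(seed, "annotation", {
    cov <- config$annotation_coverage
    member <- vapply(cov, function(p) stats::runif(length(annotated_pool)) < p,
                     logical(length(annotated_pool)))
    member <- matrix(member, nrow = length(annotated_pool),
                     dimnames = list(NULL, names(cov)))
    orphan <- rowSums(member) == 0
    if (any(orphan)) {   # guarantee every non-planted gene >= 1 resource
      member[cbind(which(orphan),
                   sample.int(ncol(member), sum(orphan), replace = TRUE))] <- TRUE
    }
    membership <- lapply(colnames(member),
                         function(r) annotated_pool[member[, r]])
    names(membership) <- colnames(member)

    go_members <- membership$GO_BP
    n_terms <- pmin(3L, 1L + stats::rpois(length(go_members), 0.8))
    go_table <- tibble::tibble(
      gene_id = rep(go_members, n_terms),
      go_id = sprintf("GO:%07d", sample.int(500, sum(n_terms), replace = TRUE)),
      aspect = "P",
      evidence = sample(c("EXP", "IDA", "IEA"), sum(n_terms), replace = TRUE)
    )
    # decoy molecular-function / cellular-component rows (annotated genes only)
    decoy <- sample(annotated_pool, min(200L, length(annotated_pool)))
    go_table <- dplyr::bind_rows(go_table, tibble::tibble(
      gene_id = decoy,
      go_id = sprintf("GO:%07d", sample.int(500, length(decoy), replace = TRUE)),
      aspect = sample(c("F", "C"), length(decoy), replace = TRUE),
      evidence = "IEA"
    ))

    chunk_sets <- function(members, prefix, size = 25L) {
      members <- sample(members)
      idx <- ceiling(seq_along(members) / size)
      tibble::tibble(
        set_name = sprintf("%s_%03d", prefix, sort(unique(idx)))[idx],
        gene = members
      ) |>
        dplyr::group_by(.data$set_name) |>
        dplyr::summarise(genes = list(.data$gene), .groups = "drop") |>
        dplyr::mutate(description = paste0(prefix, " synthetic set"))
    }
    reactome_sets <- chunk_sets(membership$Reactome, "REACTOME")
    msigdb_sets <- chunk_sets(membership$MSigDB, "MSIGDB")

    pair_up <- function(members) {
      members <- sample(members)
      if (length(members) < 2) return(tibble::tibble(gene_a = integer(0),
                                                     gene_b = integer(0)))
      if (length(members) %% 2 == 1) members <- c(members, members[1])
      half <- length(members) / 2
      tibble::tibble(gene_a = members[seq_len(half)],
                     gene_b = members[half + seq_len(half)])
    }
    pc_pairs <- pair_up(membership$PathwayCommons)
    pc_table <- dplyr::mutate(
      pc_pairs, pathway = sprintf("PWY_%03d", sample.int(60, nrow(pc_pairs),
                                                         replace = TRUE)))
    # decoy rows without pathway annotation, reusing already-annotated genes
    if (nrow(pc_table) > 5) {
      decoy_idx <- sample.int(nrow(pc_table), min(50L, nrow(pc_table) %/% 4))
      pc_table <- dplyr::bind_rows(
        pc_table,
        tibble::tibble(gene_a = pc_table$gene_a[decoy_idx],
                       gene_b = pc_table$gene_b[decoy_idx], pathway = "")
      )
    }

    op_pairs <- pair_up(membership$OmniPath)
    non_ppi <- c("SIGNOR", "KEGG", "SignaLink")
    op_table <- dplyr::mutate(op_pairs, sources = paste0(
      sample(non_ppi, nrow(op_pairs), replace = TRUE),
      ifelse(stats::runif(nrow(op_pairs)) < 0.5, ";BioGRID", "")))
    if (nrow(op_table) > 5) {
      decoy_idx <- sample.int(nrow(op_table), min(50L, nrow(op_table) %/% 4))
      op_table <- dplyr::bind_rows(
        op_table,
        tibble::tibble(gene_a = op_table$gene_a[decoy_idx],
                       gene_b = op_table$gene_b[decoy_idx],
                       sources = sample(c("BioGRID", "HPRD;IntAct", "IntAct"),
                                        length(decoy_idx), replace = TRUE))
      )
    }
    list(membership = membership, go_table = go_table,
         reactome_sets = reactome_sets, msigdb_sets = msigdb_sets,
         pc_table = pc_table, op_table = op_table)
  })

  ## --- planted DEG sets ----------------------------------------------------
  all_compounds <- c(config$compounds$most_dili, config$compounds$no_dili)
  groups <- stats::setNames(
    rep(c("most_dili", "no_dili"),
        c(length(config$compounds$most_dili), length(config$compounds$no_dili))),
    all_compounds)
  dm <- config$deg_model
  deg_sets <- with_substream(seed, "degs", {
    quota <- max(2L, round(dm$dark_deg_fraction * dm$n_deg_per_compound))
    quota <- min(quota, length(planted_dark))
    sets <- lapply(all_compounds, function(cmp) {
      dark_part <- sample(planted_dark, quota)
      rest <- sample(annotated_pool, dm$n_deg_per_compound - quota)
      sort(c(dark_part, rest))
    })
    stats::setNames(sets, all_compounds)
  })

  ## --- expression ----------------------------------------------------------
  truth0 <- list(planted_dark = planted_dark, deg_sets = deg_sets)
  expression <- simulate_expression(config, truth0)

  ## --- interactomes --------------------------------------------------------
  im <- config$interactome_model
  edge_tables <- with_substream(seed, "interactome", {
    tabs <- lapply(im$snapshots, function(sn) {
      nodes <- genes[stats::runif(n) < im$node_inclusion]
      w <- (seq_along(nodes))^(-im$tail_exponent)
      perm <- sample(seq_along(nodes))   # which genes get the heavy tail
      weights <- w[order(perm)]
      n_draw <- im$n_edges * 2L
      a <- sample(nodes, n_draw, replace = TRUE, prob = weights)
      b <- sample(nodes, n_draw, replace = TRUE, prob = weights)
      ed <- tibble::tibble(gene_a = pmin(a, b), gene_b = pmax(a, b))
      ed <- dplyr::distinct(dplyr::filter(ed, .data$gene_a != .data$gene_b))
      utils::head(ed, im$n_edges)
    })
    stats::setNames(tabs, im$snapshots)
  })

  ## --- literature ----------------------------------------------------------
  lm_ <- config$literature_model
  lit <- with_substream(seed, "literature", {
    dis_genes <- genes[stats::runif(n) < lm_$p_disease]
    n_dis <- 1L + stats::rpois(length(dis_genes), lm_$mean_diseases)
    disease_table <- tibble::tibble(
      entrez_id = rep(dis_genes, n_dis),
      disease_id = sprintf("C%06d", sample.int(400, sum(n_dis), replace = TRUE)),
      source_tier = ifelse(stats::runif(sum(n_dis)) < lm_$curated_fraction,
                           "curated", "text_mining")
    ) |> dplyr::distinct()

    rif_genes <- genes[stats::runif(n) < lm_$p_rif]
    n_rif <- 1L + stats::rpois(length(rif_genes), lm_$mean_rifs)
    rif_table <- tibble::tibble(
      entrez_id = rep(rif_genes, n_rif),
      rif_text = sprintf("functional statement %05d",
                         sample.int(99999, sum(n_rif), replace = TRUE)),
      pmid = as.character(10000000 + sample.int(899999, sum(n_rif),
                                                replace = TRUE))
    )

    pub_genes <- genes[stats::runif(n) < lm_$p_pub]
    n_pub <- 1L + stats::rpois(length(pub_genes), lm_$mean_pubs)
    pub_table <- tibble::tibble(
      entrez_id = rep(pub_genes, n_pub),
      pmid = as.character(20000000 + sample.int(5000, sum(n_pub),
                                                replace = TRUE))
    )
    list(disease_table = disease_table, rif_table = rif_table,
         pub_table = pub_table)
  })

  ## --- regulons with planted group consensus -------------------------------
  dark_degs <- lapply(deg_sets, intersect, y = planted_dark)
  rm_ <- config$regulon_model
  reg <- with_substream(seed, "regulon", {
    consensus_tfs <- list(
      most_dili = sprintf("TF_CONS_MD%d", seq_len(rm_$n_consensus_per_group)),
      no_dili = sprintf("TF_CONS_ND%d", seq_len(rm_$n_consensus_per_group))
    )
    rows <- list()
    for (grp in names(consensus_tfs)) {
      for (tf in consensus_tfs[[grp]]) {
        targets <- unlist(lapply(config$compounds[[grp]], function(cmp) {
          sample(dark_degs[[cmp]], min(2L, length(dark_degs[[cmp]])))
        }))
        targets <- unique(c(targets,
                            sample(genes, rm_$targets_per_tf, replace = FALSE)))
        rows[[tf]] <- tibble::tibble(tf = tf, target = targets)
      }
    }
    for (i in seq_len(rm_$n_tfs)) {
      tf <- sprintf("TF_%03d", i)
      rows[[tf]] <- tibble::tibble(
        tf = tf, target = sample(genes, rm_$targets_per_tf))
    }
    regulons <- dplyr::bind_rows(rows)
    regulons$grade <- sample(LETTERS[1:5], nrow(regulons), replace = TRUE)
    list(regulons = regulons, consensus_tfs = consensus_tfs)
  })

  sm_ <- config$signature_model
  sig <- with_substream(seed, "signature", {
    consensus_pw <- list(
      most_dili = sprintf("PW_CONS_MD%d", seq_len(sm_$n_consensus_per_group)),
      no_dili = sprintf("PW_CONS_ND%d", seq_len(sm_$n_consensus_per_group))
    )
    rows <- list()
    for (grp in names(consensus_pw)) {
      for (pw in consensus_pw[[grp]]) {
        members <- unlist(lapply(config$compounds[[grp]], function(cmp) {
          sample(dark_degs[[cmp]], min(2L, length(dark_degs[[cmp]])))
        }))
        members <- unique(c(members, sample(genes, sm_$genes_per_pathway)))
        rows[[pw]] <- tibble::tibble(pathway = pw, gene = members)
      }
    }
    for (i in seq_len(sm_$n_pathways)) {
      pw <- sprintf("PW_%03d", i)
      rows[[pw]] <- tibble::tibble(
        pathway = pw, gene = sample(genes, sm_$genes_per_pathway))
    }
    list(signatures = dplyr::bind_rows(rows), consensus_pathways = consensus_pw)
  })

  ## --- orthologs -----------------------------------------------------------
  orth <- with_substream(seed, "ortholog", {
    has_orth <- stats::runif(n) < config$ortholog_rate
    # guarantee a few dark genes carry orthologs for the pathology planting
    anchor <- planted_dark[seq_len(min(5L, length(planted_dark)))]
    has_orth[match(anchor, genes)] <- TRUE
    orthologs <- tibble::tibble(
      human_entrez = genes[has_orth],
      rat_gene = paste0("r", genes[has_orth])
    )
    multi <- stats::runif(nrow(orthologs)) < config$multi_ortholog_rate
    orthologs <- dplyr::bind_rows(
      orthologs,
      tibble::tibble(human_entrez = orthologs$human_entrez[multi],
                     rat_gene = paste0(orthologs$rat_gene[multi], "b"))
    ) |> dplyr::arrange(.data$human_entrez, .data$rat_gene)
    list(orthologs = orthologs, anchor = anchor)
  })

  ## --- modules + pathology -------------------------------------------------
  mm <- config$module_model
  mods <- with_substream(seed, "module", {
    rat_genes <- unique(orth$orthologs$rat_gene)
    in_mod <- stats::runif(length(rat_genes)) < mm$p_in_module
    modules <- tibble::tibble(
      rat_gene = rat_genes[in_mod],
      module_id = as.character(sample.int(mm$n_modules, sum(in_mod),
                                          replace = TRUE))
    )
    # anchor dark-gene orthologs into module "1"
    anchor_rat <- paste0("r", orth$anchor)
    modules <- dplyr::bind_rows(
      modules[!modules$rat_gene %in% anchor_rat, , drop = FALSE],
      tibble::tibble(rat_gene = anchor_rat, module_id = "1")
    ) |> dplyr::arrange(.data$rat_gene, .data$module_id)

    path_labels <- c("BDH", "Fibrosis", "Necrosis", "Hypertrophy",
                     "Adverse at 29 days", "Increased mitosis",
                     "Single cell necrosis", "Vacuolation")
    gobp_labels <- c("Cell cycle", "Inflammatory response",
                     "Extracellular matrix organization", "Protein folding",
                     "Signal transduction", "")
    has_path <- stats::runif(mm$n_modules) < mm$p_pathology
    has_path[1] <- TRUE   # the anchor module carries a pathology
    module_annotation <- tibble::tibble(
      module_id = as.character(seq_len(mm$n_modules)),
      pathology = ifelse(has_path,
                         sample(path_labels, mm$n_modules, replace = TRUE), ""),
      go_bp = sample(gobp_labels, mm$n_modules, replace = TRUE)
    )
    list(modules = modules, module_annotation = module_annotation)
  })

  # planted module-pathology genes: dark genes whose ortholog sits in a
  # pathology-labelled module (recomputed from the generated tables)
  path_modules <- mods$module_annotation$module_id[
    mods$module_annotation$pathology != ""]
  rat_in_path <- mods$modules$rat_gene[mods$modules$module_id %in% path_modules]
  humans_in_path <- orth$orthologs$human_entrez[
    orth$orthologs$rat_gene %in% rat_in_path]
  module_pathology_genes <- sort(intersect(planted_dark, humans_in_path))

  structure(list(
    config = config,
    gene_info = gene_info,
    go_table = ann$go_table,
    reactome_sets = ann$reactome_sets,
    msigdb_sets = ann$msigdb_sets,
    pc_table = ann$pc_table,
    op_table = ann$op_table,
    edge_tables = edge_tables,
    disease_table = lit$disease_table,
    rif_table = lit$rif_table,
    pub_table = lit$pub_table,
    regulons = reg$regulons,
    signatures = sig$signatures,
    orthologs = orth$orthologs,
    modules = mods$modules,
    module_annotation = mods$module_annotation,
    expression = expression,
    groups = groups,
    truth = list(
      planted_dark = planted_dark,
      deg_sets = deg_sets,
      dark_degs = dark_degs,
      consensus_tfs = reg$consensus_tfs,
      consensus_pathways = sig$consensus_pathways,
      module_pathology_genes = module_pathology_genes,
      membership = ann$membership
    )
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", x$config$n_genes, " genes, ",
      length(x$truth$planted_dark), " planted dark, ",
      length(x$groups), " compounds\n", sep = "")
  invisible(x)
}

#' Simulate the log2 expression matrix for a world
#'
#' Control arms draw Normal(baseline, noise_sd) per gene; planted DEGs of a
#' compound are shifted in its treated arm by the drawn effect (random sign,
#' magnitude `effect_size_mean` plus Normal(0, `effect_size_sd`) jitter), all
#' on the log2 scale. Each compound contributes one stratum (highest dose,
#' 24 h) with `n_replicates` treated and `n_replicates` time-matched control
#' samples.
#'
#' @param config A [world_config()].
#' @param truth A list with at least `deg_sets` (named per-compound planted
#'   DEG vectors), e.g. the `truth` element of [simulate_world()].
#' @return A list with `values` (gene x sample log2 matrix, Entrez row names)
#'   and `sample_meta` (tibble: `sample_id`, `compound`, `dose_level`,
#'   `time_h`, `role`, `group`).
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "world_config"), !is.null(truth$deg_sets))
  dm <- config$deg_model
  if (dm$n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  n <- config$n_genes
  genes <- seq_len(n) + 1000L
  all_compounds <- c(config$compounds$most_dili, config$compounds$no_dili)
  groups <- stats::setNames(
    rep(c("most_dili", "no_dili"),
        c(length(config$compounds$most_dili), length(config$compounds$no_dili))),
    all_compounds)

  with_substream(config$seed, "expression", {
    baseline <- stats::rnorm(n, mean = 7, sd = 1)
    cols <- list(); meta <- list()
    for (cmp in all_compounds) {
      planted <- truth$deg_sets[[cmp]]
      effect <- numeric(n)
      idx <- match(planted, genes)
      idx <- idx[!is.na(idx)]
      magn <- dm$effect_size_mean +
        stats::rnorm(length(idx), 0, dm$effect_size_sd)
      sign <- sample(c(-1, 1), length(idx), replace = TRUE)
      effect[idx] <- sign * magn
      for (r in seq_len(dm$n_replicates)) {
        sid <- paste0(cmp, "_ctrl_", r)
        cols[[sid]] <- baseline + stats::rnorm(n, 0, dm$noise_sd)
        meta[[sid]] <- tibble::tibble(sample_id = sid, compound = cmp,
                                      dose_level = "high", time_h = 24,
                                      role = "control",
                                      group = unname(groups[[cmp]]))
      }
      for (r in seq_len(dm$n_replicates)) {
        sid <- paste0(cmp, "_trt_", r)
        cols[[sid]] <- baseline + effect + stats::rnorm(n, 0, dm$noise_sd)
        meta[[sid]] <- tibble::tibble(sample_id = sid, compound = cmp,
                                      dose_level = "high", time_h = 24,
                                      role = "treated",
                                      group = unname(groups[[cmp]]))
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- as.character(genes)
    list(values = values, sample_meta = dplyr::bind_rows(meta))
  })
}
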
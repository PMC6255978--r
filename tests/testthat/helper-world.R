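# shared fixtures, all built in code

# four-record catalog exercising the symbol -> synonym -> UniProt cascade:
#  - "ALPHA" is the primary symbol of 101 and a synonym of 102
#  - "SHARED" is a synonym of both 103 and 104 (ambiguous at synonym step)
tiny_catalog <- function() {
  gene_catalog(tibble::tibble(
    GeneID = c(101L, 102L, 103L, 104L),
    Symbol = c("ALPHA", "BETA", "GAMMA", "DELTA"),
    Synonyms = c("A1|A2", "ALPHA|B2", "SHARED|G1", "SHARED"),
    UniProt = c("P00001", "P00002", "P00003", "-"),
    biotype = c("protein_coding", "lincRNA", "protein_coding", "pseudogene")
  ))
}

# small but complete world: fast enough for per-test pipeline runs
small_world_config <- function(seed = 7) {
  world_config(
    seed = seed, n_genes = 400, n_planted_dark = 40,
    deg_model = list(n_deg_per_compound = 60, effect_size_mean = 1.2,
                     effect_size_sd = 0, noise_sd = 0.25, n_replicates = 3,
                     dark_deg_fraction = 0.2),
    interactome_model = list(snapshots = c("BIANA", "HIPPIE", "INBIOMAP",
                                           "INTACT"),
                             n_edges = 800, node_inclusion = 0.75,
                             tail_exponent = 0.8),
    regulon_model = list(n_tfs = 15, targets_per_tf = 15,
                         n_consensus_per_group = 2),
    signature_model = list(n_pathways = 8, genes_per_pathway = 20,
                           n_consensus_per_group = 1),
    module_model = list(n_modules = 15, p_in_module = 0.5, p_pathology = 0.3)
  )
}

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_world(small_world_config())
    cache
  }
})

# expression fixture: two compounds, one with planted effects
toy_expression <- function(seed = 42, n_genes = 50, planted = 1:5,
                           effect = 2, noise_sd = 0.25) {
  set.seed(seed)
  genes <- seq_len(n_genes) + 1000L
  baseline <- rnorm(n_genes, 7, 1)
  mk <- function(shift) baseline + shift + rnorm(n_genes, 0, noise_sd)
  eff <- numeric(n_genes); eff[planted] <- effect
  values <- cbind(
    drugA_ctrl_1 = mk(0), drugA_ctrl_2 = mk(0), drugA_ctrl_3 = mk(0),
    drugA_trt_1 = mk(0) + eff, drugA_trt_2 = mk(0) + eff,
    drugA_trt_3 = mk(0) + eff
  )
  rownames(values) <- as.character(genes)
  meta <- tibble::tibble(
    sample_id = colnames(values), compound = "drugA",
    role = rep(c("control", "treated"), each = 3)
  )
  list(values = values, meta = meta, genes = genes)
}

# quadratic-time Benjamini-Hochberg reference, straight from the step-up
# definition: sort ascending, q_(i) = min(1, min_{j >= i} p_(j) * m / j)
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[o[i]] <- min(1, min(ps[i:m] * m / (i:m)))
  q
}
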
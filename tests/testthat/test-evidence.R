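make_degree_tab <- function(rows, genes, snaps) {
  d <- rows
  attr(d, "genes") <- genes
  attr(d, "snapshots") <- snaps
  class(d) <- c("degree_table", class(d))
  d
}

test_that("evidence flags follow the >=1 conventions per source", {
  genes <- 1:4
  deg <- make_degree_tab(
    tibble::tibble(entrez_id = 1L, snapshot = "HIPPIE", degree = 3L),
    genes, c("BIANA", "HIPPIE", "INBIOMAP", "INTACT"))
  dis <- tibble::tibble(entrez_id = 2L, n_diseases = 2L)
  rif <- tibble::tibble(entrez_id = 2L, n_generifs = 1L, highlighted = FALSE)
  m <- build_evidence_matrix(genes, degree_table = deg,
                             disease_curated = dis, disease_all = dis,
                             generif_counts = rif)
  expect_true(m$PIN_HIPPIE[m$entrez_id == 1])
  expect_false(any(m$PIN_BIANA))              # degree only in one PIN
  expect_true(m$DISEASE_CURATED[m$entrez_id == 2])
  expect_true(m$GENERIF[m$entrez_id == 2])
  # gene with nothing anywhere: all-false row
  expect_false(any(as.logical(m[m$entrez_id == 4, evidence_sources()])))
})

test_that("gene-set mismatch raises with the offending IDs", {
  deg <- make_degree_tab(
    tibble::tibble(entrez_id = 99L, snapshot = "HIPPIE", degree = 1L),
    1:3, "HIPPIE")
  expect_error(build_evidence_matrix(1:3, degree_table = deg),
               "mismatch.*99")
})

test_that("20-gene fixture matrix equals a hand-built truth table", {
  set.seed(81)
  genes <- 1:20
  snaps <- c("BIANA", "HIPPIE", "INBIOMAP", "INTACT")
  deg_rows <- tibble::tibble(
    entrez_id = sample(genes, 30, TRUE),
    snapshot = sample(snaps, 30, TRUE),
    degree = sample(1:9, 30, TRUE)
  ) |> (\(d) dplyr::distinct(d, entrez_id, snapshot, .keep_all = TRUE))()
  deg <- make_degree_tab(deg_rows, genes, snaps)
  dis_c <- tibble::tibble(entrez_id = sample(genes, 5), n_diseases = 1:5)
  pub <- tibble::tibble(entrez_id = sample(genes, 7),
                        n_publications = sample(1:9, 7, TRUE))
  reg_map <- tibble::tibble(compound = c("a", "b"),
                            n_dark = 10,
                            regulators = list("T1", character(0)),
                            mapped_genes = list(c(3L, 4L), integer(0)),
                            n_regulators = c(1, 0), n_mapped = c(2, 0))
  orth <- map_orthologs(genes, tibble::tibble(
    human_entrez = c(1, 2, 5), rat_gene = c("r1", "r2", "r5")))
  mods <- assign_modules(orth$rat_genes,
                         tibble::tibble(rat_gene = c("r1", "r5"),
                                        module_id = c("1", "2")))
  m <- build_evidence_matrix(genes, degree_table = deg,
                             disease_curated = dis_c,
                             publication_counts = pub,
                             regulon_mappings = reg_map,
                             ortholog_mapping = orth,
                             module_assignment = mods)
  for (g in genes) {
    row <- m[m$entrez_id == g, ]
    for (sn in snaps) {
      expect_equal(row[[paste0("PIN_", sn)]],
                   any(deg_rows$entrez_id == g & deg_rows$snapshot == sn))
    }
    expect_equal(row$DISEASE_CURATED, g %in% dis_c$entrez_id)
    expect_equal(row$PUBTATOR, g %in% pub$entrez_id)
    expect_equal(row$REGULON, g %in% c(3L, 4L))
    expect_equal(row$RAT_ORTHOLOG, g %in% c(1, 2, 5))
    expect_equal(row$WGCNA_MODULE, g %in% c(1, 5))
  }
})

test_that("scores are row sums and tiers follow the cutoffs", {
  genes <- 1:6
  m <- build_evidence_matrix(genes)
  src <- evidence_sources()
  # plant flag patterns: 8 -> high, 4 -> moderate, 0 -> none, 1 -> low
  for (j in 1:8) m[[src[j]]][1] <- TRUE
  for (j in 1:4) m[[src[j]]][2] <- TRUE
  m[[src[1]]][3] <- TRUE
  st <- score_and_tier(m)
  expect_equal(st$score[1:4], c(8L, 4L, 1L, 0L))
  expect_equal(as.character(st$tier[1:4]),
               c("high", "moderate", "low", "none"))

  # oracle: score equals the row sum on random matrices; tier monotone in S
  set.seed(82)
  for (i in 1:100) {
    mm <- build_evidence_matrix(1:15)
    for (s in src) mm[[s]] <- runif(15) < 0.4
    attr(mm, "sources") <- src
    st <- score_and_tier(mm)
    expect_equal(st$score, unname(rowSums(as.matrix(mm[, src]))))
    o <- order(st$score)
    expect_true(all(diff(as.integer(st$tier[o])) >= 0))
  }
})

test_that("adding an evidence source never lowers a tier", {
  set.seed(83)
  for (i in 1:30) {
    m <- build_evidence_matrix(1:10)
    src <- evidence_sources()
    for (s in src) m[[s]] <- runif(10) < 0.3
    t1 <- score_and_tier(m)$tier
    m2 <- m
    j <- sample(src, 1)
    m2[[j]] <- m2[[j]] | (runif(10) < 0.5)
    t2 <- score_and_tier(m2)$tier
    expect_true(all(t2 >= t1))
  }
})

test_that("exclusivity flags require zero no-DILI hits", {
  mk <- function(deg_ids) tibble::tibble(entrez_id = 1:10,
                                         is_deg = 1:10 %in% deg_ids)
  tabs <- list(
    d1 = mk(c(1, 2, 3)), d2 = mk(c(1, 2)), d3 = mk(c(1, 2)),
    d4 = mk(c(1, 2)), d5 = mk(c(1)),
    n1 = mk(c(2)), n2 = mk(integer(0)), n3 = mk(integer(0)),
    n4 = mk(integer(0)), n5 = mk(integer(0))
  )
  groups <- stats::setNames(rep(c("most_dili", "no_dili"), each = 5),
                            names(tabs))
  fl <- exclusivity_flags(tabs, groups)
  # gene 1: DEG in 5 DILI, 0 no-DILI -> both flags
  expect_true(fl$most_dili_exclusive[fl$entrez_id == 1])
  expect_true(fl$deg_in_4of5_dili[fl$entrez_id == 1])
  # gene 2: 4 DILI but 1 no-DILI -> contamination kills both
  expect_false(fl$most_dili_exclusive[fl$entrez_id == 2])
  expect_false(fl$deg_in_4of5_dili[fl$entrez_id == 2])
  # gene 3: 1 DILI only -> exclusive but not 4-of-5
  expect_true(fl$most_dili_exclusive[fl$entrez_id == 3])
  expect_false(fl$deg_in_4of5_dili[fl$entrez_id == 3])
  # implication: 4-of-5 flag implies exclusivity flag
  expect_true(all(!fl$deg_in_4of5_dili | fl$most_dili_exclusive))
  expect_error(exclusivity_flags(tabs[-1], groups), "missing DEG table")
})

test_that("coverage fraction floors the percentage like published counts", {
  m <- build_evidence_matrix(1:4)
  m$GENERIF <- c(TRUE, TRUE, TRUE, FALSE)
  cf <- coverage_fraction(m)
  expect_equal(cf$fraction, 75)
  expect_equal(cf$pct_floor, 75)
  m2 <- build_evidence_matrix(1:4)
  expect_equal(coverage_fraction(m2)$fraction, 0)
  expect_error(coverage_fraction(m[0, ]), "empty")
})
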
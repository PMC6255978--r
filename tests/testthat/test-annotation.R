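test_that("GMT parsing unions members and skips short lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("set1\tdesc\t1\t2", "set2\tdesc\t2\t3", "bad_line\tonly2fields"),
             f)
  expect_warning(res <- parse_gmt(f, name = "MSigDB"), "skipped")
  expect_setequal(res$genes, c(1L, 2L, 3L))

  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), f2)
  expect_equal(parse_gmt(f2)$genes, integer(0))
})

test_that("GMT member symbols resolve through the catalog, losses logged", {
  ct <- tiny_catalog()
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("s\td\tALPHA\tBETA\tNOSUCH", f)
  expect_warning(res <- parse_gmt(f, catalog = ct), "unmapped")
  expect_setequal(res$genes, c(101L, 102L))
})

test_that("GO parsing keeps only the biological-process aspect", {
  tab <- tibble::tibble(
    gene_id = c(1, 1, 2, 3, 4, 5),
    go_id = paste0("GO:", 1:6),
    aspect = c("P", "C", "F", "P", "C", "Q")
  )
  expect_warning(res <- parse_go_annotations(tab), "unknown aspect")
  expect_setequal(res$genes, c(1L, 3L))   # gene 2 (F only), 4 (C only) out
  expect_equal(res$name, "GO_BP")
})

test_that("GO evidence-code exclusion list is honoured when set", {
  tab <- tibble::tibble(gene_id = c(1, 2), go_id = c("GO:1", "GO:2"),
                        aspect = "P", evidence = c("IEA", "EXP"))
  expect_setequal(parse_go_annotations(tab)$genes, c(1L, 2L))
  expect_equal(parse_go_annotations(tab, exclude_evidence = "IEA")$genes, 2L)
})

test_that("Pathway Commons filter drops genes seen only without pathway", {
  tab <- tibble::tibble(
    gene_a = c(1, 3, 5, 1),
    gene_b = c(2, 4, 6, 5),
    pathway = c("P1", "", "  ", "P2")
  )
  res <- parse_pathway_commons(tab)
  # 3,4,6 appear only in rows with blank pathway; 5 also in an annotated row
  expect_setequal(res$genes, c(1L, 2L, 5L))
})

test_that("OmniPath filter drops rows supported only by PPI databases", {
  tab <- tibble::tibble(
    gene_a = c(1, 3, 5, 7),
    gene_b = c(2, 4, 6, 8),
    sources = c("BioGRID", "BioGRID;SIGNOR", "KEGG", "HPRD;IntAct")
  )
  res <- parse_omnipath(tab)
  expect_setequal(res$genes, c(3L, 4L, 5L, 6L))

  tab2 <- tibble::tibble(gene_a = 1, gene_b = 2, sources = "")
  expect_warning(res2 <- parse_omnipath(tab2), "empty source")
  expect_equal(res2$genes, integer(0))
})

test_that("darkness is absence from every resource", {
  uni <- annotation_universe(list(
    gene_set_resource("GO_BP", c(1, 2)),
    gene_set_resource("Reactome", c(2, 3))
  ))
  calls <- classify_darkness(c(1, 2, 3, 4), uni)
  expect_equal(calls$dark, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(calls$present_in[[1]], "GO_BP")
  expect_setequal(calls$present_in[[2]], c("GO_BP", "Reactome"))
  expect_equal(calls$present_in[[4]], character(0))
  # dark <=> present_in empty, per call
  expect_equal(calls$dark, lengths(calls$present_in) == 0)
})

test_that("darkness calls equal a brute-force membership scan on random universes", {
  set.seed(31)
  for (i in 1:100) {
    n_res <- sample(2:5, 1)
    resources <- lapply(seq_len(n_res), function(j) {
      gene_set_resource(paste0("R", j), sample(1:200, sample(10:100, 1)))
    })
    uni <- annotation_universe(resources)
    genes <- sample(1:250, 200)
    calls <- classify_darkness(genes, uni)
    brute <- vapply(genes, function(g) {
      !any(vapply(resources, function(r) g %in% r$genes, logical(1)))
    }, logical(1))
    expect_equal(calls$dark, brute)
    # resource order must not matter
    calls2 <- classify_darkness(genes, annotation_universe(rev(resources)))
    expect_equal(calls2$dark, calls$dark)
  }
})

test_that("adding a resource never enlarges the dark set", {
  set.seed(32)
  for (i in 1:25) {
    r1 <- gene_set_resource("A", sample(1:100, 40))
    r2 <- gene_set_resource("B", sample(1:100, 40))
    genes <- 1:100
    d1 <- classify_darkness(genes, annotation_universe(list(r1)))
    d2 <- classify_darkness(genes, annotation_universe(list(r1, r2)))
    expect_true(all(d1$entrez_id[d2$dark] %in% d1$entrez_id[d1$dark]))
  }
})

test_that("coverage report carries raw, rounded and floored percentages", {
  calls <- classify_darkness(1:10, annotation_universe(list(
    gene_set_resource("A", 1:8))))
  rep <- coverage_report(calls)
  expect_equal(rep$n_dark, 2)
  expect_equal(rep$dark_fraction, 20)
  expect_equal(rep$pct_round, 20)

  all_ann <- classify_darkness(1:5, annotation_universe(list(
    gene_set_resource("A", 1:5))))
  expect_equal(coverage_report(all_ann)$dark_fraction, 0)
  expect_error(coverage_report(calls[0, ]), "empty")
})

test_that("biotype tally categorizes known biotypes and sidelines unknowns", {
  ct <- gene_catalog(tibble::tibble(
    GeneID = 1:5, Symbol = paste0("G", 1:5),
    biotype = c("protein_coding", "protein_coding", "lincRNA",
                "unknown", "unknown")))
  tally <- tally_biotypes(1:5, ct,
                          group_membership = list(g1 = c(1, 3, 4),
                                                  g2 = c(1, 5)))
  total <- tally[tally$biotype == "Total", ]
  uncat <- tally[tally$biotype == "uncategorized", ]
  expect_equal(total$all_dark, 3)        # 2 coding + 1 lincRNA
  expect_equal(uncat$all_dark, 2)
  expect_equal(total$g1, 2)              # genes 1 (coding) + 3 (lincRNA)
  expect_equal(total$g2, 1)              # gene 1 counted again in g2
  # column total equals sum of the per-biotype rows
  vocab_rows <- !tally$biotype %in% c("Total", "uncategorized")
  expect_equal(sum(tally$all_dark[vocab_rows]), total$all_dark)

  ct_unknown <- gene_catalog(tibble::tibble(GeneID = 1:5,
                                            Symbol = paste0("G", 1:5)))
  t2 <- tally_biotypes(1:5, ct_unknown)
  expect_equal(t2$all_dark[t2$biotype == "Total"], 0)
  expect_equal(t2$all_dark[t2$biotype == "uncategorized"], 5)
})
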
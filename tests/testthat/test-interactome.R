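test_that("edge cleaning dedups, drops self-loops and predicted rows", {
  tab <- tibble::tibble(gene_a = c(1, 2, 1, 3),
                        gene_b = c(2, 1, 1, 4),
                        predicted = c(FALSE, FALSE, FALSE, TRUE))
  sn <- as_interactome(tab, "X", predicted_col = "predicted")
  expect_equal(nrow(sn$edges), 1)          # A-B == B-A, A-A dropped, 3-4 predicted
  expect_equal(sn$edges$from, 1)
  expect_equal(sn$edges$to, 2)
  # without the flag configured the predicted row stays
  sn2 <- as_interactome(tab, "X")
  expect_equal(nrow(sn2$edges), 2)

  empty <- as_interactome(tab[0, ], "E")
  expect_equal(nrow(empty$edges), 0)
  expect_equal(length(empty$nodes), 0)
})

test_that("degrees match simple graphs and adjacency row sums", {
  triangle <- as_interactome(
    tibble::tibble(gene_a = c(1, 2, 3), gene_b = c(2, 3, 1)), "tri")
  d <- degree_profile(1:3, list(triangle))
  expect_equal(d$degree, c(2L, 2L, 2L))

  star <- as_interactome(
    tibble::tibble(gene_a = 10, gene_b = 11:15), "star")
  ds <- degree_profile(10:15, list(star))
  expect_equal(ds$degree[ds$entrez_id == 10], 5L)
  expect_true(all(ds$degree[ds$entrez_id != 10] == 1L))

  set.seed(41)
  for (i in 1:100) {
    n <- 50
    m <- sample(20:120, 1)
    tab <- tibble::tibble(gene_a = sample(n, m, TRUE),
                          gene_b = sample(n, m, TRUE))
    sn <- as_interactome(tab, "rand")
    adj <- matrix(0L, n, n)
    for (j in seq_len(nrow(sn$edges))) {
      adj[sn$edges$from[j], sn$edges$to[j]] <- 1L
      adj[sn$edges$to[j], sn$edges$from[j]] <- 1L
    }
    d <- degree_profile(1:n, list(sn))
    expected <- rowSums(adj)
    expect_equal(d$degree, unname(expected[d$entrez_id]))
    # handshake lemma
    expect_equal(sum(d$degree), 2 * nrow(sn$edges))
  }
})

test_that("degrees agree with igraph on a random graph", {
  skip_if_not_installed("igraph")
  set.seed(42)
  tab <- tibble::tibble(gene_a = sample(30, 80, TRUE),
                        gene_b = sample(30, 80, TRUE))
  sn <- as_interactome(tab, "g")
  g <- igraph::graph_from_edgelist(as.matrix(sn$edges), directed = FALSE)
  dg <- igraph::degree(g)   # indexed by vertex id
  ours <- degree_profile(1:30, list(sn))
  expect_equal(ours$degree, as.integer(dg[ours$entrez_id]))
})

test_that("degree computation ignores row and endpoint order", {
  set.seed(43)
  tab <- tibble::tibble(gene_a = sample(20, 40, TRUE),
                        gene_b = sample(20, 40, TRUE))
  flipped <- tibble::tibble(gene_a = tab$gene_b, gene_b = tab$gene_a)
  d1 <- degree_profile(1:20, list(as_interactome(tab, "a")))
  d2 <- degree_profile(1:20, list(as_interactome(flipped[sample(40), ], "a")))
  expect_equal(d1, d2, ignore_attr = TRUE)
})

test_that("presence summary counts >=1 and all-snapshot genes", {
  sn1 <- as_interactome(tibble::tibble(gene_a = 1, gene_b = 2), "s1")
  sn2 <- as_interactome(tibble::tibble(gene_a = c(1, 3), gene_b = c(2, 4)), "s2")
  d <- degree_profile(1:5, list(sn1, sn2))
  ps <- presence_summary(d)
  expect_equal(ps$present_any, 4)   # 1,2,3,4
  expect_equal(ps$present_all, 2)   # 1,2
  expect_lte(ps$present_all, ps$present_any)

  # brute-force presence matrix scan on random cases
  set.seed(44)
  for (i in 1:50) {
    snapshots <- lapply(1:3, function(j) {
      as_interactome(tibble::tibble(gene_a = sample(15, 20, TRUE),
                                    gene_b = sample(15, 20, TRUE)),
                     paste0("s", j))
    })
    genes <- 1:15
    d <- degree_profile(genes, snapshots)
    pres <- sapply(snapshots, function(sn) genes %in% sn$nodes)
    expect_equal(presence_summary(d)$present_any, sum(rowSums(pres) >= 1))
    expect_equal(presence_summary(d)$present_all, sum(rowSums(pres) == 3))
  }
})

test_that("top-connected ranking follows the statistic with Entrez tie-break", {
  sn1 <- as_interactome(
    tibble::tibble(gene_a = rep(1, 5), gene_b = 2:6), "s1")   # deg(1)=5
  sn2 <- as_interactome(
    tibble::tibble(gene_a = rep(2, 3), gene_b = c(3, 4, 5)), "s2") # deg(2)=3
  d <- degree_profile(1:6, list(sn1, sn2))
  top <- top_connected(d, k = 3, rank_statistic = "max")
  expect_equal(top$entrez_id[1], 1)
  expect_equal(top$rank_stat[1], 5)

  # max vs sum can change the order: A(405,44) beats B(8,87) on max,
  # and on sum 449 > 95 as hand-computed
  da <- tibble::tibble(entrez_id = c(1L, 2L, 1L, 2L),
                       snapshot = c("x", "x", "y", "y"),
                       degree = c(405L, 8L, 44L, 87L))
  attr(da, "genes") <- c(1L, 2L)
  attr(da, "snapshots") <- c("x", "y")
  class(da) <- c("degree_table", class(da))
  expect_equal(top_connected(da, 2, "max")$entrez_id, c(1L, 2L))
  sums <- top_connected(da, 2, "sum")
  expect_equal(sums$rank_stat, c(449, 95))

  # all-equal degrees -> ascending Entrez order
  de <- tibble::tibble(entrez_id = c(5L, 3L, 9L), snapshot = "x",
                       degree = 2L)
  attr(de, "genes") <- c(5L, 3L, 9L)
  attr(de, "snapshots") <- "x"
  class(de) <- c("degree_table", class(de))
  expect_equal(top_connected(de, 5)$entrez_id, c(3L, 5L, 9L))
})

test_that("minimum-score filter and TSV loading work", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_a = c(1, 2), gene_b = c(3, 4),
                                  score = c(0.9, 0.1)), f)
  sn <- load_edge_list(f, name = "scored", score_col = "score",
                       min_score = 0.5)
  expect_equal(nrow(sn$edges), 1)
  expect_setequal(sn$nodes, c(1L, 3L))
})
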
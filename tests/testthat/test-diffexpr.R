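test_that("log2 fold change is the difference of arm means", {
  values <- rbind(
    g1 = c(5, 5, 5, 5.585, 5.585, 5.585),   # +0.585, passes the FC gate
    g2 = c(6, 6, 6, 6, 6, 6),               # no change
    g3 = c(6, 6, 6, 4, 4, 4)                # -2
  )
  rownames(values) <- c("1", "2", "3")
  colnames(values) <- paste0("s", 1:6)
  meta <- tibble::tibble(sample_id = paste0("s", 1:6), compound = "x",
                         role = rep(c("control", "treated"), each = 3))
  fc <- compute_log2fc(values, meta, "x")
  expect_equal(fc$log2fc, c(0.585, 0, -2))
  expect_true(abs(fc$log2fc[1]) >= log2(1.5))
})

test_that("missing control stratum names the compound", {
  values <- matrix(1, 2, 2, dimnames = list(1:2, c("a", "b")))
  meta <- tibble::tibble(sample_id = c("a", "b"), compound = "x",
                         role = "treated")
  expect_error(compute_log2fc(values, meta, "x"), "control.*'x'")
})

test_that("pooled t matches the closed-form oracle on {1,2,3} vs {4,5,6}", {
  values <- matrix(c(4, 5, 6, 1, 2, 3), nrow = 1,
                   dimnames = list("1", paste0("s", 1:6)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:6), compound = "x",
                         role = rep(c("control", "treated"), each = 3))
  res <- test_differential(values, meta, "x", method = "t_pooled")
  # pooled variance 1, t = -3 / sqrt(2/3) = -3.6742 on 4 df
  t_oracle <- -3 / sqrt(2 / 3)
  expect_equal(res$p_value, 2 * pt(t_oracle, df = 4), tolerance = 1e-12)
  # and agrees with stats::t.test var.equal = TRUE
  expect_equal(res$p_value,
               t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("constant identical arms give p = 1 by convention", {
  values <- matrix(3, 2, 6, dimnames = list(1:2, paste0("s", 1:6)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:6), compound = "x",
                         role = rep(c("control", "treated"), each = 3))
  for (m in c("t_pooled", "t_welch", "eb_moderated")) {
    expect_equal(test_differential(values, meta, "x", method = m)$p_value,
                 c(1, 1))
  }
})

test_that("null p-values are approximately uniform across 2000 genes", {
  set.seed(303)
  values <- matrix(rnorm(2000 * 6, 7, 0.4), nrow = 2000,
                   dimnames = list(1:2000, paste0("s", 1:6)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:6), compound = "x",
                         role = rep(c("control", "treated"), each = 3))
  p <- test_differential(values, meta, "x", method = "t_pooled")$p_value
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("moderated test agrees with limma's moderated t shape on a fixture", {
  skip_if_not_installed("limma")
  set.seed(99)
  values <- matrix(rnorm(500 * 6, 7, 0.3), nrow = 500,
                   dimnames = list(1:500, paste0("s", 1:6)))
  values[1:20, 4:6] <- values[1:20, 4:6] + 1.5
  meta <- tibble::tibble(sample_id = paste0("s", 1:6), compound = "x",
                         role = rep(c("control", "treated"), each = 3))
  ours <- test_differential(values, meta, "x", method = "eb_moderated")
  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(values, design))
  p_limma <- fit$p.value[, 2]
  # not the same estimator (fixed prior df, pooled target) but both must
  # rank the planted block on top
  expect_gte(sum(order(ours$p_value)[1:20] %in% 1:20), 18)
  expect_gte(sum(order(p_limma)[1:20] %in% 1:20), 18)
  expect_gt(cor(-log10(ours$p_value), -log10(p_limma), method = "spearman"),
            0.95)
})

test_that("BH adjustment matches hand values and the quadratic reference", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.03), 0.03)
  expect_error(adjust_bh(c(0.1, NA)), "NA")
  expect_error(adjust_bh(c(0.1, 1.2)), "outside")

  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:1000, 1)
    p <- round(runif(n), sample(c(1, 2, 3, 6), 1))  # force ties sometimes
    expect_equal(adjust_bh(p), bh_reference(p))
  }
})

test_that("DEG gate uses exact log2(1.5) and both thresholds", {
  tox <- toy_expression(seed = 5, n_genes = 100, planted = 1:10, effect = 1.2)
  res <- call_degs(tox$values, tox$meta, "drugA")
  expect_s3_class(res, "deg_result")
  # gate is exactly reproducible from the columns
  expect_equal(res$is_deg,
               abs(res$log2fc) >= log2(1.5) & res$fdr_q < 0.05)
  # a gene passing FDR but with |log2fc| = 0.5 < log2(1.5) is not a DEG
  expect_false(any(res$is_deg & abs(res$log2fc) < log2(1.5)))
  g <- glance(res)
  expect_equal(g$compound, "drugA")
  expect_equal(g$n_deg, sum(res$is_deg))
  expect_equal(nrow(tidy(res)), 100)
})

test_that("50 strong planted effects are nearly all recovered", {
  tox <- toy_expression(seed = 8, n_genes = 300, planted = 1:50,
                        effect = 1.2, noise_sd = 0.25)
  res <- call_degs(tox$values, tox$meta, "drugA")
  recovered <- sum(res$is_deg[1:50])
  expect_gte(recovered, 45)
})

test_that("DEG calling is invariant to gene and sample order", {
  tox <- toy_expression(seed = 13, n_genes = 60, planted = 1:6, effect = 1.5)
  res <- call_degs(tox$values, tox$meta, "drugA")
  gperm <- sample(nrow(tox$values))
  sperm <- sample(ncol(tox$values))
  res2 <- call_degs(tox$values[gperm, sperm], tox$meta[sample(6), ], "drugA")
  merged <- merge(tidy(res), tidy(res2), by = "entrez_id")
  expect_equal(merged$log2fc.x, merged$log2fc.y)
  expect_equal(merged$is_deg.x, merged$is_deg.y)
})

test_that("group union merges DEG sets and counts overlaps", {
  mk <- function(ids, deg) tibble::tibble(entrez_id = ids, is_deg = deg)
  tabs <- list(c1 = mk(1:4, c(TRUE, TRUE, FALSE, FALSE)),
               c2 = mk(1:4, c(FALSE, TRUE, TRUE, FALSE)),
               c3 = mk(1:4, c(FALSE, FALSE, FALSE, TRUE)))
  groups <- c(c1 = "g1", c2 = "g1", c3 = "g2")
  u <- union_group_degs(tabs, groups)
  expect_setequal(u$group_degs$g1, c(1L, 2L, 3L))
  expect_setequal(u$group_degs$g2, 4L)
  expect_setequal(u$all_degs, 1:4)
  expect_equal(u$counts$n_compounds[u$counts$entrez_id == 2 &
                                      u$counts$group == "g1"], 2L)
  expect_error(union_group_degs(tabs, groups[-3]), "without a group")

  # brute-force union on random sets
  set.seed(77)
  for (i in 1:30) {
    sets <- lapply(1:10, function(j) sample(1:50, sample(0:20, 1)))
    names(sets) <- paste0("cmp", 1:10)
    tabs <- lapply(sets, function(s) mk(1:50, 1:50 %in% s))
    groups <- stats::setNames(rep(c("a", "b"), each = 5), names(sets))
    u <- union_group_degs(tabs, groups)
    expect_setequal(u$all_degs, Reduce(union, sets))
    expect_lte(length(u$all_degs), sum(lengths(sets)))
  }
})
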
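#' Map per-compound dark genes to regulators or pathway signatures
#'
#' A regulator (transcription factor or pathway signature) is "mapped" for a
#' compound when its target/signature set intersects that compound's dark
#' genes — membership, not a statistical over-representation test. An
#' optional hypergeometric over-representation mode is available for
#' exploratory filtering.
#'
#' @param dark_genes_by_compound Named list: compound label -> vector of dark
#'   Entrez IDs (typically dark DEGs of that compound).
#' @param reg_table Data frame with a regulator column and a target column:
#'   a TF-regulon table (`tf`, `target`, optional `grade`) or a
#'   pathway-signature table (`pathway`, `gene`).
#' @param regulator_col,target_col Column names.
#' @param grades Optional confidence grades to keep (requires a `grade`
#'   column); `NULL` keeps all rows.
#' @param overrepresentation If `TRUE`, additionally require a hypergeometric
#'   over-representation p-value below `or_alpha`, with the union of all dark
#'   genes as background. Off by default.
#' @param or_alpha Significance level for the over-representation mode.
#' @return A tibble of class `compound_mapping`: one row per compound with
#'   `compound`, `n_dark`, list-columns `regulators` and `mapped_genes`, and
#'   counts `n_regulators`, `n_mapped`. `n_regulators` is 0 exactly when
#'   `n_mapped` is 0.
#' @export
map_regulators <- function(dark_genes_by_compound, reg_table,
                           regulator_col = names(reg_table)[1],
                           target_col = names(reg_table)[2],
                           grades = NULL, overrepresentation = FALSE,
                           or_alpha = 0.05) {
  stopifnot(is.list(dark_genes_by_compound),
            !is.null(names(dark_genes_by_compound)),
            all(c(regulator_col, target_col) %in% names(reg_table)))
  if (!is.null(grades) && "grade" %in% names(reg_table)) {
    reg_table <- reg_table[reg_table$grade %in% grades, , drop = FALSE]
  }
  targets <- split(as.integer(reg_table[[target_col]]),
                   as.character(reg_table[[regulator_col]]))
  targets <- lapply(targets, unique)
  background <- unique(as.integer(unlist(dark_genes_by_compound)))

  rows <- purrr::imap_dfr(dark_genes_by_compound, function(dark, cmp) {
    dark <- unique(as.integer(dark))
    hit_n <- vapply(targets, function(tg) length(intersect(tg, dark)), integer(1))
    hit <- hit_n >= 1
    if (overrepresentation && length(dark) > 0) {
      # P[X >= k] for k dark targets among the regulator's targets present
      # in the background
      pvals <- vapply(names(targets), function(r) {
        tg_bg <- intersect(targets[[r]], background)
        k <- length(intersect(tg_bg, dark))
        stats::phyper(k - 1, length(dark), length(background) - length(dark),
                      length(tg_bg), lower.tail = FALSE)
      }, numeric(1))
      hit <- hit & pvals < or_alpha
    }
    regs <- sort(names(targets)[hit])
    mapped <- sort(unique(unlist(targets[regs])))
    mapped <- intersect(mapped, dark)
    tibble::tibble(
      compound = cmp, n_dark = length(dark),
      regulators = list(regs), mapped_genes = list(mapped),
      n_regulators = length(regs), n_mapped = length(mapped)
    )
  })
  class(rows) <- c("compound_mapping", class(rows))
  rows
}

#' Group-wise consensus of per-compound regulator sets
#'
#' Intersects the regulator sets mapped per compound. Under the `"strict"`
#' policy one empty set forces an empty consensus; `"exclude_empty"` drops
#' compounds with no mapped regulator before intersecting (the behaviour
#' needed when one compound has no hit at all, as happens for weakly active
#' compounds).
#'
#' @param mappings A [map_regulators()] result (or tibble with `compound` and
#'   list-column `regulators`), covering the compounds of one group.
#' @param empty_policy `"strict"` or `"exclude_empty"`.
#' @param group Optional group label recorded in the output.
#' @return A list of class `consensus_result`: `group`, `policy`,
#'   `per_compound` (named list of sets), `consensus` (character vector),
#'   `venn_regions` (tibble from [venn_region_counts()]; `NULL` when more
#'   than 6 compounds).
#' @export
consensus_sets <- function(mappings, empty_policy = c("strict", "exclude_empty"),
                           group = NA_character_) {
  empty_policy <- match.arg(empty_policy)
  stopifnot(nrow(mappings) >= 2)
  sets <- stats::setNames(lapply(mappings$regulators, as.character),
                          mappings$compound)
  use <- sets
  if (empty_policy == "exclude_empty") use <- use[lengths(use) > 0]
  if (length(use) == 0) {
    warning("all regulator sets empty; consensus is empty", call. = FALSE)
    consensus <- character(0)
  } else {
    consensus <- sort(Reduce(intersect, use))
  }
  venn <- if (length(sets) <= 6) venn_region_counts(sets) else NULL
  structure(
    list(group = group, policy = empty_policy, per_compound = sets,
         consensus = consensus, venn_regions = venn),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>", if (!is.na(x$group)) paste0(" group=", x$group),
      " policy=", x$policy, "\n", sep = "")
  cat("  consensus (", length(x$consensus), "): ",
      paste(x$consensus, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Venn region counts for 2-6 sets
#'
#' Partitions the union of the sets into disjoint regions indexed by the
#' subset of sets containing each element, and counts elements per non-empty
#' region. The region covered by all sets has exactly the size of the strict
#' intersection.
#'
#' @param sets Named list of 2-6 vectors.
#' @param labels Optional labels overriding `names(sets)`.
#' @return Tibble `region` (label names joined by `"&"`), `n_sets`, `count`,
#'   ordered by `n_sets` then region. Region counts sum to the union size.
#' @export
venn_region_counts <- function(sets, labels = names(sets)) {
  if (length(sets) < 2 || length(sets) > 6) {
    stop("venn_region_counts needs between 2 and 6 sets", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("set", seq_along(sets))
  universe <- unique(unlist(sets, use.names = FALSE))
  if (length(universe) == 0) {
    return(tibble::tibble(region = character(0), n_sets = integer(0),
                          count = integer(0)))
  }
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  sig <- apply(member, 1, function(row) paste(labels[row], collapse = "&"))
  tab <- table(sig)
  tibble::tibble(
    region = names(tab),
    n_sets = lengths(strsplit(names(tab), "&", fixed = TRUE)),
    count = as.integer(tab)
  ) |>
    dplyr::arrange(.data$n_sets, .data$region)
}
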
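#' Clean an interaction table into an interactome snapshot
#'
#' Edges are undirected: endpoint order is ignored, duplicates collapse to a
#' single edge, and self-loops are removed. When a predicted-interaction flag
#' column is named, flagged rows are dropped before cleaning. Participants
#' are resolved to Entrez IDs through the catalog when one is supplied; rows
#' with an unmappable participant are dropped with a warning. An optional
#' minimum-confidence filter is available for snapshots carrying scores.
#'
#' @param edges Data frame of interactions.
#' @param name Snapshot name (e.g. `"HIPPIE"`, `"IntAct"`).
#' @param a_col,b_col Participant column names.
#' @param predicted_col Optional name of a logical/0-1 column flagging
#'   predicted interactions to drop.
#' @param score_col,min_score Optional confidence-score filter (rows with
#'   score below `min_score` are dropped); off by default.
#' @param catalog Optional [gene_catalog()].
#' @return A list of class `interactome_snapshot` with `name`, `edges`
#'   (tibble with ordered integer columns `from` < `to`, one row per unordered
#'   pair) and `nodes` (union of edge endpoints).
#' @export
as_interactome <- function(edges, name, a_col = "gene_a", b_col = "gene_b",
                           predicted_col = NULL, score_col = NULL,
                           min_score = NULL, catalog = NULL) {
  stopifnot(is.data.frame(edges), all(c(a_col, b_col) %in% names(edges)))
  keep <- rep(TRUE, nrow(edges))
  if (!is.null(predicted_col) && predicted_col %in% names(edges)) {
    keep <- keep & !as.logical(edges[[predicted_col]])
  }
  if (!is.null(score_col) && !is.null(min_score) && score_col %in% names(edges)) {
    keep <- keep & edges[[score_col]] >= min_score
  }
  a <- as.character(edges[[a_col]][keep])
  b <- as.character(edges[[b_col]][keep])

  if (is.null(catalog)) {
    ia <- suppressWarnings(as.integer(a))
    ib <- suppressWarnings(as.integer(b))
  } else {
    mp <- map_to_entrez(unique(c(a, b)), catalog)
    lut <- stats::setNames(mp$entrez_id, mp$token)
    ia <- unname(lut[a]); ib <- unname(lut[b])
  }
  drop <- is.na(ia) | is.na(ib)
  if (any(drop)) {
    warning(sum(drop), " edge(s) with unmappable participants dropped in ",
            name, call. = FALSE)
  }
  ia <- ia[!drop]; ib <- ib[!drop]
  ed <- tibble::tibble(from = pmin(ia, ib), to = pmax(ia, ib))
  ed <- dplyr::distinct(dplyr::filter(ed, .data$from != .data$to))
  structure(
    list(name = name, edges = ed,
         nodes = sort(unique(c(ed$from, ed$to)))),
    class = "interactome_snapshot"
  )
}

#' @export
print.interactome_snapshot <- function(x, ...) {
  cat("<interactome_snapshot> ", x$name, ": ", nrow(x$edges), " edges, ",
      length(x$nodes), " nodes\n", sep = "")
  invisible(x)
}

#' Load an interactome snapshot from an edge-list TSV
#'
#' @param path Path to a headered TSV with two participant columns.
#' @inheritParams as_interactome
#' @inheritDotParams as_interactome -edges
#' @return An `interactome_snapshot`.
#' @export
load_edge_list <- function(path, name = basename(path), ...) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_interactome(tab, name = name, ...)
}

#' Per-snapshot degree profile of a gene set
#'
#' Degree is the count of distinct interaction partners within one snapshot.
#' A gene absent from a snapshot (no retained edge) gets no row for it, so
#' presence in a snapshot is equivalent to degree >= 1.
#'
#' @param genes Vector of Entrez IDs to profile.
#' @param snapshots List of `interactome_snapshot` objects.
#' @return A tibble of class `degree_table` in long form: `entrez_id`,
#'   `snapshot`, `degree`. The profiled gene set and snapshot names are kept
#'   as attributes.
#' @export
degree_profile <- function(genes, snapshots) {
  stopifnot(length(snapshots) >= 1,
            all(vapply(snapshots, inherits, logical(1), "interactome_snapshot")))
  genes <- unique(as.integer(genes))
  rows <- purrr::map_dfr(snapshots, function(sn) {
    long <- tibble::tibble(
      entrez_id = c(sn$edges$from, sn$edges$to),
      partner = c(sn$edges$to, sn$edges$from)
    )
    long |>
      dplyr::filter(.data$entrez_id %in% genes) |>
      dplyr::distinct() |>
      dplyr::count(.data$entrez_id, name = "degree") |>
      dplyr::mutate(snapshot = sn$name, .after = "entrez_id")
  })
  attr(rows, "genes") <- genes
  attr(rows, "snapshots") <- vapply(snapshots, `[[`, character(1), "name")
  class(rows) <- c("degree_table", class(rows))
  rows
}

#' Presence counts across interactome snapshots
#'
#' @param degree_table A [degree_profile()] result.
#' @param n_snapshots Number of snapshots profiled; defaults to the number
#'   recorded on the table.
#' @return A tibble with `n_genes` (profiled), `present_any` (degree >= 1 in
#'   at least one snapshot) and `present_all` (in every snapshot).
#' @export
presence_summary <- function(degree_table, n_snapshots = NULL) {
  if (is.null(n_snapshots)) {
    n_snapshots <- length(attr(degree_table, "snapshots"))
  }
  per_gene <- dplyr::count(degree_table, .data$entrez_id, name = "n_present")
  tibble::tibble(
    n_genes = length(attr(degree_table, "genes")),
    present_any = nrow(per_gene),
    present_all = sum(per_gene$n_present == n_snapshots)
  )
}

#' Top-connected genes across snapshots
#'
#' Ranks profiled genes by a statistic over their per-snapshot degrees
#' (maximum by default — "highly connected in at least one resource"); ties
#' break by ascending Entrez ID. Genes absent from a snapshot contribute
#' degree 0 to `sum` and `mean` and are shown as 0.
#'
#' @param degree_table A [degree_profile()] result.
#' @param k Number of genes to return; if larger than the number of profiled
#'   genes with any presence, all are returned.
#' @param rank_statistic `"max"`, `"sum"` or `"mean"` over snapshots.
#' @return A wide tibble: `entrez_id`, one degree column per snapshot,
#'   `rank_stat`, ordered by decreasing `rank_stat`.
#' @export
top_connected <- function(degree_table, k = 10,
                          rank_statistic = c("max", "sum", "mean")) {
  stopifnot(k >= 1)
  rank_statistic <- match.arg(rank_statistic)
  snaps <- attr(degree_table, "snapshots")
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(degree_table),
    names_from = "snapshot", values_from = "degree", values_fill = 0L
  )
  for (s in setdiff(snaps, names(wide))) wide[[s]] <- integer(nrow(wide))
  if (nrow(wide) == 0) {
    wide$rank_stat <- numeric(0)
    return(wide[, c("entrez_id", snaps, "rank_stat")])
  }
  deg_mat <- as.matrix(wide[, snaps, drop = FALSE])
  stat <- switch(rank_statistic,
                 max = apply(deg_mat, 1, max),
                 sum = rowSums(deg_mat),
                 mean = rowMeans(deg_mat))
  wide$rank_stat <- stat
  wide <- wide[order(-wide$rank_stat, wide$entrez_id), , drop = FALSE]
  utils::head(wide, k)
}

#' Degree histogram on log-spaced bins
#'
#' @param degree_table A [degree_profile()] result.
#' @param breaks Bin edges (degrees); default powers of 2 up to the maximum.
#' @return Tibble: `snapshot`, `bin` (factor label), `n`.
#' @export
degree_histogram <- function(degree_table, breaks = NULL) {
  if (is.null(breaks)) {
    kmax <- max(degree_table$degree)
    breaks <- unique(c(2^(0:ceiling(log2(max(kmax, 2)))), kmax + 1))
  }
  degree_table |>
    dplyr::mutate(bin = cut(.data$degree, breaks = c(0, breaks),
                            include.lowest = TRUE, right = FALSE)) |>
    dplyr::count(.data$snapshot, .data$bin, name = "n", .drop = FALSE)
}
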
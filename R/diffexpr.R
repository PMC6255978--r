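#' Differential-expression parameters
#'
#' Bundles the gates used to call differentially expressed genes (DEGs): an
#' absolute fold change of at least `fc_threshold` (on the natural scale; the
#' gate is applied as `|log2fc| >= log2(fc_threshold)`, using the exact
#' logarithm, not a rounded 0.585) together with a Benjamini-Hochberg
#' FDR below `fdr_alpha`.
#'
#' @param fc_threshold Fold-change threshold, > 1. Default 1.5.
#' @param fdr_alpha FDR level in (0, 1). Default 0.05.
#' @param test_method One of `"eb_moderated"` (pooled t after shrinking
#'   per-gene variances toward the grand mean variance with `prior_df` prior
#'   degrees of freedom; the default — with 3 replicates per arm an
#'   unmoderated t has far too little power), `"t_pooled"` (equal-variance
#'   two-sample t), or `"t_welch"`.
#' @param prior_df Prior degrees of freedom for `"eb_moderated"`. Default 4.
#' @return A list of class `deg_params`.
#' @export
deg_params <- function(fc_threshold = 1.5, fdr_alpha = 0.05,
                       test_method = c("eb_moderated", "t_pooled", "t_welch"),
                       prior_df = 4) {
  stopifnot(fc_threshold > 1, fdr_alpha > 0, fdr_alpha < 1, prior_df > 0)
  structure(
    list(fc_threshold = fc_threshold, fdr_alpha = fdr_alpha,
         test_method = match.arg(test_method), prior_df = prior_df),
    class = "deg_params"
  )
}

# sample columns for one compound stratum, split by role
stratum_samples <- function(sample_meta, compound) {
  m <- sample_meta[sample_meta$compound == compound, , drop = FALSE]
  treated <- m$sample_id[m$role == "treated"]
  control <- m$sample_id[m$role == "control"]
  if (length(control) == 0) {
    stop("no control samples for compound stratum '", compound, "'",
         call. = FALSE)
  }
  if (length(treated) == 0) {
    stop("no treated samples for compound stratum '", compound, "'",
         call. = FALSE)
  }
  list(treated = treated, control = control)
}

check_matrix <- function(values, sample_meta, arms) {
  miss <- setdiff(c(arms$treated, arms$control), colnames(values))
  if (length(miss) > 0) {
    stop("samples missing from expression matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Per-gene log2 fold change versus time-matched controls
#'
#' @param values Gene-by-sample matrix of log2 intensities with Entrez IDs as
#'   row names and sample IDs as column names.
#' @param sample_meta Data frame with columns `sample_id`, `compound`,
#'   `role` (`"treated"` or `"control"`), and optionally `dose_level`,
#'   `time_h`, `group`. Filter to one stratum (e.g. highest dose, 24 h)
#'   before calling; every row is used.
#' @param compound Compound label selecting the stratum.
#' @return A tibble with `entrez_id` and `log2fc` = mean(treated) −
#'   mean(control), in log2 units.
#' @export
compute_log2fc <- function(values, sample_meta, compound) {
  arms <- stratum_samples(sample_meta, compound)
  check_matrix(values, sample_meta, arms)
  t_mean <- rowMeans(values[, arms$treated, drop = FALSE])
  c_mean <- rowMeans(values[, arms$control, drop = FALSE])
  tibble::tibble(entrez_id = as.integer(rownames(values)),
                 log2fc = unname(t_mean - c_mean))
}

# vectorized two-sample t over matrix rows; returns two-sided p-values
row_t_test <- function(x_treat, x_ctrl, method = "t_pooled", prior_df = 4) {
  n1 <- ncol(x_treat); n2 <- ncol(x_ctrl)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per arm", call. = FALSE)
  m1 <- rowMeans(x_treat); m2 <- rowMeans(x_ctrl)
  v1 <- apply(x_treat, 1, stats::var); v2 <- apply(x_ctrl, 1, stats::var)
  dm <- m1 - m2

  if (method == "t_welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tt <- dm / sqrt(se2)
  } else {
    df <- n1 + n2 - 2
    s2 <- (v1 * (n1 - 1) + v2 * (n2 - 1)) / df
    if (method == "eb_moderated") {
      # shrink per-gene variances toward the grand mean variance
      s2_prior <- mean(s2)
      s2 <- (prior_df * s2_prior + df * s2) / (prior_df + df)
      df <- df + prior_df
    }
    tt <- dm / sqrt(s2 * (1 / n1 + 1 / n2))
  }

  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate rows: zero variance in both arms
  zero_var <- !is.finite(tt)
  p[zero_var & dm == 0] <- 1
  p[zero_var & dm != 0] <- 0
  unname(p)
}

#' Two-sided per-gene differential-expression p-values
#'
#' Compares treated to time-matched control samples of one compound stratum
#' with a two-sample t statistic. `"eb_moderated"` shrinks per-gene variances
#' toward the grand mean variance with a fixed prior degrees of freedom before
#' forming the statistic. Rows with zero variance in both arms and equal means
#' get p = 1 by the no-signal convention.
#'
#' @inheritParams compute_log2fc
#' @param method Test statistic; see [deg_params()].
#' @param prior_df Prior degrees of freedom for `"eb_moderated"`.
#' @return A tibble with `entrez_id` and `p_value`.
#' @export
test_differential <- function(values, sample_meta, compound,
                              method = c("eb_moderated", "t_pooled", "t_welch"),
                              prior_df = 4) {
  method <- match.arg(method)
  arms <- stratum_samples(sample_meta, compound)
  check_matrix(values, sample_meta, arms)
  p <- row_t_test(values[, arms$treated, drop = FALSE],
                  values[, arms$control, drop = FALSE],
                  method = method, prior_df = prior_df)
  tibble::tibble(entrez_id = as.integer(rownames(values)), p_value = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]. `NA`/`NaN` input is
#'   an error.
#' @return Adjusted q-values, capped at 1.
#' @export
adjust_bh <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values)) stop("p_values contain NA/NaN", call. = FALSE)
  if (any(p_values < 0 | p_values > 1)) {
    stop("p_values outside [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes for one compound
#'
#' A gene is a DEG when `|log2fc| >= log2(fc_threshold)` (exact logarithm)
#' and its BH-adjusted q-value is below `fdr_alpha`.
#'
#' @inheritParams compute_log2fc
#' @param params A [deg_params()] object.
#' @return A tibble of class `deg_result` with columns `entrez_id`, `log2fc`,
#'   `p_value`, `fdr_q`, `is_deg`; the compound label and parameters are kept
#'   as attributes and surfaced by [generics::glance()].
#' @examples
#' set.seed(1)
#' vals <- matrix(rnorm(60, 7, 0.3), nrow = 10,
#'                dimnames = list(1:10, paste0("s", 1:6)))
#' vals[1, 1:3] <- vals[1, 1:3] + 2
#' meta <- tibble::tibble(sample_id = paste0("s", 1:6), compound = "drugA",
#'                        role = rep(c("treated", "control"), each = 3))
#' call_degs(vals, meta, "drugA")
#' @export
call_degs <- function(values, sample_meta, compound, params = deg_params()) {
  stopifnot(inherits(params, "deg_params"))
  fc <- compute_log2fc(values, sample_meta, compound)
  pv <- test_differential(values, sample_meta, compound,
                          method = params$test_method,
                          prior_df = params$prior_df)
  out <- dplyr::mutate(
    dplyr::left_join(fc, pv, by = "entrez_id"),
    fdr_q = adjust_bh(.data$p_value),
    is_deg = abs(.data$log2fc) >= log2(params$fc_threshold) &
      .data$fdr_q < params$fdr_alpha
  )
  attr(out, "compound") <- compound
  attr(out, "params") <- params
  class(out) <- c("deg_result", class(out))
  out
}

#' @export
tidy.deg_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "deg_result")
  attr(out, "compound") <- NULL
  attr(out, "params") <- NULL
  out
}

#' @export
glance.deg_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    compound = attr(x, "compound"),
    n_genes = nrow(x),
    n_deg = sum(x$is_deg),
    fc_threshold = p$fc_threshold,
    fdr_alpha = p$fdr_alpha,
    test_method = p$test_method
  )
}

#' Merge per-compound DEG calls group-wise
#'
#' @param deg_tables Named list of [call_degs()] results (or tibbles with
#'   `entrez_id` and `is_deg`), one per compound.
#' @param groups Named character vector mapping each compound label to its
#'   group (e.g. `"most_dili"` / `"no_dili"`). Every compound in `deg_tables`
#'   must be present.
#' @return A list with `group_degs` (named list of per-group DEG union
#'   vectors), `all_degs` (overall unique union), `counts` (tibble with one
#'   row per gene: `entrez_id`, `group`, `n_compounds` in which it is a DEG),
#'   and `per_compound` (tibble of per-compound DEG counts).
#' @export
union_group_degs <- function(deg_tables, groups) {
  stopifnot(is.list(deg_tables), length(deg_tables) >= 1)
  miss <- setdiff(names(deg_tables), names(groups))
  if (length(miss) > 0) {
    stop("compound(s) without a group label: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  deg_sets <- purrr::map(deg_tables, ~ .x$entrez_id[.x$is_deg])
  long <- purrr::imap_dfr(deg_sets, function(g, cmp) {
    tibble::tibble(compound = cmp, group = unname(groups[[cmp]]),
                   entrez_id = g)
  })
  group_degs <- long |>
    dplyr::distinct(.data$group, .data$entrez_id) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(genes = list(sort(.data$entrez_id)), .groups = "drop")
  group_degs <- stats::setNames(group_degs$genes, group_degs$group)

  counts <- long |>
    dplyr::count(.data$group, .data$entrez_id, name = "n_compounds")

  list(
    group_degs = group_degs,
    all_degs = sort(unique(long$entrez_id)),
    counts = counts,
    per_compound = tibble::tibble(
      compound = names(deg_sets),
      group = unname(groups[names(deg_sets)]),
      n_deg = lengths(deg_sets)
    )
  )
}
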
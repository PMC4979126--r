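#' Gene-centric Benford MAE scoring
#'
#' For every gene, the first-digit distribution of its expression values
#' across all samples (or cells) is tabulated and its mean absolute error
#' from the Benford expectation is computed. This is the mode used to rank
#' individual genes by Benford adherence; it needs many samples per gene to
#' be informative (on the order of a thousand), so a warning is emitted when
#' fewer than 50 usable digits back a score.
#'
#' @param m An `ExpressionMatrix` on any non-log metric.
#' @param exclude_below_one Drop values in (0, 1) before digit extraction
#'   (appropriate for CPM-like metrics where sub-unity values mark
#'   near-absent expression). Default `FALSE`.
#' @param min_used Minimum number of usable (digit-bearing) values a gene
#'   needs to receive a score; genes below it are omitted from the table and
#'   recorded in the `"omitted"` attribute. Default 1.
#' @return A `mae_table` data frame (one row per gene) with columns
#'   `gene_id`, `mae`, `n_used`, `d1`..`d9` (observed digit frequencies) and
#'   `mean_expression` (mean across samples on the matrix's metric scale).
#'   Attributes: `mode = "gene_centric"`, `metric`, `omitted`.
#' @export
gene_centric_mae <- function(m, exclude_below_one = FALSE, min_used = 1L) {
  .assert_expression_matrix(m)
  .refuse_log2(m, "Gene-centric Benford scoring")
  if (ncol(m$values) < 1L) stop("at least one sample is required", call. = FALSE)
  if (min_used < 1L) stop("`min_used` must be >= 1", call. = FALSE)

  counts <- .digit_counts_by_row(m$values, exclude_below_one)
  n_used <- rowSums(counts)
  keep <- n_used >= min_used
  omitted <- rownames(m$values)[!keep]
  if (length(omitted) > 0L) {
    message(length(omitted), " gene(s) omitted with fewer than ", min_used,
            " usable value(s)")
  }
  freqs <- counts[keep, , drop = FALSE] / n_used[keep]
  ref <- benford_expected()
  mae <- rowMeans(abs(sweep(freqs, 2, ref)))
  tab <- data.frame(
    gene_id = rownames(m$values)[keep],
    mae = unname(mae),
    n_used = unname(n_used[keep]),
    stats::setNames(as.data.frame(freqs), paste0("d", 1:9)),
    mean_expression = unname(rowMeans(m$values)[keep]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(tab, mode = "gene_centric", metric = m$metric, omitted = omitted,
            class = c("mae_table", "data.frame"))
}

#' Individual-centric Benford MAE scoring
#'
#' For each sample (individual), the values of every gene category are
#' pooled into one first-digit distribution, yielding one MAE per
#' (sample, category) pair — e.g. three MAE values per individual for
#' housekeeping, tissue-specific and random gene sets. A category with no
#' usable values in a sample keeps its row with `mae = NA` and is counted in
#' the `"undefined"` attribute rather than being dropped silently.
#'
#' @param m An `ExpressionMatrix` on any non-log metric.
#' @param labels Data frame with columns `gene_id` and `category` (see
#'   [read_gene_labels()]); every category must overlap the matrix's genes.
#' @param exclude_below_one As in [gene_centric_mae()].
#' @return A `mae_table` data frame with columns `sample_id`, `category`,
#'   `mae`, `n_used`, `d1`..`d9`; attribute `mode = "individual_centric"`.
#' @export
individual_centric_mae <- function(m, labels, exclude_below_one = FALSE) {
  .assert_expression_matrix(m)
  .refuse_log2(m, "Individual-centric Benford scoring")
  labels <- .check_labels(labels)
  cats <- unique(labels$category)
  ref <- benford_expected()
  rows <- vector("list", length(cats))
  for (ci in seq_along(cats)) {
    ids <- intersect(labels$gene_id[labels$category == cats[ci]], rownames(m$values))
    if (length(ids) == 0L) {
      stop("category '", cats[ci], "' shares no genes with the matrix", call. = FALSE)
    }
    sub <- m$values[ids, , drop = FALSE]
    counts <- .digit_counts_by_col(sub, exclude_below_one)
    n_used <- colSums(counts)
    freqs <- matrix(NA_real_, ncol(sub), 9)
    ok <- n_used > 0L
    freqs[ok, ] <- counts[, ok, drop = FALSE] |> t() |> sweep(1, n_used[ok], "/")
    mae <- ifelse(ok, rowMeans(abs(sweep(freqs, 2, ref))), NA_real_)
    rows[[ci]] <- data.frame(
      sample_id = colnames(m$values), category = cats[ci],
      mae = mae, n_used = unname(n_used),
      stats::setNames(as.data.frame(freqs), paste0("d", 1:9)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(match(tab$sample_id, colnames(m$values)), match(tab$category, cats)), ]
  rownames(tab) <- NULL
  n_undef <- sum(is.na(tab$mae))
  if (n_undef > 0L) {
    warning(n_undef, " (sample, category) pair(s) have no usable values; mae set to NA",
            call. = FALSE)
  }
  structure(tab, mode = "individual_centric", metric = m$metric,
            undefined = n_undef, class = c("mae_table", "data.frame"))
}

#' Rank genes by MAE and select the extremes
#'
#' Genes are sorted by ascending MAE with ties broken by gene identifier, so
#' the selection is deterministic across runs. Up to `n_top` best-adhering
#' (lowest MAE) and `n_bottom` least-adhering (highest MAE) genes are
#' returned; when the table holds fewer than `n_top + n_bottom` genes the
#' two lists overlap and a warning says so.
#'
#' @param tab A gene-centric `mae_table`.
#' @param n_top,n_bottom Number of genes to take from each end; default 300.
#' @return A list with character vectors `lowest_mae` and `highest_mae`.
#' @export
rank_and_select <- function(tab, n_top = 300L, n_bottom = 300L) {
  .assert_gene_centric(tab)
  if (nrow(tab) == 0L) stop("empty MAE table", call. = FALSE)
  if (n_top <= 0L || n_bottom <= 0L) stop("`n_top` and `n_bottom` must be positive", call. = FALSE)
  asc <- tab[order(tab$mae, tab$gene_id), ]
  lowest <- utils::head(asc$gene_id, min(n_top, nrow(tab)))
  desc <- tab[order(-tab$mae, tab$gene_id), ]
  highest <- utils::head(desc$gene_id, min(n_bottom, nrow(tab)))
  if (nrow(tab) < n_top + n_bottom) {
    warning("table has ", nrow(tab), " genes, fewer than n_top + n_bottom = ",
            n_top + n_bottom, "; the selections overlap", call. = FALSE)
  }
  list(lowest_mae = lowest, highest_mae = highest)
}

#' Select genes by MAE and mean-expression thresholds
#'
#' Strict-inequality filters applied conjunctively, matching cutoff idioms
#' such as "MAE < 0.065" or "mean log2 CPM > 8 and MAE > 0.04". At least one
#' bound must be supplied. `mean_expr_*` bounds act on the table's
#' `mean_expression` column, i.e. on whatever metric scale the table was
#' scored on — convert (e.g. to log2 CPM) before scoring if cutoffs are
#' quoted on another scale.
#'
#' @param tab A gene-centric `mae_table`.
#' @param mae_below,mae_above,mean_expr_below,mean_expr_above Optional
#'   numeric bounds (strict `<` / `>`).
#' @return Character vector of gene identifiers satisfying all bounds
#'   (possibly empty).
#' @export
threshold_select <- function(tab, mae_below = NULL, mae_above = NULL,
                             mean_expr_below = NULL, mean_expr_above = NULL) {
  .assert_gene_centric(tab)
  bounds <- list(mae_below = mae_below, mae_above = mae_above,
                 mean_expr_below = mean_expr_below, mean_expr_above = mean_expr_above)
  if (all(vapply(bounds, is.null, logical(1)))) {
    stop("supply at least one threshold", call. = FALSE)
  }
  if (!is.null(mae_above) && !is.null(mae_below) && mae_above >= mae_below) {
    stop("contradictory MAE bounds: mae_above >= mae_below", call. = FALSE)
  }
  if (!is.null(mean_expr_above) && !is.null(mean_expr_below) &&
      mean_expr_above >= mean_expr_below) {
    stop("contradictory mean-expression bounds", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(mae_below)) keep <- keep & tab$mae < mae_below
  if (!is.null(mae_above)) keep <- keep & tab$mae > mae_above
  if (!is.null(mean_expr_below)) keep <- keep & tab$mean_expression < mean_expr_below
  if (!is.null(mean_expr_above)) keep <- keep & tab$mean_expression > mean_expr_above
  tab$gene_id[keep]
}

# Per-row (gene) digit counts across all columns, vectorized through a single
# tabulate over (row, digit) cells; zeros (and optionally values below 1)
# never contribute a digit.
.digit_counts_by_row <- function(v, exclude_below_one) {
  use <- if (exclude_below_one) v >= 1 else v > 0
  idx <- which(use)
  d <- first_digit(v[idx])
  g <- ((idx - 1L) %% nrow(v)) + 1L
  matrix(tabulate(g + (d - 1L) * nrow(v), nbins = 9L * nrow(v)),
         nrow = nrow(v), ncol = 9L, dimnames = list(rownames(v), as.character(1:9)))
}

# Per-column (sample) digit counts across all rows; returns 9 x n_samples.
.digit_counts_by_col <- function(v, exclude_below_one) {
  use <- if (exclude_below_one) v >= 1 else v > 0
  idx <- which(use)
  d <- first_digit(v[idx])
  s <- ((idx - 1L) %/% nrow(v)) + 1L
  matrix(tabulate(d + (s - 1L) * 9L, nbins = 9L * ncol(v)),
         nrow = 9L, ncol = ncol(v), dimnames = list(as.character(1:9), colnames(v)))
}

.check_labels <- function(labels) {
  if (!is.data.frame(labels) || !all(c("gene_id", "category") %in% names(labels))) {
    stop("`labels` must be a data frame with columns gene_id and category", call. = FALSE)
  }
  if (anyDuplicated(labels$gene_id)) stop("duplicate gene ids in labels", call. = FALSE)
  labels$gene_id <- as.character(labels$gene_id)
  labels$category <- as.character(labels$category)
  labels
}

.assert_gene_centric <- function(tab) {
  if (!inherits(tab, "mae_table") || !identical(attr(tab, "mode"), "gene_centric")) {
    stop("expected a gene-centric mae_table", call. = FALSE)
  }
  invisible(tab)
}
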
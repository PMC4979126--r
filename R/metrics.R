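#' Counts per million (CPM)
#'
#' Scales each sample's raw counts to a library size of one million:
#' \eqn{CPM_{gs} = 10^6 \, c_{gs} / \sum_g c_{gs}}.
#'
#' @param m An `ExpressionMatrix` with `metric = "raw"`.
#' @return An `ExpressionMatrix` with `metric = "cpm"`; every column sums to
#'   1e6.
#' @export
cpm <- function(m) {
  .assert_expression_matrix(m)
  if (m$metric != "raw") stop("cpm() expects raw counts, got metric '", m$metric, "'", call. = FALSE)
  lib <- colSums(m$values)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m$values)[lib == 0], collapse = ", "), call. = FALSE)
  }
  ExpressionMatrix(sweep(m$values, 2, lib, "/") * 1e6, metric = "cpm")
}

#' Reads per kilobase per million (RPKM)
#'
#' Length-normalized expression:
#' \eqn{RPKM_{gs} = 10^9 \, c_{gs} / (L_g \sum_g c_{gs})} with \eqn{L_g} the
#' gene length in base pairs.
#'
#' @param m An `ExpressionMatrix` with `metric = "raw"`.
#' @param lengths Named numeric vector of positive gene lengths (bp) covering
#'   every gene in `m` (see [read_gene_lengths()]).
#' @return An `ExpressionMatrix` with `metric = "rpkm"`.
#' @export
rpkm <- function(m, lengths) {
  .assert_expression_matrix(m)
  if (m$metric != "raw") stop("rpkm() expects raw counts, got metric '", m$metric, "'", call. = FALSE)
  len <- .match_lengths(m, lengths)
  lib <- colSums(m$values)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m$values)[lib == 0], collapse = ", "), call. = FALSE)
  }
  v <- m$values * 1e9 / outer(len, lib)
  ExpressionMatrix(v, metric = "rpkm")
}

#' Transcripts per million (TPM)
#'
#' Length-rate renormalization: per-gene read rates \eqn{c_{gs}/L_g} are
#' rescaled within each sample to sum to one million, so TPM columns are
#' directly comparable across samples.
#'
#' @inheritParams rpkm
#' @return An `ExpressionMatrix` with `metric = "tpm"`; every column sums to
#'   1e6.
#' @export
tpm <- function(m, lengths) {
  .assert_expression_matrix(m)
  if (m$metric != "raw") stop("tpm() expects raw counts, got metric '", m$metric, "'", call. = FALSE)
  len <- .match_lengths(m, lengths)
  rate <- m$values / len
  denom <- colSums(rate)
  if (any(denom == 0)) {
    stop("zero total rate in sample(s): ",
         paste(colnames(m$values)[denom == 0], collapse = ", "), call. = FALSE)
  }
  ExpressionMatrix(sweep(rate, 2, denom, "/") * 1e6, metric = "tpm")
}

.match_lengths <- function(m, lengths) {
  if (is.null(names(lengths))) stop("`lengths` must be named by gene id", call. = FALSE)
  ids <- rownames(m$values)
  missing <- setdiff(ids, names(lengths))
  if (length(missing) > 0L) {
    stop("no length for gene(s): ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5), call. = FALSE)
  }
  len <- as.numeric(lengths[ids])
  bad <- !is.finite(len) | len <= 0
  if (any(bad)) {
    stop("non-positive length for gene(s): ", paste(ids[bad][1:min(5, sum(bad))], collapse = ", "),
         call. = FALSE)
  }
  len
}

#' Log2 transform of an expression matrix
#'
#' Computes `log2(value + offset)` and tags the result `log2`. Benford
#' scoring refuses such matrices by design — log-scaled expression does not
#' follow the first-digit law, so the tag acts as a guard.
#'
#' @param m An `ExpressionMatrix` on any non-log metric.
#' @param offset Positive pseudocount added before the log; default 1, so
#'   zero expression maps to zero.
#' @return An `ExpressionMatrix` with `metric = "log2"`.
#' @export
log2_transform <- function(m, offset = 1) {
  .assert_expression_matrix(m)
  if (m$metric == "log2") stop("matrix is already log2-transformed", call. = FALSE)
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset) || offset <= 0) {
    stop("`offset` must be a single positive number", call. = FALSE)
  }
  ExpressionMatrix(log2(m$values + offset), metric = "log2")
}

#' Expressed-gene filter by mean CPM rank
#'
#' Unexpressed genes inherently deviate from the Benford law (their digit
#' distributions are empty or dominated by noise), so genes are retained only
#' if their mean CPM across all samples falls in the top `top_fraction` of
#' per-gene means. The cutoff is the `ceiling(top_fraction * n)`-th largest
#' mean (an order statistic, so the rule is deterministic), and genes exactly
#' at the cutoff are included — ties expand the set.
#'
#' @param m An `ExpressionMatrix` with `metric = "cpm"`.
#' @param top_fraction Fraction of genes to keep, in (0, 1\]; default 0.4.
#' @return Character vector of retained gene identifiers, in matrix order.
#' @export
expressed_genes <- function(m, top_fraction = 0.4) {
  .assert_expression_matrix(m)
  if (m$metric != "cpm") {
    stop("expressed_genes() expects CPM values, got metric '", m$metric, "'", call. = FALSE)
  }
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction > 1) {
    stop("`top_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (nrow(m$values) == 0L || ncol(m$values) == 0L) stop("empty expression matrix", call. = FALSE)
  means <- rowMeans(m$values)
  k <- ceiling(top_fraction * length(means))
  cutoff <- sort(means, decreasing = TRUE)[k]
  rownames(m$values)[means >= cutoff]
}
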
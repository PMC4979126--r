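#' Expression matrix with a metric tag
#'
#' A light container for gene-by-sample expression values. The `metric` tag
#' records what the numbers are (`raw` counts, `cpm`, `rpkm`, `tpm`, or
#' `log2`-transformed), and downstream Benford scoring refuses `log2`
#' matrices: log-transformed expression no longer spans orders of magnitude
#' multiplicatively, so its leading digits are uninformative and scoring them
#' silently would be a correctness trap.
#'
#' @param values Numeric matrix (genes in rows, samples in columns), finite,
#'   and non-negative unless `metric = "log2"`.
#' @param gene_ids,sample_ids Unique identifier vectors; default to the
#'   dimnames of `values`.
#' @param metric One of `"raw"`, `"cpm"`, `"rpkm"`, `"tpm"`, `"log2"`.
#' @return An object of class `ExpressionMatrix` with elements `values`
#'   (dimnamed matrix) and `metric`.
#' @examples
#' m <- ExpressionMatrix(matrix(1:6, 3, dimnames = list(paste0("g", 1:3), c("s1", "s2"))),
#'                       metric = "raw")
#' dim(m)
#' @export
ExpressionMatrix <- function(values,
                             gene_ids = rownames(values),
                             sample_ids = colnames(values),
                             metric = c("raw", "cpm", "rpkm", "tpm", "log2")) {
  metric <- match.arg(metric)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required (set dimnames or pass them)", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths must match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample identifiers must be unique", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  if (metric != "log2" && any(values < 0)) {
    stop("negative values are not valid for metric '", metric, "'", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, metric = metric), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, metric = %s\n",
              nrow(x$values), ncol(x$values), x$metric))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' Subset an ExpressionMatrix by gene and/or sample
#'
#' @param x An `ExpressionMatrix`.
#' @param i,j Gene and sample indices (integer, logical or identifier).
#' @param ... Ignored.
#' @return An `ExpressionMatrix` with the same metric.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  ExpressionMatrix(v, metric = x$metric)
}

#' Gene identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector.
#' @export
sample_ids <- function(x) colnames(x$values)

.assert_expression_matrix <- function(m) {
  if (!inherits(m, "ExpressionMatrix")) {
    stop("expected an ExpressionMatrix", call. = FALSE)
  }
  invisible(m)
}

.refuse_log2 <- function(m, what) {
  if (m$metric == "log2") {
    stop(what, " is undefined for log2-transformed expression: the log ",
         "transform destroys the multiplicative spread the first-digit law ",
         "relies on. Score the untransformed matrix instead.", call. = FALSE)
  }
  invisible(m)
}
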
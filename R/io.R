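#' Read an expression matrix from delimited text or MatrixMarket files
#'
#' Dense tables (`.tsv`/`.csv`, delimiter auto-detected from the extension)
#' carry gene identifiers in the first column and sample identifiers in the
#' header row. Sparse MatrixMarket triplets (`.mtx`) follow the Drop-seq
#' distribution convention: gene and sample (barcode) identifiers come from
#' sidecar files with one identifier per line.
#'
#' @param path Path to a `.tsv`, `.csv` or `.mtx` file.
#' @param metric Metric tag for the values (see [ExpressionMatrix()]).
#' @param gene_file,sample_file Sidecar identifier files; required for
#'   `.mtx` input, ignored otherwise. Default to `<path>.genes.txt` and
#'   `<path>.samples.txt` next to the matrix.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path,
                            metric = c("raw", "cpm", "rpkm", "tpm", "log2"),
                            gene_file = NULL, sample_file = NULL) {
  metric <- match.arg(metric)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    if (is.null(gene_file)) gene_file <- paste0(path, ".genes.txt")
    if (is.null(sample_file)) sample_file <- paste0(path, ".samples.txt")
    for (f in c(gene_file, sample_file)) {
      if (!file.exists(f)) stop("missing identifier sidecar file: ", f, call. = FALSE)
    }
    v <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    samples <- readLines(sample_file)
    if (length(genes) != nrow(v) || length(samples) != ncol(v)) {
      stop("sidecar identifier counts do not match matrix dimensions in ", path, call. = FALSE)
    }
    return(ExpressionMatrix(v, genes, samples, metric = metric))
  }
  sep <- switch(ext, tsv = "\t", txt = "\t", csv = ",",
                stop("unrecognized extension '.", ext, "' (use .tsv, .csv or .mtx)", call. = FALSE))
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, comment.char = "")
  ExpressionMatrix(as.matrix(tab), metric = metric)
}

#' Write an expression matrix to delimited text or MatrixMarket files
#'
#' The inverse of [read_expression()]; the format is chosen by the output
#' extension. Metric tags are not stored in the file — record them in a run
#' manifest or pass them when reading back.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path ending in `.tsv`, `.csv` or `.mtx`. For `.mtx`,
#'   sidecar identifier files `<path>.genes.txt` and `<path>.samples.txt` are
#'   written next to the matrix.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  .assert_expression_matrix(m)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(rownames(m$values), paste0(path, ".genes.txt"))
    writeLines(colnames(m$values), paste0(path, ".samples.txt"))
    return(invisible(path))
  }
  sep <- switch(ext, tsv = "\t", csv = ",",
                stop("unrecognized extension '.", ext, "' (use .tsv, .csv or .mtx)", call. = FALSE))
  tab <- data.frame(gene_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-length table
#'
#' Two delimited columns: gene identifier and length in base pairs.
#'
#' @param path Path to a `.tsv`/`.csv` file (header optional, detected from
#'   a non-numeric second field in the first line).
#' @return Named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  tab <- .read_two_column(path, c("gene_id", "length"))
  len <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(len)) stop("non-numeric gene length in ", path, call. = FALSE)
  stats::setNames(len, tab[[1]])
}

#' Read gene-category labels
#'
#' Two delimited columns: gene identifier and category (e.g. `housekeeping`,
#' `tissue_specific`, `random`). Each gene may appear once.
#'
#' @param path Path to a `.tsv`/`.csv` file.
#' @return A data frame with columns `gene_id` and `category`.
#' @export
read_gene_labels <- function(path) {
  tab <- .read_two_column(path, c("gene_id", "category"))
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene identifiers in label file ", path, call. = FALSE)
  }
  tab
}

.read_two_column <- function(path, col_names) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  header <- length(first) >= 2 && identical(tolower(first[1:2]), tolower(col_names))
  tab <- utils::read.table(path, header = header, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2) stop("expected two columns in ", path, call. = FALSE)
  stats::setNames(tab[, 1:2], col_names)
}

#' Write or read a MAE score table
#'
#' Tab-separated serialization of the tables produced by
#' [gene_centric_mae()] and [individual_centric_mae()]: identifier
#' column(s), `mae`, `n_used`, the nine digit-frequency columns `d1`..`d9`,
#' and `mean_expression` (gene-centric only). The calculation mode and
#' metric travel in a `# mode=` comment line so a round trip restores them.
#'
#' @param tab A `mae_table` data frame.
#' @param path Output `.tsv` path.
#' @return `path` invisibly (write); a `mae_table` data frame (read).
#' @export
write_mae_table <- function(tab, path) {
  if (!inherits(tab, "mae_table")) stop("expected a mae_table", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s metric=%s", attr(tab, "mode"), attr(tab, "metric")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mae_table
#' @export
read_mae_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- readLines(path, n = 1)
  mode <- sub(".*mode=(\\S+).*", "\\1", meta)
  metric <- sub(".*metric=(\\S+).*", "\\1", meta)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                           stringsAsFactors = FALSE, comment.char = "")
  structure(tab, mode = mode, metric = metric, class = c("mae_table", "data.frame"))
}
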
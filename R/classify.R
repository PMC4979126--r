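#' Build Benford feature vectors from a gene-centric MAE table
#'
#' Each gene is represented by a 10-dimensional feature vector: its nine
#' observed first-digit frequencies followed by its MAE score. All
#' components lie in \[0, 1\] (MAE is bounded by 2/9), so the features are
#' commensurate and are used unscaled by default downstream.
#'
#' @param tab A gene-centric `mae_table`.
#' @param labels Optional data frame (`gene_id`, `category`); genes present
#'   in the labels get a `label`, others stay `NA` (unlabeled).
#' @return A `feature_table` data frame with columns `gene_id`, `d1`..`d9`,
#'   `mae` and `label`. Genes with undefined frequencies are excluded and
#'   reported via the `"excluded"` attribute.
#' @export
build_features <- function(tab, labels = NULL) {
  .assert_gene_centric(tab)
  freq_cols <- paste0("d", 1:9)
  ok <- stats::complete.cases(tab[, c(freq_cols, "mae")])
  excluded <- tab$gene_id[!ok]
  if (length(excluded) > 0L) {
    message(length(excluded), " gene(s) with undefined frequencies excluded from features")
  }
  f <- tab[ok, c("gene_id", freq_cols, "mae")]
  f$label <- NA_character_
  if (!is.null(labels)) {
    labels <- .check_labels(labels)
    f$label <- labels$category[match(f$gene_id, labels$gene_id)]
  }
  rownames(f) <- NULL
  structure(f, excluded = excluded, class = c("feature_table", "data.frame"))
}

#' Classical multidimensional scaling of Benford features
#'
#' Embeds genes into `dims` coordinates by classical (Torgerson) metric MDS
#' on pairwise Euclidean distances between feature vectors, via
#' [stats::cmdscale()]. Coordinates are centered (column means zero) and are
#' determined only up to sign and rotation; distances, not coordinates, are
#' the meaningful output.
#'
#' @param f A `feature_table`.
#' @param dims Number of embedding dimensions, default 2.
#' @return Numeric matrix (genes x dims) with gene identifiers as row names.
#' @export
mds_embed <- function(f, dims = 2L) {
  .assert_feature_table(f)
  if (dims < 1L) stop("`dims` must be >= 1", call. = FALSE)
  if (nrow(f) < dims + 1L) stop("need at least dims + 1 genes to embed", call. = FALSE)
  x <- as.matrix(f[, c(paste0("d", 1:9), "mae")])
  rownames(x) <- f$gene_id
  coords <- stats::cmdscale(stats::dist(x), k = dims)
  if (ncol(coords) < dims) {  # degenerate geometry: pad exact-zero axes
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  }
  colnames(coords) <- paste0("dim", seq_len(dims))
  coords
}

#' Stratified train/test split of labeled features
#'
#' Reproducible split given a seed; with `stratified = TRUE` (default) the
#' class proportions of the two labels are preserved within rounding.
#'
#' @param f A `feature_table` in which every gene carries one of the two
#'   class labels.
#' @param train_fraction Fraction assigned to training, default 0.7.
#' @param seed Integer seed controlling the split.
#' @param stratified Split within each class (default) or over the pooled
#'   set.
#' @return A list with `feature_table`s `train` and `test`.
#' @export
split_train_test <- function(f, train_fraction = 0.7, seed, stratified = TRUE) {
  .assert_feature_table(f)
  if (missing(seed)) stop("`seed` is required for a reproducible split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (anyNA(f$label)) stop("all genes must be labeled for splitting", call. = FALSE)
  classes <- sort(unique(f$label))
  if (length(classes) != 2L) stop("exactly two classes are required", call. = FALSE)
  if (any(table(f$label) < 2L)) stop("each class needs at least 2 members", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  take <- logical(nrow(f))
  if (stratified) {
    for (cl in classes) {
      i <- which(f$label == cl)
      take[sample(i, round(train_fraction * length(i)))] <- TRUE
    }
  } else {
    take[sample(nrow(f), round(train_fraction * nrow(f)))] <- TRUE
  }
  list(train = .subset_features(f, take), test = .subset_features(f, !take))
}

#' K-nearest-neighbour prediction of tissue specificity
#'
#' Classifies each test gene by majority vote among its `k` nearest training
#' genes in the 10-dimensional Benford feature space (Euclidean distance).
#' Neighbour order is deterministic: distance ties are broken toward the
#' lexicographically smaller training gene identifier. With two classes and
#' odd `k` a vote tie cannot occur; with even `k` a warning is emitted and
#' vote ties resolve toward `tissue_specific`.
#'
#' @param train,test `feature_table`s; all training genes must be labeled
#'   with the two classes.
#' @param k Number of neighbours, default 7.
#' @param positive Label treated as the positive class for
#'   sensitivity/specificity; default `"tissue_specific"`.
#' @return A `classifier_report` list: `predictions` (data frame `gene_id`,
#'   `actual`, `predicted`), and — when test labels are available —
#'   `confusion`, `sensitivity`, `specificity`, plus `k`. Unlabeled test
#'   genes yield predictions without metrics.
#' @export
knn_classify <- function(train, test, k = 7L, positive = "tissue_specific") {
  .assert_feature_table(train)
  .assert_feature_table(test)
  if (k < 1L || k > nrow(train)) stop("`k` must be in 1..nrow(train)", call. = FALSE)
  if (anyNA(train$label)) stop("all training genes must be labeled", call. = FALSE)
  classes <- sort(unique(train$label))
  if (length(classes) != 2L) stop("training set must contain exactly two classes", call. = FALSE)
  if (!positive %in% classes) stop("positive class '", positive, "' absent from training labels",
                                   call. = FALSE)
  if (k %% 2L == 0L) {
    warning("even k allows vote ties; ties resolve toward '", positive, "'", call. = FALSE)
  }
  cols <- c(paste0("d", 1:9), "mae")
  a <- as.matrix(test[, cols])
  b <- as.matrix(train[, cols])
  # squared Euclidean cross-distances; clamp tiny negatives from cancellation
  d2 <- pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0)
  tie_rank <- order(train$gene_id)  # smaller id wins distance ties
  id_pos <- integer(nrow(train)); id_pos[tie_rank] <- seq_len(nrow(train))
  predicted <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    nb <- order(d2[i, ], id_pos)[seq_len(k)]
    votes <- sum(train$label[nb] == positive)
    predicted[i] <- if (votes > k / 2 || votes == k / 2) positive else setdiff(classes, positive)
  }
  out <- list(
    predictions = data.frame(gene_id = test$gene_id, actual = test$label,
                             predicted = predicted, stringsAsFactors = FALSE),
    k = as.integer(k)
  )
  if (!anyNA(test$label)) {
    out <- c(out, confusion_metrics(test$label, predicted, positive = positive))
  }
  structure(out, class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("KNN classifier report (k =", x$k, ")\n")
  if (!is.null(x$confusion)) {
    print(x$confusion)
    cat(sprintf("sensitivity %.3f, specificity %.3f\n", x$sensitivity, x$specificity))
  } else {
    cat(nrow(x$predictions), "predictions (no test labels; metrics unavailable)\n")
  }
  invisible(x)
}

#' Confusion matrix, sensitivity and specificity
#'
#' Builds the 2x2 confusion grid (rows: actual, columns: predicted; class
#' order `housekeeping`, `tissue_specific`) and the derived metrics with
#' `tissue_specific` as the positive class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP).
#'
#' @param actual,predicted Equal-length label vectors over the two classes.
#' @param classes The two class labels, negative first; default
#'   `c("housekeeping", "tissue_specific")`.
#' @param positive Positive class, default `"tissue_specific"`.
#' @return A list with `confusion` (2x2 integer matrix), `sensitivity` and
#'   `specificity`.
#' @examples
#' confusion_metrics(
#'   actual = rep(c("housekeeping", "tissue_specific"), c(100, 104)),
#'   predicted = rep(c("housekeeping", "tissue_specific", "housekeeping", "tissue_specific"),
#'                   c(95, 5, 4, 100))
#' )
#' @export
confusion_metrics <- function(actual, predicted,
                              classes = c("housekeeping", "tissue_specific"),
                              positive = "tissue_specific") {
  if (length(actual) != length(predicted)) stop("label vectors differ in length", call. = FALSE)
  bad <- setdiff(unique(c(actual, predicted)), classes)
  if (length(bad) > 0L) {
    stop("label(s) outside the two classes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!positive %in% classes) stop("`positive` must be one of `classes`", call. = FALSE)
  negative <- setdiff(classes, positive)
  confusion <- table(actual = factor(actual, classes), predicted = factor(predicted, classes))
  confusion <- unclass(confusion)  # plain integer matrix
  tp <- confusion[positive, positive]
  fn <- confusion[positive, negative]
  tn <- confusion[negative, negative]
  fp <- confusion[negative, positive]
  list(
    confusion = confusion,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  )
}

.subset_features <- function(f, i) {
  out <- f[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"))
}

.assert_feature_table <- function(f) {
  if (!inherits(f, "feature_table")) stop("expected a feature_table", call. = FALSE)
  invisible(f)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
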
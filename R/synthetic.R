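#' Values following the Benford law exactly in expectation
#'
#' Draws \eqn{x = 10^U} with \eqn{U} uniform on (0, `orders`). Because the
#' fractional part of \eqn{\log_{10} x} is then uniform on (0, 1), the
#' leading-digit distribution of these values matches the Benford
#' probabilities exactly in expectation — the canonical construction for a
#' dataset "spread evenly over several orders of magnitude".
#'
#' @param n Number of values.
#' @param orders Number of decades spanned, default 3.
#' @param seed Integer seed.
#' @return Numeric vector of `n` positive values in (1, 10^orders).
#' @export
generate_benford_exact <- function(n, orders = 3, seed) {
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (orders < 1) stop("`orders` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  10^stats::runif(n, 0, orders)
}

#' Configuration for the synthetic expression generator
#'
#' Describes a lognormal gene-by-sample expression simulation. Each category
#' emulates a gene class through its dynamic range: per gene a location
#' `mu_g` is drawn uniformly from `log10_mu_range`, and sample values are
#' `10^Normal(mu_g, log10_sigma)`, so `log10_sigma` is directly the number
#' of orders of magnitude a gene's expression spreads over. The default
#' categories mirror the empirical contrast driving Benford behaviour in
#' expression data: housekeeping genes vary narrowly around a high level —
#' sigma 0.15 and a 0.4-decade location band, so the category is narrow both
#' per gene and as a set — while tissue-specific genes span multiple decades
#' (sigma 1.0 over a 3-decade band) and a random background sits in between
#' (sigma 0.5).
#'
#' @param n_samples Number of samples (individuals or cells); default 1000,
#'   the scale at which per-gene digit distributions become informative.
#' @param seed Integer seed; the full output is reproducible from it.
#' @param categories List of category descriptors as produced by
#'   [synthetic_category()].
#' @param zero_inflation Probability in \[0, 1) that any cell is replaced by
#'   zero (uniform, expression-independent); default 0.
#' @param count_layer If `TRUE`, each continuous value v is replaced by a
#'   Poisson(v) integer draw and the matrix is tagged `raw`; otherwise the
#'   continuous values are tagged `cpm`. Default `FALSE`.
#' @param benford_exact_genes Number of additional genes whose values are
#'   drawn from [generate_benford_exact()] (category `benford_exact`);
#'   default 0.
#' @param metric Metric tag for the continuous layer, default `"cpm"`
#'   (ignored when `count_layer = TRUE`).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 1000L,
                             seed = 1L,
                             categories = list(
                               synthetic_category("housekeeping", 300L, c(1.8, 2.2), 0.15),
                               synthetic_category("tissue_specific", 306L, c(0, 3), 1.0),
                               synthetic_category("random", 300L, c(0.5, 2.5), 0.5)
                             ),
                             zero_inflation = 0,
                             count_layer = FALSE,
                             benford_exact_genes = 0L,
                             metric = c("cpm", "rpkm", "tpm", "raw")) {
  metric <- match.arg(metric)
  if (!is.numeric(n_samples) || n_samples < 1) stop("invalid field n_samples", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L) stop("invalid field seed", call. = FALSE)
  if (!is.list(categories) || length(categories) == 0L) {
    stop("invalid field categories", call. = FALSE)
  }
  for (cc in categories) {
    if (!inherits(cc, "synthetic_category")) stop("invalid field categories", call. = FALSE)
  }
  nm <- vapply(categories, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("invalid field categories: duplicate names", call. = FALSE)
  if (!is.numeric(zero_inflation) || zero_inflation < 0 || zero_inflation >= 1) {
    stop("invalid field zero_inflation (must be in [0, 1))", call. = FALSE)
  }
  if (!is.numeric(benford_exact_genes) || benford_exact_genes < 0) {
    stop("invalid field benford_exact_genes", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), seed = as.integer(seed),
         categories = categories, zero_inflation = zero_inflation,
         count_layer = isTRUE(count_layer),
         benford_exact_genes = as.integer(benford_exact_genes),
         metric = if (isTRUE(count_layer)) "raw" else metric),
    class = "synthetic_config"
  )
}

#' Describe one synthetic gene category
#'
#' @param name Category name (e.g. `"housekeeping"`).
#' @param n_genes Number of genes, >= 1.
#' @param log10_mu_range Length-2 range for the per-gene log10 location.
#' @param log10_sigma Per-gene spread in orders of magnitude, > 0.
#' @return A `synthetic_category` list.
#' @export
synthetic_category <- function(name, n_genes, log10_mu_range, log10_sigma) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("invalid field name", call. = FALSE)
  }
  if (!is.numeric(n_genes) || n_genes < 1) stop("invalid field n_genes", call. = FALSE)
  if (!is.numeric(log10_mu_range) || length(log10_mu_range) != 2L ||
      log10_mu_range[1] > log10_mu_range[2]) {
    stop("invalid field log10_mu_range", call. = FALSE)
  }
  if (!is.numeric(log10_sigma) || log10_sigma <= 0) {
    stop("invalid field log10_sigma", call. = FALSE)
  }
  structure(list(name = name, n_genes = as.integer(n_genes),
                 log10_mu_range = as.numeric(log10_mu_range),
                 log10_sigma = as.numeric(log10_sigma)),
            class = "synthetic_category")
}

#' Named simulation presets
#'
#' * `"gtex-lung-like"` — 1000 samples with the three default categories
#'   (300 housekeeping, 306 tissue-specific, 300 random genes), continuous
#'   values; emulates a bulk multi-donor tissue panel.
#' * `"retina-like"` — 2000 cells, Poisson count layer and 40\% zero
#'   inflation over lower expression levels; emulates sparse droplet-based
#'   single-cell counts.
#' * `"benford-exact"` — 2000 genes x 100 samples of exact-Benford values
#'   (category `benford_exact` only); the aggregate digit distribution
#'   matches the law in expectation.
#'
#' @param name Preset name.
#' @param n_samples Optional override of the preset's sample count.
#' @param seed Integer seed, default 1.
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("gtex-lung-like", "retina-like", "benford-exact"),
                             n_samples = NULL, seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    "gtex-lung-like" = synthetic_config(n_samples = 1000L, seed = seed),
    "retina-like" = synthetic_config(
      n_samples = 2000L, seed = seed,
      categories = list(
        synthetic_category("housekeeping", 300L, c(1.3, 1.7), 0.15),
        synthetic_category("tissue_specific", 296L, c(0, 2.5), 1.0),
        synthetic_category("random", 300L, c(0.5, 2.0), 0.5)
      ),
      zero_inflation = 0.4, count_layer = TRUE
    ),
    "benford-exact" = synthetic_config(
      n_samples = 100L, seed = seed,
      categories = list(synthetic_category("placeholder", 1L, c(1, 1), 0.1)),
      benford_exact_genes = 2000L
    )
  )
  if (name == "benford-exact") cfg$categories <- list()  # exact genes only
  if (!is.null(n_samples)) cfg$n_samples <- as.integer(n_samples)
  cfg
}

#' Generate a synthetic expression matrix with category labels
#'
#' Deterministic given the config (including its seed): per-gene locations,
#' sample values, zero inflation and the optional Poisson count layer are
#' drawn in a fixed order.
#'
#' @param config A [synthetic_config()].
#' @return A list with `matrix` (an `ExpressionMatrix`) and `labels` (data
#'   frame `gene_id`, `category`).
#' @export
generate_expression <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must be a synthetic_config", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  ns <- config$n_samples
  blocks <- list()
  ids <- character(0)
  cats <- character(0)
  for (cc in config$categories) {
    ng <- cc$n_genes
    mu <- stats::runif(ng, cc$log10_mu_range[1], cc$log10_mu_range[2])
    v <- matrix(10^stats::rnorm(ng * ns, mean = mu, sd = cc$log10_sigma), ng, ns)
    blocks[[length(blocks) + 1L]] <- v
    ids <- c(ids, sprintf("%s_%04d", cc$name, seq_len(ng)))
    cats <- c(cats, rep(cc$name, ng))
  }
  if (config$benford_exact_genes > 0L) {
    ng <- config$benford_exact_genes
    v <- matrix(10^stats::runif(ng * ns, 0, 3), ng, ns)
    blocks[[length(blocks) + 1L]] <- v
    ids <- c(ids, sprintf("benford_exact_%04d", seq_len(ng)))
    cats <- c(cats, rep("benford_exact", ng))
  }
  v <- do.call(rbind, blocks)
  if (config$zero_inflation > 0) {
    v[stats::runif(length(v)) < config$zero_inflation] <- 0
  }
  if (config$count_layer) {
    v <- matrix(stats::rpois(length(v), v), nrow(v), ncol(v))
  }
  rownames(v) <- ids
  colnames(v) <- sprintf("sample_%04d", seq_len(ns))
  list(
    matrix = ExpressionMatrix(v, metric = config$metric),
    labels = data.frame(gene_id = ids, category = cats, stringsAsFactors = FALSE)
  )
}

#' Binomial thinning of a count matrix
#'
#' Downsamples integer counts by keeping each read independently with
#' probability `keep_fraction` — the count-level analogue of sequencing a
#' library to lower depth. Expected column sums scale by `keep_fraction`.
#'
#' @param m An `ExpressionMatrix` with `metric = "raw"` and integer values.
#' @param keep_fraction Retention probability in (0, 1).
#' @param seed Integer seed.
#' @return A thinned `ExpressionMatrix`, metric `raw`.
#' @export
thin_counts <- function(m, keep_fraction, seed) {
  .assert_expression_matrix(m)
  if (m$metric != "raw") stop("thin_counts() expects raw counts", call. = FALSE)
  if (any(m$values != round(m$values))) {
    stop("thin_counts() requires integer counts", call. = FALSE)
  }
  if (keep_fraction <= 0 || keep_fraction >= 1) {
    stop("`keep_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  v <- matrix(stats::rbinom(length(m$values), size = as.integer(round(m$values)),
                            prob = keep_fraction),
              nrow(m$values), ncol(m$values), dimnames = dimnames(m$values))
  ExpressionMatrix(v, metric = "raw")
}

#' Pooled first-digit summary of a whole expression matrix
#'
#' Pools every value in the matrix into one digit distribution and reports
#' the MAE and chi-squared goodness of fit against the Benford expectation —
#' the whole-dataset view in which expression data typically shows the
#' Benford trend. Refuses log2-tagged matrices.
#'
#' @param m An `ExpressionMatrix` on a non-log metric.
#' @param exclude_below_one As in [digit_distribution()].
#' @return A list with `distribution` (a [digit_distribution()]), `mae`, and
#'   the chi-squared `statistic`, `p_value`, `df`.
#' @export
matrix_digit_summary <- function(m, exclude_below_one = FALSE) {
  .assert_expression_matrix(m)
  .refuse_log2(m, "Whole-matrix Benford summary")
  dist <- digit_distribution(as.vector(m$values), exclude_below_one = exclude_below_one)
  gof <- benford_chisq(dist)
  list(distribution = dist, mae = benford_mae(dist),
       statistic = gof$statistic, p_value = gof$p_value, df = gof$df)
}
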
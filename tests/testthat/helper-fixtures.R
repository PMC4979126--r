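# Shared fixtures built in code.

# String-based oracle for the first significant digit: format with plenty of
# significant digits and take the first non-zero character.
first_digit_oracle <- function(x) {
  vapply(x, function(v) {
    s <- formatC(v, format = "e", digits = 15)
    as.integer(substr(s, 1, 1))
  }, integer(1))
}

# A value multiset whose first-digit counts are exactly `counts[d]` copies of
# digit d (values d, d*10, d*100, ... to vary magnitude deterministically).
values_with_digit_counts <- function(counts) {
  unlist(lapply(1:9, function(d) {
    k <- counts[d]
    if (k == 0) return(numeric(0))
    d * 10^(seq_len(k) %% 4)
  }))
}

# Small raw-count ExpressionMatrix with reproducible pseudo-random entries.
random_raw_matrix <- function(n_genes = 5, n_samples = 3, seed = 42, max_count = 500) {
  set.seed(seed)
  v <- matrix(sample.int(max_count, n_genes * n_samples, replace = TRUE),
              n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  ExpressionMatrix(v, metric = "raw")
}

# Brute-force per-gene MAE: the independent oracle for gene_centric_mae.
brute_force_gene_mae <- function(m, exclude_below_one = FALSE) {
  E <- log10(1 + 1 / (1:9))
  vapply(seq_len(nrow(m$values)), function(g) {
    vals <- m$values[g, ]
    vals <- vals[vals > 0]
    if (exclude_below_one) vals <- vals[vals >= 1]
    if (length(vals) == 0) return(NA_real_)
    digs <- first_digit_oracle(vals)
    A <- tabulate(digs, nbins = 9) / length(vals)
    mean(abs(A - E))
  }, numeric(1))
}

two_class_labels <- function(labels) {
  labels[labels$category %in% c("housekeeping", "tissue_specific"), ]
}
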
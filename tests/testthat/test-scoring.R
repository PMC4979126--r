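test_that("gene-centric MAE reproduces constructed identity and point-mass cases", {
  E <- benford_expected()
  # values across samples proportioned exactly like Benford counts
  counts <- round(E * 1e4)
  benford_vals <- values_with_digit_counts(counts)
  # one Benford-proportioned gene, one constant gene
  n <- length(benford_vals)
  v <- rbind(benford = benford_vals, constant5 = rep(5, n))
  colnames(v) <- sprintf("c%05d", seq_len(n))
  tab <- gene_centric_mae(ExpressionMatrix(v, metric = "raw"))
  expect_lt(tab$mae[tab$gene_id == "benford"], 1e-4)
  # point mass on digit 5: closed form 2(1 - E_5)/9 = 0.204626...
  expect_equal(tab$mae[tab$gene_id == "constant5"],
               2 * (1 - log10(6 / 5)) / 9, tolerance = 1e-12)
  expect_equal(tab$mae[tab$gene_id == "constant5"], 0.204626389767194, tolerance = 1e-9)
  expect_equal(tab$mean_expression[tab$gene_id == "constant5"], 5)
})

test_that("gene-centric MAE equals the brute-force per-gene oracle", {
  set.seed(31)
  for (rep in 1:3) {
    v <- matrix(rlnorm(20 * 50, meanlog = 2, sdlog = 2), 20, 50,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:50)))
    v[sample(length(v), 100)] <- 0
    m <- ExpressionMatrix(v, metric = "cpm")
    for (ebo in c(FALSE, TRUE)) {
      tab <- gene_centric_mae(m, exclude_below_one = ebo)
      oracle <- brute_force_gene_mae(m, exclude_below_one = ebo)
      names(oracle) <- rownames(v)
      expect_equal(tab$mae, unname(oracle[tab$gene_id]), tolerance = 1e-12)
    }
  }
})

test_that("gene-centric MAE table is digit-frequency-consistent and filters by min_used", {
  m <- random_raw_matrix(15, 40, seed = 32)
  tab <- gene_centric_mae(m)
  E <- benford_expected()
  freq <- as.matrix(tab[, paste0("d", 1:9)])
  expect_equal(tab$mae, unname(rowMeans(abs(sweep(freq, 2, E)))), tolerance = 1e-12)
  expect_equal(unname(rowSums(freq)), rep(1, nrow(tab)), tolerance = 1e-12)

  v <- matrix(c(rep(0, 39), 5), 1, 40,
              dimnames = list("sparse", sprintf("s%02d", 1:40)))
  m2 <- ExpressionMatrix(rbind(m$values, v), metric = "raw")
  expect_message(tab2 <- gene_centric_mae(m2, min_used = 10), "omitted")
  expect_false("sparse" %in% tab2$gene_id)
  expect_identical(attr(tab2, "omitted"), "sparse")
})

test_that("MAE scores are invariant under sample permutation and powers of ten", {
  m <- random_raw_matrix(12, 60, seed = 33)
  tab <- gene_centric_mae(m)
  perm <- ExpressionMatrix(m$values[, sample(ncol(m$values))], metric = "raw")
  expect_equal(gene_centric_mae(perm)$mae, tab$mae, tolerance = 1e-14)
  scaled <- ExpressionMatrix(m$values * 10, metric = "raw")
  expect_equal(gene_centric_mae(scaled)$mae, tab$mae, tolerance = 1e-14)
})

test_that("individual-centric MAE pools category values per sample", {
  E <- benford_expected()
  counts <- round(E * 2000)
  vals <- values_with_digit_counts(counts)
  ng <- length(vals)
  v <- cbind(sampleA = vals, sampleB = rep(7, ng))
  rownames(v) <- sprintf("g%04d", seq_len(ng))
  m <- ExpressionMatrix(v, metric = "raw")
  labels <- data.frame(gene_id = rownames(v), category = "all")
  tab <- individual_centric_mae(m, labels)
  expect_identical(nrow(tab), 2L)
  # Benford-proportioned sample scores near zero; constant sample is a point mass
  expect_lt(tab$mae[tab$sample_id == "sampleA"], 1e-3)
  expect_equal(tab$mae[tab$sample_id == "sampleB"],
               2 * (1 - log10(8 / 7)) / 9, tolerance = 1e-12)
  # one category covering all genes reduces to the whole-sample digit distribution
  whole <- benford_mae(digit_distribution(v[, "sampleA"]))
  expect_equal(tab$mae[tab$sample_id == "sampleA"], whole, tolerance = 1e-14)
})

test_that("individual-centric MAE yields one row per sample and category, flags empties", {
  sim <- generate_expression(synthetic_preset("gtex-lung-like", n_samples = 20, seed = 34))
  tab <- individual_centric_mae(sim$matrix, sim$labels)
  expect_identical(nrow(tab), 20L * 3L)
  expect_identical(sort(unique(tab$category)),
                   c("housekeeping", "random", "tissue_specific"))
  # gene permutation within categories leaves scores unchanged
  set.seed(35)
  perm <- sample(nrow(sim$matrix$values))
  mp <- ExpressionMatrix(sim$matrix$values[perm, ], metric = "cpm")
  tp <- individual_centric_mae(mp, sim$labels)
  key <- function(t) t[order(t$sample_id, t$category), c("mae", "n_used")]
  expect_equal(key(tp), key(tab), ignore_attr = TRUE, tolerance = 1e-14)

  # a category with zero usable values in a sample is flagged, not dropped
  v <- matrix(c(0, 5, 3, 2), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  v["b", "s1"] <- 0
  labs <- data.frame(gene_id = c("a", "b"), category = c("x", "x"))
  expect_warning(t2 <- individual_centric_mae(ExpressionMatrix(v, metric = "raw"), labs),
                 "no usable values")
  expect_true(is.na(t2$mae[t2$sample_id == "s1"]))
  expect_identical(nrow(t2), 2L)

  expect_error(individual_centric_mae(sim$matrix,
                                      data.frame(gene_id = "absent", category = "x")),
               "no genes")
})

test_that("housekeeping genes score higher MAE than tissue-specific genes in both modes", {
  sim <- generate_expression(synthetic_preset("gtex-lung-like", n_samples = 300, seed = 36))
  tab <- merge(gene_centric_mae(sim$matrix), sim$labels, by = "gene_id")
  hk <- tab$mae[tab$category == "housekeeping"]
  ts <- tab$mae[tab$category == "tissue_specific"]
  expect_gt(median(hk), median(ts))
  expect_lt(wilcox.test(hk, ts, alternative = "greater")$p.value, 0.05)

  itab <- individual_centric_mae(sim$matrix, sim$labels)
  ihk <- itab$mae[itab$category == "housekeeping"]
  its <- itab$mae[itab$category == "tissue_specific"]
  expect_gt(median(ihk), median(its))
  expect_lt(wilcox.test(ihk, its, alternative = "greater")$p.value, 0.05)
})

test_that("rank_and_select orders by MAE with deterministic identifier tie-breaks", {
  tab <- structure(
    data.frame(gene_id = c("g05", "g01", "g03", "g02", "g04"),
               mae = c(0.01, 0.20, 0.05, 0.05, 0.10),
               n_used = 100L, d1 = 0.3, d2 = 0.18, d3 = 0.12, d4 = 0.1, d5 = 0.08,
               d6 = 0.07, d7 = 0.06, d8 = 0.05, d9 = 0.04, mean_expression = 1),
    mode = "gene_centric", metric = "cpm", class = c("mae_table", "data.frame"))
  sel <- suppressWarnings(rank_and_select(tab, n_top = 2, n_bottom = 2))
  expect_identical(sel$lowest_mae, c("g05", "g02"))  # g02 beats g03 lexicographically
  expect_identical(sel$highest_mae, c("g01", "g04"))
  expect_warning(rank_and_select(tab, n_top = 3, n_bottom = 3), "overlap")
  sel2 <- suppressWarnings(rank_and_select(tab, n_top = 300, n_bottom = 300))
  expect_identical(length(sel2$lowest_mae), 5L)
  expect_error(rank_and_select(tab, n_top = 0), "positive")
})

test_that("threshold_select applies strict conjunctive bounds", {
  tab <- structure(
    data.frame(gene_id = sprintf("g%02d", 1:6),
               mae = c(0.02, 0.065, 0.07, 0.03, 0.10, 0.064),
               n_used = 100L, d1 = 0.3, d2 = 0.18, d3 = 0.12, d4 = 0.1, d5 = 0.08,
               d6 = 0.07, d7 = 0.06, d8 = 0.05, d9 = 0.04,
               mean_expression = c(2, 9, 10, 4, 12, 8.5)),
    mode = "gene_centric", metric = "cpm", class = c("mae_table", "data.frame"))
  expect_identical(threshold_select(tab, mae_below = 0.065), c("g01", "g04", "g06"))
  expect_identical(threshold_select(tab, mean_expr_above = 8, mae_above = 0.04),
                   c("g02", "g03", "g05", "g06"))
  expect_identical(threshold_select(tab, mae_below = 0.001), character(0))
  expect_error(threshold_select(tab), "at least one")
  expect_error(threshold_select(tab, mae_above = 0.1, mae_below = 0.05), "contradictory")
})
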
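# benfordexpr

Benford first-digit analysis of digital gene expression.

## The problem

The Benford (first-digit) law says that in many count-rich datasets the
leading significant digit *d* of a value is not uniform but logarithmic:

    P(leading digit = d) = log10(1 + 1/d),   d = 1, ..., 9

so digit 1 leads about 30.1% of the time and digit 9 about 4.6%. RNA-seq
expression tables are exactly the kind of data this law applies to: gene
expression is approximately lognormal, and whenever a set of values spreads
over several orders of magnitude its leading digits follow the law.

That makes the *deviation* from the law informative at the gene level. A
gene whose expression across hundreds or thousands of samples/cells spans
multiple decades (typical of tissue-specific genes) adheres to the law; a
gene confined to a narrow band (typical of constitutively expressed
housekeeping genes) violates it. `benfordexpr` turns this into a pipeline
for transcriptomics analysts:

* **Conformity statistic** — the mean absolute error between observed and
  expected digit frequencies,

      MAE = (1/9) * sum_d |A_d - E_d|

  plus a Pearson chi-squared goodness-of-fit test (8 df; p > 0.05 read as
  adherence).
* **Two scoring modes** — *gene-centric* (one MAE per gene, digits pooled
  across samples) and *individual-centric* (one MAE per sample per gene
  category, digits pooled within the sample).
* **Normalization and filtering** — CPM / RPKM / TPM, a log2 guard (log
  data violates the law, so scoring refuses it), the top-40% mean-CPM
  expressed-gene filter, ranking and threshold selection of extreme genes.
* **Prediction** — per-gene features (nine digit frequencies + MAE) feed a
  deterministic 7-nearest-neighbour classifier of housekeeping vs.
  tissue-specific status, with classical MDS for visualization.
* **Synthetic data** — a lognormal generator whose presets reproduce the
  dynamic-range structure above, so the whole pipeline is testable without
  external downloads.

## Worked example

```r
library(benfordexpr)

sim <- generate_expression(synthetic_preset("gtex-lung-like", seed = 1))
sim$matrix
#> ExpressionMatrix: 906 genes x 1000 samples, metric = cpm

tab <- gene_centric_mae(sim$matrix)
merged <- merge(tab, sim$labels, by = "gene_id")
tapply(merged$mae, merged$category, median)
#>    housekeeping          random tissue_specific
#>     0.086269448     0.007372715     0.007261093

f  <- build_features(tab, subset(sim$labels, category != "random"))
f  <- f[!is.na(f$label), ]
sp <- split_train_test(f, train_fraction = 0.7, seed = 1)
knn_classify(sp$train, sp$test, k = 7)
#> KNN classifier report (k = 7 )
#>                  predicted
#> actual            housekeeping tissue_specific
#>   housekeeping              90               0
#>   tissue_specific            0              92
#> sensitivity 1.000, specificity 1.000
```

Housekeeping genes (narrow dynamic range) sit an order of magnitude above
tissue-specific genes in MAE, and the digit-frequency features separate the
two classes essentially perfectly on this synthetic preset.

A command-line front-end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "benfordexpr.R", package = "benfordexpr"))')
Rscript $CLI simulate --preset gtex-lung-like --seed 1 --out sim/
Rscript $CLI digits   --input sim/matrix.tsv --metric cpm --out digits/
Rscript $CLI score    --input sim/matrix.tsv --metric cpm --mode gene --out scores/
Rscript $CLI classify --scores scores/mae_table.tsv --labels labels2.tsv --k 3,5,7,9 --seed 1 --out knn/
```

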
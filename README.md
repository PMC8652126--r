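# grnconsensus

Consensus gene regulatory network (GRN) construction from gene-expression
data. Given a matrix of expression values with genes in rows and conditions
(samples, experiments) in columns, `grnconsensus` scores every gene pair with
four complementary connectivity measures, attaches bootstrap-based
significance to each score, and combines the four lines of evidence into a
single consensus edge list ready for Cytoscape.

It is aimed at analysts who want a reproducible, scriptable version of the
common "run several network inference methods and keep the edges they agree
on" workflow, with every statistical step explicit and tested.

## The method

All scores are computed on standardized expression rows
(mean 0, sample sd 1). For genes *i*, *k* with profiles *x_i*, *x_k* over
*n* conditions:

* **Correlation**: S_ik = x_i'x_k / sqrt((x_i'x_i)(x_k'x_k)) — the Pearson
  correlation.
* **PCR**: regress each gene *g* on the leading *k* principal-component
  scores of the remaining genes and back-transform the component
  coefficients through the eigenvector matrix V:
  s_g = V b̂_g, one coefficient per partner gene.
* **PLS**: for each gene, extract *v* latent components t^(l) = Σ_k c_k^(l)
  X_k^(l) with normalized covariance weights c^(l), regress the gene on each
  component (coefficient b̂_l), deflate, and score each partner by
  Σ_l b̂_l c_k^(l).
* **Ridge**: s_g = (X̃_g'X̃_g + λI)⁻¹ X̃_g'x_g with the leave-one-gene-out
  design X̃_g.

The directional regression scores are symmetrized by averaging the two
ordered coefficients of each pair. Edge confidence comes from *B* bootstrap
resamples of the conditions: per edge, the replicate mean s̄ and standard
error Se give t = s̄/Se (regression methods) or
t = s̄·sqrt(n−2)/sqrt(1−s̄²) (correlation). A robust empirical null fitted
to each method's t-statistics (half-normal scale σ₀ = median|t|/Φ⁻¹(0.75),
null proportion η₀) yields two-sided p-values and tail-area false discovery
rates. Finally the per-method p-values are combined per edge with Fisher's
method,

    Fw = −2 ln(p₁ p₂ p₃ p₄)  ~  χ²(8) under the null,

and edges are selected by Benjamini–Hochberg on the combined p-value.

A built-in Gaussian graphical model simulator plants a known network
(sparse precision matrix) so the whole pipeline can be validated against
ground truth without any external data.

## Worked example

```r
library(grnconsensus)

f <- system.file("extdata", "example_expression.csv", package = "grnconsensus")
x <- read_expression_matrix(f)   # 8 genes x 10 conditions, 3 planted edges
fit <- consensus_grn(x, B = 100, seed = 1)
fit
#> <grn_fit> 8 genes, 28 gene pairs, methods: correlation, pcr, pls, ridge
#>   B = 100, seed = 1, significant edges at alpha = 0.05: 6

dplyr::arrange(tidy(fit), p_combined)
#> # A tibble: 28 x 10
#>   gene_a gene_b    p_cor   p_pcr   p_pls p_ridge    Fw  p_combined q_combined
#> 1 g2     g4     0.000764 0.00627 0.00665 0.0123   43.3 0.000000766  0.0000214
#> 2 g2     g7     0.0142   0.00188 0.0157  0.00353  40.7 0.00000241   0.0000337
#> 3 g7     g8     0.0107   0.0257  0.0491  0.0330   29.2 0.000287     0.00268
#> 4 g1     g4     0.0285   0.0672  0.00859 0.0463   28.2 0.000442     0.00309
#> # ...
```

Each row is one unordered gene pair: the four per-method p-values, the
Fisher statistic `Fw` (larger = stronger joint evidence), its combined
p-value against the χ²(8) reference, the BH-adjusted `q_combined`, and the
significance flag at α = 0.05. The two strongest calls, g2–g4 and g2–g7,
are two of the three planted edges of this fixture
(`example_truth_edges.csv`); with only 10 conditions the third (g1–g2) is
not separable, which is exactly the sample-size behaviour the bootstrap
t-statistics are there to expose. `glance(fit)` gives the one-row run
summary and `autoplot(fit)` the volcano-style overview.

The same run from the shell, writing per-method edge tables, the consensus
tables and a reproducibility manifest:

```sh
Rscript inst/cli/consensus-grn run --input expr.csv --outdir out/ --B 100 --seed 1
Rscript inst/cli/consensus-grn simulate --genes 30 --edges 40 --n 60 --seed 1 --outdir sim/
```

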
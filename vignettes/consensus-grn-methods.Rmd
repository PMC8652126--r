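---
title: "Methods: consensus gene regulatory network construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus gene regulatory network construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnconsensus)
```

## The inference problem

A gene regulatory network is inferred from a p × n expression matrix —
p genes measured under n conditions — as a weighted undirected graph on the
genes. No single association measure is reliable across data regimes:
marginal correlation cannot separate direct from indirect co-expression,
while full conditional (regression-based) measures are unstable when p
approaches or exceeds n. `grnconsensus` therefore scores every unordered
gene pair four ways and combines the evidence, keeping edges that several
estimators support.

The pipeline is: standardize → score (4 methods) → bootstrap → per-method
p/fdr → Fisher combination → edge selection. Each stage is a small exported
function, so any slice can be run, inspected or replaced on its own;
`consensus_grn()` runs the chain in memory and `run_pipeline()` adds the
file contract.

## Connectivity scores

All scorers operate on rows standardized to mean 0 and sample standard
deviation 1 (denominator n − 1, the usual unbiased convention). For genes
i and k:

* **Correlation** — `score_correlation()`:
  $S_{ik} = x_i^\top x_k \,/\, \sqrt{(x_i^\top x_i)(x_k^\top x_k)}$, the
  Pearson correlation across conditions. Fast, marginal, bounded in [−1, 1].
* **Principal component regression** — `score_pcr(x, k)`: for each target
  gene g, the remaining p − 1 genes are reduced to their leading k
  principal components (eigendecomposition of the leave-one-out covariance,
  components ordered by descending eigenvalue), the target is regressed on
  the component scores, and the coefficients are back-transformed through
  the eigenvector matrix V to one score per partner gene,
  $s_g = V\hat\beta_g$. With k = p − 1 on a full-rank design this is
  ordinary least squares.
* **Partial least squares** — `score_pls(x, v)`: per target gene, v latent
  components are extracted by the univariate NIPALS recursion — weights
  $c^{(l)} \propto X^{(l)\top} x_i$ normalized to unit length, component
  $t^{(l)} = X^{(l)} c^{(l)}$, one-dimensional regression coefficient
  $\hat\beta_l = (t^{(l)\top}t^{(l)})^{-1} t^{(l)\top} x_i$, then deflation
  of the predictor block by the fitted component. The partner score is
  $\sum_l \hat\beta_l c_k^{(l)}$. The deflation step is the standard NIPALS
  update; published component-wise formulations of this scorer leave the
  deflation operator implicit, and NIPALS is the convention of the PLS
  literature, so that is what we fix here. If the weight norm vanishes
  before v components (predictor block exhausted), the loop caps at the
  realized rank with a warning.
* **Ridge regression** — `score_ridge(x, lambda)`:
  $s_g = (\tilde X_g^\top \tilde X_g + \lambda I)^{-1} \tilde X_g^\top x_g$
  on the leave-one-gene-out design. λ = 0 requires a full-rank design and
  reproduces OLS; the error message for a singular λ = 0 solve says to use
  λ > 0.

Regression scorers are directional ($s_{gk} \ne s_{kg}$); a single per-pair
score is formed by the arithmetic mean of the two ordered coefficients
(`symmetrize_scores()`). Averaging preserves sign — important because
negative scores (repression) are biologically meaningful — and is the
convention in the differential-network lineage these scorers come from. The
diagonal is stored as 0 and never emitted as an edge.

**Defaults**: k = 3 components, v = 3 components, λ = 1.0 — the defaults of
the established R implementation of these network scorers; all three are
arguments of `scoring_params()` and CLI flags. No cross-validation is
attempted: the point of the consensus is robustness across fixed,
documented estimators, not per-dataset tuning.

## Bootstrap edge confidence

`bootstrap_scores()` resamples the n **conditions** with replacement (full
n per replicate), because every edge score is a statistic computed *across
conditions* — resampling genes would break the quantity being estimated.
Each replicate is re-standardized on its resampled columns before scoring;
without this, duplicated columns change row means/sds and the correlation
bound |S| ≤ 1 can fail. A replicate that leaves any gene constant (possible
when a column is drawn n times) is redrawn, at most 100 times, then errors.

Per edge over B replicates (default B = 100): mean $\bar s$, standard error
$Se = \sqrt{(B-1)^{-1}\sum_j (s^{(j)} - \bar s)^2}$, and the t-statistic

* regression methods: $t = \bar s / Se$;
* correlation: $t = \bar s \sqrt{n-2} / \sqrt{1 - \bar s^2}$, the classical
  correlation test statistic with n − 2 degrees of freedom evaluated at the
  bootstrap mean.

Using the bootstrap mean (rather than the full-data correlation) in the
correlation t keeps the four methods on the same resampling footing; the
`cor_t_source = "full-data"` option switches to the plug-in estimate, and
the two agree closely because the bootstrap mean is consistent for it.
Degenerate cases are explicit: Se = 0 with a non-zero mean gives a signed
±1e12 sentinel (effectively p ≈ 0), and a correlation mean at ±1 is clamped
to ±(1 − 1e−12); both warn.

## Empirical null, p-values and fdr

Each method's edge t-statistics are modelled as a two-component mixture
$f = \eta_0 f_0 + (1-\eta_0) f_1$ with null $f_0 = N(0, \sigma_0^2)$. The
scale is the robust half-normal estimate
$\sigma_0 = \mathrm{median}(|t|)/\Phi^{-1}(0.75)$: the median is
essentially untouched by a minority of true-edge t-values in the tails,
which is the sparse-network regime this tool assumes. The null proportion
is $\eta_0 = \min(1,\, 2\,\overline{1\{p > 0.5\}})$ from provisional
p-values under $N(0, \sigma_0^2)$ — under a pure null half the p-values
exceed 0.5, so doubling that fraction estimates the null mass. This is a
deliberately simple, fully specified alternative to censored-MLE /
Grenander empirical-null machinery: every step is a one-line formula that
can be checked by simulation, and at the null it is calibration-equivalent
(the test suite verifies the fraction of p < 0.05 on pure-noise data and
the KS distance of the p-values from uniformity).

p-values are two-sided, $p = 2(1 - \Phi(|t|/\sigma_0))$. The fdr column is
the tail-area false discovery rate: sort p ascending, take
$\min(1, \eta_0\, p_{(r)} N / r)$, and enforce monotonicity by the step-up
cumulative minimum — the Benjamini–Hochberg q-value scaled by $\eta_0$.
Local (density) fdr is deliberately not emitted; one fdr column with a
tail-area interpretation is what the downstream edge tables carry.

With fewer than 50 finite t-statistics the mixture fit is unstable, so the
model falls back to $\sigma_0 = 1, \eta_0 = 1$ with a warning; tiny
examples stay runnable and conservative. All t-values identical (median
|t| = 0) is a degenerate-null error.

## Fisher consensus

Per edge, $F_w = -2\sum_m \ln p_m$ over the m selected methods (default all
four), computed as a sum of logs with p floored at 1e−300 so a zero cannot
overflow. Under independent uniform nulls $F_w \sim \chi^2_{2m}$ (8 df for
four methods), giving `p_combined`; BH across all p(p−1)/2 edges gives
`q_combined` and the significance flag at α = 0.05 (configurable; `adjust =
"none"` thresholds the raw combined p instead). An optional per-method
weight vector generalizes to $F_w = -2\sum w_m \ln p_m$; it is off (all 1)
by default and exists only as an extension point.

The four p-values come from the same data, so they are positively
dependent and the χ² reference is anti-conservative: combined p-values on
real (null) data run somewhat smaller than uniform. This is a known,
documented property of Fisher consensus on shared data; the BH layer is
the default guard, and the pure-null validation study reports the realized
number of flagged edges so the effect is visible rather than hidden.
Dependence-corrected combination (Brown's method) is out of scope.

If fewer than four methods are selected, the reference distribution uses
2m df; a single method is refused — combining one p-value is degenerate and
the per-method table already exists for that use.

## The synthetic ground truth

`make_planted_network()` builds a Gaussian graphical model: `n_edges` pairs
chosen uniformly at random receive precision-matrix entries ±`strength`
(random signs), the diagonal is set to each row's sum of absolute
off-diagonals plus 0.1 — strict diagonal dominance, hence positive
definiteness by Gershgorin — and the matrix is rescaled to unit diagonal so
off-diagonals are directly the negated partial correlations.
`simulate_expression()` draws i.i.d. condition profiles from
$N(0, \Omega^{-1})$. Under this model the planted edges are exactly the
conditional dependencies the regression scorers estimate, which is what
makes recovery tests meaningful rather than circular for any one method.

Note that `strength` is the off-diagonal magnitude *before* unit-diagonal
rescaling; the realized |partial correlation| of a planted edge is
`strength` divided by the geometric mean of the two diagonal boosts, e.g.
≈ 0.3–0.45 at 30 genes / 40 edges / strength 0.5. The `edges` table of the
returned object records the realized values.

What the generator does **not** emulate: count noise (RNA-seq
overdispersion), nonlinear or time-lagged regulation, hub-biased degree
distributions, batch effects, or missing values. Passing the validation
studies therefore demonstrates correctness of the statistical machinery
under its own model, not performance on any particular real dataset.

The default validation sizes are chosen as the smallest instances where the
asymptotic behaviour is visible: calibration on 50 genes × 20 conditions
(1225 edges, B = 100), recovery on 30 genes / 40 edges / 60 conditions
(435 edges, B = 100), and 10,000 draws for distributional checks.

## Numerical and interface choices

* Eigenvector signs in PCR are fixed (largest-magnitude coordinate
  positive) so runs are bit-reproducible across LAPACK builds.
* Symmetrized matrices are exactly symmetric (the average is computed once
  and mirrored), and all per-edge vectors follow one canonical pair order
  (`pair_index()`, the column-major upper triangle).
* All resampling goes through a single integer seed
  (`withr::with_seed`, one derived seed per method), so the same call is
  bitwise reproducible and the global RNG state is left untouched.
* Input is CSV/TSV only — genes in rows, header of condition ids, first
  column gene ids — parsed strictly: any non-numeric or empty cell errors
  with its coordinates. Missing values are a hard error; imputation is a
  modelling decision that does not belong inside a network tool.
  Spreadsheet formats are out of scope; export from a spreadsheet to CSV
  is lossless for this layout.
* Constant (zero-variance) genes error by default, because correlation is
  undefined for them; `drop_constant = TRUE` removes and names them
  instead. Fewer than 4 conditions is rejected outright (the correlation
  t-statistic needs n > 2 and the bootstrap needs variation).
* Edge tables are written in descending |score| order with a lexical
  tie-break, with round-trip-exact number formatting; re-reading a written
  table reproduces it.
* The CLI (`inst/cli/consensus-grn`) is a thin wrapper over
  `run_pipeline()`/`write_simulation()`; flags map one-to-one to function
  arguments, so shell runs and library runs are identical by construction,
  and the JSON manifest written with every run suffices to reproduce it.

## Known limitations

* The χ²(2m) reference ignores between-method dependence (above); combined
  p-values are honest rankings but optimistic in absolute level — rely on
  `q_combined` and, where possible, on the per-method fdr columns.
* Bootstrap with small n (tens of conditions) discretizes the resample
  space; B beyond a few hundred buys little there.
* The empirical null assumes a unimodal, symmetric t distribution under
  the null and a minority of true edges; dense networks violate the
  median-based scale estimate.
* Runtime scales as B · p · (cost of one p×p regression sweep); the
  per-target eigendecomposition makes PCR the most expensive scorer,
  O(B p⁴) overall, fine for hundreds of genes but not for whole
  transcriptomes without pre-filtering.
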
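---
title: "Methods: disease similarity from shared causal genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease similarity from shared causal genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalmap)
```

## The model

`causalmap` asks, for two diseases with causal gene sets $A$ and $B$, how
surprising their overlap $x = |A \cap B|$ is. The reference distribution
must respect that curated corpora have heavy-tailed gene degrees: a hub
gene associated with a fifth of all diseases will appear in many overlaps
by bookkeeping alone, so a null that samples all genes uniformly (as the
Fisher exact test implies) overstates significance for hub-heavy pairs.

The null is therefore *frequency-preserving*: a random gene set $R$
includes gene $g$ independently with probability
$\deg(g)/N_\mathrm{diseases}$, the gene's association frequency in the
data. This is exactly the distribution obtained by drawing one disease
uniformly for every gene and keeping the gene when the drawn disease is
associated with it. Conditioning on the set size $|R| = n$, the expected
overlap of a fixed set $A$ with $R$ grows with $n$; this conditional mean
$\lambda(n)$ is estimated by weighted least-squares regression on the
sampled sets, grouped by size: each distinct size $X$ contributes one
point with response $Y$ (mean observed overlap at that size) and weight
$W(X)$ (number of sets of that size). Size-zero sets, when sampled,
contribute the point $(0, 0, W)$.

The regression family is
$$\hat\lambda(n) = c\,\hat\beta_0 + \sum_{k=1}^{k_\mathrm{max}}
\hat\beta_k\, n^{1/k}, \qquad c \in \{0,1\},\; k_\mathrm{max} \in
\{1,\dots,4\},$$
fitted for all eight $(c, k_\mathrm{max})$ combinations. The selected
model minimizes the AIC among candidates that are non-decreasing and
strictly positive over the relevant size range — a mean overlap cannot
shrink as the random set grows, and the Poisson rate must be positive.
The observed overlap is then scored by the Poisson upper tail
$P(X \ge x)$ at rate $\hat\lambda_A(|B|)$. Because each disease carries
its own model, a pair yields two directional P-values; they are combined
by the geometric mean, $\exp\big(\tfrac12(\ln P_A + \ln P_B)\big)$, which
treats the directions symmetrically and is computed in log space.

Gene–gene similarity (the number of shared diseases) uses the identical
machinery with the roles transposed: `transpose_associations()` swaps the
two sides, random *disease* sets include disease $d$ with probability
$\deg(d)/N_\mathrm{genes}$, and the regression runs unchanged. The
transposition is exact role symmetry; no separate gene-side code path
exists.

### Why Poisson, and what it costs

The true unconditional overlap count is Poisson–binomial (a sum of
independent, non-identical Bernoullis). The Poisson surrogate with
matched mean is simpler, needs only the regression estimate, and — as the
test suite verifies against an exact dynamic-programming oracle — errs on
the conservative side: away from hub-dominated sets it tracks the exact
tail closely in the bulk (within a factor of two down to tail mass about
$10^{-2}$) and overstates the far tail, because the Poisson–binomial has
bounded support and decays faster. P-values are therefore conservative,
never anti-conservative; the calibration check on module-free synthetic
tables (fraction of pairs at $P \le 0.01$ with overlap $\ge 2$) reflects
this by staying well below its 0.02 ceiling.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_degree` (disease side) | 5 genes | diseases with fewer causal genes carry too little annotation to compare |
| `min_degree` (gene side) | 5 diseases | gene-comparison universe for prediction |
| `n_sets` (disease models) | 200,000 | random sets per axis; the regression is fitted once and reused |
| `n_sets` (gene models, CV re-estimation) | 100,000 | |
| map threshold | overlap ≥ 2, $P \le 0.001$ | disease-map edges |
| vicinity / prediction threshold | $P \le 0.01$, overlap ≥ 2 | both prediction steps use the same cut-off |
| cross-validation | 20 rounds × 5 removed | leave-k-out protocol |
| RWR restart $r$ | 0.75 | follows the candidate-prioritization literature the score adopts; tolerance $10^{-6}$, max $10^4$ iterations |

The minimal-overlap cut-off of 2 complements the P-value: it suppresses
single-hub-gene links regardless of significance. All four prediction
cut-offs interact; runs through `cm_run()` always write the effective
configuration next to the outputs so they are auditable.

## Numerical choices

* **AIC convention.** Weighted fits use `stats::lm(weights = W)` and
  `stats::AIC`, i.e. the Gaussian likelihood with precision weights:
  $\mathrm{AIC} = n\ln(\mathrm{RSS}_w/n) + n\ln 2\pi + n - \sum_i \ln W_i
  + 2(p+1)$. Only differences matter; the convention is fixed.
* **Constraint grid.** "Non-decreasing and positive" is checked on the
  integer grid spanning the range of causal-set sizes observed among the
  retained entities — the sizes at which models are later evaluated —
  by pairwise differences (tolerance $-10^{-9}$) and strict positivity.
* **Fallback.** If no candidate passes (possible for degenerate curves,
  e.g. an all-zero response), the intercept-free linear fit is used; if
  its slope is non-positive, a constant model at the weighted mean
  overlap. Fallbacks are flagged on the model object.
* **Floors and clamps.** Predictions are floored at $\varepsilon =
  10^{-9}$ so the Poisson tail stays defined; sizes outside the model's
  valid range are clamped to the nearest boundary and the pair flagged
  `clamped` — the model is never extrapolated.
* **Log-space P-values.** Tails are computed by `ppois(..., log.p =
  TRUE)` (regularized incomplete gamma) and combined in log space;
  serialization uses scientific notation with six significant digits.
* **Determinism.** One integer seed drives each sampling run; uniforms
  are consumed row-major over (set, gene) with genes sorted, so results
  are independent of the internal chunk size. Component labels order by
  decreasing size with lexicographic-smallest-member tie-break; term
  rankings break ties by assigned P-value, then term id.

## Open design points and how they were resolved

* **Preponderance gap.** The "smallest difference" in the preponderance
  statistic is read as $\log_{10}P_2 - \log_{10}P_1$, the gap between the
  two most significant P-values — the reading consistent with its two
  explicit arguments; it is non-negative under the ascending ordering.
  P-values equal to 1 stay in the sum (contributing zero). An all-ones
  vector has no preferred cluster: `preponderance()` raises an error and
  the cluster pipeline flags the term with `NA` rather than 0.
* **Filtering.** Degree filters are single-pass per side (drop the
  entities below threshold, then opposite-side orphans), not iterated to
  a joint fixpoint: the disease-comparison and gene-comparison universes
  are constructed independently, each from the full table. Diseases
  incident to the gene universe are kept regardless of their own degree.
* **FDR.** q-values are Benjamini–Hochberg — assumption-light and fully
  specified — rather than a mixture-model local-fdr estimate, whose
  density-estimation knobs are hard to pin down; numeric q-values are
  therefore not comparable with mixture-based Fdr output.
* **Prediction bookkeeping.** The false-positive universe for threshold
  sweeps is pinned to: gene-comparison universe minus the query's known
  genes minus the truth set. Candidates within 10% of the P cut-off are
  flagged `borderline`, since sampling noise in the rate estimation can
  move them across the threshold between runs. Anchors (known genes of
  the query) must belong to the gene universe; predictions can be lost
  for sparsely annotated anchors.
* **Network clustering.** All tied shortest paths within the step limit
  are included (the inclusive reading of "connect as many input
  molecules as possible"); clusters are weak components with at least two
  seeds, connectors labelled.

## The synthetic generator

`generate_associations()` emulates the statistical shape the method
assumes: gene degrees follow a discrete power law truncated at
`max_degree`, genes attach to uniformly chosen diseases without
replacement, and planted modules draw their genes without replacement
from a dedicated pool so pairwise overlaps have closed hypergeometric
forms for test oracles. The defaults (375 diseases, 3051 genes, exponent
1.8, truncation 78) were chosen so that about 86% of genes link to at
most five diseases while the largest hub reaches 78 — the regime of
curated disease/gene corpora. The generator does **not** emulate
disease-term hierarchies (e.g. MeSH ancestry, which induces overlap
between nested disease entities), literature evidence codes, annotation
biases that correlate gene degree with disease class, or directed
signalling semantics. Passing tests on synthetic data therefore show
that the statistics behave as designed under the stated degree model,
not that real-corpus associations are free of hierarchy- or
curation-driven artefacts.

Fixtures used by the validation suite: calibration uses module-free
tables of 100 diseases × 500 genes with 20,000 random sets over 5 seeds;
map recovery plants two disjoint 5-disease modules (pool 20, draw 10) on
the same background; prediction and cross-validation use a 10-disease
module (pool 20, draw 10) on a 60 × 300 background, 20,000 sets per axis.
These sizes keep a full validation run in the minutes range while leaving
the planted effects far above the null. In deletion/recovery fixtures the
removed gene is chosen among module genes with at least six disease
links, so that it remains inside the five-link gene-comparison universe
after deletion — the test then exercises the similarity machinery rather
than the universe filter. The cross-validation fixture is a fixed dataset
(generator seed 11); run seeds vary the removals and the sampling.

## Known limitations

* **AIC recovery is bounded away from 1.** Model selection by AIC
  retains a scale-invariant probability of roughly
  $P(\chi^2_1 > 2) \approx 0.16$ of preferring each one-extra-parameter
  competitor, and the $n^{1/k}$ regressors are nearly collinear on
  realistic size ranges, so the richer family members are barely
  identifiable. On simulated curves with 5% proportional noise the
  validation suite measures the recovery rate of a known linear
  generating model (`model_selection_recovery`); values in the 0.7–0.8
  range are the expected consequence of AIC's overfitting probability,
  while the *predicted rate* stays within 10% of truth essentially
  always (`lambda_within_10pct_rate`) — overfitted members nest the
  truth, so prediction accuracy, which is what the P-values consume, is
  unaffected.
* **Conservatism.** The combined P-value is conservative in the far tail
  (see above); at the map threshold this costs sensitivity for weakly
  overlapping pairs, not specificity.
* **Cross-validation recovery is data-limited.** A removed gene is only
  recoverable if it retains enough disease links to stay in the gene
  universe and enough co-occurrence with the query's remaining anchors;
  recovery rates therefore measure corpus redundancy as much as method
  quality, and vary substantially across removal draws.
* **Unweighted edges.** The interaction network is treated as unweighted
  and undirected for RWR; confidence scores, if present, are ignored.
* **Cluster labels are inputs.** Disease-cluster assignments for the
  enrichment analysis are user-supplied (historically drawn from visual
  map regions); the package does not attempt to reproduce any particular
  clustering.
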
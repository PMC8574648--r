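---
title: "Simulating and scoring biclusterings: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring biclusterings: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biclusteval)
```

This vignette is the package's own account of the science it implements:
the generative model behind the simulator, the evaluation metrics and
their conventions, and the design decisions taken where more than one
reasonable choice existed.

## The generative model

A bicluster is a subset of samples together with a subset of genes;
`biclusteval` represents it as the Cartesian product of the two index
sets, so all metrics operate on cell sets. Datasets are simulated on a
multi-tissue grid: `m` individuals observed in each of `t` tissues give
`n = m * t` samples, listed tissue by tissue with individuals in the same
order within each tissue (`tensor_sample_maps()`). Every implanted
bicluster is therefore a flattened tricluster — a block of individuals
crossed with a contiguous run of tissues and a block of genes — which
keeps the data usable by tensor factorisation methods and plain matrix
methods alike.

For each bicluster `k`:

1. the gene count `g_k` and individual count `m_k` are drawn uniformly
   from regime-specific candidate sets — mixed:
   `{p/100, p/10, p/5, p/2, p}` (and the analogue in `m`); sparse:
   `{p/20, 2p/20, 3p/20}`; dense: `{3p/10, 5p/10, 9p/10}`; in the square
   regimes one fraction is drawn and applied to both axes;
2. the tissue count `t_k` is uniform on `1..t`;
3. blocks are placed uniformly at random (gene start on `[0, p - g_k]`,
   and so on), so biclusters overlap with positive probability at the
   default `K = 20`;
4. a bicluster mean `mu_k ~ Gamma(shape 2, rate 1/600)` is drawn — mean
   1200, standard deviation ~849 on the count scale, spanning easy,
   visually obvious biclusters through to pairs with similar means;
5. cell values are `NegBin(n_k, p)` with `n_k = mu_k * p / (1 - p)`, so
   the values have mean `mu_k` and variance `mu_k / p` (sd ~63.2 at
   `mu_k = 1200, p = 0.3`).

Bicluster contributions add, and background `NegBin(1, p)` noise is added
on top. Gaussian variants draw cell values `N(mu_k, sigma^2)`; noiseless
variants use the constant `mu_k`. The shift-scale variants replace the
count values inside each bicluster with `alpha_j * pi_il + beta_j`, where
`pi_il ~ Exp(1)`, `beta_j ~ Exp(1)` (mean 1, mode 0) and
`alpha_j ~ Exp(2) + 1/2` (mean 1, mode 1/2 — bounded away from zero so
scale factors never flatten the signal); exponential draws keep the data
non-negative for NMF-style methods. The `"shift"`, `"scale"` and
`"constant-samples"` variants pin `alpha = 1`, `beta = 0`, or both.

Named presets (`preset_names()`) pin the dataset families used in the
benchmark: dimensions from `10 x 10 x 100` up to `300 x 20 x 10000`, `K`
from 5 to 400, negative-binomial noise at `p` in {0.3, 0.1, 0.01},
Gaussian noise at sigma in {20, 100, 300}, and the size-regime and
shift-scale variants.

### Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `p_negbin` | 0.3 | NB success parameter; smaller = noisier (variance `mu/p`) |
| Gamma shape/rate | 2, 1/600 | bicluster mean distribution (counts) |
| `sigma` | 20–300 | Gaussian noise sd (count scale) |
| `theta` | 0.01 | thresholding fraction of a factor's max |
| `q_threshold` | 0.05 | enrichment significance (caller-supplied, never hard-coded: 0.01 is equally defensible for pure gene-clustering summaries) |

### Decisions the model left open

* **Fractional candidate sizes** (e.g. `m/100` at `m = 10`) are rounded
  to the nearest integer with a floor of 1, keeping every bicluster
  non-degenerate.
* **Tissue subsets are contiguous runs**, mirroring the contiguous gene
  and individual blocks; placement is uniform without wrap-around.
* **Non-integer `n_k`** is handled by the Gamma–Poisson mixture, the
  standard real-valued extension of the negative binomial (this is what
  `rnbinom(size =)` implements).
* **Gaussian-noise background** is `N(0, sigma^2)` and the final matrix
  is clipped at zero so count-oriented consumers still function. The
  clipping is a modelling choice isolated in the noise family; nothing
  else depends on it.
* **Shift-scale parameters are drawn independently per bicluster.** The
  gene-indexed notation could also be read as one shared parameter set
  per gene; per-bicluster draws preserve bicluster identifiability when
  biclusters overlap on genes, which is the property the benchmark needs.
* **Seeding**: one master seed per dataset, with derived sub-streams per
  bicluster and purpose (shape, mean, values, background), so increasing
  `K` never perturbs the draws of earlier biclusters, and identical seeds
  reproduce datasets bit for bit.

## The knockout fixture

`simulate_knockout_fixture()` emulates the structure of a multi-tissue
knockout experiment: genotype x tissue x replicate samples, genes grouped
into pathways, each knockout perturbing its own pathway's genes in all of
its samples (additive NB effect, default mean 200 against a background
mean of ~2.3), and tissue main effects implanted as dense biclusters so
that between-tissue variation dominates — as it does in real multi-tissue
data. The gene universe is exactly the pathway-linked genes, matching the
usual restriction of a real analysis to genes sharing a pathway with some
knockout. Defaults (10 genotypes, 3 tissues, 3 replicates, 20 genes per
pathway) are a deliberately small rendition of such a design: large
enough for the enrichment tests to have power, small enough to run in
seconds.

What the fixture does *not* emulate: library-size variation, per-gene
dispersion heterogeneity, correlated pathways, wild-type baselines, or
missing replicates. Metrics validated on it are validated for their
*logic* (selection, matching, correction), not for robustness to real
RNA-seq noise.

## Metrics: conventions and numerical choices

**Clustering error.** `CE = d_max / |U|`. `d_max` is the maximum over
one-to-one bicluster pairings of the summed cell intersections, solved as
a maximum-weight bipartite matching (igraph); intersections are integers,
so no floating-point ties arise in the matching. `|U|` is computed from
per-cell coverage counts as `sum over cells of max(count_A, count_R)` —
the overlap-aware union, reconstructed from the metric's published
properties (it penalises omitted biclusters, extra copies and merging;
all three are asserted in the test suite, and the whole metric is checked
against exhaustive matching enumeration on 200 random instances).
Degenerate conventions are fixed as: both biclusterings empty of cells,
CE = 1; exactly one empty, CE = 0. Empty biclusters are retained in the
sequence but contribute zero cells everywhere; recovered-K counts only
non-empty biclusters.

**MBR** needs at least two biclusters; `K < 2` returns `NA` with a
warning rather than a silent 0. **NRE** with both `Y` and the
reconstruction all-zero is an error, not 0/0. **Jaccard** of two empty
biclusters is 0. **F1** against an empty bicluster sample set is 0, so
the max over biclusters is always defined. **Pearson** correlation is
used for robustness summaries (between initial K, recovered K, CE); a
constant input is signalled with a warning and `NA`.

**Thresholding.** Membership is `|loading| > theta * scale(factor)`. The
scale rule is per-column maximum absolute value by default: it is
invariant to the arbitrary per-factor rescalings that different
factorisation models produce. The rule is pluggable (`"matrix-max"`,
`"column-norm"`) because reasonable alternatives exist; all satisfy the
monotone-support property (raising theta never adds a member), which the
suite fuzz-tests. Absolute values are compared, so negative loadings
count as members — membership is about magnitude, not direction. Binary
0/1 loading matrices (methods that only return memberships) are detected
and passed through untouched.

**Enrichment.** One-tailed hypergeometric p-values (`phyper`), verified
against direct summation of the mass function to relative error 1e-10.
Benjamini–Yekutieli adjustment is applied *jointly across all
(bicluster, pathway) tests* in `pathway_enrichment_proportion()` —
one evaluation call is one family — but *per knockout, across its own
pathways* in `knockout_biclustering_score()`, the narrower family
matching the per-knockout question; both choices are recorded in the
result's `adjust_family` attribute. Ties (best-F1 bicluster, top-enriched
pathway) break deterministically by lowest index / id order.

## What the tests do and do not show

The suite (and `scripts/acceptance.R`) verifies: closed-form and
Monte-Carlo moments of the generator's distributions (1e6 draws, three
standard errors); exact metric values on constructed cases; equality of
the assignment-based CE with a brute-force oracle; the end-to-end
round trip simulate → indicator factorisation → threshold at 0.01 →
CE = 1 on a noiseless base-scale dataset (100 x 1000, K = 20); and
null-rate behaviour of the enrichment scores on random biclusterings
(20 seeds). Unit-test simulations use deliberately small grids (tens of
samples, 50–1000 genes) — large enough to exercise every code path and
keep Monte-Carlo tolerances honest, small enough that the whole suite
runs in well under a minute.

Passing these tests shows the machinery is correct; it does not show that
any particular biclustering algorithm will do well on real data, nor that
the simulator's noise matches any given RNA-seq protocol.

## Known limitations

* `|U|` uses dense per-cell coverage counts (`n x p` integers): fine at
  the package's desk scales, wasteful beyond ~10^7 cells.
* The simulator implants contiguous blocks; scattered-membership
  biclusters are representable (`bicluster()` takes arbitrary index
  sets) but not generated.
* Library-size normalisation is limited to `log1p_transform()` and
  `quantile_normalise_genes()` (rank-to-normal, average ties);
  median-of-ratios size factors are out of scope.
* No wrappers for external biclustering algorithms are included;
  factorisations enter as loading-matrix files.
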
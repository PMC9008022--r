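---
title: "Confused cell identity: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confused cell identity: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cciscore)
```

## The model

Esophageal squamous epithelium is maintained by three transcriptional
populations — basal stem cells (BS), proliferating basal keratinocytes (BK)
and differentiated keratinocytes (DK). A cell's relationship to the three
lineages is summarized by the triple of signature scores `(a, b, c)`, where
each score is the arithmetic mean of the normalized expression of that
lineage's signature genes in the cell. Two derived quantities are computed
from the triple:

1. **Barycentric coordinates** `(a, b, c) / (a + b + c)` place the cell
   inside the BS–BK–DK simplex for ternary maps. The axis order is fixed as
   (BS, BK, DK) = (a, b, c) in every function and output file.
2. **The CCI score.** With the origin as the common vertex, the angle
   between each axis and the segment to the point `(a, b, c)` has cosine
   `coordinate / sqrt(a² + b² + c²)` (the law-of-cosines expression
   simplifies to this because the axes are orthogonal). The CCI score is
   `f / sd(cosθ1, cosθ2, cosθ3)`. Cells expressing one program dominantly
   have spread cosines and a low score; cells expressing all three equally
   have nearly equal cosines and a high score. The score depends only on
   the direction of `(a, b, c)`, so it is invariant to any common rescaling
   of the three signature scores and symmetric under axis permutation.

Assumptions worth keeping in mind: the three signature scores must be on a
common, nonnegative scale (the package scores all three from the same
normalized matrix); the score says nothing about malignancy per se — it
measures co-expression of the three programs, and its interpretation as a
malignant state rests on the biology of the cohort being scored.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `f` | 10 | display scale of the CCI score. No principled value exists; 10 puts typical corner-like cells near 17–30. It cancels out of every rank-based downstream step (cut-point, AUROC, correlations), so it is a convention, not a fitted quantity. |
| `epsilon` | 1e-6 | floor on `sd(cos)`; caps the score at `f/epsilon` for exactly-central directions instead of dividing by zero. |
| `sd_mode` | `"sample"` | n−1 denominator over the three cosines. `"population"` (n denominator) rescales every score by √(3/2) and changes nothing downstream. |
| QC bounds | 200 / 7500 genes, 20% mito, 3 cells | the exclusion rules are strict inequalities ("lower than", "higher than"): a cell with exactly 200 or 7500 detected genes survives. Mitochondrial genes are recognized by a configurable, case-insensitive id prefix (`"MT-"`). |
| marker thresholds | logFC ≥ 0.25, pct ≥ 0.25, BH p < 0.05 | one-vs-rest marker calling. Fold change is natural-log by default (`logfc_base = 2` switches). |
| `max_pct2` | 0.4 | lineage-signature selection keeps markers detected in under 40% of out-group cells (strict). |
| CCI-gene thresholds | logFC > 0.25, base-mean > 0.8, pct.1 > 0.8 | all strict. A 0.2 fold-change variant exists in the literature this follows; pass `min_logfc = 0.2` to use it. Base-mean is computed on the lognorm scale (configurable judgment call; the count scale would weight highly expressed genes more). |
| cut-point background | all squamous cells below the cut | the comparison population for CCI signature genes. A malignant-only background is available via the pipeline's `background = "malignant_only"` option. |

## Marker-test details

The rank-sum p-value is computed exactly (via the Wilcoxon distribution)
when both groups have fewer than 20 observations and the combined sample is
tie-free, and otherwise by the normal approximation with tie correction and
continuity correction. Fold change is
`ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))` — pseudocount 1 on
the un-logged scale, the convention of the standard single-cell toolkits —
and "detected" means expression strictly above zero on the lognorm layer.
BH adjustment is applied within each group's tested genes. The test suite
checks all of this against an independent brute-force implementation built
on `stats::wilcox.test`.

## The positivity cut-point

The cohort cut-point is found where the empirical CDF of CCI scores first
crosses, from above to below, a two-parameter logistic curve fitted to
(score, ECDF) by binomial-family maximum likelihood. The rationale: over
the lower component of a two-component mixture the empirical mass
accumulates faster than any single logistic can, so ECDF > fitted there;
the first drop below the fit marks the transition into the inter-component
valley. Two numerical choices matter:

* **Noise band.** A crossing is trusted only where the deviation exceeds
  `max(1e-3, 1.36/√n)` on both sides — the second term is the large-sample
  95% Kolmogorov–Smirnov band. A score sample that is itself
  logistic-shaped stays inside the band and produces an error rather than
  an arbitrary threshold; the error asks the caller to inspect the
  distribution.
* **Fitting axis.** The CCI score is the reciprocal of a dispersion, so its
  upper component is strongly right-skewed; on the raw axis a logistic
  cannot track both components and the crossing lands inside the upper
  component's tail. `transform = "log"` fits on the log-score axis, where
  the two components have comparable scale, and maps the cut-point back
  through the monotone transform. The pipeline uses the log axis for CCI
  scores; the identity axis remains the default for generic scores and
  preserves exact translation equivariance.

The cut-point is interpolated linearly between the two bracketing grid
points of the sign change. Cells strictly above it are CCI-positive.

## Survival cut-points

`maxstat_cutpoint()` scans every distinct score between the 10% and 90%
score quantiles and keeps the split maximizing the absolute standardized
log-rank statistic, breaking ties toward the median. Because the split is
chosen to maximize the statistic, the naive log-rank p-value at the
selected cut-point is anti-conservative; the package reports it as
descriptive ("post-selection") and the test suite demonstrates the
inflation under a null simulation. Survival times are carried through in
their input units; no conversion is attempted.

## What the synthetic cohort does and does not emulate

`generate_cohort()` draws negative-binomial counts
(variance = μ + μ²·dispersion) with a lognormal per-cell library factor and
independent dropout. Defaults and their reasons:

* 200 cells per pure population, 300 confused cells, 2000 genes, 25 genes
  per lineage signature — a desk-scale cohort that runs in seconds.
* `effect = 1.5`: each pure population's own signature genes are lifted by
  e^1.5 ≈ 4.5×, a strong but realistic lineage program.
* `confusion = 0.6`: confused cells express all three programs at
  e^(0.6·1.5) ≈ 2.5×, i.e. clearly on but below the pure level ("at
  slightly lower levels"). Each confused cell draws its own level
  (lognormal jitter, sd 0.15); the top half of draws is labeled stage
  II/III, so a CCI–stage association is built in and testable.
* signature-gene baseline means are drawn in [0.3, 0.6] — low enough that
  out-group detection stays below the pct.2 < 0.4 selection bound.
* malignant-only genes have a near-silent baseline (mean 0.045, under 5%
  detection) and are lifted by `exp(cci_effect_scale · effect)` with
  `cci_effect_scale = 3` in confused cells. A single `exp(effect)` lift
  cannot take a gene from <5% detection to the >80% detection the CCI-gene
  thresholds require, so the malignant program gets its own gain; at
  `effect = 0` it vanishes with everything else, preserving the null.
* `nb_dispersion = 0.3`, `dropout = 0.05`, `libsize_sigma = 0.2`: typical
  droplet scRNA-seq magnitudes.

Not emulated: batch effects, doublets, ambient RNA, realistic signature
sizes (real lineage signatures run to hundreds of genes), gene–gene
correlation beyond the planted programs, and — importantly — the degree of
centrality of real tumors. Synthetic confused cells sit nearly exactly on
the centroid direction (median CCI ≈ 114 at `f = 10`), whereas real ESCC
cohorts show tumor medians around 3–4× `f`. A green end-to-end test
therefore establishes that the machinery recovers planted structure under
its own assumptions, not that real tumors will separate this cleanly.

## Degenerate inputs and tie-breaks

Negative signature scores (possible on centered external data) are clipped
to zero before projection and scoring; observations that are all-zero after
clipping are flagged `degenerate`, excluded from maps and from the
cut-point fit, and carried as `NA` rather than guessed. Equal cosines give
`sd = 0` and the capped score `f/epsilon`. In `maxstat_cutpoint()`,
candidate splits where one side has no events are skipped; ties in the
maximal statistic resolve toward the median score.

## Known limitations

* The cut-point construction assumes a two-component score distribution;
  unimodal cohorts correctly error rather than yield a threshold.
* The CCI signature background ("other squamous epithelium") mixes normal
  and sub-threshold malignant cells by default; with very impure cohorts
  the malignant-only background option is more appropriate.
* `export_ternary_density()` uses a product Gaussian kernel in the 2-D
  embedding; densities near the simplex edges lose the kernel mass that
  falls outside and are mildly underestimated.
* The maximally selected cut-point p-value is not corrected for selection.
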
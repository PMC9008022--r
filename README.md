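# cciscore

Quantifying **confused cell identity (CCI)** in esophageal squamous cell
carcinoma (ESCC) transcriptomes.

Normal esophageal squamous epithelium contains three transcriptional
populations: basal stem cells (**BS**), transient proliferating basal
keratinocytes (**BK**) and postmitotic differentiated keratinocytes
(**DK**). When cells or bulk samples are scored against the three lineage
signatures and projected onto a BS–BK–DK ternary map, normal cells sit at
the corners while malignant ESCC cells crowd the centroid: they express all
three lineage programs at once, at moderately reduced levels — a "confused"
identity. This package turns that qualitative picture into numbers and
provides the downstream statistics used to relate them to tumor stage and
survival.

## The score

For an observation with signature-score triple (a, b, c) — the mean
normalized expression of the BS, BK and DK signature genes —
the cosine of the angle between each axis and the segment from the origin
to the point (a, b, c) is

    cos θk = coordinate_k / sqrt(a² + b² + c²),   k = 1, 2, 3

and the CCI score is

    CCI = f / sd(cos θ1, cos θ2, cos θ3)

with `f` a display constant (default 10) and `sd` the sample standard
deviation. At a corner the cosines are (1, 0, 0) and the score is minimal
(f/0.577 ≈ 17.3); toward the centroid the three cosines converge and the
score grows, capped at `f/ε` (ε = 1e-6) for the exactly central direction.

Around that core the package implements:

* **io_and_qc** — 10x-style MatrixMarket / dense-table readers and writers,
  GMT gene-set IO, single-cell QC (cells with fewer than 200 or more than
  7,500 detected genes, or more than 20% mitochondrial counts, removed;
  genes detected in fewer than 3 cells removed), library-size + log1p
  normalization.
* **lineage_signatures** — one-vs-rest marker calling (Wilcoxon rank-sum,
  log fold change ≥ 0.25, detection fraction ≥ 0.25, BH-adjusted p < 0.05),
  lineage-signature selection at pct.2 < 0.4, cross-cohort stage-progression
  signatures.
* **cci_core** — signature scoring, barycentric ternary projection, the CCI
  score, the cohort positivity cut-point (first robust crossing of the
  score ECDF below its fitted binomial-ML logistic curve), CCI signature
  genes (fold change > 0.25, base-mean > 0.8, pct.1 > 0.8), ternary kernel
  density export.
* **association_stats** — score–signature correlation, two-group tests,
  hypergeometric gene-set overlap, maximally selected log-rank survival
  cut-points, Kaplan–Meier / log-rank stratification.
* **synthetic_data** — a negative-binomial scRNA-seq cohort generator with
  three pure corner populations, a confused malignant population, planted
  malignant-only genes, dropout, library-size variation and stage labels,
  so the whole pipeline runs and validates without any download.
* **cli** — `simulate`, `pipeline`, `survival`, … subcommands
  (`exec/cciscore`), a flat key=value config format, and a JSON run summary.

## Worked example

```r
library(cciscore)
co  <- generate_cohort(cohort_spec())        # 900 cells x 2000 genes, seed 1
m   <- lognormalize(qc_filter(co$matrix))
tab <- cci_table(m, co$truth$signatures[c("BS", "BK", "DK")])
pop <- co$truth$population[m$obs_ids]
round(tapply(tab$cci, pop, median), 1)
#>       BK       BS confused       DK
#>     28.5     30.5    113.9     30.9
cut <- cci_cutpoint(tab$cci, transform = "log")
cut$cutpoint
#> 68.84
positive <- tab$cci > cut$cutpoint
sum(positive)
#> 264 of 900 cells are CCI-positive
sig <- cci_signature_genes(m, tab$obs_id[positive], tab$obs_id[!positive])
sig
#> SignatureSet 'CCI': 30 genes (gene0090, gene0104, gene0077, ...)
```

The three pure populations score ~29–31 (their cosine triples are spread:
one large, two small), while the confused malignant population scores ~114
(its cosines are nearly equal). The cut-point at 68.8 calls 264 cells
CCI-positive — against the planted truth of 300 confused cells that is
precision 0.99 and recall 0.87 — and the CCI signature recovers all 30
planted malignant-only genes.

The same scoring applies to bulk cohorts: read a normalized matrix with
`read_matrix(..., "dense_table")`, score with `cci_table()`, and stratify
survival with `maxstat_cutpoint()` + `km_logrank()`.

## Command line

```sh
exec/cciscore simulate --outdir sim --seed 1
exec/cciscore pipeline --matrix sim/matrix --metadata sim/metadata.tsv \
    --outdir out --seed 1
exec/cciscore survival --input cohort_survival.tsv --outdir out
```

`pipeline` writes `cci_table.tsv` (per-cell scores, cosines, positivity),
`markers.tsv`, `signatures.gmt`, `cci_signature.gmt` and
`run_summary.json` under `--outdir`.

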
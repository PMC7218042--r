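# sirtagree

Inter-observer agreement analysis for Y-90 SIRT voxel dosimetry.

## The problem

In selective internal radiation therapy (SIRT) of hepatocellular carcinoma
with Y-90 microspheres, post-treatment PET/CT dosimetry yields four
quantities per treatment: tumor volume (TV, ml), total liver volume (TLV,
ml), mean tumor dose (TD, Gy) and mean healthy-liver dose (THLD, Gy), with
the non-tumoral volume THLV = TLV − TV. TD predicts response and THLD
predicts toxicity, but both depend on manual segmentation — so two readers
of the same scan report different doses, and sometimes different clinical
decisions. `sirtagree` is for medical physicists and biostatisticians who
want to quantify that inter-observer component: it implements the full
multi-reader agreement battery, a calibrated synthetic-cohort generator with
known ground truth, and a voxel-phantom pipeline that propagates
segmentation perturbations into dose variability mechanistically.

## What it computes

For a cohort of n treatments each read by k observers:

- **ICC(A,1)** — two-way random-effects, absolute-agreement, single-rater
  intraclass correlation with F-based 95% CI, three-way and pairwise;
- **pairwise CV** — root-mean-square within-pair coefficient of variation,
  `100 * sqrt(mean((|x−y|/√2 / ((x+y)/2))²))` %;
- **Bland-Altman** — bias and limits of agreement at bias ± 2 SD;
- **RDC** — the reproducibility coefficient, the maximum ratio between the
  k readers' values expected in 95% of cases:
  `RDC = exp(q₀.₉₅ · σ̂_w)`, where σ̂_w is the within-treatment SD of the
  log readings (one-way variance components) and q₀.₉₅ the 95th percentile
  of the range of k iid standard normals (3.31449 for k = 3); bootstrap CI;
- **location tests** — Shapiro-Wilk-gated paired t / two-way ANOVA or
  Wilcoxon signed-rank / Friedman;
- **threshold concordance** — the fraction of treatments classified
  differently by the observers against the clinical targets TD > 200 Gy,
  THLD < 50 Gy, THLD < 75 Gy.

The phantom layer builds 3-D activity maps (ellipsoidal liver, spherical
tumors, optional PET blur), computes voxel dose by the Y-90 local-deposition
method (49.3908 J/GBq to complete decay), and emulates observers by
morphological perturbation of the segmentation masks.

## A worked example

```r
library(sirtagree)

cfg <- run_config("table", n_treatments = 25, n_observers = 3,
                  n_bootstrap = 2000, seed = 1)
rep <- run_pipeline(cfg)

rep$quantities$TD$rdc$estimate
#> [1] 1.554325
rep$quantities$THLD$rdc$estimate
#> [1] 1.170785
rep$quantities$TD$icc[["all observers"]]$estimate
#> [1] 0.8954558
sapply(rep$concordance, function(x) x$fraction_discordant)
#> [1] 0.20 0.08 0.08
```

Read: across this simulated cohort the three observers' tumor doses differ
by up to a factor 1.55 in 95% of treatments, but healthy-liver doses only by
1.17 — tumor dosimetry is markedly less reproducible than healthy-liver
dosimetry, which the three-way ICCs echo (TD 0.90 vs THLD 0.99 here). At the
TD > 200 Gy efficacy target, 20% of treatments (5/25) would be classified
differently depending on who performed the dosimetry; at the THLD < 50 Gy
safety target, 8% (2/25).

A voxel-level run replaces `"table"` with `"phantom"`; a thin CLI with
`simulate` / `phantom` / `analyze` / `all` subcommands is installed at
`inst/cli/sirtagree`.

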
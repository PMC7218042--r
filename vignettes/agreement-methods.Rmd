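---
title: "Methods: inter-observer reproducibility of Y-90 SIRT dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-observer reproducibility of Y-90 SIRT dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtagree)
```

## The problem

After transarterial radioembolization of hepatocellular carcinoma with
Y-90-loaded glass microspheres, post-treatment PET/CT allows voxel dosimetry:
the mean absorbed dose to the tumor (TD, Gy) predicts response, and the mean
dose to the non-tumoral ("healthy") liver (THLD, Gy) predicts toxicity. Both
depend on manual or semi-automated segmentation of the tumor volume (TV, ml)
and total liver volume (TLV, ml), with the non-tumoral volume obtained by
subtraction, THLV = TLV − TV. Different readers contour differently — the
tumor boundary especially, where misregistration between the contrast CT and
the PET/CT must be corrected by hand — so the clinically reported doses carry
an inter-observer component of uncertainty. This package quantifies that
component with the standard agreement battery and lets you study, on
synthetic data with known ground truth, how segmentation variability
propagates into dose variability and into discordant clinical decisions.

## The measurement model

Readings are modelled as log-normal with a multiplicative observer error.
For quantity $q$, treatment $i$ and observer $j$:

$$x_{ijq} = \exp\!\left(\mu_q + B_{iq} + b_{jq} + \epsilon_{ijq}\right),
\qquad B_{iq}\sim N(0,\sigma^2_{b,q}),\quad
\epsilon_{ijq}\sim N(0,\sigma^2_{w,q}).$$

The patient effect $B$ carries the (large) between-patient spread, $b_j$ an
optional fixed per-observer bias (default 0), and $\epsilon$ the
inter-observer measurement error. A multiplicative model is the natural
companion of the reproducibility coefficient, which is a max/min *ratio*
statistic, and of strictly positive, right-skewed clinical quantities. The
data-generating distribution of real observer error is not known; log-normal
is this package's working assumption and is stated as such.

Quantities are simulated independently per $q$: no joint covariance between,
say, the TV error and the THLD error is imposed, because no such covariance
is published — even though a mechanistic link exists (the healthy-liver dose
is influenced by the tumor delineation, since THLV is obtained by
subtraction). The voxel phantom layer (below) does reproduce that coupling
mechanistically.

### Default calibration

`default_cohort_model()` matches the marginal mean ± SD of a published
25-treatment, 3-observer glass-microsphere HCC series
(TLV 1749 ± 507 ml, THLD 45.3 ± 30.2 Gy, TV 179 ± 208 ml, TD 238 ± 120 Gy)
by solving, per quantity, $\sigma^2_{tot} = \log(1 + s^2/m^2)$ and
$\mu = \log m - \sigma^2_{tot}/2$, then splitting
$\sigma^2_{tot} = \sigma^2_b + \sigma^2_w$ with fixed observer-error SDs

| quantity | $\sigma_w$ (log) | implied pairwise CV | implied RDC (k = 3) |
|---|---|---|---|
| TLV  | 0.02 | ~2 %  | 1.07 |
| THLD | 0.05 | ~5 %  | 1.18 |
| TV   | 0.18 | ~18 % | 1.82 |
| TD   | 0.14 | ~14 % | 1.59 |

These $\sigma_w$ values reproduce the study's *ordering* — tumor quantities
markedly less reproducible than whole-liver ones, and RDC(TD) ≈ 1.5-1.6
against RDC(THLD) well below it. They cannot simultaneously reproduce the
published TD CV range (20-27 %) and the published RDC of 1.52: under a pure
log-normal error model CV ≈ 100·σ_w, and the published pair is internally
heterogeneous because the real TD errors are heavy-tailed ("large variations
in a limited number of patients"), which inflates an RMS CV more than a
variance-component RDC. The defaults favor consistency with the RDC, the
quantity this package treats as primary; they are documented as calibration,
not as estimated truth.

### Degenerate draws

TV and TLV are drawn independently, so a draw can produce a tumor at least
as large as its liver. Such a treatment is redrawn wholesale — patient
effects and all observer errors — with a warning, up to 100 times, then the
generator fails declaring the parameters incompatible. The redraw is at the
treatment-block level rather than per row because the violation is almost
always driven by the between-patient draws, which a row-level redraw of the
small observer error cannot repair. Under the default calibration a redraw
occurs in roughly 1 % of treatments; the induced truncation of the joint
(TV, TLV) distribution is negligible at that rate.

## The voxel phantom layer

`build_phantom()` realizes an ellipsoidal liver (default ~1.68 L) with
spherical tumors inside it on a (z, y, x) voxel grid, 4 mm isotropic by
default — the grid of clinical Y-90 PET reconstructions. The injected
activity (default 1.98 GBq) is partitioned with each tumor voxel receiving
`uptake_ratio` (default 4) times the weight of a non-tumor liver voxel, and
normalized so the grid sums to the injected activity exactly. An optional
isotropic Gaussian blur (separable shift-and-add convolution, kernel
truncated at ±3 SD and renormalized so total activity is conserved exactly)
emulates PET resolution; default FWHM 8 mm where enabled. Acquisition
physics beyond voxel size and blur — reconstruction, scatter, attenuation,
registration — is out of scope.

Dose comes from the **local-deposition method**: every decay deposits its
mean beta energy in its own voxel, so
$D = k\,A_{voxel}/m_{voxel}$ with $m_{voxel}$ = density × voxel volume
(density default 1.05 kg/L) and

$$k = E_{mean}\,T_{1/2}/\ln 2
   = 0.9267\ \mathrm{MeV} \times 64.05\ \mathrm{h}/\ln 2
   = 49.3908\ \mathrm{J/GBq},$$

pinned as `y90_energy_per_gbq()` and verified in the tests against numeric
integration of $A_0 e^{-\lambda t}E_{mean}$ over all time. Energy is
conserved voxel-for-voxel by construction; the test suite checks
$\sum D\,m = k \sum A$ to a relative 1e-9. The lung shunt fraction is fixed
at 0 % — all activity is hepatic — since a constant shunt cannot contribute
to inter-observer variability.

Observer segmentations are emulated by `perturb_mask()`: a deterministic
morphological margin (6-connected dilation or erosion, implemented as
zero-padded array shifts and cross-checked against a brute-force
neighborhood-scan oracle) followed by seeded Bernoulli flips of boundary
voxels, then re-clipping of tumors into the observer's liver. Volumes are
voxel count × voxel volume with no partial-volume weighting, matching the
granularity of slice-wise manual contouring; non-enhancing tumor subregions
are not modelled separately, so a tumor mask is a single region by
construction. In `simulate_phantom_cohort()` the tumor masks get
per-observer systematic margins (default 0, +1, −1 voxels) plus a 0.3
boundary-flip probability while liver masks get flips only (0.05): tumor
delineation is where readers genuinely differ, liver segmentation being
semi-automated. The phantom cohort enables blur by default because without
a dose gradient at the tumor rim, contour changes would barely move TD.

## The agreement battery

* **ICC** — two-way random effects, absolute agreement, single rater
  (ICC(A,1)). The variant is a design choice: the observers are a sample of
  possible readers, and systematic offsets between readers matter clinically,
  so they must count against agreement. The variant label travels inside
  every `icc_result` so alternates can be compared. The 95 % CI is the
  F-based interval with Satterthwaite degrees of freedom; n < 5 flags the
  interval unstable.
* **Pairwise CV** — root-mean-square within-pair CV,
  $100\sqrt{\mathrm{mean}_i\,(s_i/m_i)^2}$ with $s_i = |x_i-y_i|/\sqrt2$.
  Chosen (the formula being unspecified in the source literature) as the
  standard test-retest CV for ratio-scale data; scale-invariant.
* **Bland-Altman** — bias, SD of differences, and limits bias ± **2** SD.
  The multiplier is exactly 2, matching the figure convention of the
  reproducibility literature this package follows, not 1.96.
* **RDC** — the maximum ratio between the k readers' values expected in
  95 % of cases. Estimated on the log scale: the within-treatment SD
  $\hat\sigma$ is the square root of the one-way residual mean square
  (treatments as random blocks), and
  $\mathrm{RDC} = \exp(q_{0.95}\hat\sigma)$ where $q_{0.95}$ is the 95th
  percentile of the range of k iid standard normals, computed by numeric
  quadrature of the range CDF (3.31449 for k = 3; for k = 2 the quadrature
  reproduces the closed form $\sqrt2\,\Phi^{-1}(0.975)$ to 1e-8). The
  empirical per-treatment max/min percentile is kept as a cross-check in the
  tests, never as the estimator. The CI construction for the RDC is not
  standardized; this package uses a seeded nonparametric bootstrap over
  treatments (rows), percentile method, B = 2000 by default.
* **Location tests** — a Shapiro-Wilk gate per observer column at α = 0.05
  chooses, per quantity, paired t + additive two-way ANOVA (observer-effect
  p) or Wilcoxon signed-rank + Friedman. The ANOVA is additive because with
  one reading per cell the interaction is inestimable. Pairs with all-zero
  differences are flagged degenerate instead of carrying a p-value; a
  constant nonzero difference takes the infinite-t limit (p = 0). Pairwise
  p-values are reported raw — no multiplicity correction by default, with a
  Bonferroni adjustment left to the user — because raw pairwise p-values are
  what reproducibility studies in this area report.
* **Concordance** — each treatment is classified per observer against the
  clinical targets TD > 200 Gy (efficacy), THLD < 50 Gy and THLD < 75 Gy
  (safety); a treatment is discordant when its classifications are not all
  identical. A value exactly at the cutoff counts as *not reached* — a
  deterministic convention; the boundary has probability zero for
  continuous doses.

## Numerical choices and degenerate inputs

* RDC on identical columns returns exactly 1 with a degenerate CI (1, 1);
  non-positive readings are rejected (the log transform requires them).
* ICC on a constant matrix is an error (undefined); identical columns with
  row variation return exactly 1, CI (1, 1).
* The range-distribution quantile is cached per (k, p) within a session.
* THLV consistency on table ingestion is checked to 0.5 ml, the rounding
  granularity of exported volumes; block completeness and positivity are
  hard errors naming the offending row.
* All randomness — cohort draws, mask flips, bootstrap — flows from
  explicit seeds; identical configuration and seed reproduce the JSON
  report byte for byte (the provenance timestamp aside).

## Problem sizes in the test suite

The suite exercises the estimators at the sizes where their sampling error
is well below the assertion tolerances: moment recovery at n = 10 000
treatments, RDC versus the empirical ratio percentile at n = 10 000 with a
$10^7$-draw Monte-Carlo for the range quantile, ICC recovery at n = 500 over
50 seeds, Bland-Altman coverage at n = 100 000 differences, and the
tumor-versus-liver ordering (RDC(TD) > RDC(THLD), CV(TV) > CV(TLV)) over 100
end-to-end n = 25 pipeline runs. Phantom checks use 32-48 voxel grids, which
already contain the full geometry (liver, tumor, boundary) at lower cost
than the clinical 144-169 voxel matrices.

## What passing tests do and do not show

The generator emulates the *statistical structure* the analysis assumes —
complete blocks, log-normal spread and error, noisier tumor quantities —
with known truth, so the tests demonstrate estimator correctness and
recovery. They do not demonstrate anything about real readers: real observer
error is heavy-tailed in the highest-dose lesions, correlated across
quantities through the shared tumor contour (only the phantom layer
reproduces this), and possibly experience-dependent. Cohort-level numbers
from the original 25-treatment series cannot be reproduced exactly because
the per-patient readings were never published; the package targets the
reproducible properties instead: orderings, null limits, identities, and
parameter recovery.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config("table", n_treatments = 25, n_observers = 3,
                  n_bootstrap = 2000, seed = 1)
rep <- run_pipeline(cfg)
rep$quantities$TD$rdc$estimate      # ~1.55
rep$quantities$THLD$rdc$estimate    # ~1.17
rep$concordance[[1]]                # discordance at TD > 200 Gy
```
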
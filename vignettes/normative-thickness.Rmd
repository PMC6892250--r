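---
title: "Methods: normative modeling of visual-area cortical thickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative modeling of visual-area cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thicknorm)
```

This vignette is the package's account of its statistical methods: the
models it fits, the assumptions they rest on, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where more than one
reasonable convention exists.

## The analysis in one paragraph

Per-vertex cortical thickness maps (mm) on a common surface mesh are
reduced to a subjects × areas table by pooling, for each of 25
retinotopic visual areas, the non-missing vertices of both hemispheres
under a maximum-probability-map (MPM) labeling. Each area's
across-subject distribution of mean thickness is then summarised by a
Gaussian normative model; the table of per-area `(mu, sigma)` is the
deliverable against which new individuals are z-scored. Around that
core sit four secondary analyses: the inter-areal correlation matrix
and its cluster tree (is the thickness hierarchy a subject-level
phenomenon?), hemispheric agreement and bias (are left and right more
alike within a person than between people, and which areas are
lateralised?), a demographic mixed ANOVA with an age-slope estimate,
and a leave-p-out reliability bound on each regional mean.

## Normative model and its assumptions

For area $a$, subject means are modelled as
$m_{s,a} \sim \mathcal{N}(\mu_a, \sigma_a^2)$, with $\mu_a$ and
$\sigma_a$ estimated by the sample mean and the $n-1$ sample SD
(maximum likelihood up to the $n/(n-1)$ factor; the estimator choice is
ours, as only "a Gaussian fit" is specified by convention in this
literature). The model is unconditional: no age or gender terms enter
the normative parameters, because the age effect (~0.002 mm/yr over a
16-year age range) is an order of magnitude below $\sigma_a$
(0.10–0.20 mm) and gender shows no effect. Users needing
age-conditioned references should regress before scoring.

Two fit diagnostics are attached per area:

* **Binned R²** — the data range is split into `n_bins` equal bins
  (default 100); the empirical density `count/(n·width)` is compared to
  the model density, and $R^2 = 1 - SS_{res}/SS_{tot}$ over bins with
  $SS_{tot}$ about the mean empirical density. The model density is the
  Gaussian bin probability divided by the bin width (CDF differences)
  rather than a midpoint evaluation: at 100 bins the two differ little,
  but CDF differences are exact for the binned model and are the
  default; `midpoint = TRUE` exposes the variant for sensitivity
  checks. The bin range is the data min/max. With 100 bins this
  statistic needs on the order of a thousand subjects to be
  informative (≈10 observations per bin); for small cohorts, pass a
  smaller `n_bins`.
* **Anderson–Darling under FDR** — the composite-normality case
  (parameters estimated, small-sample-adjusted p), as implemented in
  `nortest::ad.test()`, with Benjamini–Hochberg adjustment across
  exactly the areas tested. An area is "normal" when its adjusted p is
  at or above `alpha` (default 0.05). The composite case is the correct
  one when `mu`/`sigma` come from the same sample; which case the
  field's informal usage intends is rarely stated, so this choice is
  recorded here.

Z-scoring is a pure lookup: $z = (m - \mu_a)/\sigma_a$ against either a
freshly built table or the packaged reference
(`reference_normative_table()`, 25 areas from a 960-subject healthy
young-adult cohort).

## Area assignment and aggregation

`build_mpm()` implements thresholded argmax: a vertex joins the area
with the highest probability when that probability strictly exceeds
`max(0, min_prob)`; ties break to the lowest label id, making the
labeling invariant to the order areas are supplied. The full published
atlas-construction selection algorithm is more elaborate; argmax with a
floor is a documented simplification, and `min_prob` (default 0) exposes
the question of whether assignment should be restricted to confidently
visual vertices.

"Mean across both hemispheres" is implemented as vertex pooling, not as
the average of two hemisphere means — the two differ when hemispheres
contribute unequal vertex counts. The choice is testable: the pooled
mean must equal the vertex-count-weighted average of the hemisphere
means to 1e-12, and the test suite asserts exactly that. `sd_within` is
the SD across the pooled vertices with the $n-1$ denominator; we read
the within-subject variability measure as a vertex-wise SD, not a
standard error, consistent with its use as a per-area variability band.
Missing vertices (medial wall/non-cortex) are excluded from every
statistic and never imputed.

## Similarity clustering

The subjects × areas table of pooled means yields pairwise Pearson
correlations (pairwise-complete over subjects). Clustering uses
distance $d = 1 - r$ with complete ("fully connected") linkage; flat
clusters come from cutting at the 50th percentile of the 24 merge
heights (linear-interpolation percentile). Neither the distance nor the
linkage is forced by the method's name alone; complete linkage is the
reading of "fully connected", and `distance = "neg_r"` exposes the
alternative convention of clustering on $-r$. Note a structural fact
about percentile cuts used by the tests: with five latent groups, most
merges are within-group, so the median height falls among them and the
flat clusters at that cut are finer than the groups; the tree itself
still separates the groups exactly (cutting to $k = 5$ recovers them),
and no flat cluster mixes the dorsal and ventral streams.

## Hemispheric agreement and bias

ICC is fixed to the two-way random, absolute-agreement, single-measure
form ICC(A,1),
$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)},$$
computed from two-way ANOVA mean squares. *Within-subject* agreement
takes subject × area rows with L/R columns, pooled across areas.
*Between-subject* agreement applies the same formula to all
$\binom{n}{2}$ distinct subject pairs per area and hemisphere (columns =
the two subjects' matched-hemisphere values), averaging the left-pair
and right-pair results; the pairing scheme is not canonical, so
all-distinct-pairs — the exhaustive, deterministic option — is
implemented, from accumulated sufficient statistics rather than a
materialised pair table (11.5M rows at n = 960). Pooled rows carry the
between-area thickness differences, which contribute genuine
row-to-row agreement for within-subject pairs but also lift the
between-subject value above what area-wise analysis would give; the
`per_area` option of `icc_within()` exposes the area-wise alternative.

Bias is each subject's left-minus-right pooled mean per area (positive
= thicker left), tested area-wise with one-sample t-tests under BH-FDR;
the effect size is the one-sample Cohen's d (mean difference over the
SD of differences). Effect-size categories follow the convention of the
asymmetry literature this analysis sits in: `medium_to_large` for
$0.3 < |d| \le 0.8$ and `large` above 0.8 — 0.3 is a nonstandard
"medium" anchor, recorded here deliberately.

## Demographic ANOVA and the age slope

The mixed (split-plot) ANOVA treats age in integer years and gender as
between-subject factors and area as the within-subject factor. Because
the design is balanced within subjects (every subject contributes every
area) the strata separate exactly: between-subject effects (age,
gender, age × gender) are tested on per-subject means with type-II sums
of squares (`car::Anova`), and the within stratum reports the area main
effect on subject-centered data with the balanced degrees of freedom
$(k-1)$ and $(n-1)(k-1)$. Area × demographic interactions are not
reported: the generator contains none, and the between-subject effects
are the substantive outputs. Eta-squared is relative to its stratum's
total. The age *slope* is deliberately simpler than the ANOVA: the mean
over areas of the least-squares slope of area mean on age in years
(mm/yr) — age is categorical in the F-test (so nonlinear age profiles
are not assumed away) but numeric for the slope.

The within-SD ANCOVA models `sd_within` with the mean-thickness
covariate entered first (it is the "controlling for" variable), then
area, then subject, with sequential sums of squares and subject as a
categorical factor. A subject × area interaction is not estimable with
one observation per cell and is omitted. With subject as a factor its
numerator df is $n-1$; published analyses of this design sometimes show
1 numerator df for the subject term, which would require coding subject
as a single covariate — both readings are possible and the factor model
is the one implemented.

## Leave-p-out reliability

Per subject and area, `n_samples` (default 1,000) draws of
`round(fraction * V)` vertices (default 90%) are taken without
replacement from the pooled vertices and averaged; the 2.5–97.5
empirical percentile span of those means is the reliability estimate
(percentile CI — the plain reading of "the span of the 95% CI over
resampled means"). Implementation note: when `fraction > 0.5` the
complement is drawn and the mean recovered as
`(total − sum(left_out))/m`, which is distribution-identical and much
faster. The independent check is the finite-population closed form
$2 z_{0.975} S \sqrt{(1-f)/(fV)}$: simulated spans agree with it within
15%, and at the default 400 vertices per area per hemisphere and vertex
SDs at or below 0.7 mm every span is far below the 0.1 mm scale of
test–retest measurement error for cortical thickness.

## What the synthetic generator emulates — and what it does not

The generator exists because the analysis's observed phenomena need a
data source with the right joint structure. No published generative
model exists for this design, so the package uses the minimal latent
structure reproducing the phenomena the analysis measures: for subject
$s$, area $a$, hemisphere $h$,
$$y = \mu_a + \beta_{\mathrm{age}}(\mathrm{age}_s - \overline{\mathrm{age}})
 + \sigma_a\left(\sqrt{g}\,u_s + \sqrt{h_a}\,u_{s,grp(a)}
 + \sqrt{1-g-h_a}\,e_{s,a}\right) \pm b_a/2 + \nu,$$
with a global factor ($g$), one factor per anatomical group
(dorsal/ventral/parietal/parahippocampal, fraction $h_a$), independent
area noise scaled so the between-subject SD is exactly $\sigma_a$, a
left/right offset $\pm b_a/2$, and i.i.d. vertex noise
$\nu \sim \mathcal{N}(0, \sigma_{w,a}^2)$. Defaults, chosen once as the
study conditions and not revisited:

| parameter | default | why |
|---|---|---|
| `n_subjects` | 960 | the normative cohort scale |
| twin pairs | 143 MZ + 72 DZ | MZ count from the reference cohort's structure; DZ at half of MZ, a realistic twin-registry ratio (no reference value exists) |
| `age_range` | 22–37, uniform integer years | only the range is known |
| `female_per_male` | 1.17 | the cohort's gender ratio |
| `area_params` | packaged reference $\mu_a, \sigma_a$ | the published per-area parameters |
| `age_slope` | −0.002 mm/yr | the published thinning rate |
| `cluster_model` | global 0.25, each group 0.36 | within-stream correlation ≈ 0.61 vs cross-stream ≈ 0.25; inter-areal correlation magnitudes are published only as a colour matrix, so these are free parameters set to make the dorsal/ventral clusters recoverable |
| `within_subject_sd` | 0.35–0.65 mm by area | vertex-level SDs consistent with within-area variability bands, largest in parahippocampal areas; all below 0.7 mm |
| `hemi_bias` | ±0.03 mm on the 9 lateralised areas | directions follow the reported left-/right-thicker lists; magnitudes are not printed, 0.03 mm gives medium-to-large d at vertex-noise scale |
| `vertices_per_area` | 400/hemisphere | desk-scale runtime with leave-p-out spans well below 0.1 mm |
| `missing_frac` | 0.5 of off-atlas vertices | exercises missing-value handling (medial-wall analogue) |

Twins share an age (they are born together) but are otherwise ordinary
subjects: zygosity has no effect on thickness in the generator, because
the analysis uses twin structure only for selection.

What it does **not** emulate: cortical geometry, curvature or folding
(the "mesh" is a 1-D vertex list with contiguous area blocks); spatial
autocorrelation of vertex noise (real neighbouring vertices are
correlated, so real resampling spans would be somewhat wider than the
i.i.d. prediction); segmentation error; heavier-than-Gaussian tails; or
genuine twin heritability of thickness. Passing tests therefore
certify the statistical machinery — estimators, tests, resamplers,
bookkeeping — under the assumed model, not the behaviour of any
estimator under real cortical data.

## Numerical and degenerate-input choices

* All stochastic functions take explicit integer seeds;
  `withr::with_seed` scopes them so library calls never perturb the
  caller's RNG state. Identical config + seed gives byte-identical
  outputs end to end.
* Thickness is strictly positive; the generator clamps the (≈1e-5
  probability) negative vertex-noise tail at 0.01 mm, a bias of order
  1e-4 mm.
* Degenerate Gaussian fits (all values equal) return `sigma = 0` with a
  flag; `binned_r2` refuses `sigma = 0`; z-scoring refuses a reference
  with `sigma = 0`.
* MPM ties break to the lowest label id; atlas block-boundary vertices
  with probability sums above 1 are renormalised (argmax-preserving).
* The one-per-MZ-pair tie-break retains the lexicographically smaller
  id — no convention dictates which twin to keep, and this rule is
  deterministic. An MZ pair whose other member already failed an
  eligibility criterion triggers no extra exclusion.
* BH adjustment spans exactly the areas tested (normality screen, bias
  tests); `q >= p` and monotonicity hold by construction and are
  asserted.

## Problem sizes in the shipped tests

The test suite favours the smallest sizes at which each property is
identified: moment-recovery and stream-recovery cohorts use 960 × 200
and 300 × 100 (subjects × vertices/area); the reliability acceptance
check runs 100 subjects at the full 400 vertices/area/hemisphere with
1,000 resamples; slope recovery uses five 960-subject cohorts at 50
vertices/area, since vertex count does not enter the slope's
identification. The acceptance script reports quantities at the full
study conditions.

## Known limitations

* The normative model is unconditional Gaussian; no covariate-adjusted
  or non-Gaussian normative families.
* Surface registration is out of scope: all data are assumed to live on
  one common mesh, and the GIFTI reader/writer handles metric and label
  arrays only (ASCII encoding).
* The between-subject ICC's all-pairs construction is one of several
  defensible pairing schemes; alternatives would give different
  numerical values on the same data.
* The cluster tree ships without a bootstrap stability analysis; flat
  clusters at a percentile cut should be read alongside the dendrogram.
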
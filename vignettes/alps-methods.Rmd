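---
title: "Models and methods behind dtialps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dtialps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the forward models, the estimators, the derived clinical scores, the
statistical framework, and the design decisions taken where the methodology
leaves genuine room.

## 1. The signal model and the phantom

Each phantom voxel is a mixture of Gaussian diffusion compartments,

$$S(b, \mathbf{g}) = S_0 \sum_i f_i \exp(-b\, \mathbf{g}^\top D_i \mathbf{g}),$$

with volume fractions summing to one. Fibre compartments are axially
symmetric tensors (default axial 1.7e-3, radial 0.3e-3 mm²/s — typical
3 T white matter); the perivascular compartment is an x-dominant tensor
(axial 1.5e-3, radial 0.2e-3 mm²/s, default fraction 0.1), which encodes
the geometric premise of ALPS: perivascular water at the lateral-ventricle
body moves left–right, orthogonal to the y-oriented SLF and z-oriented
SCR tracts. Background voxels are isotropic at 0.8e-3 mm²/s.

The acquisition preset reproduces a clinical 4-shell scheme: b = 50 s/mm² × 17 directions, 300 × 8, 1000 × 64,
2000 × 64, plus one b = 0. Directions are laid out by a spherical-Fibonacci
spiral: fully deterministic, approximately uniform, and independent of
vendor tables. Noise is Rician (magnitude of a complex Gaussian), default
SNR(b=0) = 30, typical of 3 T diffusion MRI. The noise seed affects only
the signal; the ground truth (per-voxel compartments, mean tensor, ROI
labels) is a pure function of the configuration.

ROI geometry: atlas ROI definitions for ALPS are template-space points
without a canonical radius or shape, and template registration is out of
scope here, so
ROIs are spheres in the phantom's own frame — default radius 2 voxels,
configurable. Because the index is a ratio of ROI means, the shape choice
affects variance, not the expected value. A configurable fraction of ROI
voxels (default 0.2) carries a second, orthogonal fibre bundle holding
0.35 of the white-matter fraction; this is what gives the complexity
metric something real to detect and mirrors the crossing-fibre
contamination the complexity covariate is designed to correct for.

**Two compartment modes.** `compartment_model = "multi"` (default) sums
the compartment exponentials — biophysically honest, but a single tensor
fitted to it at b ≤ 1000 under-reads the mean-tensor diagonals by a few
percent (the log-signal is no longer mono-exponential). The tests measure
this bias (about −3 to −5% on ROI diagonals) rather than hiding it.
`compartment_model = "averaged"` generates each voxel from its single
volume-fraction-weighted mean tensor, making the tensor model exact; the
formula-correctness and round-trip checks run in this mode so that
agreement with the analytic oracle is tested at machine precision, not
confounded with model error.

What the generator does **not** emulate: susceptibility or eddy
artefacts, motion, Gibbs ringing, partial-volume CSF/GM, axonal
undulation, or template-space anatomy. Passing tests therefore show that
the estimators are correct under their stated models — not that ALPS is a
valid glymphatic marker on real data.

## 2. Tensor fit and the ALPS index

The tensor is fitted voxel-wise by log-linear least squares with one
weighted re-fit (weights = squared predicted signal), the standard WLLS
scheme: deterministic and cheap. Only shells with b ≤ `max_b` (default
1000 s/mm²) enter the fit, since the Gaussian tensor model degrades at
high b; shell-selection conventions vary between sites, so the cut-off is
exposed as a parameter. Non-positive signals are clamped at 1e-6·S0
before the log. Non-positive-definite fits are flagged, never altered —
ALPS consumes the raw scanner-frame diagonals (Dxx, Dyy, Dzz), not
eigenvalues, so "repairing" tensors would quietly change the index.

The index itself is

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{xx}^{proj}, D_{xx}^{assoc})}
                      {\mathrm{mean}(D_{yy}^{proj}, D_{zz}^{assoc})},$$

where each term is an ROI mean and the outer means are unweighted
two-term averages of ROI means (the literal reading of the defining
two-argument mean), not pooled-voxel means. It is computed per hemisphere
(hemisphere membership comes from ROI identity, not an x-midline split)
and averaged bilaterally. The analytic oracle `ground_truth_alps()`
applies the same formula to the noiseless mean-tensor diagonals; the
pipeline must and does match it to 1e-6 on noiseless DTI-consistent
phantoms, and ALPS is invariant to uniform diffusivity scaling and to
b=0 padding by construction.

## 3. FODs, fixels and complexity

Clinical pipelines typically use multi-shell 3-tissue CSD and mrtrix
fixel tools. The phantoms contain no grey-matter or CSF partial volume, and the
complexity metric depends only on the white-matter FOD shape, so the
package implements single-shell (default b = 2000), single-tissue CSD:

1. **Response**: signals from single-fibre voxels are rotated to a common
   zenith and projected onto zonal (m = 0) even spherical harmonics.
   At order 16 the zonal expansion reproduces the analytic single-fibre
   profile to better than 1e-6; the working default order is 8.
2. **Deconvolution**: per voxel, the shell signal (b0-normalized) is
   deconvolved with the response by least squares, with an iterative hard
   non-negativity constraint on a deterministic 300-point hemisphere grid
   (amplitudes below 0.1 × the initial mean amplitude are driven to zero;
   the active set is iterated until stable, cap 50).
3. **Fixels**: grid local maxima are found by steepest ascent on a
   k-nearest-neighbour graph (antipodally symmetric metric); each grid
   point drains to its uphill maximum (discrete watershed) and the fibre
   density of a fixel is its lobe's weighted amplitude sum. This replaces
   Bingham lobe fitting with the same lobe-integral quantity, which is all
   the complexity ratio consumes. Peak orientations are refined off-grid
   by Nelder–Mead on the spherical-harmonic amplitude. Peaks below 0.1 ×
   the largest refined peak are discarded, and a voxel whose FOD
   amplitude range is under 10% of its maximum is treated as isotropic
   (no fixels) — without that guard a flat FOD sprouts ripple maxima.

Complexity per voxel, with descending fixel densities $f_1 \ge \dots \ge
f_N$:

$$C = \begin{cases} 0 & N \le 1 \\
\dfrac{N}{N-1}\left(1 - \dfrac{f_1}{\sum_i f_i}\right) & N \ge 2.
\end{cases}$$

Only the metric's behaviour is externally constrained (range [0, 1]; 0
when all fibres share an orientation; larger when the dominant bundle
holds a smaller share); the formula above is the standard fixel-to-voxel
complexity definition and satisfies every required property — including the exact upper bound 1
for equal-density bundles, which the tests assert for N = 2…5. The
subject-level covariate is the mean of the four ROI means; the ROI means
are returned individually so a voxel-pooled alternative can be formed if
preferred.

Recorded resolution limit: with order-8 CSD the two-fixel recovery on
noiseless crossings is reliable for crossing angles ≥ 45°; below that the
lobes merge.

## 4. Derived clinical scores

* **Composite cognition**: z-scored average of MoCA plus one task per
  domain (Stroop colour naming, category fluency, letter fluency, Hooper);
  timed tasks are sign-flipped so higher is better everywhere. The
  z-scoring reference population is a design choice; the default is the
  control group (conventional normative practice), with a
  full-sample option.
* **NPI-4 estimate**: the item mapping from available instruments (HADS
  or PHQ-9, UMPDHQ, UPDRS-I) is site-specific, so the mapping is runtime
  configuration — a list of
  items, each with an ordered field list (first non-missing wins, and the
  provenance of which instrument fed each item is recorded per subject).
* **LBD symptom composite**: severity-aligned z-average of the NPI-4
  estimate, UPDRS-III, DCFS and MoCA (sign-flipped). z-scoring is the default, with a raw-average option since an "averaged"
  composite can be read either way.
* **Vascular risk (0–7)**: count of seven self-reported factors.
* **SVD burden (0–4)**: one point each for ≥1 lacune, ≥1 microbleed,
  basal-ganglia EPVS grade 2–4, and modified Fazekas 2–3.
* **Inclusion filters**: controls with MMSE < 25 are excluded; patients
  more than 10 years from diagnosis (PDD: from the dementia diagnosis)
  are excluded. "Within 10 years" is read inclusively — exactly 10 years
  is retained — and the boundary is a parameter. Filters log every
  exclusion with a rule identifier and are idempotent.

## 5. The statistics layer

All group models run through one least-squares engine (`stats::lm`
underneath) with per-analysis listwise deletion and an explicit error on
aliased designs. The omnibus group test is full-versus-reduced:
$F = \frac{(RSS_r - RSS_f)/\Delta df}{RSS_f/df_f}$, dropping the group
factor from a model that keeps age and sex (and optionally complexity) —
the unique sums-of-squares decomposition for one factor plus covariates.

Planned contrasts are two-group ANCOVAs per pair (matching the "planned
post hoc comparisons" design, and keeping residual variance local to the
pair), with BH-FDR applied jointly across the six pairs. Cohen's d admits several definitions in the ANCOVA setting; the adopted
one is the covariate-adjusted
group-mean difference divided by the pooled residual SD of the two-group
model, with a raw-means option. Simulation tests show the estimator
recovers injected adjusted standardized differences with mean bias under
0.05 at the default cohort's group sizes (1000 replicates), and the omnibus test
holds its nominal 5% size under the global null (2000 replicates,
binomial confidence band).

BH-FDR wraps `stats::p.adjust(method = "BH")` behind input validation and
is tested against a brute-force step-up oracle. VIF is computed from its
definition ($1/(1-R^2_j)$, auxiliary regressions) and cross-checked
against `car::vif`. The hemisphere comparison is a paired t-test with an
explicit guard: identical hemispheres give t = 0, constant non-zero
differences raise the infinite-t error. Nonparametric table tests use
`kruskal.test` / `wilcox.test`, with a hand-implemented Dunn post hoc
(tie-corrected z on joint ranks, BH-adjusted) since no Dunn implementation
ships with the environment.

FDR families are explicit (the six planned pairs form one family; the
regression family is adjusted per covariate set across outcomes), and
outcomes with fewer than 10 complete cases are flagged and kept out of
the family rather than silently adjusted.

## 6. Cohort generator defaults

Group sizes, age structure and sex ratios follow published Lewy-body
imaging cohorts of this design (26 control / 60 PD-NC / 35 PDD / 51 DLB;
ages 66.7 ± 9.3, 63.1 ± 7.3, 69.5 ± 7.8, 72.7 ± 5.5). ALPS group means
are reported in the literature only in arbitrary units, so the defaults
place the groups at 1.496 / 1.500 / 1.420 / 1.319 with a
common residual SD of 0.14 — chosen once so that the implied adjusted
standardized differences reproduce the reported effect-size ordering
(control ≈ PD-NC > PDD > DLB, with the largest gap for DLB vs PD-NC).
Clinical columns (MoCA, MMSE, UPDRS-III) use group means/SDs typical of
such cohorts. Covariate effects on ALPS (`beta_age`, `beta_sex`) default to
zero and are switched on explicitly in simulations that need them.

## 7. Numerical choices and problem sizes

* Tensor design is shared across voxels; its QR factorization is reused,
  and one WLLS pass (not iterated) keeps the fit deterministic.
* CSD constraint grid: 300 hemisphere points; fixel neighbour graphs are
  cached per grid size. Peak refinement uses Nelder–Mead with relative
  tolerance 1e-10.
* Test phantoms use a 20 × 12 × 8 grid with radius-2 ROIs (~33 voxels
  each); the hemisphere-agreement check uses radius-3 ROIs (~120 voxels),
  the scale at which the ROI-mean noise floor at SNR 30 sits comfortably
  below the 2% band being tested. Simulation suites use 1000 replicates
  for estimator recovery and 2000 for test size; these sizes give Monte
  Carlo error well inside the asserted tolerances.
* All simulation entry points take explicit integer seeds; identical
  configuration plus seed is bit-reproducible, which the tests assert.

## 8. Known limitations

* The complexity pipeline is single-shell single-tissue by design; it is
  not a reimplementation of multi-shell 3-tissue CSD and will differ on
  real data with partial-volume effects.
* The multi-compartment tensor bias (section 1) means phantom ALPS from
  the default mode sits a few percent below the analytic oracle at
  b ≤ 1000; this is a property of the DTI model itself, and is measured,
  not corrected.
* Template-space ROI coordinates from the atlas literature are carried as
  documentation only; nothing here performs registration, so they are usable only on
  maps already in that template space.
* The statistics layer is cross-sectional: no mixed models, no
  longitudinal structure.
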
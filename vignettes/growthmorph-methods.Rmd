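---
title: "Longitudinal tensor-based morphometry with growthmorph: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal tensor-based morphometry with growthmorph: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthmorph)
```

## The problem

Early brain development in infants at familial risk of autism spectrum
disorder (ASD) is characterised not by a volume difference at any single
age but by group differences in the *growth trajectory* between roughly 6
and 24 months. Tensor-based morphometry (TBM) turns this into a voxel-wise
question: nonlinear registration maps every scan into a common reference
anatomy, and the local volume ratio between native anatomy and reference —
the Jacobian determinant of the deformation — becomes the response
variable of a longitudinal regression.

growthmorph implements that whole chain at desk scale: two-channel
(T1/T2-like) volumes in, cluster tables out. Because infant cohort imaging
data are not freely redistributable, the package pairs every stage with a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, so the pipeline can be exercised and validated
end-to-end without any external data.

## Data model and conventions

A `gm_volume` is a 3-D array plus voxel spacing (mm) and a 4×4
voxel-to-world affine; continuous voxel coordinates are 0-based, and
`world = A[1:3,1:3] %*% voxel + A[1:3,4]`. A `gm_field` stores a dense
displacement field as an `(nx, ny, nz, 3)` array of **mm vectors in the
world frame of its reference grid**; the induced map is
`x -> x + u(x)`. This is the single coordinate convention used everywhere.

Fields are produced by registration in *resampling* convention: the field
returned by `diffeo_register(moving, fixed)` lives on the fixed grid and
pulls moving-image intensities to fixed-space points, i.e. `x + u(x)` maps
fixed-space points into the moving image. Consequently the field obtained
by registering a scan to its template is already the template-to-native
point map, and its Jacobian determinant is `> 1` where native anatomy is
larger than the template.

On disk, volumes are NIfTI-1 (written in double precision so round-trips
are bit-exact) and fields are 5-D NIfTI-1 with intent code 1007 (vector),
the de-facto dialect for displacement fields. Cohorts are plain CSV with
header `subject_id,group,sex,site,visit,age_days[,t1_path,t2_path]`.

## Intensity normalization

Each scan is matched to a target histogram by the best linear map of
decile landmarks: the 0th–100th percentiles in steps of 10 are computed
for source and target over a foreground mask (positive voxels by default,
so a dominant zero background cannot drive the fit), the 11 landmark pairs
are fitted by ordinary least squares — the "best linear mapping"
criterion, which the method description leaves open, is here declared to
be least squares — and intensities are mapped and clamped to the working
range [0, 100].

## Registration

Two layers:

* **Affine pre-alignment** (`affine_register`): a three-stage optimisation
  — translation, then rigid + isotropic scale, then the full affine — over
  a coarse-to-fine grid schedule, each stage run with restarted
  Nelder-Mead on normalized mutual information (default) or mean squared
  error, parameterised about the world centre of the fixed grid. The named
  five-stage hierarchical tool used in the original processing chain is an
  external program; this three-stage optimiser is a functional stand-in
  with a declared similarity. Affine transforms align images but are
  **excluded** from all Jacobian analysis, so global size differences
  never masquerade as local growth.

* **Diffeomorphic registration** (`diffeo_register`): greedy
  multi-resolution registration driven by the gradient of the windowed
  (local) cross-correlation, summed over the T1 and T2 channels with
  configurable weights. The squared local correlation `A²/(BC)` supplies
  the update force, so edges attract regardless of contrast polarity —
  essential in infants, where T1 and T2 grey–white contrast inverts with
  myelination at different times per channel. Windows whose variance is a
  negligible fraction (10⁻³) of the image's maximum window variance carry
  no anatomy — smoothed background noise is locally smooth and correlates
  spuriously — and contribute neither force nor energy. Each iteration
  smooths the update field (σ = `update_sigma_vox`), rescales it so its
  largest vector is `gradient_step` voxels, adds it to the total field,
  and smooths the total field (σ = `total_sigma_vox`). A step is accepted
  only if the deformation keeps a strictly positive Jacobian determinant
  *and* decreases the energy `1 − weighted mean CC²` (halving the step up
  to five times otherwise), so descent is monotone by construction and
  every returned field passes the positivity check. Registration contains
  no stochastic step: identical inputs give bit-identical fields.

Default parameters are the standard SyN-style settings for dual-channel
infant templates — gradient step 0.25, update/total field smoothing
2.0/0.3 voxels, equal channel weights, shrink factors 16/8/4/2/1 with
smoothing sigmas 9.44/7.08/4.72/2.36/0 mm. Per-level iteration counts
(40/30/20/10/5) and the correlation window radius (2 voxels) are package
defaults, since the upstream description does not state them. Pyramid
levels whose shrunken grid would fall below 5 voxels per axis are skipped,
which is how the published shrink schedule degrades gracefully on
desk-scale phantoms.

## Unbiased age templates

`build_template` iterates: register every T1 scan to the current average,
subtract the voxel-wise mean of all deformation fields from each field
(after which the mean deformation is numerically zero — the unbiasing
step), warp, intensity-normalize to the current average, re-average. After
the last iteration the T2 scans are warped through the T1-derived fields
and averaged, which guarantees the T1 and T2 templates share one space
exactly. Intensity matching happens after warping within each iteration;
the original description leaves the order open. Four iterations is the
default; the template grid is the grid of the first scan, both declared
choices. Inter-template transforms (6 m→12 m, 24 m→12 m) come from
`register_templates`: affine alignment followed by dual-channel
diffeomorphic registration on the reference (12-month) grid, with only the
nonlinear part passed downstream.

## Field calculus and log-Jacobian maps

`compose_fields(f, g)` implements "apply `g`, then `f`":
`(f∘g)(x) = g(x) + f(x + g(x))`. `invert_field` solves
`u_inv(x) = −u(x + u_inv(x))` by fixed-point iteration with adaptive
under-relaxation (plain iteration oscillates when displacement gradients
approach one); boundary values are edge-extended during inversion because
zero-extension makes the iteration oscillate at the domain edge.
Convergence tolerance is 0.01 voxels with at most 200 sweeps, and
non-convergence is an error carrying the residual magnitude, never a
silent result. `jacobian_determinant` evaluates `det(I + ∂u/∂x)` with
second-order central differences in the interior and first-order one-sided
stencils at the boundary, with derivatives of mm-valued displacements
taken with respect to world mm coordinates, so anisotropic voxels are
handled exactly.

`subject_log_jacobian` produces the per-scan analysis map: the scan's
native→age-template map is concatenated with the age-template→reference
map, "normalized" — interpreted here as resampled onto the common
reference grid, a declared reading of an underspecified step — inverted,
and the natural log of the Jacobian determinant of the resulting
reference→native map is returned. Zero means no local volume change,
positive values mean the native structure is larger than the reference.
Scans acquired at the reference age use the zero field in place of the
inter-template transform. The pipeline orchestrator computes the same
reference→native map directly by composing the two registration outputs
(which are already in resampling convention), avoiding two numerical
inversions.

## The voxel-wise growth model

At every in-mask voxel the log-Jacobian value of scan `i` is modelled as

  J_i = γ0_subject + γ0_site + β0 + β1·age + β2·age² + β3·group
        + β4·(group × age) + β5·sex + ε,

with independent random intercepts for subject and acquisition site,
fitted by maximum likelihood (ML, not REML) through lme4 — ML because
forward selection compares nested fixed-effect structures with
log-likelihood ratio tests, which REML fits do not license. Age enters in
days, centred at 183 days (6 months) so that group main effects are
evaluated at the first wave, and scaled by 365.25 for numerical
conditioning; slopes are therefore per year. Group uses dummy coding
against the low-risk (LR-) reference, so the two group×age coefficients
are growth-rate differences, and the HR+ vs HR- growth-rate contrast is
derived from the same fit rather than refitting pairs — one model, three
pairwise comparisons.

Forward selection (`forward_select`) walks a nested candidate ladder
(age; +age²; +group; +group×age; +sex by default; a cubic age term is
available but not in the default ladder since the generating trajectory is
quadratic). A more complex candidate is accepted when the voxel-wise LRT
is significant at α for a strict majority of voxels *and* the mean LRT
statistic across voxels exceeds the chi-squared critical value at the
Bonferroni-corrected level α/(number of comparisons) — a declared
operationalisation of "mean statistic significant after correction".

Voxel-wise t statistics use residual degrees of freedom
(`n_scans − n_fixed`). For interval estimation at a single voxel,
`fit_lmm(..., ddf = "satterthwaite")` computes per-coefficient
Satterthwaite degrees of freedom via lmerTest; with only four sites, the
intercept's effective df is closer to 3 than to `n − p`, and residual-df
intervals undercover it noticeably. The parameter-recovery validation
therefore uses Satterthwaite df; the voxel-wise maps keep the residual
approximation, which is accurate for all covariates that vary within
site.

## Pooled FDR and clusters

The uncorrected two-sided p-values of every model-term t-map are pooled
across all effects and all in-mask voxels and submitted to
Benjamini–Hochberg step-up at q = 0.05. The resulting single p-value
threshold is converted to a two-sided t threshold per map through that
map's degrees of freedom; voxels with |t| at or above the threshold are
significant. When nothing survives, the threshold is the +Inf sentinel.
The derived pairwise contrast map is thresholded but not pooled — it is
not an additional model effect. Suprathreshold voxels are grouped into
connected components (26-connectivity by default, 6 by option), with
positive and negative excursions labelled separately so opposite-sign
blobs never merge; peak ties break to the lowest linear voxel index.
Optional atlas and tissue label volumes annotate each cluster with its
dominant region (full label histograms are retained) and a GM/WM/Mixed
call at an 80% majority rule.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` fixes the study conditions:

* **Design.** 20 HR+ / 60 HR- / 40 LR- subjects (the characteristic
  ~1:3:2 imbalance of large infant-sibling cohorts, scaled down); three
  visit waves with ages drawn Normal(6.7, 0.7), (12.8, 0.7), (25.0, 0.9)
  months; each visit independently missed with probability 0.28, giving
  ~37% of subjects all three scans; four sites; sex ratios 85.6/58.3/59.3
  percent male per group.
* **Response.** Quadratic trajectory `−0.30 + 0.55 t − 0.15 t²` (t in
  years since 6 months) — a realistic log-Jacobian course for anatomy
  measured against a 12-month reference: about −0.3 at 6 months, near 0
  at 12, positive at 24 with decelerating growth. Sex effect 0.02. Group
  offset zero and HR+ growth-rate offset +0.06/year, applied **only**
  inside two opposite-sign spherical signal regions covering ~10% of the
  default 10³ grid: outside them the groups are exchangeable.
* **Noise.** Subject and site intercept SDs 0.05 and 0.02, residual SD
  0.04, all Gaussian. These magnitudes were set by an a-priori power
  calculation targeting an interaction t of about 5 at this design, i.e.
  sensitivity above 0.8 after FDR thresholding; no empirical
  residual-variance value is available for this scale.

`demo_cohort()` complements the stochastic generator with a deterministic
1,088-scan / 503-participant table reproducing the per-group visit-pattern
bookkeeping of a large published three-wave cohort, for exercising cohort
summaries at full scale.

The imaging phantom (`simulate_growth_phantom`) is a deterministic
layered sphere (inner band, core, shell, zero background) whose geometry —
including the sigmoid transition widths — scales linearly with a growth
factor, so tissue volume scales with its cube, and whose channel levels
make the core/shell contrast invert with age, earlier and faster in the
T1-like channel than the T2-like one.

What the generator does **not** emulate: real cortical anatomy or
topology, MR physics (bias fields, motion, distortion), spatially
correlated residual noise, or site-by-sequence interactions. Passing the
package's validation therefore demonstrates that the machinery is correct
and calibrated under its own assumptions — exchangeable Gaussian noise and
a correctly specified growth model — not that effect sizes or FDR levels
transfer to any particular scanner cohort.

## Numerical choices and degenerate inputs

* Out-of-domain samples: 0 for intensities and labels, zero vector for
  fields (edge-extension only inside the fixed-point inversion).
* Trilinear interpolation for intensities, nearest-neighbour enforced for
  label volumes; trilinear on labels is an error, not a warning.
* NaN voxels are rejected at construction with a count; label volumes
  must be non-negative integers; spacings must be strictly positive.
* Constant images are rejected by both registrations; constant
  normalization sources are rejected (zero landmark spread).
* Variance components are constrained non-negative by lme4's bounded
  optimisation; boundary fits (variance exactly 0) are legal and
  reported. Rank-deficient designs fail with the collinear columns named.
* Non-positive Jacobian determinants are flagged (and clamped at 10⁻⁸
  before taking logs, with a warning) — never silently used.

## Validation problem sizes

The shipped validation uses: an 8³ grid with ~10.5% signal voxels and 50
simulated cohorts for the FDR-control study (measured mean false-discovery
proportion ≈ 3% at q = 0.05); 100 cohorts at the default design for
parameter recovery (all |relative biases| < 3%, pooled 95%-interval
coverage ≈ 94.5%); 48³ phantoms with 10% linear growth for the end-to-end
registration check (mean interior log-Jacobian within 10% of ln 1.1³ =
0.2859, using update-field smoothing of 5 voxels — appropriate
regularisation when the true deformation is a global uniform scaling);
and a 16³ full-pipeline smoke study with three age templates. The phantom
registration check uses a common contrast state for both phantoms,
mirroring the pipeline's own operating regime of registering scans to
age-matched templates precisely because neighbouring-age contrast is
similar.

## Known limitations

* The greedy regularised-gradient registration captures the published
  parameter semantics but is not an implementation of symmetric geodesic
  optimisation; no claim of output compatibility with ANTs SyN is made.
* Mutual-information-driven *deformable* registration is out of scope;
  the NMI similarity is available for the affine stage only.
* With strong contrast reversal between moving and fixed images (e.g. a
  6-month phantom against a 24-month one), the sign-insensitive local-CC
  force still aligns edges but recovers deformation magnitudes poorly;
  the pipeline avoids this regime by construction (age-matched templates
  anchor each registration).
* Residual-df t maps are slightly anticonservative for effects that do
  not vary within site; Satterthwaite df are available per fit but are
  not propagated to the voxel-wise maps.
* The fixed-point inversion assumes displacement gradients below one;
  fields violating it abort with a diagnostic rather than returning an
  approximate inverse.
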
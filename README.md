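# growthmorph

Longitudinal tensor-based morphometry (TBM) of early brain growth, as a
tested, reusable R pipeline. The scientific setting is longitudinal infant
neuroimaging — three visit waves near 6, 12 and 24 months, three groups
(low-risk controls `LR-`, high-familial-risk infants without and with an
ASD outcome, `HR-` / `HR+`) — where the question is not whether brain
volume differs at a given age but whether local anatomy *grows at a
different rate* between groups.

The chain, each stage an exported, unit-tested function:

1. **Intensity normalization** — decile-landmark histogram matching:
   the 0th–100th percentiles in steps of 10 are fitted by least squares
   between scan and target, and intensities are mapped into [0, 100].
2. **Unbiased age templates** — iterative T1-driven template construction
   with mean-deformation subtraction; T2 scans are warped through the
   T1-derived fields so both templates share one space exactly.
3. **Registration** — affine pre-alignment (restarted Nelder–Mead on
   normalized mutual information or MSE), then greedy multi-resolution
   diffeomorphic registration driven by the windowed cross-correlation of
   both channels simultaneously (gradient step 0.25, update/total field
   smoothing 2.0/0.3 voxels, shrink factors 16/8/4/2/1, smoothing sigmas
   9.44/7.08/4.72/2.36/0 mm). Every accepted update keeps the Jacobian
   determinant positive and decreases the registration energy.
4. **Field calculus** — composition, fixed-point inversion and
   log-Jacobian determinant maps: per-scan nonlinear transforms are
   concatenated with the inter-template transform, normalized onto the
   12-month reference grid and inverted, giving at every voxel
   `ln det(I + ∂u/∂x)` of the reference-to-native map — 0 for no volume
   change, positive where native anatomy is larger. Affine transforms are
   excluded, so overall head size never masquerades as local growth.
5. **Voxel-wise mixed models** — at each voxel
   `J = γ0_subj + γ0_site + β0 + β1 age + β2 age² + β3 group +
   β4 group×age + β5 sex + ε`, fitted by maximum likelihood (lme4) with
   age in days centred at 183; forward model selection over a nested
   candidate ladder via voxel-wise likelihood-ratio tests.
6. **Pooled FDR and clusters** — Benjamini–Hochberg step-up on the
   p-values pooled across all effects and voxels, converted to one
   two-sided t threshold per map; connected suprathreshold clusters
   (26-connectivity, opposite signs never merged) reported with size,
   peak t and optional atlas region / GM–WM tissue labels.

A synthetic-data module generates cohort tables, log-Jacobian stacks with
the full longitudinal covariance structure (subject and site intercepts,
group-specific trajectories confined to signal regions of either sign),
and two-channel growth phantoms whose T1/T2 contrast inverts across age at
channel-specific rates — so every stage is testable without access to any
real cohort.

## Worked example

Simulate a scaled-down cohort (20 HR+ / 60 HR- / 40 LR- subjects, 28%
per-visit dropout) with an HR+ growth-rate excess of +0.06/year inside two
opposite-sign spherical regions of a 10³ grid, fit the growth model at
every voxel, and threshold at pooled FDR q = 0.05:

```r
library(growthmorph)

cfg    <- sim_config()
cohort <- simulate_cohort(cfg, seed = 1)
sim    <- simulate_logjac_stack(cohort, cfg, seed = 2)
fit    <- fit_voxelwise(sim$stack, cohort, model_spec(), grid = sim$grid)
fit
#> <gm_voxel_stats 1000 voxels, 262 scans, df = 254>
#>   maps: age_c, I(age_c^2), groupHR-, groupHR+, sexM,
#>         age_c:groupHR-, age_c:groupHR+, group:age HR+ vs HR-

fdr <- pooled_fdr_threshold(fit, q = 0.05)
c(p = fdr$p_threshold, t = fdr$t_thresholds[[1]], n = fdr$n_rejected)
#>            p            t            n
#>    0.0217878    2.3082716 3125.0000000

extract_clusters(fit$tmaps[["age_c:groupHR+"]], fdr$t_thresholds[[1]],
                 min_size = 5)
#>   cluster_id size_voxels    peak_t peak_x peak_y peak_z     sign
#> 1          1          59 -7.448492      8      9      7 decrease
#> 2          2          57  7.834861      5      3      3 increase
```

The two recovered clusters are the two planted signal spheres (56 voxels
each, one accelerating and one decelerating HR+ growth): sizes 57/59,
signs correct, peaks at the sphere centres. Voxel-wise sensitivity inside
the true signal mask is 1.00 at this seed. The cohort bookkeeping helpers
reproduce published-scale demographics exactly — `demo_cohort()` has
1,088 scans from 503 participants with 40.0% / 38.2% of participants
contributing exactly two / three timepoints.

The full imaging chain (phantoms → normalization → templates →
registration → log-Jacobians → statistics → clusters) runs from one
configuration with `run_pipeline(config, out_dir)`, which logs per-stage
provenance (parameter echo, config hash, output md5s) and skips stages
whose outputs are current. A thin command-line front end with the same
stages lives at `inst/cli/growthmorph.R`.

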
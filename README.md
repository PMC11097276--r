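# dmnsubsys

Activation profiling and resting-state connectivity of default mode network
(DMN) subsystems.

## What it does

Demanding tasks typically deactivate the DMN, but during internally oriented
cognition (semantic retrieval, recall) parts of it also activate — sometimes
different voxels of the *same* subsystem in both directions at once, which a
region-averaged statistic cannot see. `dmnsubsys` implements, as a tested R
package plus a numbered analysis workflow, a chain built around a
voxel-counting statistic that keeps both directions visible:

1. **Activation profiling** — per participant, condition, and subsystem
   (medial temporal MT, Core, frontotemporal FT; mutually exclusive masks
   from a labelled parcellation), the percentage of voxels with z ≥ τ
   (activating) and z ≤ −τ (deactivating), τ = 1.96 by default (2.3, 2.6 as
   robustness alternates):

   pct = 100 · |{z over threshold} ∩ S| / |S|  for subsystem mask S.

2. **Group statistics** — within-subject repeated-measures ANOVAs
   (condition × subsystem) with partial η², and Bonferroni-corrected paired-t
   posthocs.
3. **Consensus seeds** — per-voxel participant fractions of the binarized
   maps, averaged across conditions, thresholded at 20%, and intersected with
   the subsystem masks: six seeds, {MT, Core, FT} × {activation,
   deactivation}.
4. **Resting-state connectivity** — CompCor + motion/spike censoring +
   0.01–0.1 Hz bandpass denoising, seed-to-voxel Fisher-z maps, paired seed
   contrasts with sign-flip permutation cluster-extent FWE inference
   (voxel p < 0.001, cluster FWE p < 0.05, Bonferroni 0.017 over three
   contrasts).
5. **Gradient localization** — masked spatial correlation of each
   participant's connectivity maps with three whole-brain connectivity
   gradients (G1 heteromodal–sensory, G2 visual–motor, G3 control–default),
   analysed with the same ANOVA machinery.

A synthetic-data module (`simulation_spec()`, `make_atlas()`, `make_zmaps()`,
`make_rest()`, `make_gradients()`) generates every input with recorded ground
truth, so the whole chain runs and is tested without any data download.
Volumes are NIfTI-1 (via RNifti); tables are TSV.

## Worked example

The numbered drivers under `analysis/` run the chain end to end on a
simulated cohort (20³ grid, 12 participants, reading/recall conditions,
120 rest frames at TR = 3 s) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_activation_profiles.R
Rscript analysis/03_consensus_seeds.R
Rscript analysis/04_connectivity.R
Rscript analysis/05_gradient_localization.R
```

Stage 2 prints the percentage-of-activating-voxels ANOVA for this cohort:

```
pct_activating ANOVA (condition x subsystem):
              effect      ss ss_error df1 df2     F         p eta_sq_partial
1          condition  390.83    10.27   1  11 418.5 4.192e-10         0.9744
2          subsystem 1012.20    40.61   2  22 274.2 2.814e-16         0.9614
3 condition:subsystem  268.94    29.26   2  22 101.1 8.119e-12         0.9019
```

The generator plants more activation for recall than reading in MT and Core
but not FT, so the condition main effect and the condition × subsystem
interaction are both large; F is each effect's mean square over its own
effect-by-subject error term, and partial η² = SS_effect / (SS_effect +
SS_error). Mean percentages land at the planted fraction plus the ~2.5%
Gaussian-tail background that thresholded z-maps carry (e.g. 16.4% for MT
recall at a planted 15%). Stage 3 reports the six seed sizes, stage 4 the
cluster table of the activation-vs-deactivation contrasts, and stage 5 the
per-gradient polarity × subsystem ANOVAs.

In code, the core statistic on one map:

```r
library(dmnsubsys)
spec  <- simulation_spec(seed = 7)
atlas <- make_atlas(spec)
zm    <- make_zmaps(spec, atlas)
prof  <- profile_zmap(threshold_zmap(zm$zmaps[[1]], threshold_config(1.96)),
                      atlas)
prof
#   subsystem n_subsystem_voxels pct_activating pct_deactivating
# 1        MT                200        7.50000         9.000000
# 2      Core                800        5.25000        22.000000
# 3        FT                900       16.77778         7.777778
```

This is participant p01's "reading" map: planted activation fractions were
0.05 (MT), 0.03 (Core), 0.15 (FT), and each recovered percentage is the
planted value plus the ~2.5% background tail, within binomial noise.

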
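#!/usr/bin/env Rscript
# Stage 5: situate each participant's six seed-connectivity maps on the three
# gradients by masked spatial correlation, then run the polarity-by-subsystem
# repeated-measures ANOVA per gradient.

source(file.path("analysis", "00_config.R"))

spec <- cohort_spec()
grads <- lapply(c("G1", "G2", "G3"), function(g)
  read_volume(file.path(SIM_DIR, paste0(g, ".nii.gz")), role = "gradient"))
names(grads) <- c("G1", "G2", "G3")
mask <- volume3d(array(1, dim = spec$grid_shape), grads$G1$grid,
                 role = "binary")
ga <- gradient_atlas(grads, mask)

fc_maps <- readRDS(file.path(SIM_DIR, "fc_maps.rds"))
profile <- gradient_profile(fc_maps, ga)
write_tsv(profile, "gradient_correlations.tsv")

anovas <- gradient_anovas(profile)
for (g in names(anovas)) {
  message("\n", g, " polarity x subsystem ANOVA:")
  print(anovas[[g]], digits = 4)
  write_tsv(anovas[[g]], paste0("gradient_anova_", g, ".tsv"))
}

message("\nMean r by seed and gradient:")
print(aggregate(r ~ seed + gradient, profile, mean), digits = 3)
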
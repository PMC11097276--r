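#!/usr/bin/env Rscript
# Stage 3: consensus maps of commonly activated/deactivated voxels (fraction
# of participants over threshold per condition, combined across conditions,
# 20% cutoff) and the six subsystem seeds.

source(file.path("analysis", "00_config.R"))

spec <- cohort_spec()
labels <- read_volume(file.path(SIM_DIR, "atlas_labels.nii.gz"))
atlas <- build_atlas(labels,
                     read_label_mapping(file.path(RESULTS_DIR, "atlas_mapping.tsv")))

files <- list.files(SIM_DIR, pattern = "_zmap\\.nii\\.gz$", full.names = TRUE)
keys <- sub("_zmap\\.nii\\.gz$", "", basename(files))
cond_of <- sub("^p[0-9]+_", "", keys)

consensus_for <- function(direction) {
  per_cond <- lapply(spec$conditions, function(cond) {
    maps <- lapply(files[cond_of == cond], function(f)
      threshold_zmap(read_volume(f))[[direction]])
    consensus_fraction(maps)
  })
  combine_conditions(per_cond)
}

act_cons <- consensus_for("activation")
deact_cons <- consensus_for("deactivation")
write_volume(act_cons, file.path(SIM_DIR, "consensus_activation.nii.gz"))
write_volume(deact_cons, file.path(SIM_DIR, "consensus_deactivation.nii.gz"))

seeds <- build_seed_set(threshold_consensus(act_cons, 0.20),
                        threshold_consensus(deact_cons, 0.20), atlas)
sizes <- data.frame(seed = names(seeds),
                    n_voxels = vapply(seeds, function(s) sum(s$values),
                                      numeric(1)))
write_tsv(sizes, "seed_sizes.tsv")
for (nm in names(seeds))
  write_volume(seeds[[nm]], file.path(SIM_DIR, paste0("seed_", nm, ".nii.gz")))
message("Six seeds derived; voxel counts:")
print(sizes)
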
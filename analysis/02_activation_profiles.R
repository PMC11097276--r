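#!/usr/bin/env Rscript
# Stage 2: per-participant percentages of activating/deactivating voxels in
# each subsystem (z >= 1.96 / z <= -1.96), the condition-by-subsystem
# repeated-measures ANOVAs, and Bonferroni posthocs — at the default and the
# two alternate thresholds.

source(file.path("analysis", "00_config.R"))

spec <- cohort_spec()
labels <- read_volume(file.path(SIM_DIR, "atlas_labels.nii.gz"))
mapping <- read_label_mapping(file.path(RESULTS_DIR, "atlas_mapping.tsv"))
atlas <- build_atlas(labels, mapping)

files <- list.files(SIM_DIR, pattern = "_zmap\\.nii\\.gz$", full.names = TRUE)
keys <- sub("_zmap\\.nii\\.gz$", "", basename(files))
zmaps <- lapply(files, read_volume)
names(zmaps) <- sub("_", "|", keys)

for (tau in c(1.96, 2.3, 2.6)) {
  tab <- build_profile_table(zmaps, atlas, threshold_config(tau))
  write_tsv(tab, sprintf("profile_table_tau%.2f.tsv", tau))
  if (tau == 1.96) {
    for (dv in c("pct_activating", "pct_deactivating")) {
      tab$value <- tab[[dv]]
      an <- rm_anova_within(tab, dv = "value", subject = "participant",
                            within = c("condition", "subsystem"))
      message("\n", dv, " ANOVA (condition x subsystem):")
      print(an, digits = 4)
      write_tsv(an, paste0("anova_", dv, ".tsv"))
      ph <- pairwise_paired_t(tab, dv = "value", subject = "participant",
                              within = "subsystem", m = 3)
      write_tsv(ph, paste0("posthoc_subsystem_", dv, ".tsv"))
    }
  }
}

message("\nMean percentages by condition and subsystem (tau = 1.96):")
tab <- build_profile_table(zmaps, atlas)
print(aggregate(cbind(pct_activating, pct_deactivating)
                ~ condition + subsystem, tab, mean), digits = 3)
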
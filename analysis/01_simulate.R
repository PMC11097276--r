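#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort every later stage consumes.
# Writes NIfTI volumes and motion files under scratch/sim/ and the ground
# truth tables under results/.

source(file.path("analysis", "00_config.R"))

spec <- cohort_spec()
atlas <- make_atlas(spec)

message("Atlas voxel counts:")
print(subsystem_voxel_counts(atlas))

# task z-maps, one per participant x condition
zm <- make_zmaps(spec, atlas)
for (key in names(zm$zmaps)) {
  f <- file.path(SIM_DIR, paste0(gsub("\\|", "_", key), "_zmap.nii.gz"))
  write_volume(zm$zmaps[[key]], f)
}
write_tsv(zm$truth, "simulated_zmap_truth.tsv")

# resting scans with planted motion spikes for the first participants
for (p in 1:spec$n_participants) {
  spec_p <- spec
  spec_p$seed <- spec$seed + 100L + p
  rest <- make_rest(spec_p, atlas, spike_frames = c(30L, 75L))
  pid <- sprintf("p%02d", p)
  write_volume(rest$bold, file.path(SIM_DIR, paste0(pid, "_rest.nii.gz")))
  write.table(rest$motion, file.path(SIM_DIR, paste0(pid, "_motion.par")),
              row.names = FALSE, col.names = FALSE)
  if (p == 1)
    write_volume(rest$noise_roi, file.path(SIM_DIR, "noise_roi.nii.gz"))
}

# label volume + mapping, and the three gradients
write_volume(volume3d(array(as.numeric(atlas$labels), dim = atlas$grid$shape),
                      atlas$grid), file.path(SIM_DIR, "atlas_labels.nii.gz"))
write_tsv(data.frame(label = atlas$mapping$label,
                     subsystem = atlas$mapping$subsystem),
          "atlas_mapping.tsv")
ga <- make_gradients(spec)
for (g in names(ga$gradients))
  write_volume(ga$gradients[[g]], file.path(SIM_DIR, paste0(g, ".nii.gz")))

message("Simulated cohort: ", spec$n_participants, " participants, ",
        length(spec$conditions), " conditions, grid ",
        paste(spec$grid_shape, collapse = "x"))
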
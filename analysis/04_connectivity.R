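#!/usr/bin/env Rscript
# Stage 4: denoise each resting scan (censoring, CompCor, confound
# regression, 0.01-0.1 Hz bandpass), compute seed-to-voxel Fisher-z maps for
# the six seeds, and contrast activation vs deactivation connectivity within
# each subsystem with sign-flip permutation cluster inference.

source(file.path("analysis", "00_config.R"))

spec <- cohort_spec()
noise_roi <- read_volume(file.path(SIM_DIR, "noise_roi.nii.gz"), role = "binary")
seed_files <- list.files(SIM_DIR, pattern = "^seed_.*\\.nii\\.gz$",
                         full.names = TRUE)
seeds <- lapply(seed_files, read_volume, role = "binary")
names(seeds) <- sub("^seed_(.*)\\.nii\\.gz$", "\\1", basename(seed_files))

cfg <- denoise_config(fd_threshold = 0.5, global_z_threshold = 3,
                      n_compcor = 5, band = c(0.01, 0.1))

fc_maps <- list()
for (p in 1:spec$n_participants) {
  pid <- sprintf("p%02d", p)
  bold <- read_volume(file.path(SIM_DIR, paste0(pid, "_rest.nii.gz")))
  motion <- read_motion_params(file.path(SIM_DIR, paste0(pid, "_motion.par")))
  den <- denoise_rest(bold, motion, noise_roi, cfg)
  fc_maps[[pid]] <- lapply(seeds, function(s) seed_to_voxel_fc(den$bold, s))
  message(pid, ": censored ", sum(!den$keep), " frames, ",
          ncol(den$confounds), " confound columns")
}
saveRDS(fc_maps, file.path(SIM_DIR, "fc_maps.rds"))

# activation vs deactivation contrast per subsystem, Bonferroni over the three
inf <- inference_config(voxel_p = 0.001, cluster_alpha = 0.05,
                        n_contrasts = 3, n_permutations = 1000,
                        rng_seed = SIM_SEED)
rows <- list()
for (sys in c("MT", "Core", "FT")) {
  a <- lapply(fc_maps, `[[`, paste0(sys, "_activation"))
  b <- lapply(fc_maps, `[[`, paste0(sys, "_deactivation"))
  con <- paired_contrast_map(a, b)
  res <- permutation_cluster_fwe(con$diff, spec$grid_shape, inf)
  if (nrow(res$clusters)) {
    res$clusters$contrast <- paste0(sys, ": activation vs deactivation")
    res$clusters$p_bonferroni <- bonferroni_adjust(res$clusters$p_fwe, 3)
    rows[[sys]] <- res$clusters
  }
  message(sys, ": ", nrow(res$clusters), " clusters at |t| > ",
          round(res$t_crit, 2))
}
clusters <- do.call(rbind, rows)
if (!is.null(clusters)) write_tsv(clusters, "fc_contrast_clusters.tsv")
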
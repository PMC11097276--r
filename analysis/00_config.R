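# Shared configuration for the analysis drivers. Each numbered script sources
# this file, so every stage sees one cohort: a 20^3 common grid, three
# subsystem blocks, two task conditions (reading, recall), 12 participants,
# and 120 rest frames at TR = 3 s.

library(dmnsubsys)

SIM_SEED <- 2026L
SIM_DIR <- file.path("scratch", "sim")
RESULTS_DIR <- "results"
dir.create(SIM_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

cohort_spec <- function() {
  simulation_spec(
    grid_shape = c(20, 20, 20),
    subsystem_sizes = c(MT = 200, Core = 800, FT = 900),
    conditions = c("reading", "recall"),
    n_participants = 12, T_rest = 120, tr = 3,
    beta = 0.5, seed = SIM_SEED)
}

write_tsv <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  message("wrote ", path)
  path
}
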
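# Gradient localization: situate each participant's connectivity maps along
# macroscale cortical gradients (G1 heteromodal-sensory, G2 visual-motor,
# G3 control-default) by masked voxelwise Pearson correlation, computed at the
# individual level and fed into the repeated-measures ANOVA machinery.

#' Gradient atlas
#'
#' @param gradients Ordered list of `volume3d` (role `"gradient"`), e.g. the
#'   top three cortical gradients.
#' @param mask Binary `volume3d` analysis mask on the same grid.
#' @return A `gradient_atlas`.
#' @export
gradient_atlas <- function(gradients, mask) {
  if (length(gradients) < 1L) stop("gradient_atlas: need >= 1 gradient")
  for (g in gradients) {
    stopifnot(inherits(g, "volume3d"))
    assert_same_grid(g, gradients[[1]])
  }
  assert_same_grid(mask, gradients[[1]])
  if (sum(mask$values == 1, na.rm = TRUE) == 0)
    stop("gradient_atlas: empty mask")
  if (is.null(names(gradients)))
    names(gradients) <- paste0("G", seq_along(gradients))
  structure(list(gradients = gradients, mask = mask), class = "gradient_atlas")
}

#' Masked spatial correlation of two volumes
#'
#' Pearson r over voxels inside the mask where both volumes are non-missing.
#' Invariant to positive affine rescaling of either input.
#'
#' @param map,gradient `volume3d` on one grid.
#' @param mask Binary `volume3d`.
#' @return Pearson correlation (scalar).
#' @export
spatial_correlation <- function(map, gradient, mask) {
  assert_same_grid(map, gradient)
  assert_same_grid(map, mask)
  ok <- mask$values == 1 & !is.na(map$values) & !is.na(gradient$values)
  if (sum(ok, na.rm = TRUE) < 10)
    stop("spatial_correlation: fewer than 10 jointly valid voxels ",
         "(insufficient overlap)")
  ok[is.na(ok)] <- FALSE
  stats::cor(map$values[ok], gradient$values[ok])
}

#' Individual-level gradient correlation table
#'
#' Full crossing of participants x seeds x gradients: for every participant's
#' seed FC map, the masked spatial correlation with each gradient. Seed names
#' of the form `"<subsystem>_<polarity>"` are split into `subsystem` and
#' `polarity` columns so the table feeds [rm_anova_within()] with factors
#' polarity (2) x subsystem (3), one ANOVA per gradient.
#'
#' @param fc_maps Nested named list: `fc_maps[[participant]][[seed]]` is a
#'   `volume3d` FC map. Every participant must have every seed.
#' @param atlas_g A [gradient_atlas()].
#' @return Data frame: `participant`, `seed`, `subsystem`, `polarity`,
#'   `gradient`, `r`.
#' @export
gradient_profile <- function(fc_maps, atlas_g) {
  stopifnot(inherits(atlas_g, "gradient_atlas"))
  seeds <- names(fc_maps[[1]])
  rows <- list()
  for (pid in names(fc_maps)) {
    if (!identical(sort(names(fc_maps[[pid]])), sort(seeds)))
      stop("gradient_profile: participant '", pid,
           "' is missing seed map(s) (incomplete design)")
    for (sd_ in seeds) {
      m <- fc_maps[[pid]][[sd_]]
      for (gi in seq_along(atlas_g$gradients)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pid, seed = sd_,
          gradient = names(atlas_g$gradients)[gi],
          r = spatial_correlation(m, atlas_g$gradients[[gi]], atlas_g$mask),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  parts <- regmatches(tab$seed, regexpr("_(?=[^_]+$)", tab$seed, perl = TRUE),
                      invert = TRUE)
  tab$subsystem <- vapply(parts, `[`, "", 1)
  tab$polarity <- vapply(parts, `[`, "", 2)
  tab <- tab[order(tab$participant, tab$seed, tab$gradient),
             c("participant", "seed", "subsystem", "polarity", "gradient", "r")]
  rownames(tab) <- NULL
  tab
}

#' Per-gradient polarity-by-subsystem ANOVA
#'
#' Runs [rm_anova_within()] with factors `polarity` and `subsystem` on the
#' correlations of one gradient at a time, optionally Fisher-z transforming
#' the correlations first.
#'
#' @param profile Output of [gradient_profile()].
#' @param fisher Transform r with [fisher_z()] before the ANOVA (off by
#'   default; correlations are analysed directly).
#' @return Named list of ANOVA tables, one per gradient.
#' @export
gradient_anovas <- function(profile, fisher = FALSE) {
  val <- if (fisher) fisher_z(profile$r) else profile$r
  profile$value <- val
  lapply(split(profile, profile$gradient), function(d)
    rm_anova_within(d, dv = "value", subject = "participant",
                    within = c("polarity", "subsystem")))
}
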
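# Within-subject ANOVA and posthoc machinery shared by the activation-profile
# and gradient-correlation analyses. The decomposition is the classical
# repeated-measures partition: each within-subject effect is tested against
# its own effect-by-subject interaction.

#' Within-subject repeated-measures ANOVA
#'
#' One or two within-subject factors on a complete balanced long-format table.
#' Sums of squares follow the classical partition: `SS_subject`; `SS_A` tested
#' against `SS_{A x subject}`; `SS_B` against `SS_{B x subject}`; `SS_{A x B}`
#' against `SS_{A x B x subject}`. `F = MS_effect / MS_error` with uncorrected
#' (sphericity-assuming) degrees of freedom, matching the conventional
#' `F(a-1, (a-1)(n-1))` reporting. Effect size is partial eta-squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table Long-format data frame.
#' @param dv Name of the value column.
#' @param subject Name of the subject-identifier column.
#' @param within Character vector of 1 or 2 within-subject factor columns.
#' @param gg Apply the Greenhouse–Geisser sphericity correction to the p-values
#'   (degrees of freedom scaled by the epsilon estimate). Off by default;
#'   uncorrected dfs are reported either way.
#' @return Data frame with one row per effect (`A`, `B`, `A:B` using the actual
#'   factor names): `effect`, `ss`, `ss_error`, `df1`, `df2`, `F`, `p`,
#'   `eta_sq_partial`.
#' @export
rm_anova_within <- function(table, dv = "value", subject = "subject",
                            within, gg = FALSE) {
  stopifnot(is.data.frame(table), length(within) %in% 1:2)
  miss <- setdiff(c(dv, subject, within), names(table))
  if (length(miss)) stop("rm_anova_within: missing column(s): ",
                         paste(miss, collapse = ", "))
  y <- table[[dv]]
  if (anyNA(y)) stop("rm_anova_within: missing values in dv")
  s <- factor(table[[subject]])
  n <- nlevels(s)
  if (n < 2L) stop("rm_anova_within: insufficient data (need >= 2 subjects)")
  f1 <- factor(table[[within[1]]])
  f2 <- if (length(within) == 2L) factor(table[[within[2]]]) else NULL
  cell <- if (is.null(f2)) interaction(s, f1, drop = FALSE)
          else interaction(s, f1, f2, drop = FALSE)
  counts <- table(cell)
  if (any(counts != 1L))
    stop("rm_anova_within: unbalanced design (every subject needs exactly one ",
         "observation per cell)")
  gm <- mean(y)
  ss_of <- function(groups) {
    m <- tapply(y, groups, mean)
    cnt <- table(groups)
    sum(cnt * (m - gm)^2)
  }
  a <- nlevels(f1)
  out <- list()
  if (is.null(f2)) {
    ss_s <- ss_of(s)
    ss_a <- ss_of(f1)
    ss_tot <- sum((y - gm)^2)
    ss_as <- ss_tot - ss_s - ss_a
    out[[within[1]]] <- c(ss = ss_a, ss_err = ss_as,
                          df1 = a - 1, df2 = (a - 1) * (n - 1))
  } else {
    b <- nlevels(f2)
    ss_s <- ss_of(s)
    ss_a <- ss_of(f1)
    ss_b <- ss_of(f2)
    ss_ab <- ss_of(interaction(f1, f2)) - ss_a - ss_b
    ss_as <- ss_of(interaction(s, f1)) - ss_s - ss_a
    ss_bs <- ss_of(interaction(s, f2)) - ss_s - ss_b
    ss_tot <- sum((y - gm)^2)
    ss_abs <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
    out[[within[1]]] <- c(ss = ss_a, ss_err = ss_as,
                          df1 = a - 1, df2 = (a - 1) * (n - 1))
    out[[within[2]]] <- c(ss = ss_b, ss_err = ss_bs,
                          df1 = b - 1, df2 = (b - 1) * (n - 1))
    out[[paste(within, collapse = ":")]] <-
      c(ss = ss_ab, ss_err = ss_abs,
        df1 = (a - 1) * (b - 1), df2 = (a - 1) * (b - 1) * (n - 1))
  }
  eps <- if (gg) gg_epsilon(table, dv, subject, within) else NULL
  res <- do.call(rbind, lapply(names(out), function(e) {
    v <- out[[e]]
    ms_eff <- v["ss"] / v["df1"]
    ms_err <- v["ss_err"] / v["df2"]
    Fv <- if (ms_err > 0) ms_eff / ms_err else if (ms_eff == 0) 0 else Inf
    ep <- if (gg) eps[[e]] else 1
    p <- stats::pf(Fv, ep * v["df1"], ep * v["df2"], lower.tail = FALSE)
    data.frame(effect = e, ss = unname(v["ss"]), ss_error = unname(v["ss_err"]),
               df1 = unname(v["df1"]), df2 = unname(v["df2"]),
               F = unname(Fv), p = unname(p),
               eta_sq_partial = unname(v["ss"] / (v["ss"] + v["ss_err"])),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

# Greenhouse-Geisser epsilon per effect, from the subject-by-cell covariance
# of the relevant marginal scores.
gg_epsilon <- function(table, dv, subject, within) {
  s <- factor(table[[subject]])
  eff_eps <- function(fac) {
    m <- tapply(table[[dv]], list(s, fac), mean)
    k <- ncol(m)
    if (k <= 2L) return(1)
    S <- stats::cov(m)
    d <- mean(diag(S)) - mean(S)
    num <- (k * d)^2
    den <- (k - 1) * (sum(S^2) - 2 * k * mean(rowMeans(S)^2) + k^2 * mean(S)^2)
    min(1, max(1 / (k - 1), num / den))
  }
  eps <- list()
  f1 <- factor(table[[within[1]]])
  eps[[within[1]]] <- eff_eps(f1)
  if (length(within) == 2L) {
    f2 <- factor(table[[within[2]]])
    eps[[within[2]]] <- eff_eps(f2)
    eps[[paste(within, collapse = ":")]] <- eff_eps(interaction(f1, f2))
  }
  eps
}

#' Paired t test from per-subject values
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` with `df = n - 1` and a two-sided Student-t
#' p-value. Zero-variance differences with a nonzero mean yield an infinite t
#' and `p = 0` (flagged), rather than an error, so that voxelwise maps with
#' degenerate voxels stay computable.
#'
#' @param x,y Equal-length numeric vectors paired by subject.
#' @return List with `t`, `df`, `p`, `mean_diff`, and `degenerate` (TRUE when
#'   the difference variance is zero).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired_t: x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("paired_t: insufficient data (n < 2)")
  d <- x - y
  if (anyNA(d)) stop("paired_t: missing values")
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0,
                             degenerate = TRUE))
    return(list(t = sign(md) * Inf, df = n - 1, p = 0, mean_diff = md,
                degenerate = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
       mean_diff = md, degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param m Number of comparisons (>= 1).
#' @return `min(1, m * p)`, elementwise.
#' @export
bonferroni_adjust <- function(p, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("bonferroni_adjust: 'm' must be >= 1 (configuration error)")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("bonferroni_adjust: p outside [0, 1]")
  pmin(1, m * p)
}

#' Bonferroni-corrected pairwise paired t tests
#'
#' All level pairs of `within` on a balanced table, each a paired t over
#' subjects, corrected for the number of pairs (3 for the three subsystem
#' contrasts).
#'
#' @inheritParams rm_anova_within
#' @param within Single factor column whose levels are compared pairwise.
#' @param m Number of comparisons for the correction; defaults to the number
#'   of pairs.
#' @return Data frame: `level_a`, `level_b`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`, `direction` (sign of the mean difference a - b).
#' @export
pairwise_paired_t <- function(table, dv = "value", subject = "subject",
                              within, m = NULL) {
  f <- factor(table[[within]])
  s <- factor(table[[subject]])
  levs <- levels(f)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  if (is.null(m)) m <- length(pairs)
  res <- lapply(pairs, function(pr) {
    xa <- tapply(table[[dv]][f == pr[1]], droplevels(s[f == pr[1]]), mean)
    xb <- tapply(table[[dv]][f == pr[2]], droplevels(s[f == pr[2]]), mean)
    stopifnot(identical(names(xa), names(xb)))
    tt <- paired_t(as.numeric(xa), as.numeric(xb))
    data.frame(level_a = pr[1], level_b = pr[2], t = tt$t, df = tt$df,
               p_raw = tt$p, p_bonferroni = bonferroni_adjust(tt$p, m),
               direction = sign(tt$mean_diff), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
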
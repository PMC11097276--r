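# Independent oracles used across the suite. These deliberately use plain
# loops and explicit formulas, not the package's code paths.

# Brute-force within-subject ANOVA from cell means, 1 or 2 factors.
bf_rm_anova <- function(d, dv = "value", subject = "subject", within) {
  y <- d[[dv]]
  s <- as.character(d[[subject]])
  subj <- sort(unique(s))
  n <- length(subj)
  gm <- mean(y)
  mean_where <- function(cond) mean(y[cond])
  if (length(within) == 1L) {
    A <- as.character(d[[within[1]]])
    al <- sort(unique(A))
    a <- length(al)
    ss_a <- 0
    for (ai in al) ss_a <- ss_a + n * (mean_where(A == ai) - gm)^2
    ss_s <- 0
    for (si in subj) ss_s <- ss_s + a * (mean_where(s == si) - gm)^2
    ss_tot <- sum((y - gm)^2)
    ss_as <- ss_tot - ss_a - ss_s
    Fa <- (ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1)))
    return(data.frame(effect = within[1], F = Fa,
                      df1 = a - 1, df2 = (a - 1) * (n - 1),
                      eta = ss_a / (ss_a + ss_as)))
  }
  A <- as.character(d[[within[1]]]); B <- as.character(d[[within[2]]])
  al <- sort(unique(A)); bl <- sort(unique(B))
  a <- length(al); b <- length(bl)
  ss_a <- 0; for (ai in al) ss_a <- ss_a + n * b * (mean_where(A == ai) - gm)^2
  ss_b <- 0; for (bi in bl) ss_b <- ss_b + n * a * (mean_where(B == bi) - gm)^2
  ss_s <- 0; for (si in subj) ss_s <- ss_s + a * b * (mean_where(s == si) - gm)^2
  ss_ab <- 0
  for (ai in al) for (bi in bl)
    ss_ab <- ss_ab + n * (mean_where(A == ai & B == bi) -
                          mean_where(A == ai) - mean_where(B == bi) + gm)^2
  ss_as <- 0
  for (ai in al) for (si in subj)
    ss_as <- ss_as + b * (mean_where(A == ai & s == si) -
                          mean_where(A == ai) - mean_where(s == si) + gm)^2
  ss_bs <- 0
  for (bi in bl) for (si in subj)
    ss_bs <- ss_bs + a * (mean_where(B == bi & s == si) -
                          mean_where(B == bi) - mean_where(s == si) + gm)^2
  ss_tot <- sum((y - gm)^2)
  ss_abs <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
  Fcalc <- function(ss, df1, ss_e, df2) (ss / df1) / (ss_e / df2)
  data.frame(
    effect = c(within, paste(within, collapse = ":")),
    F = c(Fcalc(ss_a, a - 1, ss_as, (a - 1) * (n - 1)),
          Fcalc(ss_b, b - 1, ss_bs, (b - 1) * (n - 1)),
          Fcalc(ss_ab, (a - 1) * (b - 1), ss_abs, (a - 1) * (b - 1) * (n - 1))),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    eta = c(ss_a / (ss_a + ss_as), ss_b / (ss_b + ss_bs),
            ss_ab / (ss_ab + ss_abs)))
}

# random balanced long-format table for a subjects x 2 x 3 within design
random_rm_table <- function(n_subj = 6, a = 2, b = 3) {
  d <- expand.grid(subject = factor(seq_len(n_subj)),
                   A = factor(paste0("a", seq_len(a))),
                   B = factor(paste0("b", seq_len(b))))
  d$value <- rnorm(nrow(d)) + rnorm(n_subj)[d$subject]
  d
}

# tiny volume helpers
tiny_grid <- function(shape = c(4, 4, 4), scale = 1, origin = c(0, 0, 0)) {
  a <- diag(c(rep(scale, 3), 1))
  a[1:3, 4] <- origin
  grid_spec(shape, a)
}

vol_of <- function(values, grid = NULL, role = "zstat") {
  volume3d(values, grid, role = role)
}

rand_binary_vol <- function(shape = c(4, 4, 4), p = 0.3, grid = NULL) {
  volume3d(array(as.numeric(runif(prod(shape)) < p), shape), grid,
           role = "binary")
}

# T x V matrix of a volume4d over an optional binary mask (independent of the
# package's internal flattening helper)
bold_mat_for_test <- function(bold, mask = NULL) {
  dm <- dim(bold$series)
  m <- t(matrix(bold$series, prod(dm[1:3]), dm[4]))
  if (!is.null(mask)) m <- m[, as.vector(mask$values == 1), drop = FALSE]
  m
}
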
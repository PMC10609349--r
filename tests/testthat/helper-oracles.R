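# Independent oracles used across the suite.

# IoU by explicit pixel-by-pixel counting (no vectorized set ops).
iou_bruteforce <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      ai <- isTRUE(a[i, j] > 0); bi <- isTRUE(b[i, j] > 0)
      if (ai && bi) inter <- inter + 1L
      if (ai || bi) uni <- uni + 1L
    }
  }
  if (uni == 0L) return(1)
  inter / uni
}

# Mixed-design RM-ANOVA by explicit design-matrix projections: sequential
# residual sums of squares from QR-projected fits, assembled against the
# mixed-model error strata. Independent of stats::anova / stats::aov.
rss <- function(y, X) {
  f <- qr.fitted(qr(X), y)
  sum((y - f)^2)
}

rm_anova_glm_oracle <- function(d) {
  y <- d$y
  g <- factor(d$g); s <- factor(d$s); t <- factor(d$t)
  n_sub <- nlevels(s); n_g <- nlevels(g); n_t <- nlevels(t)
  X1 <- matrix(1, length(y), 1L)
  Xg <- stats::model.matrix(~g)
  Xs <- stats::model.matrix(~s)              # spans the group space
  Xst <- stats::model.matrix(~s + t)
  Xfull <- stats::model.matrix(~s + t + g:t)
  ss_g <- rss(y, X1) - rss(y, Xg)
  ss_s <- rss(y, Xg) - rss(y, Xs)
  ss_t <- rss(y, Xs) - rss(y, Xst)
  ss_gt <- rss(y, Xst) - rss(y, Xfull)
  ss_e <- rss(y, Xfull)
  df <- c(g = n_g - 1L, s = n_sub - n_g, t = n_t - 1L,
          gt = (n_g - 1L) * (n_t - 1L), e = (n_sub - n_g) * (n_t - 1L))
  list(F_group = (ss_g / df[["g"]]) / (ss_s / df[["s"]]),
       F_time = (ss_t / df[["t"]]) / (ss_e / df[["e"]]),
       F_inter = (ss_gt / df[["gt"]]) / (ss_e / df[["e"]]),
       SS = c(ss_g, ss_s, ss_t, ss_gt, ss_e), df = df)
}

random_balanced_design <- function() {
  g <- sample(2:4, 1); n <- sample(3:6, 1); Tt <- sample(3:6, 1)
  d <- expand.grid(s = seq_len(g * n), t = seq_len(Tt))
  d$g <- paste0("G", (d$s - 1L) %/% n + 1L)
  d$y <- stats::rnorm(nrow(d)) +
    0.5 * as.integer(factor(d$g)) + 0.2 * d$t +
    rep(stats::rnorm(g * n, 0, 0.7), times = Tt)
  d
}

# Small fast scene for imaging tests that do not probe the defaults.
tiny_scene <- function(n_frames = 40L) {
  scene_config(image_size = c(160L, 160L), n_frames = n_frames)
}

ref_times <- c(0, 2, 4, 10, 20, 39)
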
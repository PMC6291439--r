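# Independent oracles and small fixtures shared across tests.

# tiny phantom used where geometry details don't matter
tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(4, 8, 16), ...)
}

# small phantom with a non-empty medulla at erosion depth 1
small_spec <- function(...) {
  phantom_spec(grid_shape = c(6, 12, 24), cortex_depth = 1, ...)
}

# brute-force in-plane city-block distance to the nearest background voxel
# (or array border), per coronal section; d-fold 4-connected erosion keeps
# exactly the voxels with distance > d
cityblock_interior_depth <- function(mask) {
  out <- array(0L, dim = dim(mask))
  nr <- dim(mask)[2]; nc <- dim(mask)[3]
  for (s in seq_len(dim(mask)[1])) {
    sl <- mask[s, , ]
    bg <- which(!sl, arr.ind = TRUE)
    for (idx in which(sl)) {
      i <- (idx - 1) %% nr + 1
      j <- (idx - 1) %/% nr + 1
      d_border <- min(i, nr - i + 1, j, nc - j + 1)
      d_bg <- if (nrow(bg)) min(abs(bg[, 1] - i) + abs(bg[, 2] - j)) else Inf
      out[s, i, j] <- min(d_border, d_bg)
    }
  }
  out
}

# closed-form major-axis slope from the covariance components
ma_slope_closed_form <- function(x, y) {
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  if (sxy == 0) stop("degenerate for the closed form")
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
wilcoxon_exact_enumeration <- function(d) {
  stopifnot(all(d != 0))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# long-hand repeated-measures ANOVA from sums of squares
rm_anova_by_hand <- function(Y) {
  n <- nrow(Y); t_ <- ncol(Y)
  grand <- mean(Y)
  ss_time <- n * sum((colMeans(Y) - grand)^2)
  ss_sub <- t_ * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_time - ss_sub
  F_ <- (ss_time / (t_ - 1)) / (ss_err / ((n - 1) * (t_ - 1)))
  list(F = F_, p = pf(F_, t_ - 1, (n - 1) * (t_ - 1), lower.tail = FALSE))
}
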
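test_that("region summaries pool finite voxels per region and method", {
  p <- asl_protocol()
  spec <- small_spec(noise_sd = 0)
  gt <- make_phantom(spec)
  pwi <- as_pwi(simulate_acquisition(gt, spec, p))
  fit <- fit_gkm_volume(pwi, gt$masks$whole)
  seg <- cortex_by_erosion(gt$masks$whole, 1)
  rows <- summarize_regions(fit, seg, subject = "s01", scan = "scan1")
  expect_setequal(unique(rows$region), c("whole", "cortex", "medulla"))
  cortex_multi <- rows[rows$region == "cortex" & rows$method == "multi_ti", ]
  expect_equal(cortex_multi$mean_f, 190, tolerance = 1e-6)
  expect_equal(cortex_multi$sd_f, 0, tolerance = 1e-4)
  expect_equal(cortex_multi$mean_t1, 790, tolerance = 1e-6)
  whole_multi <- rows[rows$region == "whole" & rows$method == "multi_ti", ]
  expect_equal(whole_multi$n_vox, sum(gt$masks$whole))
  # all-sentinel region errors
  fit_bad <- fit
  fit_bad$f_map[seg$medulla] <- NA
  expect_error(summarize_regions(fit_bad, seg), "no finite")
})

test_that("grand mean over balanced scans equals the mean of scan means", {
  expect_equal(grand_mean(c(182.39, 194.70))$mean, 188.545)
  expect_equal(grand_mean(c(262.45, 277.01))$mean, 269.73)
  expect_equal(grand_mean(5)$mean, 5)
  # invariant to ordering
  set.seed(2)
  v <- rnorm(12)
  expect_equal(grand_mean(v)$mean, grand_mean(rev(v))$mean)
})

test_that("Bland-Altman bias and limits follow the hand computation", {
  ba <- bland_altman(c(1, 3, 5), c(2, 3, 4))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(-1.96, 1.96))
  expect_true(ba$loa[1] < ba$bias && ba$bias < ba$loa[2])
  # identical methods: zero bias and zero-width limits
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(ba0$bias, 0)
  expect_equal(diff(ba0$loa), 0)
  # antisymmetry
  set.seed(4)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(bland_altman(x, y)$bias, -bland_altman(y, x)$bias)
  expect_error(bland_altman(1:2, 2:3), "at least 3")
})

test_that("published between-method biases are recovered from scan summaries", {
  cmp <- reference_method_comparison()
  expect_equal(cmp$bias$bias[cmp$bias$region == "whole"], 29.27,
               tolerance = 0.005)
  expect_equal(cmp$bias$bias[cmp$bias$region == "cortex"], 30.90,
               tolerance = 0.005)
  gm <- cmp$grand_means
  g <- function(par, reg, met)
    gm$grand_mean[gm$parameter == par & gm$region == reg & gm$method == met]
  expect_equal(g("perfusion", "whole", "multi_ti"), 188.545)
  expect_equal(g("perfusion", "whole", "single_ti"), 217.815)
  expect_equal(g("bat", "whole", "multi_ti"), 269.73)
})

test_that("major-axis regression matches its closed-form slope", {
  r <- ma_regression(1:10, 1:10)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  r2 <- ma_regression(1:10, -(1:10))
  expect_equal(r2$slope, -1)
  expect_equal(r2$r_squared, 1)
  set.seed(7)
  x <- rnorm(50); y <- 1.4 * x + rnorm(50, 0, 0.6)
  r3 <- ma_regression(x, y)
  expect_equal(r3$slope, ma_slope_closed_form(x, y), tolerance = 1e-12)
  expect_equal(r3$r_squared, cor(x, y)^2)
  # centroid lies on the line
  expect_equal(mean(y), r3$slope * mean(x) + r3$intercept)
  expect_error(ma_regression(rep(1, 5), 1:5), "variance")
})

test_that("signed-rank p-values match exhaustive sign-flip enumeration", {
  # all-positive differences, n = 6: two-sided exact p = 2/2^6
  w6 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(w6$p_value, 2 / 64)
  expect_true(w6$exact)
  # synthetic shift, n = 12: compare to the 4096-pattern enumeration
  set.seed(19)
  for (shift in c(0, 0.5)) {
    d <- round(rnorm(12, shift, 1), 3)
    d <- d[d != 0]
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcoxon_exact_enumeration(d))
  }
  # zeros are dropped before testing
  wz <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5, 6))
  expect_equal(wz$n_zero_dropped, 2)
  expect_equal(wz$p_value, 2 / 64)
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3)), "at least 5")
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(23)
  n <- 8; t_ <- 5
  d <- expand.grid(subject = sprintf("s%d", 1:n), timepoint = 1:t_)
  d$y <- rnorm(nrow(d)) + rep(rnorm(n), t_) + 0.4 * (d$timepoint == 3)
  res <- rm_anova(d, "y", "subject", "timepoint")
  Y <- matrix(d$y[order(d$subject, d$timepoint)], nrow = n, byrow = TRUE)
  oracle <- rm_anova_by_hand(Y)
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  expect_true(res$epsilon > 0 && res$epsilon <= 1 + 1e-10)
  expect_gte(res$p_gg, res$p_value)
})

test_that("repeated-measures ANOVA handles degenerate and paired designs", {
  # no within-subject variation: F = 0, p = 1
  d0 <- expand.grid(subject = letters[1:4], timepoint = 1:3)
  d0$y <- rep(c(1, 2, 3, 4), 3)
  res0 <- rm_anova(d0, "y", "subject", "timepoint")
  expect_equal(res0$F, 0)
  expect_equal(res0$p_value, 1)
  # two timepoints: F equals the squared paired-t statistic
  set.seed(31)
  d2 <- expand.grid(subject = sprintf("s%d", 1:9), timepoint = 1:2)
  d2$y <- rnorm(18) + 0.5 * (d2$timepoint == 2)
  res2 <- rm_anova(d2, "y", "subject", "timepoint")
  Y <- matrix(d2$y[order(d2$subject, d2$timepoint)], nrow = 9, byrow = TRUE)
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-10)
  # incomplete designs are rejected
  expect_error(rm_anova(d2[-1, ], "y", "subject", "timepoint"), "balanced")
})

test_that("limits of agreement cover ~95% of large normal samples", {
  set.seed(41)
  x <- rnorm(5000); y <- rnorm(5000)
  ba <- bland_altman(x, y)
  d <- x - y
  coverage <- mean(d >= ba$loa[1] & d <= ba$loa[2])
  expect_equal(coverage, 0.95, tolerance = 0.012)
})
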
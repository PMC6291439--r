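#' Per-region summaries of fitted parametric maps
#'
#' Means and standard deviations of perfusion, bolus arrival time and T1
#' over the finite in-region voxels (pooled across both kidneys), per region
#' (whole / cortex / medulla) and method (multi-TI GKM fit / single-TI
#' estimator). Voxels that were skipped or failed to converge carry `NA` in
#' the maps and are excluded; a region with no finite voxels is an error.
#'
#' @param fit an [fit_gkm_volume()] result (or any list with `f_map`,
#'   `bat_map`, `t1_map`, `single_ti_f_map`).
#' @param seg a [kidney_segmentation()] aligned with the maps.
#' @param subject,scan identifier strings carried into the output rows.
#' @return data.frame with columns `subject`, `scan`, `region`, `method`,
#'   `mean_f`, `sd_f`, `mean_bat`, `sd_bat`, `mean_t1`, `sd_t1`,
#'   `median_t1`, `n_vox`.
#' @export
summarize_regions <- function(fit, seg, subject = "s01", scan = "scan1") {
  stopifnot(inherits(seg, "kidney_seg"))
  if (!identical(dim(fit$f_map), dim(seg$whole))) {
    stop("segmentation geometry does not match the maps")
  }
  regions <- list(whole = seg$whole, cortex = seg$cortex,
                  medulla = seg$medulla)
  rows <- list()
  for (rn in names(regions)) {
    rmask <- regions[[rn]]
    if (!any(rmask)) stop(sprintf("region '%s' is empty", rn))
    for (method in c("multi_ti", "single_ti")) {
      fvals <- if (method == "multi_ti") fit$f_map[rmask]
               else fit$single_ti_f_map[rmask]
      fvals_ok <- fvals[is.finite(fvals)]
      if (length(fvals_ok) == 0) {
        stop(sprintf("region '%s' has no finite %s voxels", rn, method))
      }
      if (method == "multi_ti") {
        bat <- fit$bat_map[rmask]; bat <- bat[is.finite(bat)]
        t1 <- fit$t1_map[rmask]; t1 <- t1[is.finite(t1)]
      } else {
        bat <- t1 <- numeric(0)
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, scan = scan, region = rn, method = method,
        mean_f = mean(fvals_ok), sd_f = stats::sd(fvals_ok),
        mean_bat = if (length(bat)) mean(bat) else NA_real_,
        sd_bat = if (length(bat)) stats::sd(bat) else NA_real_,
        mean_t1 = if (length(t1)) mean(t1) else NA_real_,
        sd_t1 = if (length(t1)) stats::sd(t1) else NA_real_,
        median_t1 = if (length(t1)) stats::median(t1) else NA_real_,
        n_vox = length(fvals_ok),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Pooled mean over subject-scan summary values
#'
#' With equal numbers of scans per subject, the mean over all subject-scan
#' values equals the mean of per-scan means; both views are supported by
#' passing either the full vector or the per-scan means.
#'
#' @param values numeric vector of subject-scan (or per-scan) region means.
#' @return List with `mean`, `sd`, `n`.
#' @examples
#' grand_mean(c(182.39, 194.70))$mean  # 188.545
#' @export
grand_mean <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values")
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}

#' Bland-Altman agreement analysis
#'
#' Mean difference (bias) and 95% limits of agreement (bias +/- 1.96 sd of
#' the paired differences), with a t-based confidence interval for the bias
#' and approximate confidence intervals for the limits using the standard
#' `sd * sqrt(3/n)` standard-error approximation.
#'
#' @param x,y paired measurements of the same quantity by two methods
#'   (differences are `x - y`); at least 3 pairs.
#' @param conf confidence level (default 0.95).
#' @return An object of class `bland_altman`: `bias`, `bias_ci`, `sd_diff`,
#'   `loa` (lower, upper), `loa_ci_lower`, `loa_ci_upper`, `n`.
#' @examples
#' ba <- bland_altman(c(1, 3, 5), c(2, 3, 4))
#' ba$bias; ba$loa
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("'x' and 'y' must be paired")
  ok <- is.finite(x) & is.finite(y)
  d <- (x - y)[ok]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  # conventional 1.96 multiplier for 95% limits of agreement
  z <- if (conf == 0.95) 1.96 else stats::qnorm(1 - (1 - conf) / 2)
  loa <- bias + c(-1, 1) * z * s
  se_loa <- s * sqrt(3 / n)
  structure(
    list(bias = bias,
         bias_ci = bias + c(-1, 1) * tq * s / sqrt(n),
         sd_diff = s,
         loa = loa,
         loa_ci_lower = loa[1] + c(-1, 1) * tq * se_loa,
         loa_ci_upper = loa[2] + c(-1, 1) * tq * se_loa,
         n = n, conf = conf),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias: %.2f  [%.2f, %.2f]\n", x$bias, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  limits of agreement: [%.2f, %.2f]\n", x$loa[1], x$loa[2]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, pairs_x, pairs_y, ...) {
  m <- (pairs_x + pairs_y) / 2
  d <- pairs_x - pairs_y
  graphics::plot(m, d, xlab = "mean of methods", ylab = "difference", ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2), col = "red")
  invisible(x)
}

#' Pearson correlation with major-axis regression
#'
#' Squared Pearson correlation together with the major-axis (first
#' principal axis of the bivariate covariance) slope and intercept,
#' appropriate when both variables carry measurement error. Note this is
#' the major axis, not the standardized major axis: the slope is the
#' direction of the leading eigenvector of the covariance matrix and the
#' line passes through the centroid.
#'
#' @param x,y numeric vectors, at least 3 pairs, each with positive
#'   variance.
#' @return An object of class `ma_regression`: `r_squared`, `slope`,
#'   `intercept`, `n`.
#' @examples
#' ma_regression(1:10, 2 * (1:10) + 1)
#' @export
ma_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in 'x' or 'y'")
  }
  S <- stats::cov(cbind(x, y))
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  slope <- v[2] / v[1]
  intercept <- mean(y) - slope * mean(x)
  structure(list(r_squared = stats::cor(x, y)^2, slope = slope,
                 intercept = intercept, n = length(x)),
            class = "ma_regression")
}

#' @export
print.ma_regression <- function(x, ...) {
  cat(sprintf("major-axis regression (n = %d): r^2 = %.3f, slope = %.3f, intercept = %.3f\n",
              x$n, x$r_squared, x$slope, x$intercept))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired values
#'
#' Wrapper producing the exact-distribution p-value for small samples
#' (n <= 25 non-zero differences) and the normal approximation with
#' continuity correction otherwise. Zero differences are dropped before
#' testing (Wilcoxon's original treatment), so the exact distribution
#' remains available in their presence.
#'
#' @param x first measurement (or the differences, if `y` is `NULL`).
#' @param y optional second paired measurement.
#' @return List with `statistic` (V), `p_value`, `n` (non-zero
#'   differences), `n_zero_dropped`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  if (n < 5) stop("need at least 5 non-zero differences")
  exact <- n <= 25
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = n, n_zero_dropped = n_zero,
       exact = exact && !grepl("correction", wt$method))
}

# Greenhouse-Geisser epsilon from the subject x timepoint matrix:
# eps = tr(C S C)^2 / ((t-1) * tr((C S C)^2)) with C the centering matrix.
.gg_epsilon <- function(Y) {
  t_ <- ncol(Y)
  S <- stats::cov(Y)
  C <- diag(t_) - 1 / t_
  D <- C %*% S %*% C
  tr <- sum(diag(D))
  denom <- (t_ - 1) * sum(D * D)
  if (denom <= 0) return(NA_real_)
  tr^2 / denom
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test of a time effect with subject blocking, fitted via
#' `aov(value ~ time + Error(subject))`. Reports the uncorrected p-value
#' and the Greenhouse-Geisser sphericity-corrected p-value alongside the
#' epsilon estimate. Requires a complete balanced subject x timepoint table.
#' A table with no within-subject variation returns `F = 0`, `p = 1`.
#'
#' @param data long-format data.frame.
#' @param value,subject,time column names of the outcome, subject id and
#'   timepoint.
#' @return An object of class `rm_anova`: `F`, `df1`, `df2`, `p_value`,
#'   `epsilon`, `p_gg`, `n_subjects`, `n_timepoints`.
#' @examples
#' d <- expand.grid(subject = letters[1:4], timepoint = 1:3)
#' d$y <- rnorm(nrow(d))
#' rm_anova(d, "y", "subject", "timepoint")
#' @export
rm_anova <- function(data, value, subject, time) {
  df <- data.frame(
    y = data[[value]],
    subject = factor(data[[subject]]),
    time = factor(data[[time]])
  )
  if (any(!is.finite(df$y))) stop("outcome contains non-finite values")
  tab <- table(df$subject, df$time)
  if (any(tab != 1)) {
    stop("design must be complete and balanced (one value per cell)")
  }
  Y <- matrix(df$y[order(df$subject, df$time)],
              nrow = nlevels(df$subject), byrow = TRUE)
  n <- nrow(Y); t_ <- ncol(Y)
  df1 <- t_ - 1
  df2 <- (n - 1) * (t_ - 1)

  fit <- stats::aov(y ~ time + Error(subject), data = df)
  tabw <- summary(fit)[["Error: Within"]][[1]]
  ss_time <- tabw["time", "Sum Sq"]
  ss_err <- tabw["Residuals", "Sum Sq"]
  if (ss_time <= .Machine$double.eps * max(1, sum(df$y^2))) {
    out <- list(F = 0, df1 = df1, df2 = df2, p_value = 1,
                epsilon = NA_real_, p_gg = 1,
                n_subjects = n, n_timepoints = t_)
    class(out) <- "rm_anova"
    return(out)
  }
  F_ <- (ss_time / df1) / (ss_err / df2)
  p <- stats::pf(F_, df1, df2, lower.tail = FALSE)
  eps <- .gg_epsilon(Y)
  p_gg <- if (is.finite(eps)) {
    stats::pf(F_, eps * df1, eps * df2, lower.tail = FALSE)
  } else NA_real_
  out <- list(F = F_, df1 = df1, df2 = df2, p_value = p,
              epsilon = eps, p_gg = p_gg,
              n_subjects = n, n_timepoints = t_)
  class(out) <- "rm_anova"
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA: F(%g, %g) = %.3f, p = %.4g (GG eps = %.3f, p = %.4g)\n",
              x$df1, x$df2, x$F, x$p_value,
              ifelse(is.na(x$epsilon), NaN, x$epsilon),
              ifelse(is.na(x$p_gg), NaN, x$p_gg)))
  invisible(x)
}
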
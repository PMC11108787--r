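#' Derive Braak-conditioned tangle-density thresholds
#'
#' Two-step cutoff derivation for the LC and one allocortical region.
#' Step 1 takes the maximum density among subjects at or below the
#' conditioning Braak stage (stage 0 for the LC; one stage below the
#' stage of interest for the region). Step 2 takes the mean, with a
#' t-based 95% CI, over cognitively unimpaired subjects strictly below
#' that maximum; that mean is the operating classification threshold.
#'
#' @param records data.frame with columns `group`
#'   ("unimpaired"/"impaired"), `braak` (ordinal 0-6),
#'   `lc_tangle_density` and the regional density column
#' @param region name of the regional density column (e.g.
#'   "hippocampus_tangle_density")
#' @param lc_conditioning_stage Braak stage bound for the LC step (default 0)
#' @param region_conditioning_stage Braak stage bound for the region step
#'   (e.g. 2 when staging against Braak III)
#' @param conf level of the t interval
#' @return a `staging_thresholds` list recording both maxima, both
#'   means with CIs, and the n used at every step
#' @export
derive_thresholds <- function(records, region,
                              lc_conditioning_stage = 0L,
                              region_conditioning_stage = 2L,
                              conf = 0.95) {
  if (!region %in% names(records))
    stop("staging error: no column '", region, "' in records", call. = FALSE)
  t_ci <- function(v, what) {
    v <- v[is.finite(v)]
    if (length(v) < 2L)
      stop("staging error: fewer than 2 subjects at step '", what, "'",
           call. = FALSE)
    m <- mean(v)
    half <- stats::qt(1 - (1 - conf) / 2, length(v) - 1L) *
      stats::sd(v) / sqrt(length(v))
    list(mean = m, ci = c(m - half, m + half), n = length(v))
  }
  step_max <- function(dens, stage_bound, what) {
    sel <- records$braak <= stage_bound & is.finite(dens)
    if (!any(sel))
      stop("staging error: empty conditioning set at step '", what, "'",
           call. = FALSE)
    list(max = max(dens[sel]), n = sum(sel))
  }
  unimp <- records$group == "unimpaired"

  lc <- records$lc_tangle_density
  s1 <- step_max(lc, lc_conditioning_stage, "LC max")
  s2 <- t_ci(lc[unimp & lc < s1$max], "LC mean")

  rg <- records[[region]]
  r1 <- step_max(rg, region_conditioning_stage, paste(region, "max"))
  r2 <- t_ci(rg[unimp & rg < r1$max], paste(region, "mean"))

  structure(list(region = region,
                 lc_max_at_braak0 = s1$max, lc_cutoff_mean = s2$mean,
                 lc_cutoff_ci = s2$ci,
                 region_max_at_prior_stage = r1$max,
                 region_cutoff_mean = r2$mean, region_cutoff_ci = r2$ci,
                 n_used = c(lc_max = s1$n, lc_mean = s2$n,
                            region_max = r1$n, region_mean = r2$n)),
            class = "staging_thresholds")
}

#' Classify subjects into four LC/region concordance groups
#'
#' A subject is LC-high iff its LC tangle density strictly exceeds the
#' derived LC mean cutoff, and region-high analogously; ties at a
#' threshold classify as low. Proportions carry exact Clopper-Pearson
#' 95% CIs.
#'
#' @param records as in [derive_thresholds()]
#' @param thresholds a `staging_thresholds`
#' @param threshold_point which derived value to classify against:
#'   the mean (default) or a CI bound for sensitivity reruns
#' @return a `staging_result`: per-subject class factor
#'   (low_low/lc_only/region_only/both), counts, proportions with exact
#'   CIs and the binomial n
#' @export
classify_concordance <- function(records, thresholds,
                                 threshold_point = c("mean", "ci_low", "ci_high")) {
  threshold_point <- match.arg(threshold_point)
  pick <- function(m, ci) switch(threshold_point, mean = m,
                                 ci_low = ci[1], ci_high = ci[2])
  lc_thr <- pick(thresholds$lc_cutoff_mean, thresholds$lc_cutoff_ci)
  rg_thr <- pick(thresholds$region_cutoff_mean, thresholds$region_cutoff_ci)
  lc <- records$lc_tangle_density
  rg <- records[[thresholds$region]]
  ok <- is.finite(lc) & is.finite(rg)
  lc_high <- lc[ok] > lc_thr
  rg_high <- rg[ok] > rg_thr
  cls <- factor(ifelse(lc_high & rg_high, "both",
                ifelse(lc_high, "lc_only",
                ifelse(rg_high, "region_only", "low_low"))),
                levels = c("low_low", "lc_only", "region_only", "both"))
  counts <- table(cls)
  n <- sum(ok)
  props <- lapply(as.integer(counts), function(x) binomial_ci(x, n))
  prop_tab <- data.frame(class = names(counts), count = as.integer(counts),
                         p_hat = vapply(props, `[[`, numeric(1), "p_hat"),
                         ci_low = vapply(props, `[[`, numeric(1), "ci_low"),
                         ci_high = vapply(props, `[[`, numeric(1), "ci_high"))
  structure(list(class = cls, subject_ok = ok, counts = counts,
                 proportions = prop_tab, n = n,
                 lc_threshold = lc_thr, region_threshold = rg_thr,
                 threshold_point = threshold_point),
            class = "staging_result")
}

#' Exact binomial proportion with Clopper-Pearson interval
#'
#' `ci_low = qbeta(alpha/2, x, n-x+1)` (0 when x = 0) and
#' `ci_high = qbeta(1-alpha/2, x+1, n-x)` (1 when x = n), plus the exact
#' two-sided binomial p-value against p = 1/2.
#'
#' @param x success count
#' @param n trials
#' @param alpha 1 - confidence level
#' @return list with p_hat, ci_low, ci_high, p_value_vs_half
#' @export
binomial_ci <- function(x, n, alpha = 0.05) {
  if (n < 1L || x < 0L || x > n)
    stop("domain error: need 0 <= x <= n, n >= 1", call. = FALSE)
  lo <- if (x == 0L) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  list(p_hat = x / n, ci_low = lo, ci_high = hi,
       p_value_vs_half = stats::binom.test(x, n, 0.5)$p.value)
}

#' Pairwise Welch's t-tests across concordance groups
#'
#' Welch t with Satterthwaite degrees of freedom for every pair of
#' classes, on a continuous variable such as amyloid percent area.
#'
#' @param groups factor (or character) of class labels
#' @param values numeric vector (same length)
#' @param conf CI level for the mean difference
#' @return data.frame with group pair, n per group, mean difference,
#'   t, df, CI and two-sided p
#' @export
welch_pairwise <- function(groups, values, conf = 0.95) {
  groups <- factor(groups)
  ok <- !is.na(groups) & is.finite(values)
  groups <- droplevels(groups[ok]); values <- values[ok]
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(group1 = pr[1], group2 = pr[2],
                        n1 = length(a), n2 = length(b),
                        mean_diff = mean(a) - mean(b), t = NA_real_,
                        df = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_))
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    t <- (mean(a) - mean(b)) / se
    half <- stats::qt(1 - (1 - conf) / 2, df) * se
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(a), n2 = length(b),
               mean_diff = mean(a) - mean(b), t = t, df = df,
               ci_low = mean(a) - mean(b) - half,
               ci_high = mean(a) - mean(b) + half,
               p = 2 * stats::pt(-abs(t), df))
  })
  do.call(rbind, rows)
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms x and y (average ranks for ties), residualizes both
#' rank vectors on an intercept plus the covariates by OLS, and returns
#' the Pearson correlation of the residuals with a t-based p-value on
#' n - 2 - p degrees of freedom. With no covariates this reduces to the
#' plain Spearman rho.
#'
#' @param x,y numeric vectors
#' @param covariates optional data.frame or matrix
#' @return list with rho, p, n, df
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  keep <- stats::complete.cases(cbind(x, y, covariates))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  p <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n <= p + 2L)
    stop("too few complete cases (", n, ") for ", p, " covariates",
         call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: constant ranks", call. = FALSE)
  if (p > 0L) {
    Z <- .design_matrix(rep(0, n),
                        as.data.frame(covariates)[keep, , drop = FALSE])[, -2, drop = FALSE]
    rx <- stats::lm.fit(Z, rx)$residuals
    ry <- stats::lm.fit(Z, ry)$residuals
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - p
  tstat <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df)
}
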
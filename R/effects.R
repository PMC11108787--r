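#' Names of the five PACC5 component tests
#' @export
pacc5_tests <- c("mmse", "lm_delayed_recall", "digit_symbol",
                 "fcsrt_free_total", "category_fluency")

#' Compose the PACC5 cognitive composite
#'
#' The composite is the mean of the z-transformed scores of five tests
#' (MMSE, Logical Memory Delayed Recall, Digit Symbol, FCSRT free+total,
#' Category Fluency). Reference means/sds default to the supplied cohort
#' (so the reference cohort's composite has mean 0); any missing
#' component leaves the composite missing.
#'
#' @param raw_scores data.frame containing the columns in [pacc5_tests]
#' @param reference_stats optional data.frame with columns test, mean, sd
#' @return `raw_scores` with added z-score columns (`z_<test>`) and
#'   `pacc5_z`; the reference stats used are attached as attribute
#'   `reference_stats`
#' @export
compose_pacc5 <- function(raw_scores, reference_stats = NULL) {
  miss <- setdiff(pacc5_tests, names(raw_scores))
  if (length(miss) > 0L)
    stop("missing PACC5 component column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(reference_stats)) {
    reference_stats <- data.frame(
      test = pacc5_tests,
      mean = vapply(pacc5_tests, function(t) mean(raw_scores[[t]], na.rm = TRUE),
                    numeric(1)),
      sd = vapply(pacc5_tests, function(t) stats::sd(raw_scores[[t]], na.rm = TRUE),
                  numeric(1)))
  }
  if (any(!is.finite(reference_stats$sd)) || any(reference_stats$sd == 0))
    stop("degenerate reference: zero or undefined sd for ",
         paste(reference_stats$test[!is.finite(reference_stats$sd) |
                                      reference_stats$sd == 0],
               collapse = ", "), call. = FALSE)
  zmat <- sapply(pacc5_tests, function(t) {
    st <- reference_stats[reference_stats$test == t, ]
    (raw_scores[[t]] - st$mean) / st$sd
  })
  zmat <- matrix(zmat, ncol = length(pacc5_tests),
                 dimnames = list(NULL, paste0("z_", pacc5_tests)))
  out <- cbind(raw_scores, zmat)
  out$pacc5_z <- rowMeans(zmat)  # NA if any component missing
  attr(out, "reference_stats") <- reference_stats
  out
}

#' Robust linear regression by Huber M-estimation
#'
#' Iteratively reweighted least squares with the Huber psi (tuning
#' constant 1.345, 95% efficiency under normality) and MAD residual
#' scale, iterated to relative coefficient change < 1e-8 or 200
#' iterations. On clean data the estimate coincides with OLS.
#'
#' @param y numeric response
#' @param X numeric design matrix, or data.frame of predictors (an
#'   intercept column is added if absent)
#' @param k Huber tuning constant
#' @param max_iter,tol IRLS controls
#' @return list with coefficients, se, t, p, df, n_used, iterations, scale
#' @export
robust_fit <- function(y, X, k = 1.345, max_iter = 200L, tol = 1e-8) {
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  if (!any(apply(X, 2, function(c) all(c == c[1]))))
    X <- cbind(`(Intercept)` = 1, X)
  keep <- stats::complete.cases(cbind(y, X))
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("too few complete cases for robust fit", call. = FALSE)
  .check_design(X)
  b <- qr.coef(qr(X), y)
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% b)
    s <- stats::mad(r, center = 0)
    if (s == 0) s <- stats::sd(r)
    if (s == 0) break  # perfect fit
    u <- r / s
    w <- pmin(1, k / pmax(abs(u), .Machine$double.eps))
    b_new <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
    delta <- max(abs(b_new - b)) / max(max(abs(b)), 1e-12)
    b <- b_new
    if (delta < tol) break
  }
  if (it == max_iter && delta >= tol)
    stop("robust_fit did not converge in ", max_iter,
         " iterations (last relative change ", signif(delta, 3), ")",
         call. = FALSE)
  r <- y - drop(X %*% b)
  s <- stats::mad(r, center = 0)
  if (s == 0) s <- max(stats::sd(r), .Machine$double.eps)
  u <- r / s
  psi <- pmax(pmin(u, k), -k)
  dpsi <- as.numeric(abs(u) <= k)
  kappa <- 1 + p * stats::var(dpsi) / (n * mean(dpsi)^2)  # Huber correction
  v <- kappa^2 * (s^2 * sum(psi^2) / (n - p)) / mean(dpsi)^2
  se <- sqrt(diag(v * solve(crossprod(X))))
  tstat <- b / se
  df <- n - p
  list(coefficients = b, se = se, t = tstat,
       p = 2 * stats::pt(-abs(tstat), df), df = df, n_used = n,
       iterations = it, scale = s)
}

#' Johnson-Neyman region of significance for a moderated slope
#'
#' Fits `y ~ x + m + x:m + covariates` and solves for the moderator
#' values at which the simple slope of `x`, `b1 + b3 m`, is exactly at
#' the two-tailed critical t. Boundaries are returned in the moderator's
#' units together with the sign pattern of the significance region.
#'
#' @param y,x,m numeric vectors (outcome, focal predictor, moderator)
#' @param covariates optional data.frame
#' @param alpha two-tailed significance level
#' @return a `jn_result`: b1, b3, var entries, t_crit, df, boundaries
#'   (sorted, possibly empty), region_type in
#'   {above, below, inside, outside, everywhere, nowhere}; everywhere and
#'   nowhere are judged over the observed moderator range
#' @export
johnson_neyman <- function(y, x, m, covariates = NULL, alpha = 0.05) {
  keep <- stats::complete.cases(cbind(y, x, m, covariates))
  y <- y[keep]; x <- x[keep]; m <- m[keep]
  X <- cbind(`(Intercept)` = 1, x = x, m = m, `x:m` = x * m)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)[keep, , drop = FALSE]
    X <- .design_matrix(x, cv)  # reuse factor coding
    X <- cbind(X[, 1, drop = FALSE], x = x, m = m, `x:m` = x * m,
               X[, -(1:2), drop = FALSE])
  }
  .check_design(X)
  fit <- stats::lm.fit(X, y)
  df <- fit$df.residual
  sigma2 <- sum(fit$residuals^2) / df
  V <- sigma2 * solve(crossprod(X))
  b1 <- fit$coefficients["x"]; b3 <- fit$coefficients["x:m"]
  v11 <- V["x", "x"]; v33 <- V["x:m", "x:m"]; v13 <- V["x", "x:m"]
  t_crit <- stats::qt(1 - alpha / 2, df)
  # significant where q(M) = A M^2 + B M + C > 0
  A <- b3^2 - t_crit^2 * v33
  B <- 2 * (b1 * b3 - t_crit^2 * v13)
  C <- b1^2 - t_crit^2 * v11
  scale_q <- max(abs(c(A, B, C)), .Machine$double.eps)
  boundaries <- numeric(0)
  if (abs(A) < 1e-12 * scale_q) {
    if (abs(B) < 1e-12 * scale_q) {
      region <- if (C > 0) "everywhere" else "nowhere"
    } else {
      boundaries <- -C / B
      region <- if (B > 0) "above" else "below"
    }
  } else {
    disc <- B^2 - 4 * A * C
    if (disc <= 0) {
      region <- if (A > 0) "everywhere" else "nowhere"
    } else {
      boundaries <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
      region <- if (A > 0) "outside" else "inside"
    }
  }
  # everywhere/nowhere are judged over the observed moderator values:
  # a region of significance that no observed value reaches is "nowhere"
  if (length(boundaries) > 0) {
    sig_obs <- A * m^2 + B * m + C > 0
    if (all(sig_obs)) region <- "everywhere"
    else if (!any(sig_obs)) region <- "nowhere"
  }
  structure(list(b1 = unname(b1), b3 = unname(b3), var_b1 = v11,
                 var_b3 = v33, cov_b1_b3 = v13, t_crit = t_crit, df = df,
                 boundaries = unname(boundaries), region_type = region,
                 alpha = alpha, n_used = length(y)),
            class = "jn_result")
}

#' Simple slope of x at a given moderator value (helper for JN checks)
#' @param jn a `jn_result`
#' @param m_value moderator value(s)
#' @return data.frame with slope, se and |t| at each value
#' @export
jn_simple_slope <- function(jn, m_value) {
  slope <- jn$b1 + jn$b3 * m_value
  se <- sqrt(jn$var_b1 + m_value^2 * jn$var_b3 + 2 * m_value * jn$cov_b1_b3)
  data.frame(m = m_value, slope = slope, se = se, t_abs = abs(slope) / se)
}

#' Nonparametric bootstrap mediation
#'
#' Path model with x as predictor, a mediator and an outcome y:
#' a from `mediator ~ x + cov`; b and c' from `y ~ x + mediator + cov`;
#' total from `y ~ x + cov`. With the same covariates in all three
#' regressions the OLS identity `a*b + c' = total` holds exactly on every
#' bootstrap draw. Percentile CIs and two-tailed bootstrap p-values come
#' from `n_boot` subject resamples.
#'
#' @param x,mediator,y numeric vectors
#' @param covariates optional data.frame
#' @param n_boot bootstrap draws
#' @param seed integer seed
#' @param alpha CI level is 1-alpha
#' @return a `mediation_result` with a, b, c_prime, indirect, total,
#'   prop_mediated, their CIs and bootstrap p-values
#' @export
mediate <- function(x, mediator, y, covariates = NULL, n_boot = 5000L,
                    seed = 1L, alpha = 0.05) {
  keep <- stats::complete.cases(cbind(x, mediator, y, covariates))
  x <- x[keep]; mediator <- mediator[keep]; y <- y[keep]
  cv <- if (is.null(covariates)) NULL
        else as.matrix(.design_matrix(x, as.data.frame(covariates)[keep, , drop = FALSE])[, -(1:2), drop = FALSE])
  n <- length(x)
  if (n < 10L) stop("insufficient data: mediation needs n >= 10, got ", n,
                    call. = FALSE)
  paths <- function(idx) {
    xi <- x[idx]; mi <- mediator[idx]; yi <- y[idx]
    ci <- if (is.null(cv)) NULL else cv[idx, , drop = FALSE]
    Xa <- cbind(1, xi, ci)
    Xb <- cbind(1, xi, mi, ci)
    a <- stats::lm.fit(Xa, mi)$coefficients[2]
    cb <- stats::lm.fit(Xb, yi)$coefficients
    tot <- stats::lm.fit(Xa, yi)$coefficients[2]
    c(a = unname(a), b = unname(cb[3]), c_prime = unname(cb[2]),
      indirect = unname(a * cb[3]), total = unname(tot))
  }
  est <- paths(seq_len(n))
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 5,
                  dimnames = list(NULL, names(est)))
  for (i in seq_len(n_boot))
    draws[i, ] <- paths(sample.int(n, n, replace = TRUE))
  draws <- cbind(draws, prop_mediated = draws[, "indirect"] / draws[, "total"])
  est <- c(est, prop_mediated = unname(est["indirect"] / est["total"]))
  qs <- apply(draws, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  boot_p <- apply(draws, 2, function(d)
    2 * min(mean(d < 0, na.rm = TRUE), mean(d > 0, na.rm = TRUE)))
  unstable <- abs(est["total"]) < 1e-8 * stats::sd(y)
  structure(list(estimates = est,
                 ci_low = qs[1, ], ci_high = qs[2, ], boot_p = boot_p,
                 n_boot = as.integer(n_boot), n_used = n, seed = seed,
                 prop_mediated_unstable = unname(unstable),
                 draws = draws),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  tab <- data.frame(estimate = x$estimates, ci_low = x$ci_low,
                    ci_high = x$ci_high, boot_p = x$boot_p)
  cat(sprintf("Bootstrap mediation (n = %d, %d draws)\n", x$n_used, x$n_boot))
  print(round(tab, 4))
  invisible(x)
}

#' Two-component Gaussian mixture threshold for amyloid positivity
#'
#' Fits a two-component univariate Gaussian mixture by EM (k-means
#' initialization, best log-likelihood over restarts) and returns the
#' point between the component means where the posterior responsibility
#' equals 0.5 — the natural positivity cutoff for a bimodal tracer
#' distribution such as PiB DVR.
#'
#' @param dvr numeric vector of tracer values
#' @param n_restarts EM restarts (default 100)
#' @param max_iter,tol EM controls
#' @param seed integer seed for the restarts
#' @return scalar cutoff with attribute `fit` (means, sds, weights,
#'   loglik); NA with a warning when the components merge
#' @export
gmm_abeta_threshold <- function(dvr, n_restarts = 100L, max_iter = 500L,
                                tol = 1e-10, seed = 1L) {
  x <- dvr[is.finite(dvr)]
  n <- length(x)
  if (n < 10L) stop("need >= 10 values to fit a mixture", call. = FALSE)
  sd_floor <- 1e-3 * stats::sd(x)
  if (sd_floor == 0) stop("constant input: no mixture to fit", call. = FALSE)
  loglik <- function(mu, sg, w)
    sum(log(w[1] * stats::dnorm(x, mu[1], sg[1]) +
            w[2] * stats::dnorm(x, mu[2], sg[2])))
  em <- function(mu, sg, w) {
    ll <- -Inf
    for (i in seq_len(max_iter)) {
      d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
      d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
      g <- d1 / (d1 + d2)
      g[!is.finite(g)] <- 0.5
      w <- c(mean(g), 1 - mean(g))
      mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
      sg <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                   sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
      sg <- pmax(sg, sd_floor)
      ll_new <- loglik(mu, sg, w)
      if (is.finite(ll) && abs(ll_new - ll) < tol) break
      ll <- ll_new
    }
    list(mu = mu, sg = sg, w = w, ll = ll_new)
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- stats::kmeans(x, centers = 2L, nstart = 1L)
    mu <- as.numeric(km$centers)
    sg <- pmax(tapply(x, km$cluster, stats::sd), sd_floor)
    sg[is.na(sg)] <- sd_floor
    w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / n
    w <- pmax(w, 1e-3); w <- w / sum(w)
    fit <- em(mu, as.numeric(sg), w)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  ord <- order(best$mu)
  mu <- best$mu[ord]; sg <- best$sg[ord]; w <- best$w[ord]
  fit <- list(means = mu, sds = sg, weights = w, loglik = best$ll)
  # merged components, or a fitted mixture with no density dip between
  # the means, indicate unimodal data: no meaningful cutoff exists
  pooled_sd <- sqrt(stats::weighted.mean(sg^2, w))
  mix_dens <- function(v)
    w[1] * stats::dnorm(v, mu[1], sg[1]) + w[2] * stats::dnorm(v, mu[2], sg[2])
  grid <- seq(mu[1], mu[2], length.out = 512L)
  has_dip <- min(mix_dens(grid)) < 0.99 * min(mix_dens(mu))
  if (abs(diff(mu)) < 0.1 * pooled_sd || !has_dip) {
    warning("unimodal data: mixture components merged; cutoff undefined")
    return(structure(NA_real_, fit = fit))
  }
  # posterior log-odds stay finite where the densities underflow
  logodds <- function(v)
    (log(w[1]) + stats::dnorm(v, mu[1], sg[1], log = TRUE)) -
      (log(w[2]) + stats::dnorm(v, mu[2], sg[2], log = TRUE))
  cutoff <- if (sign(logodds(mu[1])) != sign(logodds(mu[2]))) {
    stats::uniroot(logodds, lower = mu[1], upper = mu[2], tol = 1e-10)$root
  } else {
    grid[which.min(abs(logodds(grid)))]  # flat-posterior fallback
  }
  structure(cutoff, fit = fit)
}
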
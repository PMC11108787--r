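#' Stack subject volumes into a subjects-by-voxels matrix
#'
#' @param vols list of `brain_volume` objects sharing geometry
#' @param mask analysis mask (`brain_volume`)
#' @return numeric matrix, one row per subject, one column per in-mask voxel
#' @export
stack_volumes <- function(vols, mask) {
  m <- as_mask_array(mask, vols[[1]])
  idx <- which(m)
  for (v in vols[-1]) check_same_geometry(v, vols[[1]])
  res <- vapply(vols, function(v) v$data[idx], numeric(length(idx)))
  if (length(idx) == 1L) matrix(res, ncol = 1L) else t(res)
}

.design_matrix <- function(predictor, covariates) {
  X <- cbind(`(Intercept)` = 1, predictor = predictor)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      col <- covariates[[nm]]
      if (is.factor(col) || is.character(col))
        col <- as.numeric(factor(col)) - 1  # 0/1 for two-level factors
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- nm
    }
  }
  X
}

.check_design <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design: collinear column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  qrX
}

.t_to_z <- function(t, df, eps = 1e-15) {
  p <- stats::pt(t, df)
  p <- pmin(pmax(p, eps), 1 - eps)
  stats::qnorm(p)
}

.mass_ols <- function(Y, X, term) {
  qrX <- .check_design(X)
  n <- nrow(X); p <- ncol(X); df <- n - p
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  XtXinv <- solve(crossprod(X))
  j <- match(term, colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  t <- beta[j, ] / se
  t[se == 0] <- ifelse(beta[j, se == 0] > 0, Inf,
                       ifelse(beta[j, se == 0] < 0, -Inf, 0))
  list(beta = beta[j, ], t = t, df = df, n = n, residuals = res)
}

.as_map <- function(values, mask, template) {
  m <- as_mask_array(mask, template)
  arr <- array(0, dim = dim(template$data))
  arr[which(m)] <- values
  brain_volume(arr, affine = template$affine)
}

#' Mass-univariate OLS of outcome volumes on a subject-level predictor
#'
#' Per voxel, fits `outcome ~ 1 + predictor + covariates` by OLS over
#' complete cases and reports the predictor's beta, t and z maps
#' (z obtained through the t CDF with clamping at 1e-15).
#'
#' @param outcome_maps list of per-subject `brain_volume` outcomes
#' @param predictor numeric vector, one value per subject
#' @param covariates optional data.frame of nuisance covariates
#' @param mask analysis mask
#' @return a `voxel_model_result` list: beta_map, t_map, z_map
#'   (`brain_volume`s), df, n_used, n_dropped, model_spec
#' @export
fit_voxelwise <- function(outcome_maps, predictor, covariates = NULL, mask) {
  keep <- stats::complete.cases(cbind(predictor, covariates))
  n_drop <- sum(!keep)
  Y <- stack_volumes(outcome_maps[keep], mask)
  X <- .design_matrix(predictor[keep],
                      if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE])
  if (nrow(X) < ncol(X) + 2L)
    stop("too few complete cases (", nrow(X), ") for ", ncol(X),
         " design columns", call. = FALSE)
  fit <- .mass_ols(Y, X, "predictor")
  template <- outcome_maps[[1]]
  structure(list(beta_map = .as_map(fit$beta, mask, template),
                 t_map = .as_map(fit$t, mask, template),
                 z_map = .as_map(.t_to_z(fit$t, fit$df), mask, template),
                 df = fit$df, n_used = fit$n, n_dropped = n_drop,
                 model_spec = paste("voxel ~ predictor +",
                                    paste(names(covariates), collapse = " + "))),
            class = "voxel_model_result")
}

#' Residualize outcome volumes against a nuisance covariate
#'
#' Two-step nuisance correction: per voxel, the outcome is replaced by its
#' residual from `outcome ~ 1 + nuisance`, leaving maps orthogonal to the
#' nuisance vector.
#'
#' @param outcome_maps list of per-subject `brain_volume`s
#' @param nuisance numeric vector, one value per subject
#' @param mask analysis mask
#' @return list of residualized `brain_volume`s (zero outside the mask)
#' @export
residualize_against <- function(outcome_maps, nuisance, mask) {
  Y <- stack_volumes(outcome_maps, mask)
  X <- cbind(1, nuisance)
  res <- stats::lm.fit(X, Y)$residuals
  template <- outcome_maps[[1]]
  lapply(seq_len(nrow(res)), function(i) .as_map(res[i, ], mask, template))
}

#' Voxel-wise moderation model with a mean-centered product term
#'
#' Fits `outcome ~ 1 + predictor + moderator + predictor:moderator +
#' covariates` per voxel, centering predictor and moderator before the
#' product so the z-map for the interaction is invariant to constant
#' shifts of either variable.
#'
#' @inheritParams fit_voxelwise
#' @param moderator numeric vector (e.g. neocortical amyloid DVR)
#' @return a `voxel_model_result` whose maps refer to the product term
#' @export
fit_interaction <- function(outcome_maps, predictor, moderator,
                            covariates = NULL, mask) {
  keep <- stats::complete.cases(cbind(predictor, moderator, covariates))
  Y <- stack_volumes(outcome_maps[keep], mask)
  xc <- predictor[keep] - mean(predictor[keep])
  mc <- moderator[keep] - mean(moderator[keep])
  X <- .design_matrix(xc, if (is.null(covariates)) NULL
                      else covariates[keep, , drop = FALSE])
  X <- cbind(X[, 1:2, drop = FALSE], moderator = mc, interaction = xc * mc,
             X[, -(1:2), drop = FALSE])
  fit <- .mass_ols(Y, X, "interaction")
  template <- outcome_maps[[1]]
  structure(list(beta_map = .as_map(fit$beta, mask, template),
                 t_map = .as_map(fit$t, mask, template),
                 z_map = .as_map(.t_to_z(fit$t, fit$df), mask, template),
                 df = fit$df, n_used = fit$n, n_dropped = sum(!keep),
                 model_spec = "voxel ~ x + m + x:m + covariates"),
            class = "voxel_model_result")
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates Gaussian white-noise volumes on the mask's grid, smooths them
#' with the stated FWHM, re-standardizes within the mask, thresholds at
#' the one-tailed voxel z threshold and records each iteration's maximum
#' cluster size. The returned extent threshold is one more than the
#' `ceiling((1-alpha)*n_iter)`-th order statistic of those maxima, so a
#' cluster must exceed the (1-alpha) quantile of null maxima to survive.
#'
#' @param mask analysis mask (`brain_volume`; voxel size read from affine)
#' @param smoothing_fwhm_mm assumed smoothness (FWHM, mm); smaller than
#'   the voxel size triggers a warning and no smoothing
#' @param voxel_z_threshold one-tailed voxel threshold
#' @param alpha cluster-level alpha
#' @param n_iter Monte-Carlo iterations (>= 100)
#' @param seed integer seed
#' @param connectivity cluster connectivity (default 26)
#' @return integer extent threshold, with attribute `max_sizes` carrying
#'   the simulated null distribution
#' @export
mc_cluster_threshold <- function(mask, smoothing_fwhm_mm = 8,
                                 voxel_z_threshold = 1.64, alpha = 0.05,
                                 n_iter = 10000L, seed = 1L,
                                 connectivity = 26L) {
  if (n_iter < 100L) stop("n_iter must be >= 100", call. = FALSE)
  m <- as_mask_array(mask)
  d <- dim(m)
  vs <- voxel_size(mask)
  sigma_vox <- smoothing_fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  if (smoothing_fwhm_mm > 0 && smoothing_fwhm_mm < min(vs)) {
    warning("FWHM below voxel size; simulating unsmoothed noise")
    sigma_vox <- rep(0, 3)
  }
  if (smoothing_fwhm_mm <= 0) sigma_vox <- rep(0, 3)
  idx <- which(m)
  set.seed(seed)
  max_sizes <- integer(n_iter)
  flag <- array(FALSE, dim = d)
  for (it in seq_len(n_iter)) {
    noise <- array(stats::rnorm(prod(d)), dim = d)
    if (any(sigma_vox > 0)) noise <- smooth_gaussian(noise, sigma_vox)
    v <- noise[idx]
    z <- (v - mean(v)) / stats::sd(v)
    flag[] <- FALSE
    flag[idx[z > voxel_z_threshold]] <- TRUE
    comp <- label_components(flag, connectivity)
    max_sizes[it] <- if (length(comp$sizes) > 0L) comp$sizes[1] else 0L
  }
  k <- ceiling((1 - alpha) * n_iter)
  thr <- sort(max_sizes)[k] + 1L
  structure(as.integer(thr), max_sizes = max_sizes)
}

#' Extract suprathreshold clusters surviving an extent threshold
#'
#' @param z_map z-statistic `brain_volume`
#' @param mask analysis mask
#' @param voxel_z_threshold one-tailed voxel threshold
#' @param extent_threshold minimum surviving cluster size (voxels)
#' @param connectivity 26 (default) or 6
#' @return a `cluster_set`: label_map (`brain_volume`, labels ordered by
#'   decreasing size), sizes, and the thresholds used
#' @export
extract_clusters <- function(z_map, mask, voxel_z_threshold = 1.64,
                             extent_threshold = 1L, connectivity = 26L) {
  m <- as_mask_array(mask, z_map)
  flag <- m & (z_map$data > voxel_z_threshold)
  comp <- label_components(flag, connectivity)
  keep <- which(comp$sizes >= extent_threshold)
  labels <- comp$labels
  relab <- integer(length(comp$sizes))
  relab[keep] <- seq_along(keep)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  structure(list(label_map = brain_volume(labels, affine = z_map$affine),
                 sizes = comp$sizes[keep],
                 extent_threshold = as.integer(extent_threshold),
                 voxel_z_threshold = voxel_z_threshold),
            class = "cluster_set")
}

#' Summarize a cluster_set as a table
#' @param clusters a `cluster_set`
#' @param z_map optional z-map for peak statistics
#' @return data.frame with label, size, peak z and peak voxel indices
#' @export
cluster_table <- function(clusters, z_map = NULL) {
  n <- length(clusters$sizes)
  out <- data.frame(label = seq_len(n), size = as.integer(clusters$sizes),
                    peak_z = NA_real_, peak_i = NA_integer_,
                    peak_j = NA_integer_, peak_k = NA_integer_)
  if (!is.null(z_map) && n > 0L) {
    for (l in seq_len(n)) {
      idx <- which(clusters$label_map$data == l)
      pk <- idx[which.max(z_map$data[idx])]
      co <- arrayInd(pk, dim(z_map$data))
      out$peak_z[l] <- z_map$data[pk]
      out[l, c("peak_i", "peak_j", "peak_k")] <- co - 1L  # 0-based
    }
  }
  out
}

#' Compare forward and reverse directional models over cluster voxels
#'
#' Extracts the predictor's partial correlation at every voxel of the
#' surviving clusters for both directions (partial r = t / sqrt(t^2 + df),
#' unitless and comparable across models on different scales), then runs a
#' paired t-test over voxels and reports the Pearson correlation between
#' the two coefficient vectors.
#'
#' @param forward,reverse `voxel_model_result`s sharing geometry
#' @param clusters a `cluster_set` (typically from the forward analysis)
#' @param labels which cluster labels to pool (default: all)
#' @return a `directional_comparison` list: coeffs_forward,
#'   coeffs_reverse, mean_difference, t_stat, df, ci_low, ci_high,
#'   p_value, pearson_r
#' @export
compare_directions <- function(forward, reverse, clusters,
                               labels = NULL) {
  check_same_geometry(forward$t_map, reverse$t_map)
  check_same_geometry(forward$t_map, clusters$label_map)
  lm_ <- clusters$label_map$data
  if (is.null(labels)) labels <- seq_along(clusters$sizes)
  idx <- which(lm_ %in% labels)
  if (length(idx) < 2L)
    stop("degenerate df: need >= 2 cluster voxels, got ", length(idx),
         call. = FALSE)
  pr <- function(fit) {
    t <- fit$t_map$data[idx]
    t / sqrt(t^2 + fit$df)
  }
  cf <- pr(forward); cr <- pr(reverse)
  diffs <- cf - cr
  if (stats::sd(diffs) < 1e-12 * max(abs(mean(diffs)), 1)) {
    # degenerate paired t: identical vectors give t = 0, a constant
    # nonzero shift gives an unbounded statistic
    d <- mean(diffs)
    res <- list(mean_difference = d,
                t_stat = if (d == 0) 0 else sign(d) * Inf,
                df = length(diffs) - 1L, ci_low = d, ci_high = d,
                p_value = if (d == 0) 1 else 0)
  } else {
    tt <- stats::t.test(cf, cr, paired = TRUE)
    res <- list(mean_difference = unname(tt$estimate),
                t_stat = unname(tt$statistic), df = unname(tt$parameter),
                ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                p_value = tt$p.value)
  }
  structure(c(list(coeffs_forward = cf, coeffs_reverse = cr), res,
              list(pearson_r = suppressWarnings(stats::cor(cf, cr)))),
            class = "directional_comparison")
}
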
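#' Default slab geometry for the LC simulator
#'
#' A 6-slice slab (3-mm slices) with bilateral 2 x 2 x 6 LC masks and a
#' central pontine-tegmentum reference mask.
#'
#' @param shape grid shape (default 14 x 8 x 6)
#' @return list with lc_mask_left, lc_mask_right, ref_mask
#'   (`brain_volume`s) and `affine`
#' @export
lc_slab_geometry <- function(shape = c(14L, 8L, 6L)) {
  affine <- diag(c(0.4, 0.4, 3.0, 1))
  mk <- function(ii, jj) {
    a <- array(0, dim = shape)
    a[ii, jj, ] <- 1
    brain_volume(a, affine = affine)
  }
  list(lc_mask_left = mk(3:4, 4:5),
       lc_mask_right = mk(shape[1] - 3:4 + 1L, 4:5),
       ref_mask = mk(6:9, 3:6),
       affine = affine)
}

#' Simulate an LC MRI slab with a planted bright quintet
#'
#' The slab has a flat baseline signal; the five planted voxels carry a
#' multiplicative contrast so that after per-slice reference
#' normalization they equal `contrast` exactly in the noise-free case.
#'
#' @param lc_mask LC mask (`brain_volume`) that must contain the cluster
#' @param ref_mask reference mask
#' @param planted_cluster linear voxel indices of the planted set
#'   (must be 26-connected and lie inside `lc_mask`)
#' @param contrast planted normalized contrast (default 0.3)
#' @param noise_sd noise sd on the normalized scale (default 0)
#' @param baseline raw baseline signal (default 100)
#' @param seed integer seed
#' @return list with `slab` (`brain_volume`) and a `truth` record
#' @export
gen_lc_slab <- function(lc_mask, ref_mask, planted_cluster, contrast = 0.3,
                        noise_sd = 0, baseline = 100, seed = 1L) {
  mask <- as_mask_array(lc_mask)
  d <- dim(mask)
  if (!all(mask[planted_cluster]))
    stop("spec error: planted cluster not inside the LC mask", call. = FALSE)
  flag <- array(FALSE, dim = d); flag[planted_cluster] <- TRUE
  comp <- label_components(flag)
  if (length(comp$sizes) != 1L)
    stop("spec error: planted cluster is not 26-connected", call. = FALSE)
  data <- array(baseline, dim = d)
  data[planted_cluster] <- baseline * (1 + contrast)
  if (noise_sd > 0) {
    set.seed(seed)
    data <- data + stats::rnorm(length(data), sd = noise_sd * baseline)
  }
  list(slab = brain_volume(data, affine = lc_mask$affine),
       truth = list(contrast = contrast, noise_sd = noise_sd,
                    baseline = baseline, planted_cluster = planted_cluster,
                    seed = seed))
}

#' Specification of a synthetic longitudinal cohort
#'
#' Defaults state the emulated world: 77 subjects (65% female, age
#' 42-90), a 20^3 SUVR grid at 2-mm voxels, a 27-voxel MTL cluster
#' carrying the planted LC -> follow-up-tau slope, a second cluster
#' carrying the LC x amyloid interaction, a two-component amyloid
#' mixture whose analytic posterior crossing sits near the 1.324 DVR
#' positivity cutoff, and a planted LC -> tau -> cognition mediation
#' path. Two subjects have missing amyloid and three have missing
#' follow-up cognition, mirroring per-analysis complete-case ns of
#' 75 and 74.
#'
#' @param n_subjects cohort size
#' @param grid_shape 3D grid of the tau volumes
#' @param mtl_cluster_voxels linear indices of the main-effect cluster
#'   (default: a 3 x 3 x 3 block)
#' @param interaction_cluster_voxels linear indices of the interaction
#'   cluster (default: a distinct 3 x 3 x 3 block)
#' @param beta_lc_tau planted voxel-level slope of follow-up tau on
#'   baseline LC intensity_r inside the MTL cluster
#' @param beta_interaction planted LC x centered-amyloid product slope
#'   inside the interaction cluster
#' @param mediation_a,mediation_b,mediation_c_prime planted path
#'   coefficients (indirect effect = a*b)
#' @param noise_sd_tau,noise_sd_cog noise sds (SUVR / z-score units)
#' @param abeta_mixture list(means, sds, weight) of the amyloid mixture
#' @param missing_pib,missing_cog counts of planted missing values
#' @param seed integer seed
#' @return a `cohort_sim_spec`
#' @export
cohort_sim_spec <- function(n_subjects = 77L,
                            grid_shape = c(20L, 20L, 20L),
                            mtl_cluster_voxels = NULL,
                            interaction_cluster_voxels = NULL,
                            beta_lc_tau = 0.5,
                            beta_interaction = 0.4,
                            mediation_a = 0.5,
                            mediation_b = 0.4,
                            mediation_c_prime = 0.1,
                            noise_sd_tau = 0.2,
                            noise_sd_cog = 0.5,
                            abeta_mixture = list(means = c(1.1, 1.6),
                                                 sds = c(0.05, 0.10),
                                                 weight = 0.8),
                            missing_pib = 2L,
                            missing_cog = 3L,
                            seed = 1L) {
  if ((is.null(mtl_cluster_voxels) || is.null(interaction_cluster_voxels)) &&
      min(grid_shape) < 16L)
    stop("spec error: grid too small to contain the default clusters",
         call. = FALSE)
  block <- function(i0) {
    a <- array(FALSE, dim = grid_shape)
    a[i0:(i0 + 2), i0:(i0 + 2), i0:(i0 + 2)] <- TRUE
    which(a)
  }
  if (is.null(mtl_cluster_voxels)) mtl_cluster_voxels <- block(6L)
  if (is.null(interaction_cluster_voxels))
    interaction_cluster_voxels <- block(13L)
  if (max(c(mtl_cluster_voxels, interaction_cluster_voxels)) > prod(grid_shape))
    stop("spec error: cluster voxels outside the grid", call. = FALSE)
  if (noise_sd_tau <= 0 || noise_sd_cog <= 0)
    stop("noise sds must be > 0", call. = FALSE)
  if (abeta_mixture$weight <= 0 || abeta_mixture$weight >= 1)
    stop("mixture weight must lie in (0,1)", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 mtl_cluster_voxels = mtl_cluster_voxels,
                 interaction_cluster_voxels = interaction_cluster_voxels,
                 beta_lc_tau = beta_lc_tau,
                 beta_interaction = beta_interaction,
                 mediation_a = mediation_a, mediation_b = mediation_b,
                 mediation_c_prime = mediation_c_prime,
                 noise_sd_tau = noise_sd_tau, noise_sd_cog = noise_sd_cog,
                 abeta_mixture = abeta_mixture,
                 missing_pib = as.integer(missing_pib),
                 missing_cog = as.integer(missing_cog),
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

# Reference stats used to turn latent cognition into raw test scores.
.pacc5_reference <- data.frame(
  test = c("mmse", "lm_delayed_recall", "digit_symbol",
           "fcsrt_free_total", "category_fluency"),
  mean = c(29, 13, 45, 75, 22),
  sd = c(1.2, 3.5, 10, 8, 5))

#' Generate a synthetic longitudinal cohort
#'
#' Produces the covariate table, per-subject baseline and follow-up tau
#' volumes on a common grid, the brain mask, and a truth record with
#' every planted parameter. Follow-up tau inside the MTL cluster follows
#' `intercept + beta_lc_tau * LC_r + age/sex effects + noise`; the
#' interaction cluster carries the LC x centered-amyloid product; the
#' table-level mediator (`mtl_tau_fu`) and outcome (`pacc5_fu`) follow
#' the planted mediation path.
#'
#' @param spec a `cohort_sim_spec`
#' @return list with `table`, `tau_baseline`, `tau_followup` (lists of
#'   `brain_volume`), `mask`, `truth`
#' @export
gen_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(derive_seed(spec$seed, "cohort"))
  n <- spec$n_subjects
  d <- spec$grid_shape
  affine <- diag(c(2, 2, 2, 1))  # 2-mm isotropic grid
  age <- stats::runif(n, 42, 90)
  sex <- stats::rbinom(n, 1, 0.65)          # 1 = female, 65%
  educ <- round(stats::runif(n, 8, 20))
  cdr <- ifelse(stats::runif(n) < 0.95, 0, 0.5)
  mix <- spec$abeta_mixture
  comp <- stats::rbinom(n, 1, 1 - mix$weight) + 1L   # 2 = high component
  pib <- stats::rnorm(n, mix$means[comp], mix$sds[comp])
  lc_mean_bl <- stats::rnorm(n, 0.30, 0.05)
  lc_mean_fu <- lc_mean_bl - abs(stats::rnorm(n, 0.03, 0.01))
  lc_r_bl <- -lc_mean_bl
  lc_r_fu <- -lc_mean_fu
  # planted slopes act on the standardized LC score so that effect sizes
  # are in sd units, independent of the raw contrast-ratio scale
  z_lc <- (lc_r_bl - mean(lc_r_bl)) / stats::sd(lc_r_bl)
  choroid <- stats::rnorm(n, 1.0, 0.1)
  agec <- (age - mean(age)) / stats::sd(age)
  pib_center <- mean(pib)

  base_suvr <- 1.2
  nv <- prod(d)
  mtl <- spec$mtl_cluster_voxels
  inter <- spec$interaction_cluster_voxels
  tau_bl <- vector("list", n); tau_fu <- vector("list", n)
  for (i in seq_len(n)) {
    vb <- array(base_suvr + stats::rnorm(nv, sd = spec$noise_sd_tau), dim = d)
    vf <- array(base_suvr + 0.05 * agec[i] + 0.03 * sex[i] +
                  stats::rnorm(nv, sd = spec$noise_sd_tau), dim = d)
    vf[mtl] <- vf[mtl] + spec$beta_lc_tau * z_lc[i]
    vf[inter] <- vf[inter] +
      spec$beta_interaction * z_lc[i] * (pib[i] - pib_center)
    tau_bl[[i]] <- brain_volume(vb, affine = affine)
    tau_fu[[i]] <- brain_volume(vf, affine = affine)
  }
  mask <- brain_volume(array(1, dim = d), affine = affine)

  # subject-level mediation path: LC_r -> MTL tau -> PACC5
  mtl_tau_fu <- base_suvr + spec$mediation_a * z_lc +
    stats::rnorm(n, sd = spec$noise_sd_tau)
  pacc5_fu <- spec$mediation_c_prime * z_lc +
    spec$mediation_b * mtl_tau_fu + stats::rnorm(n, sd = spec$noise_sd_cog)
  pacc5_bl <- pacc5_fu + abs(stats::rnorm(n, 0.08, 0.05))

  raw_tests <- sapply(seq_len(nrow(.pacc5_reference)), function(j) {
    st <- .pacc5_reference[j, ]
    st$mean + st$sd * (pacc5_fu + stats::rnorm(n, sd = 0.05))
  })
  colnames(raw_tests) <- .pacc5_reference$test

  tab <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    age = age, sex = sex, educ = educ, cdr = cdr,
                    pib_dvr = pib, choroid_suvr = choroid,
                    intensity_r_bl = lc_r_bl, intensity_r_fu = lc_r_fu,
                    z_intensity_r_bl = z_lc,
                    mtl_cluster_tau_fu = vapply(tau_fu, function(v)
                      mean(v$data[mtl]), numeric(1)),
                    int_cluster_tau_fu = vapply(tau_fu, function(v)
                      mean(v$data[inter]), numeric(1)),
                    mtl_tau_fu = mtl_tau_fu,
                    pacc5_bl = pacc5_bl, pacc5_fu = pacc5_fu,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, raw_tests)
  if (spec$missing_pib > 0L)
    tab$pib_dvr[sample.int(n, spec$missing_pib)] <- NA
  if (spec$missing_cog > 0L) {
    drop_cog <- sample.int(n, spec$missing_cog)
    tab$pacc5_fu[drop_cog] <- NA
    tab[drop_cog, .pacc5_reference$test] <- NA
  }
  truth <- list(spec = unclass(spec),
                indirect = spec$mediation_a * spec$mediation_b,
                total = spec$mediation_a * spec$mediation_b +
                  spec$mediation_c_prime,
                pib_center = pib_center,
                analytic_abeta_cutoff = .mixture_crossing(mix),
                pacc5_reference = .pacc5_reference)
  list(table = tab, tau_baseline = tau_bl, tau_followup = tau_fu,
       mask = mask, truth = truth)
}

# Analytic point where the generating mixture's posterior equals 0.5.
.mixture_crossing <- function(mix) {
  f <- function(v) {
    d1 <- mix$weight * stats::dnorm(v, mix$means[1], mix$sds[1])
    d2 <- (1 - mix$weight) * stats::dnorm(v, mix$means[2], mix$sds[2])
    d1 - d2
  }
  stats::uniroot(f, lower = mix$means[1], upper = mix$means[2],
                 tol = 1e-12)$root
}

#' Specification of a synthetic tangle table
#'
#' The stated world anchors to the ex vivo sample: 160 subjects with
#' planted concordance proportions (LC-only 0.20, region-only 0.05,
#' both 0.75), LC densities at Braak 0 bounded by 0.379 counts/mm^2,
#' a hippocampal Braak<=II bound of 7.91, and a planted amyloid shift of
#' 2 percent-area for the group with tangles in both regions. A subset
#' of the "both" group ("spacers": unimpaired, Braak II, hippocampal
#' density between 5 and the bound) anchors the derived regional cutoff
#' inside the low/high gap.
#'
#' @param n_subjects sample size
#' @param p_lc_only,p_hipp_only,p_both planted class proportions (the
#'   remainder is the low/low class)
#' @param abeta_shift_high_braak amyloid shift (% area) for the "both"
#'   group
#' @param lc_braak0_bound,region_prior_bound planted conditioning-stage
#'   density bounds
#' @param spacer_frac fraction of the "both" group used as Braak-II
#'   spacers
#' @param p_unimpaired_low,p_unimpaired_both probability of the
#'   unimpaired label per class tier
#' @param seed integer seed
#' @return a `tangle_sim_spec`
#' @export
tangle_sim_spec <- function(n_subjects = 160L,
                            p_lc_only = 0.20, p_hipp_only = 0.05,
                            p_both = 0.75,
                            abeta_shift_high_braak = 2.0,
                            lc_braak0_bound = 0.379,
                            region_prior_bound = 7.91,
                            spacer_frac = 0.145,
                            p_unimpaired_low = 0.70,
                            p_unimpaired_both = 0.25,
                            seed = 1L) {
  p <- c(p_lc_only, p_hipp_only, p_both)
  if (any(p < 0) || sum(p) > 1 + 1e-12)
    stop("proportions must be >= 0 and sum to <= 1", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 p_lc_only = p_lc_only, p_hipp_only = p_hipp_only,
                 p_both = p_both, p_low_low = 1 - sum(p),
                 abeta_shift_high_braak = abeta_shift_high_braak,
                 lc_braak0_bound = lc_braak0_bound,
                 region_prior_bound = region_prior_bound,
                 spacer_frac = spacer_frac,
                 p_unimpaired_low = p_unimpaired_low,
                 p_unimpaired_both = p_unimpaired_both,
                 seed = as.integer(seed)),
            class = "tangle_sim_spec")
}

#' Generate a synthetic ex vivo tangle table
#'
#' Densities are drawn on disjoint low/high supports so the Braak-
#' conditioned threshold derivation lands inside the gaps and the
#' four-group classification recovers the planted classes exactly up to
#' multinomial sampling. The Braak rule maps class structure to stages:
#' low-region subjects to 0-I, spacers to II, the remaining high-region
#' subjects to III-VI.
#'
#' @param spec a `tangle_sim_spec`
#' @return list with `table` (one row per subject) and `truth`
#'   (planted class, operating thresholds inside the gaps, spec)
#' @export
gen_tangles <- function(spec = tangle_sim_spec()) {
  stopifnot(inherits(spec, "tangle_sim_spec"))
  set.seed(derive_seed(spec$seed, "tangles"))
  n <- spec$n_subjects
  # stratified allocation: planted proportions are exact up to rounding,
  # so threshold derivation sees a deterministic set composition
  p <- c(lc_only = spec$p_lc_only, region_only = spec$p_hipp_only,
         both = spec$p_both, low_low = spec$p_low_low)
  counts <- floor(p * n)
  rem <- n - sum(counts)
  if (rem > 0L) {
    frac <- p * n - counts
    counts[order(-frac)[seq_len(rem)]] <- counts[order(-frac)[seq_len(rem)]] + 1L
  }
  cls <- sample(rep(names(counts), counts))
  # unimpaired labels, stratified per class tier
  group <- rep("impaired", n)
  for (cl in names(counts)) {
    member <- which(cls == cl)
    pu <- if (cl == "both") spec$p_unimpaired_both else spec$p_unimpaired_low
    nu <- round(pu * length(member))
    if (nu > 0L) group[sample(member, nu)] <- "unimpaired"
  }
  spacer <- rep(FALSE, n)
  both_unimp <- which(cls == "both" & group == "unimpaired")
  n_sp <- min(round(spec$spacer_frac * sum(cls == "both")), length(both_unimp))
  if (n_sp > 0L) spacer[sample(both_unimp, n_sp)] <- TRUE

  # a latent per-subject severity couples LC and regional densities
  # within class (weight 0.6), so partial rank correlations are positive
  # inside each clinical group, while the class supports stay disjoint
  severity <- stats::runif(n)
  blend <- function(who, lo, hi) {
    u <- 0.6 * severity[who] + 0.4 * stats::runif(length(who))
    lo + (hi - lo) * u
  }
  lc <- numeric(n); rg <- numeric(n)
  lc[cls == "low_low"] <- blend(which(cls == "low_low"), 0, 0.05)
  lc[cls == "region_only"] <- blend(which(cls == "region_only"), 0, 0.05)
  lc[cls == "lc_only"] <- blend(which(cls == "lc_only"), 0.30,
                                spec$lc_braak0_bound)
  lc[cls == "both"] <- blend(which(cls == "both"), 0.45, 0.80)
  rg[cls == "low_low"] <- blend(which(cls == "low_low"), 0.10, 1.00)
  rg[cls == "lc_only"] <- blend(which(cls == "lc_only"), 0.10, 1.00)
  rg[cls == "region_only"] <- blend(which(cls == "region_only"), 9.0, 20.0)
  rg[cls == "both" & !spacer] <- blend(which(cls == "both" & !spacer),
                                       9.0, 20.0)
  rg[spacer] <- blend(which(spacer), 5.0, spec$region_prior_bound)

  braak <- integer(n)
  braak[rg <= 1.0 & lc <= spec$lc_braak0_bound] <- 0L        # no cortical tau
  braak[rg <= 1.0 & lc > spec$lc_braak0_bound] <- 1L
  braak[spacer] <- 2L
  hi_rg <- rg > spec$region_prior_bound
  braak[hi_rg] <- sample(3:6, sum(hi_rg), replace = TRUE)

  abeta <- pmax(stats::rnorm(n, 3, 1), 0) +
    ifelse(cls == "both", spec$abeta_shift_high_braak, 0)
  age <- stats::runif(n, 73, 101)
  sex <- stats::rbinom(n, 1, 0.68)
  pmi <- stats::runif(n, 3, 20)
  neuron <- stats::rnorm(n, 35, 5) - 5 * lc

  # additional correlated regions for the partial-Spearman stage
  ec <- rg * stats::runif(n, 0.8, 1.2) + stats::rnorm(n, sd = 0.2)
  it <- rg * stats::runif(n, 0.5, 0.9) + stats::rnorm(n, sd = 0.2)

  tab <- data.frame(subject_id = sprintf("M%03d", seq_len(n)),
                    group = group, age = age, sex = sex, pmi = pmi,
                    braak = braak,
                    lc_tangle_density = lc,
                    lc_neuron_density = neuron,
                    hippocampus_tangle_density = rg,
                    entorhinal_tangle_density = pmax(ec, 0),
                    inferior_temporal_tangle_density = pmax(it, 0),
                    abeta_pct = abeta,
                    stringsAsFactors = FALSE)
  truth <- list(class = cls, spacer = spacer,
                lc_class_threshold = 0.175,   # inside the (0.05, 0.30) gap
                region_class_threshold = 3.0, # inside the (1.0, 5.0) gap
                proportions = c(lc_only = spec$p_lc_only,
                                region_only = spec$p_hipp_only,
                                both = spec$p_both,
                                low_low = spec$p_low_low),
                spec = unclass(spec))
  list(table = tab, truth = truth)
}

#' Hand-built tangle table reproducing the printed staging constants
#'
#' A small synthetic fixture (clearly a stand-in, not patient data)
#' whose Braak-0 LC maximum is exactly 0.379 counts/mm^2, whose
#' sub-cutoff unimpaired LC mean is exactly 0.143, and whose
#' hippocampal Braak<=II maximum and sub-cutoff unimpaired mean are
#' exactly 7.91 and 2.757.
#'
#' @return data.frame consumable by [derive_thresholds()]
#' @export
synthetic_map_fixture <- function() {
  # unimpaired LC values below 0.379 averaging exactly 0.143
  lc_sub <- c(0.049, 0.096, 0.143, 0.190, 0.237)
  # unimpaired hippocampal values below 7.91 averaging exactly 2.757
  rg_sub <- c(2.027, 2.392, 2.757, 3.122, 3.487)
  n <- length(lc_sub)
  data.frame(
    subject_id = sprintf("F%02d", seq_len(n + 2L)),
    group = c(rep("unimpaired", n), "impaired", "impaired"),
    braak = c(rep(0L, n), 0L, 2L),
    lc_tangle_density = c(lc_sub, 0.379, 0.50),
    hippocampus_tangle_density = c(rg_sub, 6.0, 7.91),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic multi-donor expression dataset
#'
#' Emulates the structure of a six-donor microarray atlas at desk scale:
#' by default 2,000 genes, 20 regions (LC, five regions with planted
#' LC correlations matching the reported similarity profile, and
#' uncorrelated background parcels), 3 donors and 2 samples per region
#' per donor, with 1-3 probes per gene. Risk-list fillers are drawn from
#' genes whose expression sits safely below the top fraction of LC and
#' every correlated region, so the planted risk overlap is exact.
#'
#' @param n_genes,n_regions,n_donors,samples_per_region sizes
#' @param correlated_regions data.frame with columns `region`,
#'   `target_r`
#' @param planted_shared_top_genes named integer vector: number of genes
#'   forced into the top fraction of both LC and the named region
#'   (default: none, preserving the correlation targets)
#' @param risk_gene_list_size size of the risk gene list
#' @param planted_risk_overlap how many risk genes are guaranteed to be
#'   in the LC/partner top-set union
#' @param noise_sd sample- and probe-level noise sd
#' @param seed integer seed
#' @return an `expression_sim_spec`
#' @export
expression_sim_spec <- function(n_genes = 2000L, n_regions = 20L,
                                n_donors = 3L, samples_per_region = 2L,
                                correlated_regions = data.frame(
                                  region = c("hippocampus", "amygdala",
                                             "rACC", "mOFC", "insula"),
                                  target_r = c(0.31, 0.24, 0.22, 0.34, 0.28)),
                                planted_shared_top_genes = integer(0),
                                risk_gene_list_size = 75L,
                                planted_risk_overlap = 3L,
                                noise_sd = 0.05,
                                seed = 1L) {
  if (any(abs(correlated_regions$target_r) >= 1))
    stop("target_r must lie in (-1, 1)", call. = FALSE)
  top_k <- floor(0.05 * n_genes)
  if (length(planted_shared_top_genes) > 0 &&
      any(planted_shared_top_genes > top_k))
    stop("planted shared top genes exceed the top-fraction set size",
         call. = FALSE)
  if (n_regions < nrow(correlated_regions) + 2L)
    stop("n_regions too small for the correlated regions plus LC",
         call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_regions = as.integer(n_regions),
                 n_donors = as.integer(n_donors),
                 samples_per_region = as.integer(samples_per_region),
                 correlated_regions = correlated_regions,
                 planted_shared_top_genes = planted_shared_top_genes,
                 risk_gene_list_size = as.integer(risk_gene_list_size),
                 planted_risk_overlap = as.integer(planted_risk_overlap),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' Generate a synthetic multi-donor expression dataset
#'
#' Returns per-donor probe x sample matrices, the probe-to-gene map,
#' per-donor sample coordinates, a region-label atlas volume, region
#' names, the risk gene list and a truth record. Region gene profiles
#' are built so that the Pearson correlation between the LC profile and
#' each planted region approaches its target; donor and probe noise is
#' small relative to the unit-variance profiles.
#'
#' @param spec an `expression_sim_spec`
#' @return list with donor_probes, probe_map, donor_coords, atlas,
#'   region_names, risk_genes, truth
#' @export
gen_expression <- function(spec = expression_sim_spec()) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(derive_seed(spec$seed, "expression"))
  ng <- spec$n_genes
  genes <- sprintf("G%05d", seq_len(ng))
  corr <- spec$correlated_regions
  n_bg <- spec$n_regions - 1L - nrow(corr)
  region_names <- c("LC", corr$region,
                    if (n_bg > 0) sprintf("ctx_%02d", seq_len(n_bg)))

  lc_prof <- stats::rnorm(ng)
  profiles <- matrix(NA_real_, nrow = ng, ncol = spec$n_regions,
                     dimnames = list(genes, region_names))
  profiles[, "LC"] <- lc_prof
  for (i in seq_len(nrow(corr))) {
    r <- corr$target_r[i]
    profiles[, corr$region[i]] <- r * lc_prof +
      sqrt(1 - r^2) * stats::rnorm(ng)
  }
  if (n_bg > 0)
    for (rg in sprintf("ctx_%02d", seq_len(n_bg)))
      profiles[, rg] <- stats::rnorm(ng)

  # planted shared-top genes get boosted in both LC and their region;
  # note the boost adds shared structure, so specs that assert the
  # correlation targets leave this empty
  planted_top <- list()
  if (length(spec$planted_shared_top_genes) > 0) {
    cursor <- 0L
    for (rg in names(spec$planted_shared_top_genes)) {
      k <- spec$planted_shared_top_genes[[rg]]
      gset <- genes[(cursor + 1L):(cursor + k)]
      cursor <- cursor + k
      profiles[gset, "LC"] <- 6 + stats::runif(k)
      profiles[gset, rg] <- 6 + stats::runif(k)
      planted_top[[rg]] <- gset
    }
  }
  # risk-list fillers must stay outside the realized LC/partner top sets:
  # take genes below the 80th percentile of every relevant column, a
  # margin no sample/probe noise at sd 0.05 can bridge to the top 5%
  relevant <- c("LC", corr$region)
  safe <- genes[apply(profiles[, relevant, drop = FALSE], 1, max) <
                  min(apply(profiles[, relevant, drop = FALSE], 2,
                            stats::quantile, probs = 0.80))]
  safe <- setdiff(safe, unlist(planted_top))

  # atlas: one 2x2x2 block per region on a 2-mm grid
  per_row <- ceiling(sqrt(spec$n_regions))
  gd <- c(per_row * 3L + 1L, ceiling(spec$n_regions / per_row) * 3L + 1L, 4L)
  atlas_arr <- array(0L, dim = gd)
  for (r in seq_len(spec$n_regions)) {
    ri <- ((r - 1L) %% per_row) * 3L + 1L
    rj <- ((r - 1L) %/% per_row) * 3L + 1L
    atlas_arr[ri:(ri + 1L), rj:(rj + 1L), 1:2] <- r
  }
  atlas <- brain_volume(atlas_arr, affine = diag(c(2, 2, 2, 1)))

  # voxel centers available to each region, world mm (0-based indices)
  region_vox <- lapply(seq_len(spec$n_regions), function(r) {
    idx <- which(atlas_arr == r)
    co <- arrayInd(idx, gd) - 1L
    t(atlas$affine %*% t(cbind(co, 1)))[, 1:3, drop = FALSE]
  })

  nspr <- spec$samples_per_region
  donor_probes <- vector("list", spec$n_donors)
  donor_coords <- vector("list", spec$n_donors)
  n_probes_per_gene <- rep_len(1:3, ng)
  probe_ids <- sprintf("P%06d", seq_len(sum(n_probes_per_gene)))
  probe_map <- data.frame(probe_id = probe_ids,
                          gene_id = rep(genes, n_probes_per_gene),
                          stringsAsFactors = FALSE)
  for (dn in seq_len(spec$n_donors)) {
    ns <- spec$n_regions * nspr
    sample_region <- rep(seq_len(spec$n_regions), each = nspr)
    coords <- do.call(rbind, lapply(seq_len(spec$n_regions), function(r)
      region_vox[[r]][seq_len(nspr), , drop = FALSE]))
    gene_vals <- sapply(seq_len(ns), function(s)
      profiles[, sample_region[s]] + stats::rnorm(ng, sd = spec$noise_sd))
    probe_vals <- gene_vals[rep(seq_len(ng), n_probes_per_gene), ,
                            drop = FALSE] +
      matrix(stats::rnorm(length(probe_ids) * ns, sd = spec$noise_sd),
             ncol = ns)
    rownames(probe_vals) <- probe_ids
    colnames(probe_vals) <- sprintf("D%d_S%03d", dn, seq_len(ns))
    donor_probes[[dn]] <- probe_vals
    donor_coords[[dn]] <- coords
  }

  # risk list: planted members from guaranteed-top genes, rest from the
  # guaranteed-outside pool
  planted_members <- character(0)
  if (spec$planted_risk_overlap > 0L) {
    pool <- unique(unlist(planted_top))
    if (length(pool) < spec$planted_risk_overlap) {
      # no planted top genes: take high-margin members of the realized
      # LC/partner profile intersections
      k <- floor(0.05 * ng)
      margins <- list()
      for (rg in corr$region) {
        both <- intersect(genes[order(-profiles[, "LC"], genes)][1:k],
                          genes[order(-profiles[, rg], genes)][1:k])
        # robustness of membership = the weaker of the two expressions
        m <- pmin(profiles[both, "LC"], profiles[both, rg])
        margins[[rg]] <- stats::setNames(m, both)
      }
      all_m <- unlist(unname(margins))
      best <- tapply(all_m, names(all_m), max)
      pool <- names(sort(best, decreasing = TRUE))
    }
    planted_members <- pool[seq_len(spec$planted_risk_overlap)]
  }
  fillers <- sample(safe,
                    spec$risk_gene_list_size - length(planted_members))
  risk_genes <- sample(c(planted_members, fillers))

  truth <- list(profiles = profiles,
                planted_top = planted_top,
                planted_risk_members = planted_members,
                region_names = region_names,
                spec = unclass(spec))
  list(donor_probes = donor_probes, probe_map = probe_map,
       donor_coords = donor_coords, atlas = atlas,
       region_names = region_names, risk_genes = risk_genes,
       truth = truth)
}
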
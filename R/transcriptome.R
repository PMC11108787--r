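#' Average probe rows into gene rows
#'
#' Expression values from multiple probes are mean-averaged per gene;
#' genes with no probes are absent from the output. Gene order follows
#' the first appearance of each gene in the probe map.
#'
#' @param probe_matrix numeric matrix, probes x samples, with probe ids
#'   as rownames
#' @param probe_to_gene data.frame with columns `probe_id`, `gene_id`
#' @return numeric matrix, genes x samples, gene ids as rownames
#' @export
aggregate_probes <- function(probe_matrix, probe_to_gene) {
  hit <- match(rownames(probe_matrix), probe_to_gene$probe_id)
  if (anyNA(hit))
    stop("probe(s) missing from the probe map: ",
         paste(utils::head(rownames(probe_matrix)[is.na(hit)], 3),
               collapse = ", "), call. = FALSE)
  gene <- probe_to_gene$gene_id[hit]
  genes <- unique(gene)
  out <- rowsum(probe_matrix, group = gene, reorder = FALSE) /
    as.vector(table(factor(gene, levels = unique(gene))))
  out[genes, , drop = FALSE]
}

#' Assign tissue samples to atlas regions by proximity
#'
#' A sample lying inside a labeled voxel takes that label; otherwise it
#' takes the label of the nearest labeled voxel center provided the
#' distance is strictly below `max_dist_mm` (ties resolved to the
#' smallest label id); otherwise it stays unassigned (NA).
#'
#' @param sample_coords_mm numeric matrix, samples x 3, world mm
#' @param atlas `brain_volume` of integer region labels (0 = unlabeled)
#' @param max_dist_mm assignment radius (default 3)
#' @return integer vector of region labels (NA when unassigned)
#' @export
assign_samples <- function(sample_coords_mm, atlas, max_dist_mm = 3.0) {
  sample_coords_mm <- as.matrix(sample_coords_mm)
  lab_idx <- which(atlas$data > 0)
  if (length(lab_idx) == 0L) stop("atlas has no labeled voxels", call. = FALSE)
  co <- arrayInd(lab_idx, dim(atlas$data)) - 1L        # 0-based voxel indices
  world <- t(atlas$affine %*% t(cbind(co, 1)))[, 1:3, drop = FALSE]
  labs <- as.integer(atlas$data[lab_idx])
  inv_aff <- solve(atlas$affine)
  d <- dim(atlas$data)
  out <- rep(NA_integer_, nrow(sample_coords_mm))
  for (s in seq_len(nrow(sample_coords_mm))) {
    vox <- round(drop(inv_aff %*% c(sample_coords_mm[s, ], 1))[1:3])
    if (all(vox >= 0) && all(vox <= d - 1L)) {
      l <- atlas$data[vox[1] + 1L, vox[2] + 1L, vox[3] + 1L]
      if (l > 0) { out[s] <- as.integer(l); next }
    }
    dist2 <- colSums((t(world) - sample_coords_mm[s, ])^2)
    dmin <- sqrt(min(dist2))
    if (dmin < max_dist_mm) {
      cand <- labs[dist2 == min(dist2)]
      out[s] <- min(cand)
    }
  }
  out
}

#' Two-level median aggregation into a region expression matrix
#'
#' Per donor and region, the median across that donor's assigned
#' samples; the group value per region is the median across donors with
#' data for that region. Regions with no contributing sample in any
#' donor are returned as NA columns and flagged.
#'
#' @param donor_matrices list of genes x samples matrices (shared gene
#'   order and rownames)
#' @param donor_labels list of per-sample region labels matching each
#'   matrix's columns
#' @param regions integer or character vector of region ids defining the
#'   column order of the result
#' @return an `expression_matrix`: genes x regions matrix with
#'   attributes `n_donors` and `missing_regions`
#' @export
regional_medians <- function(donor_matrices, donor_labels, regions) {
  stopifnot(length(donor_matrices) == length(donor_labels))
  genes <- rownames(donor_matrices[[1]])
  per_donor <- lapply(seq_along(donor_matrices), function(i) {
    m <- donor_matrices[[i]]; lb <- donor_labels[[i]]
    stopifnot(ncol(m) == length(lb))
    sapply(regions, function(r) {
      cols <- which(!is.na(lb) & lb == r)
      if (length(cols) == 0L) return(rep(NA_real_, nrow(m)))
      apply(m[, cols, drop = FALSE], 1, stats::median)
    })
  })
  arr <- simplify2array(per_donor)           # genes x regions x donors
  grp <- apply(arr, c(1, 2), stats::median, na.rm = TRUE)
  grp[is.nan(grp)] <- NA_real_
  dimnames(grp) <- list(genes, as.character(regions))
  missing_regions <- colnames(grp)[apply(grp, 2, function(c) all(is.na(c)))]
  structure(grp, class = c("expression_matrix", "matrix", "array"),
            n_donors = length(donor_matrices),
            missing_regions = missing_regions)
}

#' Regional similarity profile of a seed region's expression
#'
#' Pearson correlation across genes between the seed column (LC by
#' default) and every other region, with a permutation p-value per
#' region obtained by shuffling the partner column's gene assignment.
#' `perm_p = (1 + #{|r_null| >= |r_obs|}) / (n_perm + 1)`.
#'
#' @param expr genes x regions matrix (e.g. from [regional_medians()])
#' @param seed_region column name of the seed (default "LC")
#' @param n_perm permutations (default 10000)
#' @param seed integer RNG seed
#' @return a `similarity_profile` data.frame with region, r, perm_p,
#'   sorted by decreasing r; constant or all-NA regions are flagged with
#'   NA r
#' @export
similarity_profile <- function(expr, seed_region = "LC", n_perm = 10000L,
                               seed = 1L) {
  stopifnot(seed_region %in% colnames(expr))
  sv <- expr[, seed_region]
  partners <- setdiff(colnames(expr), seed_region)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(length(sv)))
  rows <- lapply(partners, function(rg) {
    pv <- expr[, rg]
    ok <- is.finite(sv) & is.finite(pv)
    if (sum(ok) < 3L || stats::sd(pv[ok]) == 0 || stats::sd(sv[ok]) == 0)
      return(data.frame(region = rg, r = NA_real_, perm_p = NA_real_,
                        n_genes = sum(ok)))
    r_obs <- stats::cor(sv[ok], pv[ok])
    pvf <- pv; pvf[!ok] <- NA
    null_mat <- matrix(pvf[perms], nrow = length(pvf))
    r_null <- suppressWarnings(
      stats::cor(sv, null_mat, use = "pairwise.complete.obs"))
    pp <- (1 + sum(abs(r_null) >= abs(r_obs), na.rm = TRUE)) / (n_perm + 1)
    data.frame(region = rg, r = r_obs, perm_p = pp, n_genes = sum(ok))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r), ]
  rownames(out) <- NULL
  attr(out, "seed_region") <- seed_region
  attr(out, "n_perm") <- as.integer(n_perm)
  class(out) <- c("similarity_profile", "data.frame")
  out
}

#' Top expressed gene fraction of a region
#'
#' The `floor(fraction * n_genes)` genes with the highest expression in
#' the region's column; boundary ties are broken by ascending gene id so
#' the selection is deterministic.
#'
#' @param expr genes x regions matrix with gene ids as rownames
#' @param region column name
#' @param fraction top fraction (default 0.05)
#' @return character vector of gene ids
#' @export
top_fraction_set <- function(expr, region, fraction = 0.05) {
  stopifnot(region %in% colnames(expr))
  v <- expr[, region]
  genes <- rownames(expr)
  k <- floor(fraction * length(v))
  if (k < 1L) return(character(0))
  ord <- order(-v, genes)
  genes[ord[seq_len(k)]]
}

#' Intersect a seed region's top genes with partner regions
#'
#' Pairwise intersections between the seed's top-fraction set and each
#' partner's, plus their union (the shared-gene list used downstream for
#' enrichment export and risk-gene overlap).
#'
#' @param expr genes x regions matrix
#' @param seed_region seed column (default "LC")
#' @param partner_regions character vector of partner columns
#' @param fraction top fraction (default 0.05)
#' @return a `gene_set_intersection`: per-pair gene sets, union,
#'   sizes and the background size
#' @export
intersect_with_seed <- function(expr, seed_region = "LC", partner_regions,
                                fraction = 0.05) {
  seed_set <- top_fraction_set(expr, seed_region, fraction)
  pairs <- lapply(partner_regions, function(rg)
    intersect(seed_set, top_fraction_set(expr, rg, fraction)))
  names(pairs) <- partner_regions
  union_set <- sort(unique(unlist(pairs)))
  structure(list(seed_region = seed_region, seed_set = seed_set,
                 pairs = pairs, union = union_set,
                 sizes = vapply(pairs, length, integer(1)),
                 union_size = length(union_set),
                 background_size = nrow(expr), fraction = fraction),
            class = "gene_set_intersection")
}

#' Monte-Carlo probability of a risk-gene overlap
#'
#' Draws `n_draws` random gene sets of the observed union size from the
#' background and reports the one-tailed probability of matching at
#' least the observed number of risk genes:
#' `p = (1 + #{draw >= observed}) / (n_draws + 1)`. Converges to the
#' hypergeometric upper tail.
#'
#' @param union_set character vector of shared genes
#' @param risk_list character vector of risk genes; members outside the
#'   background are dropped with a warning
#' @param background_genes character vector of all genes
#' @param n_draws Monte-Carlo draws (default 10000)
#' @param seed integer seed
#' @return list with observed_overlap, p_one_tailed, n_draws, set_size,
#'   background_size, n_risk
#' @export
risk_overlap_probability <- function(union_set, risk_list, background_genes,
                                     n_draws = 10000L, seed = 1L) {
  outside <- setdiff(risk_list, background_genes)
  if (length(outside) > 0L) {
    warning(length(outside), " risk gene(s) outside the background dropped")
    risk_list <- intersect(risk_list, background_genes)
  }
  observed <- length(intersect(union_set, risk_list))
  k <- length(union_set)
  is_risk <- background_genes %in% risk_list
  set.seed(seed)
  hits <- vapply(seq_len(n_draws), function(i)
    sum(is_risk[sample.int(length(background_genes), k)]), integer(1))
  p <- (1 + sum(hits >= observed)) / (n_draws + 1)
  list(observed_overlap = observed, p_one_tailed = p,
       n_draws = as.integer(n_draws), set_size = k,
       background_size = length(background_genes),
       n_risk = length(risk_list))
}
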
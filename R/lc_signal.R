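#' Per-slice reference normalization of an LC slab
#'
#' Each axial slice containing LC voxels is expressed as a contrast ratio
#' against the mean signal of the pontine tegmentum reference mask on that
#' slice: `(I - mean_ref(slice)) / mean_ref(slice)`. Reference voxels
#' therefore average to zero on every slice and a uniform slab maps to all
#' zeros.
#'
#' @param slab a `brain_volume` with the LC-dedicated MRI slab
#' @param ref_mask reference-region mask (same geometry)
#' @param lc_mask optional LC mask; when given, only slices carrying LC
#'   voxels are required to have reference coverage
#' @param slice_axis axis along which slices are taken (default 3)
#' @return normalized `brain_volume`
#' @export
normalize_to_reference <- function(slab, ref_mask, lc_mask = NULL,
                                   slice_axis = 3L) {
  ref <- as_mask_array(ref_mask, slab)
  d <- dim(slab$data)
  need <- rep(TRUE, d[slice_axis])
  if (!is.null(lc_mask)) {
    lc <- as_mask_array(lc_mask, slab)
    need <- apply(lc, slice_axis, any)
  }
  out <- slab$data
  idx <- slice.index(slab$data, slice_axis)
  for (s in seq_len(d[slice_axis])) {
    in_slice <- idx == s
    ref_s <- in_slice & ref
    if (!any(ref_s)) {
      if (need[s])
        stop("normalization error: empty reference mask on slice ", s,
             call. = FALSE)
      next
    }
    m <- mean(slab$data[ref_s])
    out[in_slice] <- (slab$data[in_slice] - m) / m
  }
  brain_volume(out, affine = slab$affine)
}

#' Extract LC intensity as the best contiguous 5-voxel mean
#'
#' Runs `n_seeds` deterministic searches, each seeded at one of the
#' `n_seeds` brightest in-mask voxels (ties broken by ascending linear
#' index). Each restart grows candidate sets by 26-connected in-mask
#' neighbors, keeping a small beam of the highest-sum partial sets at
#' every size (greedy growth corresponds to `beam_width = 1`; the wider
#' default avoids the myopic failures of pure brightest-neighbor growth
#' while staying deterministic). Returns the largest mean of any
#' `n_voxels`-voxel connected set found.
#'
#' @param norm_slab normalized slab (`brain_volume`)
#' @param lc_mask LC mask (same geometry)
#' @param n_voxels size of the contiguous set (default 5)
#' @param n_seeds number of seeded restarts (default 30)
#' @param connectivity 26 (default, across slices) or 6; in-plane-only
#'   search is available by passing a slab masked to one slice
#' @param beam_width partial sets retained per growth step
#' @return scalar mean intensity of the best set found
#' @export
extract_lc_intensity <- function(norm_slab, lc_mask, n_voxels = 5L,
                                 n_seeds = 30L, connectivity = 26L,
                                 beam_width = 8L) {
  mask <- as_mask_array(lc_mask, norm_slab)
  idx <- which(mask)
  if (length(idx) < n_voxels)
    stop("extraction error: mask has ", length(idx),
         " voxels, need >= ", n_voxels, call. = FALSE)
  d <- dim(norm_slab$data)
  vals <- norm_slab$data[idx]
  ord <- order(-vals, idx)              # brightest first, ties ascending index
  seeds <- idx[ord[seq_len(min(n_seeds, length(idx)))]]
  off <- .neighbor_offsets(connectivity)
  coords <- arrayInd(idx, d)
  in_mask_pos <- integer(prod(d)); in_mask_pos[idx] <- seq_along(idx)

  neighbors_of <- function(pos) {           # positions within idx
    ci <- coords[pos, , drop = FALSE]
    nb <- integer(0)
    for (r in seq_len(nrow(off))) {
      ni <- ci[, 1] + off[r, 1]; nj <- ci[, 2] + off[r, 2]
      nk <- ci[, 3] + off[r, 3]
      ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] &
        nk >= 1L & nk <= d[3]
      if (!any(ok)) next
      lin <- (nk[ok] - 1L) * d[1] * d[2] + (nj[ok] - 1L) * d[1] + ni[ok]
      p <- in_mask_pos[lin]
      nb <- c(nb, p[p > 0L])
    }
    unique(nb)
  }

  best <- -Inf
  for (s in seeds) {
    beams <- list(sort(in_mask_pos[s]))
    for (step in seq_len(n_voxels - 1L)) {
      seen <- new.env(hash = TRUE)
      cand_sets <- list(); cand_sums <- numeric(0)
      for (bm in beams) {
        nbrs <- setdiff(unique(unlist(lapply(bm, neighbors_of))), bm)
        for (p in nbrs) {
          ns <- sort(c(bm, p))
          key <- paste(ns, collapse = ",")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            cand_sets[[length(cand_sets) + 1L]] <- ns
            cand_sums <- c(cand_sums, sum(vals[ns]))
          }
        }
      }
      if (length(cand_sets) == 0L) break  # isolated component: abandon
      keys <- vapply(cand_sets, paste, "", collapse = ",")
      keep <- order(-cand_sums, keys)[seq_len(min(beam_width,
                                                  length(cand_sets)))]
      beams <- cand_sets[keep]
    }
    done <- beams[lengths(beams) == n_voxels]
    if (length(done) > 0L)
      best <- max(best, max(vapply(done, function(b) mean(vals[b]),
                                   numeric(1))))
  }
  if (!is.finite(best))
    stop("extraction error: no connected set of ", n_voxels,
         " voxels reachable from any seed", call. = FALSE)
  best
}

#' Combine hemispheric LC intensities and invert the signal
#'
#' The left and right normalized intensities are averaged;
#' `intensity_r = -intensity_mean`, so higher values indicate poorer LC
#' integrity. Negation (rather than max minus x) preserves linear-model
#' coefficients up to sign.
#'
#' @param left,right scalar normalized intensities
#' @param subject_id,timepoint optional identifiers carried through
#' @return one-row data.frame with columns subject_id, timepoint,
#'   intensity_left, intensity_right, intensity_mean, intensity_r
#' @export
invert_and_average <- function(left, right, subject_id = NA_character_,
                               timepoint = c("baseline", "followup")) {
  timepoint <- match.arg(timepoint)
  m <- (left + right) / 2
  data.frame(subject_id = subject_id, timepoint = timepoint,
             intensity_left = left, intensity_right = right,
             intensity_mean = m, intensity_r = -m,
             stringsAsFactors = FALSE)
}

#' Quantify LC intensity for one subject and timepoint
#'
#' Convenience wrapper chaining normalization, the bilateral 5-voxel
#' search and inversion.
#'
#' @param slab raw LC slab (`brain_volume`)
#' @param lc_mask_left,lc_mask_right hemispheric LC masks
#' @param ref_mask reference mask
#' @param subject_id,timepoint identifiers
#' @param ... passed to [extract_lc_intensity()]
#' @return one-row data.frame as in [invert_and_average()]
#' @export
lc_intensity_record <- function(slab, lc_mask_left, lc_mask_right, ref_mask,
                                subject_id = NA_character_,
                                timepoint = "baseline", ...) {
  both <- brain_volume(lc_mask_left$data + lc_mask_right$data,
                       affine = lc_mask_left$affine)
  norm <- normalize_to_reference(slab, ref_mask, lc_mask = both)
  L <- extract_lc_intensity(norm, lc_mask_left, ...)
  R <- extract_lc_intensity(norm, lc_mask_right, ...)
  invert_and_average(L, R, subject_id = subject_id, timepoint = timepoint)
}
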
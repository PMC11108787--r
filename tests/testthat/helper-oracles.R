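# Independent oracles used by unit and acceptance tests. These stay
# deliberately naive: frontier-growth enumeration, explicit matrix algebra,
# closed-form tails.

# Exhaustive maximum mean over all 26-connected 5-voxel subsets of a mask.
# Enumerates connected subsets by repeated frontier expansion with
# string-key deduplication; returns NA when no connected quintet exists.
brute_quintet_best <- function(vals_arr, mask_arr, k = 5L) {
  d <- dim(mask_arr); idx <- which(mask_arr)
  if (length(idx) < k) return(NA_real_)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  co <- arrayInd(idx, d)
  nb <- lapply(seq_along(idx), function(p) {
    hits <- integer(0)
    for (r in seq_len(nrow(off))) {
      ni <- co[p, 1] + off[r, 1]; nj <- co[p, 2] + off[r, 2]
      nk <- co[p, 3] + off[r, 3]
      if (ni >= 1 && ni <= d[1] && nj >= 1 && nj <= d[2] &&
          nk >= 1 && nk <= d[3]) {
        q <- match((nk - 1) * d[1] * d[2] + (nj - 1) * d[1] + ni, idx)
        if (!is.na(q)) hits <- c(hits, q)
      }
    }
    hits
  })
  sets <- as.list(seq_along(idx))
  seen <- new.env(hash = TRUE)
  for (s in seq_len(k - 1L)) {
    nxt <- list()
    for (st in sets) {
      cand <- setdiff(unique(unlist(nb[st])), st)
      for (cc in cand) {
        ns <- sort(c(st, cc)); key <- paste(ns, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1L]] <- ns
        }
      }
    }
    sets <- nxt
    if (length(sets) == 0L) return(NA_real_)
  }
  v <- vals_arr[idx]
  max(vapply(sets, function(st) mean(v[st]), numeric(1)))
}

# Partial Spearman by explicit projection algebra: rank, project onto the
# orthogonal complement of [1, Z], correlate.
partial_spearman_oracle <- function(x, y, Z) {
  rx <- rank(x); ry <- rank(y)
  Zm <- cbind(1, as.matrix(Z))
  P <- diag(length(x)) - Zm %*% solve(t(Zm) %*% Zm) %*% t(Zm)
  ex <- P %*% rx; ey <- P %*% ry
  drop((t(ex) %*% ey) / sqrt((t(ex) %*% ex) * (t(ey) %*% ey)))
}

# Clopper-Pearson bounds by direct inversion of binomial tail probabilities.
binom_ci_oracle <- function(x, n, alpha = 0.05) {
  f_lo <- function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2
  f_hi <- function(p) stats::pbinom(x, n, p) - alpha / 2
  lo <- if (x == 0) 0 else stats::uniroot(f_lo, c(1e-12, 1 - 1e-12),
                                          tol = 1e-12)$root
  hi <- if (x == n) 1 else stats::uniroot(f_hi, c(1e-12, 1 - 1e-12),
                                          tol = 1e-12)$root
  c(lo, hi)
}

# Welch's t from the textbook formulas.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  c(t = t, df = df)
}

make_mask_volume <- function(flag, affine = diag(4)) {
  brain_volume(array(as.numeric(flag), dim = dim(flag)), affine = affine)
}
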
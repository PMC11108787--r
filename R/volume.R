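#' 3D brain volume container
#'
#' A `brain_volume` is a 3D scalar array together with a 4x4 affine matrix
#' mapping 0-based voxel indices (i, j, k, 1) to world mm coordinates.
#' It is the carrier type for MRI slabs, SUVR maps, masks, z-maps and
#' atlas label volumes throughout the pipeline.
#'
#' @param data numeric 3D array; all three dimensions must be >= 1.
#' @param voxel_size_mm positive length-3 numeric, ignored when `affine`
#'   is supplied.
#' @param affine optional 4x4 numeric matrix; defaults to
#'   `diag(c(voxel_size_mm, 1))`.
#' @return an object of class `brain_volume` with elements `data` and
#'   `affine`.
#' @export
brain_volume <- function(data, voxel_size_mm = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("brain_volume: `data` must be a 3D array, got ",
         length(dim(data)), " dims", call. = FALSE)
  if (is.null(affine)) {
    if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
      stop("brain_volume: voxel_size_mm must be 3 positive reals", call. = FALSE)
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("brain_volume: affine must be 4x4", call. = FALSE)
  structure(list(data = data, affine = affine), class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<brain_volume %d x %d x %d, voxel %.3g x %.3g x %.3g mm>\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  invisible(x)
}

#' @export
dim.brain_volume <- function(x) dim(x$data)

#' Voxel size in mm derived from the affine column norms
#' @param vol a brain_volume
#' @return length-3 numeric
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Check two volumes share shape and affine
#'
#' All inter-volume operations require matching geometry; resampling and
#' registration are out of scope.
#'
#' @param a,b brain_volume objects
#' @param tol absolute tolerance on affine entries
#' @return TRUE invisibly; errors otherwise
#' @export
check_same_geometry <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("geometry mismatch: shapes ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"), call. = FALSE)
  if (max(abs(a$affine - b$affine)) > tol)
    stop("geometry mismatch: affines differ by more than ", tol, call. = FALSE)
  invisible(TRUE)
}

#' Validate a mask volume
#'
#' Masks must contain only the values 0 and 1 (NA not allowed).
#' @param mask a brain_volume
#' @param against optional volume whose geometry the mask must match
#' @return logical 3D array of the mask
#' @export
as_mask_array <- function(mask, against = NULL) {
  v <- mask$data
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop("mask contains values other than {0,1}", call. = FALSE)
  if (!is.null(against)) check_same_geometry(mask, against)
  array(v == 1, dim = dim(v))
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 reader/writer.
#
# The pre-installed R stack has no NIfTI package, so the small single-volume
# subset the pipeline needs is implemented here: 3D images, datatypes
# uint8/int16/int32/float32/float64, sform affines, optional gzip. 4D data
# and quaternion-only orientations are rejected rather than guessed.
# ---------------------------------------------------------------------------

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE)
)

#' Read a single-volume NIfTI-1 image
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @return a `brain_volume`
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L)
    stop("malformed NIfTI header (file shorter than 348 bytes): ", path,
         call. = FALSE)
  endian <- "little"
  szh <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    szh <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
    if (szh != 348L)
      stop("malformed NIfTI header (sizeof_hdr != 348): ", path, call. = FALSE)
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("malformed NIfTI header (bad magic): ", path, call. = FALSE)
  rd <- function(from, what, size, n = 1L)
    readBin(raw_hdr[from:(from + size * n - 1L)], what,
            n = n, size = size, endian = endian)
  dims <- rd(41L, "integer", 2L, 8L)
  ndim <- dims[1]
  if (ndim > 3L && any(dims[5:(ndim + 1L)] > 1L))
    stop("unsupported shape: 4D/5D NIfTI not handled (single volumes only)",
         call. = FALSE)
  if (ndim < 1L) stop("malformed NIfTI header (dim[0] < 1)", call. = FALSE)
  d3 <- pmax(dims[2:4], 1L)
  datatype <- rd(71L, "integer", 2L)
  spec <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(spec))
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  pixdim <- rd(77L, "numeric", 4L, 8L)
  vox_offset <- rd(109L, "numeric", 4L)
  scl_slope <- rd(113L, "numeric", 4L)
  scl_inter <- rd(117L, "numeric", 4L)
  sform_code <- rd(255L, "integer", 2L)
  affine <- if (sform_code > 0L) {
    rbind(rd(281L, "numeric", 4L, 4L),
          rd(297L, "numeric", 4L, 4L),
          rd(313L, "numeric", 4L, 4L),
          c(0, 0, 0, 1))
  } else {
    diag(c(abs(pixdim[2:4]), 1))
  }
  # skip extension bytes up to vox_offset (348 already consumed)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  nvox <- prod(d3)
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < nvox)
    stop("malformed NIfTI file: truncated data section", call. = FALSE)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  brain_volume(array(as.numeric(vals), dim = d3), affine = affine)
}

#' Write a brain_volume as NIfTI-1
#'
#' Data are stored as float64 so that write-then-read round-trips are
#' bit-exact; gzip compression is chosen by the `.gz` suffix.
#'
#' @param vol a `brain_volume`
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "brain_volume"))
  d <- dim(vol$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pixdim <- c(1, voxel_size(vol), 1, 1, 1, 1)
  wb(348L, 4L)                              # sizeof_hdr
  wb(raw(36L), 1L)                          # data_type..dim_info
  wb(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2L)  # dim
  wb(c(0, 0, 0), 4L)                        # intent_p1..p3
  wb(0L, 2L)                                # intent_code
  wb(64L, 2L)                               # datatype float64
  wb(64L, 2L)                               # bitpix
  wb(0L, 2L)                                # slice_start
  wb(as.numeric(pixdim), 4L)                # pixdim
  wb(352, 4L)                               # vox_offset
  wb(1, 4L); wb(0, 4L)                      # scl_slope, scl_inter
  wb(0L, 2L); wb(raw(2L), 1L)               # slice_end, slice_code+xyzt
  wb(c(0, 0, 0, 0), 4L)                     # cal_max..toffset
  wb(c(0L, 0L), 4L)                         # glmax, glmin
  wb(raw(104L), 1L)                         # descrip + aux_file
  wb(c(0L, 1L), 2L)                         # qform_code=0, sform_code=1
  wb(c(0, 0, 0, 0, 0, 0), 4L)               # quaternions + qoffsets
  wb(as.numeric(t(vol$affine[1:3, ])), 4L)  # srow_x, srow_y, srow_z
  wb(raw(16L), 1L)                          # intent_name
  writeBin(charToRaw("n+1"), con); wb(raw(1L), 1L)  # magic
  wb(raw(4L), 1L)                           # extension flag
  wb(as.numeric(vol$data), 8L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Spatial helpers shared by the LC search, cluster extraction and the
# Monte-Carlo cluster simulation.
# ---------------------------------------------------------------------------

.neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  if (connectivity == 6L) g <- g[abs(g$di) + abs(g$dj) + abs(g$dk) == 1, ]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26")
  as.matrix(g)
}

#' Label connected components of a logical 3D array
#'
#' @param flag logical 3D array
#' @param connectivity 26 (default) or 6
#' @return list with `labels` (integer array, 0 = background; components
#'   numbered by decreasing size, ties by smallest member index) and
#'   `sizes` (integer vector per label)
#' @export
label_components <- function(flag, connectivity = 26L) {
  d <- dim(flag)
  idx <- which(flag)
  labels <- array(0L, dim = d)
  if (length(idx) == 0L)
    return(list(labels = labels, sizes = integer(0)))
  coords <- arrayInd(idx, d)
  off <- .neighbor_offsets(connectivity)
  # keep one direction of each offset pair; undirected edges
  off <- off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
               (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
  pos <- match(idx, idx)  # identity, placeholder for clarity
  edges <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    ni <- coords[, 1] + off[r, 1]
    nj <- coords[, 2] + off[r, 2]
    nk <- coords[, 3] + off[r, 3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    nidx <- (nk - 1L) * d[1] * d[2] + (nj - 1L) * d[1] + ni
    hit <- match(nidx, idx)
    sel <- ok & !is.na(hit)
    if (any(sel)) edges[[r]] <- cbind(seq_along(idx)[sel], hit[sel])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  # relabel: decreasing size, ties by smallest linear index of any member
  first_idx <- vapply(seq_len(comp$no),
                      function(k) min(idx[comp$membership == k]), numeric(1))
  ord <- order(-sizes, first_idx)
  relab <- integer(comp$no); relab[ord] <- seq_len(comp$no)
  labels[idx] <- relab[comp$membership]
  list(labels = labels, sizes = sizes[ord])
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param arr numeric 3D array
#' @param sigma_vox per-axis standard deviations in voxel units; entries
#'   <= 0 leave that axis untouched
#' @return smoothed array, same dimensions
#' @export
smooth_gaussian <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    x <- seq_len(n)
    K <- exp(-outer(x, x, "-")^2 / (2 * s^2))
    K <- K / rowSums(K)  # renormalized at edges
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(arr, perm)
    m <- K %*% matrix(ap, nrow = n)
    ap <- array(m, dim = d[perm])
    arr <- aperm(ap, order(perm))
  }
  arr
}
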
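#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor cor.test dhyper fisher.test lm optimize
#'   pnorm pt qnorm rnorm runif sd setNames var wilcox.test p.adjust
#' @importFrom utils read.delim write.table head
#' @importFrom mclust Mclust mclustBIC
NULL

stop_hydromap <- function(..., class = "hydromap_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_that <- function(cond, ..., class = "hydromap_validation_error") {
  if (!isTRUE(cond)) stop_hydromap(..., class = class)
  invisible(TRUE)
}

#' Deterministically derive a sub-seed from a master seed
#'
#' Sub-seeds are spawned so that each (subject, scan) pair has its own
#' reproducible noise stream: adding a subject or scan never perturbs the
#' noise of the others. The scheme is a fixed affine hash modulo 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param ... one or more non-negative integer indices (e.g. subject index,
#'   scan index).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
spawn_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- as.numeric(seed) %% m
  for (i in idx) {
    s <- (s * 48271 + as.numeric(i) + 1) %% m
  }
  as.integer(s)
}

# 1-D Gaussian convolution matrix for an axis of length n with voxel size
# `voxel_mm`; truncated at 4 sigma. Rows are normalized so that smoothing
# preserves a constant field even at the edges.
gauss_kernel_matrix <- function(n, sigma_mm, voxel_mm) {
  if (sigma_mm <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-") * voxel_mm
  K <- exp(-d^2 / (2 * sigma_mm^2))
  K[abs(d) > 4 * sigma_mm] <- 0
  K / rowSums(K)
}

apply_along_axis <- function(vol, K, axis) {
  dm <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  p <- aperm(vol, perm)
  m <- matrix(p, nrow = dm[axis])
  r <- K %*% m
  array_p <- array(r, dim = dm[perm])
  aperm(array_p, order(perm))
}

#' Separable 3-D Gaussian smoothing
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm full width at half maximum of the kernel, in mm.
#' @param voxel_mm voxel size, length-3 numeric (mm).
#' @param mask optional logical array; if given, smoothing is renormalized
#'   within the mask (`smooth(vol * mask) / smooth(mask)`), so values outside
#'   the mask do not bleed in. Voxels outside the mask are returned unchanged.
#' @return smoothed array of the same dimension.
#' @export
gaussian_smooth <- function(vol, fwhm_mm, voxel_mm = c(1, 1, 1), mask = NULL) {
  check_that(length(dim(vol)) == 3, "gaussian_smooth expects a 3-D array")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  dm <- dim(vol)
  Ks <- lapply(1:3, function(a) gauss_kernel_matrix(dm[a], sigma, voxel_mm[a]))
  smooth1 <- function(x) {
    for (a in 1:3) x <- apply_along_axis(x, Ks[[a]], a)
    x
  }
  if (is.null(mask)) return(smooth1(vol))
  m <- array(as.numeric(mask), dim = dm)
  v <- vol
  v[!mask] <- 0  # out-of-mask values (possibly NA) must not leak in
  num <- smooth1(v)
  den <- smooth1(m)
  out <- vol
  inside <- which(mask & den > 1e-12)
  out[inside] <- num[inside] / den[inside]
  out
}

# Shift a 3-D logical array by one voxel along `axis` in direction `dir`,
# padding with FALSE.
shift_mask <- function(mask, axis, dir) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  idx_src <- lapply(dm, seq_len)
  idx_dst <- idx_src
  n <- dm[axis]
  if (dir > 0) {
    idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1)
  } else {
    idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Erode a binary mask by one voxel (6-connectivity)
#'
#' @param mask 3-D logical array.
#' @param iterations number of erosion passes.
#' @return eroded logical array.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  m <- mask
  for (k in seq_len(iterations)) {
    out <- m
    for (a in 1:3) {
      out <- out & shift_mask(m, a, +1) & shift_mask(m, a, -1)
    }
    m <- out
  }
  m
}

#' Edge-preserving median filter over the 6-connected neighbourhood
#'
#' Replaces every in-mask voxel by the median of itself and its six face
#' neighbours (out-of-mask neighbours are substituted by the centre value,
#' i.e. nearest padding). Unlike Gaussian smoothing, the median preserves
#' sharp tissue interfaces: across a locally planar boundary at most three
#' of the seven values come from the far side, so the centre voxel's class
#' always wins. Implemented as a vectorized 16-comparator sorting network.
#'
#' @param vol 3-D numeric array.
#' @param mask logical array; voxels outside are returned unchanged.
#' @return filtered array.
#' @export
median_filter <- function(vol, mask) {
  dm <- dim(vol)
  centre <- vol[mask]
  M <- matrix(centre, length(centre), 7)
  k <- 1L
  v <- vol
  v[!mask] <- NA
  for (a in 1:3) for (d in c(-1L, 1L)) {
    k <- k + 1L
    nb <- shift_volume(v, a, d)[mask]
    M[, k] <- ifelse(is.na(nb), centre, nb)
  }
  # optimal sorting network for 7 elements; element 4 is the median
  net <- list(c(2, 3), c(4, 5), c(6, 7), c(1, 3), c(4, 6), c(5, 7),
              c(1, 2), c(5, 6), c(3, 7), c(1, 5), c(2, 6),
              c(1, 4), c(3, 6), c(2, 4), c(3, 5), c(3, 4))
  for (p in net) {
    lo <- pmin(M[, p[1]], M[, p[2]])
    M[, p[2]] <- pmax(M[, p[1]], M[, p[2]])
    M[, p[1]] <- lo
  }
  out <- vol
  out[mask] <- M[, 4]
  out
}

# Shift a 3-D array by one voxel along `axis`, padding with NA.
shift_volume <- function(v, axis, dir) {
  dm <- dim(v)
  out <- array(NA_real_, dm)
  n <- dm[axis]
  src <- if (dir > 0) 1:(n - 1) else 2:n
  dst <- if (dir > 0) 2:n else 1:(n - 1)
  if (axis == 1) out[dst, , ] <- v[src, , ]
  if (axis == 2) out[, dst, ] <- v[, src, ]
  if (axis == 3) out[, , dst] <- v[, , src]
  out
}

#' Block-average downsampling and nearest-neighbour upsampling
#'
#' `block_downsample` averages non-overlapping `factor`^3 blocks (the array
#' dimensions must be divisible by `factor`); `nn_upsample` repeats each
#' voxel `factor` times per axis, inverting the grid change.
#'
#' @param vol 3-D numeric array.
#' @param factor integer downsampling factor.
#' @return resampled array.
#' @export
block_downsample <- function(vol, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  dm <- dim(vol)
  check_that(all(dm %% factor == 0),
             "volume dimensions must be divisible by the downsampling factor")
  nd <- dm %/% factor
  a <- array(vol, dim = c(factor, nd[1], factor, nd[2], factor, nd[3]))
  out <- apply(a, c(2, 4, 6), mean)
  array(out, dim = nd)
}

#' @rdname block_downsample
#' @export
nn_upsample <- function(vol, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  dm <- dim(vol)
  i1 <- rep(seq_len(dm[1]), each = factor)
  i2 <- rep(seq_len(dm[2]), each = factor)
  i3 <- rep(seq_len(dm[3]), each = factor)
  vol[i1, i2, i3]
}

#' Write a 3-D volume as NIfTI-1
#'
#' Volumes are written in RAS orientation with the voxel size recorded in the
#' header; world coordinates are in mm with the origin at the first voxel.
#'
#' @param vol numeric or logical 3-D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size, length-3 (mm).
#' @export
write_volume <- function(vol, path, voxel_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)),
                         pixdim = voxel_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}
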
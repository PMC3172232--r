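# spatial Gaussian smoothing of volumes, separable along the three axes

# multiply S (n x n) into `arr` along `axis`
apply_along_axis <- function(arr, axis, S) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  dim(a) <- c(d[axis], prod(d[-axis]))
  a <- S %*% a
  dim(a) <- d[perm]
  aperm(a, order(perm))
}

# 1D truncated-Gaussian smoothing matrix; rows renormalized so a constant
# series is preserved at the edges
gaussian_band_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  radius <- max(1L, ceiling(4 * sigma_vox))
  offsets <- -radius:radius
  w <- exp(-offsets^2 / (2 * sigma_vox^2))
  S <- matrix(0, n, n)
  for (k in seq_along(offsets)) {
    j <- seq_len(n) + offsets[k]
    ok <- j >= 1 & j <= n
    S[cbind(which(ok), j[ok])] <- S[cbind(which(ok), j[ok])] + w[k]
  }
  S / rowSums(S)
}

#' Spatially smooth a BOLD run or volume
#'
#' Convolves each spatial frame with a 3D Gaussian kernel of the stated
#' full-width half-maximum (`sigma = fwhm / (2 sqrt(2 log 2))` in mm,
#' converted to voxels per axis). `fwhm_mm = 0` is the identity. Kernel
#' tails are truncated at 4 sigma and renormalized at the volume edges, so
#' constant images pass through unchanged.
#'
#' @param x A `bold_run` (its 4D data is smoothed frame by frame) or a bare
#'   3D/4D array (the 4th dimension, if present, is treated as time).
#' @param fwhm_mm Full width at half maximum of the kernel, mm (>= 0).
#' @param voxel_mm Voxel sizes in mm, scalar or 3-vector; taken from the
#'   run's affine when `x` is a `bold_run`. If the voxels are anisotropic a
#'   per-axis sigma is used and a warning is emitted.
#' @return The same type as `x`, smoothed.
#' @export
smooth_volume <- function(x, fwhm_mm, voxel_mm = NULL) {
  if (fwhm_mm < 0) abort("`fwhm_mm` must be non-negative.")
  if (inherits(x, "bold_run")) {
    vs <- voxel_sizes(x$affine)
    x$data <- smooth_volume(x$data, fwhm_mm, voxel_mm = vs)
    return(x)
  }
  if (is.null(voxel_mm)) abort("`voxel_mm` is required for bare arrays.")
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (fwhm_mm == 0) return(x)
  if (max(voxel_mm) - min(voxel_mm) > 1e-8) {
    warn("Anisotropic voxels: using a per-axis smoothing sigma.")
  }
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(x)
  if (!length(d) %in% c(3L, 4L)) abort("`x` must be a 3D or 4D array.")
  out <- x
  for (axis in 1:3) {
    S <- gaussian_band_matrix(d[axis], sigma_mm / voxel_mm[axis])
    out <- apply_along_axis(out, axis, S)
  }
  out
}
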
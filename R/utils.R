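# shared internal helpers: grid geometry, seeds, rank statistics

# voxel-center coordinates (mm) for a grid with a 4x4 affine; voxel indices
# are 1-based in R but the affine maps 0-based indices, matching NIfTI.
voxel_centers_mm <- function(dim3, affine) {
  idx <- as.matrix(expand.grid(
    i = seq_len(dim3[1]) - 1L,
    j = seq_len(dim3[2]) - 1L,
    k = seq_len(dim3[3]) - 1L
  ))
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}

# mm coordinate of one 1-based voxel index triple
voxel_mm <- function(ijk, affine) {
  as.numeric(affine[1:3, 1:3] %*% (ijk - 1) + affine[1:3, 4])
}

# per-axis voxel sizes from the affine (column norms)
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# draw n child seeds reproducibly from one parent seed, each < 2^31
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Wilcoxon/Mann-Whitney ranking AUC of scores for positives vs negatives
ranking_auc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n_pos <- length(scores_pos)
  n_neg <- length(scores_neg)
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
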
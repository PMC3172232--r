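# shared fixtures: reduced-grid atlases and cohorts built in code.
# The block design itself always stays at the study timing (TR 2 s,
# 40 s + 30 s blocks, 7 blocks x 4 runs); only the spatial grid shrinks.

# region centers > 16 mm apart so the 8 mm spheres never overlap
small_regions <- function() {
  dplyr::mutate(
    default_regions(),
    x_mm = c(-16, 12, 0), y_mm = c(0, -8, 16), z_mm = c(0, 4, 8)
  )
}

small_atlas <- function(seed = 1, n_artifacts = 0, ...) {
  make_atlas(
    grid_shape = c(16L, 18L, 16L), voxel_mm = 4,
    regions = small_regions(), seed = seed, n_artifacts = n_artifacts, ...
  )
}

tiny_atlas <- function(seed = 1, n_artifacts = 0, ...) {
  make_atlas(
    grid_shape = c(12L, 14L, 12L), voxel_mm = 4,
    regions = dplyr::mutate(
      default_regions()[1:2, ],
      x_mm = c(-8, 8), y_mm = c(0, -8), z_mm = c(0, 4)
    ),
    seed = seed, n_artifacts = n_artifacts, ...
  )
}

# a no-effect atlas: gray matter only, nothing planted
null_atlas <- function(grid_shape = c(12L, 14L, 12L)) {
  make_atlas(
    grid_shape = grid_shape, voxel_mm = 4,
    regions = default_regions()[0, ], seed = 1, n_artifacts = 0
  )
}

noiseless_subject <- function(atlas = small_atlas(), design = study_design(),
                              gain = 1, subject_id = "sub-01", seed = 7) {
  simulate_subject(
    design, atlas,
    subject_id = subject_id, gain = gain,
    noise_sd = 0, drift_amplitude = 0, seed = seed
  )
}

# a linearly separable 2D toy problem
separable_toy <- function(n_per_class = 6, margin = 2, seed = 11) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(2 * n_per_class, mean = margin, sd = 0.3), ncol = 2),
      matrix(rnorm(2 * n_per_class, mean = -margin, sd = 0.3), ncol = 2)
    )
    list(x = x, y = rep(c(1, -1), each = n_per_class))
  })
}

# random small instance for solver property tests
random_instance <- function(n = 12, p = 3, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    list(x = x, y = y)
  })
}
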
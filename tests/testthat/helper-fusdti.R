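# Shared fixtures: reduced-size phantoms and small utilities.

# Half-scale phantom: same layout as the default, cheap enough for loops.
small_spec <- function(seed = 1, ...) {
  phantom_spec(grid_shape = c(32L, 40L, 28L), n_directions = 24,
               seed = seed, ...)
}

# Default-geometry phantom with a reduced gradient scheme, for tests that
# need the full-size brain (segmentation fraction rule) but not 129 volumes.
midi_spec <- function(seed = 1, ...) {
  phantom_spec(n_directions = 24, seed = seed, ...)
}

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Single-voxel DWI volume from explicit per-volume signals.
voxel_dwi <- function(signals, gradients, voxel_size = 1) {
  dwi_volume(array(signals, c(1, 1, 1, length(signals))),
             voxel_size, gradients)
}

# Multi-voxel (n x 1 x 1) DWI volume from a signals matrix (n_vox x n_vol).
row_dwi <- function(S, gradients, voxel_size = 1) {
  dwi_volume(array(S, c(nrow(S), 1, 1, ncol(S))), voxel_size, gradients)
}

# Random symmetric positive definite tensor on the diffusivity scale.
random_spd_tensor <- function() {
  A <- matrix(stats::rnorm(9, sd = 1e-3), 3)
  crossprod(A) + 1e-4 * diag(3)
}

# Noiseless DWI volume over a cubic grid for tracking fixtures.
# `D_of_voxel(i, j, k)` maps 1-based indices to a 3x3 tensor; the fixture
# fields used here are constant along k, so the tensor is evaluated once
# per (i, j) column and replicated.
field_dwi <- function(n, gradients, D_of_voxel, voxel_size = 1) {
  nv <- length(gradients)
  arr <- array(0, c(n, n, n, nv))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- tensor_signal(1000, D_of_voxel(i, j, 1), gradients)
    arr[i, j, , ] <- rep(s, each = n)
  }
  dwi_volume(arr, voxel_size, gradients)
}

# Axially symmetric tensor with principal axis u.
axial_tensor <- function(ev, u) {
  u <- u / sqrt(sum(u^2))
  ev[2] * diag(3) + (ev[1] - ev[2]) * tcrossprod(u)
}
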
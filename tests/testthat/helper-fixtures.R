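# Small shared fixtures, built in code at load time. Sizes are deliberately
# tiny: unit tests exercise correctness, not the full study conditions.

tiny_annulus <- function(resolution = 8) {
  build_synthetic_geometry(2, c(45, 35, 10), resolution = resolution,
                           mode = "two_domain")
}

tiny_three_domain <- function(resolution = 8) {
  build_synthetic_geometry(2, c(50, 45, 35, 10), resolution = resolution,
                           mode = "three_domain")
}

# inverse-crime observations: generated by the same discretization the
# estimator uses, so the misfit at the truth is exactly zero (used by
# gradient-stationarity and optimizer-convergence tests only)
crime_observations <- function(mesh, D_true, grid, ctx, theta = 1) {
  g <- glymadc:::.control_from_profile(mesh, boundary_profile_spec(), grid)
  states <- solve_diffusion(mesh, D_true, g, grid, theta = theta, ctx = ctx)
  observation_series(states$times, states$values)
}

# synthetic voxel image: values from a function of physical coordinates,
# identity-scaled affine with a translation so the mesh fits inside
synth_image <- function(n = 15, spacing = 1, origin = -4,
                        f = function(x, y, z) 0 * x, labels = NULL) {
  aff <- diag(4)
  aff[1, 1] <- aff[2, 2] <- aff[3, 3] <- spacing
  aff[1:3, 4] <- origin
  idx <- seq_len(n) - 1
  xs <- origin + spacing * idx
  arr <- array(0, c(n, n, n))
  for (k in seq_len(n)) for (j in seq_len(n))
    arr[, j, k] <- f(xs, xs[j], xs[k])
  voxel_image(arr, affine = aff, units = "mM", labels = labels)
}
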
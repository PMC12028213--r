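# Shared fixtures: small grids, canonical truths and series built in code.

fix_acq <- function(noise = 0, grid = c(32L, 32L, 16L)) {
  acquisition_spec(grid_shape = grid, noise_sigma = noise)
}

fix_truth <- function(class_label = "warthin", ktrans = 0.45, ve = 0.18,
                      vp = 0.04, d = 1.0e-3, dstar = 15e-3, f = 0.18,
                      center = c(16, 16, 8), radii = c(6, 6, 6)) {
  lesion_truth(class_label, ktrans, ve, vp, d, dstar, f, center, radii)
}

# sphere mask on an isotropic grid
fix_sphere <- function(r_vox = 4, grid = c(17L, 17L, 17L), spacing = 1) {
  make_lesion_mask(grid, (grid + 1) / 2, rep(r_vox * spacing, 3),
                   rep(spacing, 3))
}

dice <- function(a, b) 2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))

# random blobby ROI + values for feature tests
fix_random_roi <- function(seed, max_dim = 12L) {
  set.seed(seed)
  dims <- c(sample(6:max_dim, 1), sample(6:max_dim, 1), sample(3:6, 1))
  vals <- array(stats::rnorm(prod(dims), 50, 20), dims)
  m <- array(stats::runif(prod(dims)) < 0.7, dims)
  if (sum(m) < 10) m[seq_len(10)] <- TRUE
  list(values = vals, mask = mask3d(m, c(1, 1, 3)),
       bin_width = sample(c(2, 5, 10, 20), 1))
}
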
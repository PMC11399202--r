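# Shared fixtures, built once per test run. Everything is generated in
# code; schemes and phantoms are cached because gradient design is the
# most expensive fixture step.

.fix <- new.env()

# 64-direction b = 3000 scheme (light design settings for test speed)
fixture_scheme64 <- function() {
  if (is.null(.fix$scheme64))
    .fix$scheme64 <- design_scheme(64L, seed = 7L, n_restarts = 5L,
                                   n_iterations = 100L)
  .fix$scheme64
}

# single straight bundle along +x in a 32^3 grid, noiseless
fixture_single_bundle <- function(eigenvalues = c(1.7e-3, 0.3e-3, 0.3e-3)) {
  key <- paste0("single_", paste(eigenvalues, collapse = "_"))
  if (is.null(.fix[[key]])) {
    b <- fiber_bundle_spec(rbind(c(-40, 15.5, 15.5), c(80, 15.5, 15.5)),
                           radius = 3.5, eigenvalues = eigenvalues)
    .fix[[key]] <- simulate_signal(list(b), fixture_scheme64(),
                                   c(32L, 32L, 32L), S0 = 100,
                                   noise_sigma = 0)
  }
  .fix[[key]]
}

# 90-degree crossing phantom, noiseless
fixture_crossing90 <- function() {
  if (is.null(.fix$crossing90)) {
    bundles <- make_crossing_phantom(90, c(32L, 32L, 32L))
    .fix$crossing90 <- simulate_signal(bundles, fixture_scheme64(),
                                       c(32L, 32L, 32L), S0 = 100,
                                       noise_sigma = 0)
  }
  .fix$crossing90
}

# mask holding only pure single-fiber voxels of a single-bundle phantom
pure_fiber_mask <- function(sim) {
  m <- sim$truth$bundle_masks[[1L]] & array(sim$truth$fractions[, 1L] == 1,
                                            dim(sim$truth$tissue_mask))
  array(m, dim(sim$truth$tissue_mask))
}

# random probability vectors on the 181-point sphere
random_prob <- function(n = 181L) {
  p <- runif(n)
  p / sum(p)
}

expect_angle_le <- function(u, v, deg) {
  a <- acos(min(abs(sum(u * v)), 1)) * 180 / pi
  expect_lte(a, deg)
}
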
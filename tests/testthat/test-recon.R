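test_that("the 181-point hemisphere is unit-norm and well separated", {
  s <- hemisphere181()
  expect_equal(nrow(s), 181L)
  expect_true(all(abs(sqrt(rowSums(s^2)) - 1) < 1e-12))
  expect_gt(attr(s, "min_angle"), 8)   # documented minimum spacing
})

test_that("SH basis is orthonormal under spherical quadrature", {
  # Monte-Carlo quadrature over the full sphere
  set.seed(77)
  n <- 2e5
  d <- normalize_rows(matrix(rnorm(3 * n), n))
  B <- sh_basis(d, 6L)
  gram <- crossprod(B) / n * 4 * pi
  expect_lt(max(abs(gram - diag(ncol(B)))), 0.05)
  expect_equal(nrow(sh_index_table(8L)), 45L)
})

test_that("associated Legendre recurrence matches an independent library", {
  set.seed(41)
  x <- runif(50, -1, 1)
  leg <- hardigen:::.assoc_legendre(8L, x)
  for (l in c(2L, 4L, 6L, 8L)) {
    ref <- pracma::legendre(l, x)
    for (m in 0:l)
      expect_equal(leg$get(l, m), unname(ref[m + 1L, ]), tolerance = 1e-10)
  }
})

test_that("sampling then refitting SH reproduces coefficients", {
  set.seed(8)
  lmax <- 8L
  coef <- rnorm(45)
  s <- hemisphere181()
  vals <- as.numeric(sh_basis(s, lmax) %*% coef)
  refit <- as.numeric(hardigen:::.sh_fit_operator(s, lmax, 0) %*% vals)
  expect_lt(max(abs(refit - coef)), 1e-6)
})

test_that("lmax policy follows the direction count with cap 8", {
  expect_equal(lmax_for(32L), 6L)
  expect_equal(lmax_for(64L), 8L)
  expect_equal(lmax_for(28L), 6L)
  expect_equal(lmax_for(27L), 4L)
  expect_equal(lmax_for(6L), 2L)
  expect_equal(lmax_for(200L), 8L)
})

test_that("DTI fit recovers tensors and the FA closed form", {
  sim <- fixture_single_bundle()
  mask <- pure_fiber_mask(sim)
  tf <- fit_dti(sim$dwi, mask = mask)
  v <- which(mask)[1L]
  expect_lt(abs(tf$lambda1[v] - 1.7e-3), 1e-6)
  ev <- c(1.7, 0.3, 0.3) * 1e-3
  fa_expect <- sqrt(0.5 * ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                           (ev[1] - ev[3])^2) / sum(ev^2))
  expect_equal(tf$fa[v], fa_expect, tolerance = 1e-6)
  # isotropic voxel: FA ~ 0
  bg <- sim$truth$tissue_mask & array(sim$truth$fractions[, 1L] == 0,
                                      dim(mask))
  tfb <- fit_dti(sim$dwi, mask = bg)
  expect_lt(max(tfb$fa[which(bg)]), 1e-9)
  # principal eigenvector along the bundle (x axis)
  expect_gt(min(abs(tf$v1[, 1L])), 0.999)
  expect_error(fit_dti(sim$dwi, gradient_scheme(rbind(c(0, 0, 0), diag(3)),
                                                c(0, rep(3000, 3)))),
               ">= 6")
})

test_that("Rician noise at 2% of S0 biases FA by less than 0.05", {
  sc <- fixture_scheme64()
  b <- fiber_bundle_spec(rbind(c(-40, 15.5, 15.5), c(80, 15.5, 15.5)),
                         radius = 3.5)
  sim <- simulate_signal(list(b), sc, c(32L, 32L, 32L), S0 = 100,
                         noise_sigma = 2, seed = 99L)
  mask <- array(sim$truth$bundle_masks[[1L]] &
                  sim$truth$fractions[, 1L] == 1, c(32L, 32L, 32L))
  tf <- fit_dti(sim$dwi, mask = mask)
  ev <- c(1.7, 0.3, 0.3) * 1e-3
  fa_true <- sqrt(0.5 * ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                         (ev[1] - ev[3])^2) / sum(ev^2))
  expect_lt(abs(mean(tf$fa[which(mask)]) - fa_true), 0.05)
})

test_that("Legendre-at-zero factors used by the Funk-Radon transform", {
  ll <- sh_index_table(4L)$l
  pl0 <- vapply(unique(ll), function(l) {
    if (l == 0) return(1)
    (-1)^(l / 2) * prod(seq(1, l - 1, by = 2)) / prod(seq(2, l, by = 2))
  }, numeric(1L))
  expect_equal(pl0, c(1, -1 / 2, 3 / 8))
})

test_that("QBI resolves single fibers and 90-degree crossings", {
  sim <- fixture_single_bundle()
  mask <- pure_fiber_mask(sim)
  sel <- array(FALSE, dim(mask)); sel[which(mask)[1:4]] <- TRUE
  odf <- qbi_odf(sim$dwi, mask = sel, lmax = 8L)
  pk <- find_peaks(odf)
  v <- which(pk$npeaks > 0)[1L]
  expect_equal(pk$npeaks[v], 1L)
  expect_angle_le(pk$dirs[v, 1L, ], c(1, 0, 0), 4)
  # isotropic voxel: sampled ODF is constant (only l = 0 survives)
  bg <- sim$truth$tissue_mask & array(sim$truth$fractions[, 1L] == 0,
                                      dim(mask))
  sel2 <- array(FALSE, dim(mask)); sel2[which(bg)[1L]] <- TRUE
  odf_iso <- qbi_odf(sim$dwi, mask = sel2)
  vals <- as.numeric(sh_basis(hemisphere181(), odf_iso$lmax) %*% odf_iso$coef)
  expect_lt(sd(vals) / mean(vals), 1e-6)
  # 90-degree crossing: two peaks near the true axes at lmax 8
  simx <- fixture_crossing90()
  both <- simx$truth$bundle_masks[[1L]] & simx$truth$bundle_masks[[2L]]
  selx <- array(FALSE, dim(both)); selx[which(both)[1:4]] <- TRUE
  pkx <- find_peaks(qbi_odf(simx$dwi, mask = selx, lmax = 8L))
  vx <- which(pkx$npeaks > 0)[1L]
  expect_equal(pkx$npeaks[vx], 2L)
  errs <- vapply(1:2, function(j) {
    min(vapply(1:2, function(k)
      acos(min(abs(sum(pkx$dirs[vx, j, ] * simx$truth$directions[k, ])), 1)) *
        180 / pi, numeric(1L)))
  }, numeric(1L))
  expect_true(all(errs < 10))
  expect_error(qbi_odf(sim$dwi, lmax = 12L), "lmax")
})

test_that("GQI SDF is flat for isotropic voxels and peaks on fibers", {
  sc <- fixture_scheme64()
  sim_iso <- simulate_signal(list(), sc, c(8L, 8L, 8L))
  m <- array(FALSE, c(8L, 8L, 8L)); m[4, 4, 4] <- TRUE
  g <- gqi_sdf(sim_iso$dwi, mask = m)
  vals <- as.numeric(sh_basis(hemisphere181(), g$lmax) %*% g$coef)
  # near-flat: residual ripple of the truncated sinc kernel sum over 64
  # directions (direct kernel evaluation gives the same ratio)
  expect_lt(max(vals) / min(vals), 1.02)
  # linearity: doubling the signal doubles the SDF
  sim2 <- sim_iso
  sim2$dwi$data <- sim_iso$dwi$data * 2
  g2 <- gqi_sdf(sim2$dwi, mask = m)
  expect_equal(g2$coef, g$coef * 2, tolerance = 1e-9)
  # single fiber: peak within 4 degrees at sigma = 1.25
  sim <- fixture_single_bundle()
  mask <- pure_fiber_mask(sim)
  sel <- array(FALSE, dim(mask)); sel[which(mask)[1:4]] <- TRUE
  pk <- find_peaks(gqi_sdf(sim$dwi, mask = sel, sampling_ratio = 1.25))
  v <- which(pk$npeaks > 0)[1L]
  expect_angle_le(pk$dirs[v, 1L, ], c(1, 0, 0), 4)
})

test_that("sample_odf returns normalized probabilities", {
  sim <- fixture_single_bundle()
  mask <- pure_fiber_mask(sim)
  odf <- qbi_odf(sim$dwi, mask = mask)
  P <- sample_odf(odf)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_true(all(P >= 0))
  # pure l = 0 function: uniform 1/181
  f0 <- odf
  f0$coef <- matrix(c(1, rep(0, nrow(odf$coef) - 1L)), ncol = 1L)
  f0$voxels <- odf$voxels[1L]
  P0 <- sample_odf(f0)
  expect_equal(as.numeric(P0), rep(1 / 181, 181), tolerance = 1e-12)
})

test_that("roi_statistics reports mean/SD with the sample convention", {
  map <- array(0, c(4L, 4L, 4L))
  roi1 <- array(FALSE, c(4L, 4L, 4L)); roi1[1:2, 1, 1] <- TRUE
  map[1, 1, 1] <- 0; map[2, 1, 1] <- 1
  roi_const <- array(FALSE, c(4L, 4L, 4L)); roi_const[, 3, 3] <- TRUE
  map[, 3, 3] <- 7
  empty <- array(FALSE, c(4L, 4L, 4L))
  st <- roi_statistics(map, list(pair = roi1, const = roi_const,
                                 none = empty))
  expect_equal(st$mean[st$roi == "pair"], 0.5)
  expect_equal(st$sd[st$roi == "pair"], sqrt(0.5), tolerance = 1e-12)
  expect_equal(st$mean[st$roi == "const"], 7)
  expect_equal(st$sd[st$roi == "const"], 0)
  expect_identical(attr(st, "excluded"), "none")
})
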
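# independent two-KL evaluation used as the JSD oracle
jsd_oracle <- function(P, Q) {
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log(a[i] / b[i])
    s
  }
  M <- (P + Q) / 2
  (kl(P, M) + kl(Q, M)) / 2
}

test_that("KL divergence: worked case, identity, nonnegativity", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)), 0.14384,
               tolerance = 1e-4)
  set.seed(10)
  kls <- vapply(1:200, function(i) {
    P <- random_prob(20L); Q <- random_prob(20L)
    c(kl_divergence(P, Q), kl_divergence(P, P))
  }, numeric(2L))
  expect_true(all(kls[1L, ] >= 0))
  expect_true(all(kls[2L, ] == 0))
  expect_error(kl_divergence(c(1, 0), c(0.5, 0.25, 0.25)), "length")
  expect_error(kl_divergence(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1")
})

test_that("JSD identity, symmetry, ln 2 bound, oracle agreement", {
  set.seed(11)
  P1 <- random_prob()
  expect_equal(jsd(P1, P1), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  js <- vapply(1:1000, function(i) {
    P <- random_prob(); Q <- random_prob()
    c(jsd(P, Q), jsd(Q, P))
  }, numeric(2L))
  expect_lt(max(abs(js[1L, ] - js[2L, ])), 1e-12)
  expect_true(all(js[1L, ] >= 0))
  expect_true(all(js[1L, ] <= log(2) + 1e-12))
  # brute-force two-KL oracle on a smaller randomized suite
  orc <- vapply(1:50, function(i) {
    P <- random_prob(50L); Q <- random_prob(50L)
    abs(jsd(P, Q) - jsd_oracle(P, Q))
  }, numeric(1L))
  expect_lt(max(orc), 1e-12)
  # vectorized row-wise path agrees with the scalar definition
  Pm <- t(replicate(20L, random_prob()))
  Qm <- t(replicate(20L, random_prob()))
  jr <- hardigen:::.jsd_rows(Pm, Qm)
  for (i in 1:20) expect_equal(jr[i], jsd(Pm[i, ], Qm[i, ]),
                               tolerance = 1e-12)
})

test_that("ACC identity, scale invariance, orthogonality, antisymmetry", {
  set.seed(12)
  idx <- sh_index_table(8L)
  u <- rnorm(nrow(idx))
  expect_equal(acc(u, u), 1)
  expect_equal(acc(u, 2 * u), 1)
  # pure (l=2,m=0) vs pure (l=4,m=0): orthogonal
  a <- numeric(nrow(idx)); a[idx$l == 2 & idx$m == 0] <- 1
  b <- numeric(nrow(idx)); b[idx$l == 4 & idx$m == 0] <- 1
  expect_equal(acc(a, b), 0)
  # negating the anisotropic part flips the sign
  v <- rnorm(nrow(idx))
  vneg <- v; vneg[idx$l >= 1] <- -vneg[idx$l >= 1]
  expect_equal(acc(u, vneg), -acc(u, v), tolerance = 1e-12)
  # l = 0 is excluded: changing it does not move the ACC
  u2 <- u; u2[1L] <- u2[1L] + 100
  expect_equal(acc(u, v), acc(u2, v), tolerance = 1e-12)
  # isotropic input: undefined, flagged
  iso <- numeric(nrow(idx)); iso[1L] <- 5
  res <- acc(u, iso)
  expect_true(is.na(res))
  expect_true(attr(res, "undefined"))
})

test_that("SSIM: identity, monotone noise response, reference agreement", {
  set.seed(1234)
  pred <- array(runif(16^3), c(16L, 16L, 16L))
  ref <- array(runif(16^3), c(16L, 16L, 16L))
  expect_equal(ssim_volume(ref, ref), 1, tolerance = 1e-12)
  # frozen value from an independent volumetric SSIM implementation
  # (Gaussian-weighted, 11^3 window, sigma 1.5) on this seeded pair
  expect_equal(ssim_volume(pred, ref), -0.0171956874, tolerance = 1e-4)
  base <- array(runif(16^3, 0, 1), c(16L, 16L, 16L))
  prev <- 1
  for (s in c(0, 0.05, 0.1)) {
    noisy <- base + array(rnorm(16^3, 0, s * max(base)), dim(base))
    cur <- ssim_volume(noisy, base)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
  expect_error(ssim_volume(pred, ref, array(FALSE, dim(ref))), "empty")
})

test_that("PSNR: identity sentinel, worked case, halving rule", {
  x <- array(runif(8^3, 0, 255), c(8L, 8L, 8L))
  expect_identical(psnr_volume(x, x), Inf)
  y <- x; y[] <- pmin(x + 1, max(x))
  # +1 everywhere with MAX = 255: 10 log10(255^2) ~ 48.13 dB
  xc <- array(100, c(8L, 8L, 8L)); xc[1, 1, 1] <- 255
  yc <- xc + 1
  expect_equal(psnr_volume(yc, xc), 10 * log10(255^2), tolerance = 1e-9)
  expect_equal(10 * log10(255^2), 48.13, tolerance = 1e-3)
  # halving the MSE raises PSNR by 10 log10 2 ~ 3.0103 dB
  e <- array(rnorm(8^3), c(8L, 8L, 8L))
  p1 <- psnr_volume(xc + e, xc)
  p2 <- psnr_volume(xc + e / sqrt(2), xc)
  expect_equal(p2 - p1, 10 * log10(2), tolerance = 1e-9)
  expect_equal(10 * log10(2), 3.0103, tolerance = 1e-4)
})

test_that("Dice: identity, disjoint, worked case, symmetry, empty flag", {
  a <- array(FALSE, c(4L, 4L, 4L)); b <- a
  a[1:4, 1, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b[1:4, 2, 1] <- TRUE
  expect_equal(dice(a, b), 0)
  b <- array(FALSE, c(4L, 4L, 4L)); b[3:6] <- TRUE   # overlap 2, |x|=|y|=4
  expect_equal(dice(a, b), 0.5)
  set.seed(14)
  for (i in 1:20) {
    x <- array(runif(64) > 0.5, c(4L, 4L, 4L))
    y <- array(runif(64) > 0.5, c(4L, 4L, 4L))
    expect_identical(dice(x, y), dice(y, x))
  }
  e <- array(FALSE, c(4L, 4L, 4L))
  res <- dice(e, e)
  expect_true(is.na(res) && attr(res, "undefined"))
  expect_error(dice(a, array(FALSE, c(5L, 4L, 4L))), "grid")
})

test_that("Wilcoxon route: exact enumeration, degenerate flag, effect size", {
  # all-shifted n = 5 example: exact two-sided p = 0.0625
  res <- paired_compare(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(res$p, 0.0625)
  # sign-assignment enumeration oracle
  d <- c(2, 3, 4, 5, 6) - c(1, 2, 3, 4, 5)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5L)))
  vall <- signs %*% r
  mu <- sum(r) / 2
  expect_equal(res$p, mean(abs(vall - mu) >= abs(sum(r) - mu)))
  # identical vectors: degenerate
  res0 <- paired_compare(1:6, 1:6)
  expect_true(res0$degenerate)
  expect_equal(res0$p, 1)
  expect_equal(res0$effect_size, 0)
  # exact route agrees with wilcox.test when there are no ties
  set.seed(15)
  a <- rnorm(10); b <- a + rnorm(10)
  expect_equal(paired_compare(a, b)$p,
               wilcox.test(b, a, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Friedman route applies the three-arm Bonferroni threshold", {
  set.seed(16)
  a <- rnorm(12); b <- a + rnorm(12, 0.1); c_ <- a + rnorm(12, 1)
  res <- paired_compare(a, b, c_, method = "friedman_bonferroni")
  expect_equal(round(res$bonferroni_threshold, 4), 0.0167)
  expect_s3_class(res$pairwise, "data.frame")
  expect_equal(nrow(res$pairwise), 3L)
  expect_equal(unname(res$statistic),
               unname(friedman.test(cbind(a, b, c_))$statistic))
})
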
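# closed-form layer-wise parameter count for the configured topology
unet_param_closed_form <- function(levels, base, cin, cout, k = 3L) {
  f <- base * 2L^(0:(levels - 1L))
  k3 <- k^3
  total <- (cin * f[1L] * k3 + f[1L]) + (f[1L]^2 * k3 + f[1L])
  if (levels > 1L) {
    for (i in 2:levels)
      total <- total + (f[i - 1L] * f[i] * k3 + f[i]) + (f[i]^2 * k3 + f[i])
    for (i in (levels - 1L):1L)
      total <- total + (8L * f[i] * f[i + 1L] + f[i]) +
        (2L * f[i]^2 * k3 + f[i])
  }
  total + (f[1L] * cout + cout)
}

test_that("parameter count equals the closed-form layer count", {
  for (cfg in list(c(3L, 16L, 33L, 32L), c(2L, 8L, 5L, 4L),
                   c(3L, 4L, 2L, 3L), c(1L, 6L, 3L, 2L))) {
    m <- build_unet(unet_config(cfg[3L], cfg[4L], levels = cfg[1L],
                                base_filters = cfg[2L]), seed = 1L)
    expect_equal(unet_param_count(m),
                 unet_param_closed_form(cfg[1L], cfg[2L], cfg[3L], cfg[4L]))
  }
})

test_that("forward pass preserves spatial shape and output channels", {
  m <- build_unet(unet_config(4L, 32L, levels = 3L, base_filters = 4L),
                  seed = 2L)
  x <- array(abs(rnorm(4 * 16^3)), c(16L, 16L, 16L, 4L))
  y <- predict_unet(m, x)
  expect_equal(dim(y), c(16L, 16L, 16L, 32L))
  expect_true(all(y >= 0))
  expect_error(predict_unet(m, array(0, c(16L, 16L, 16L, 3L))), "channels")
  # shape error names the offending axis
  expect_error(predict_unet(m, array(0, c(10L, 16L, 16L, 4L))), "axis 1")
})

test_that("analytic gradients match numerical gradients", {
  cfg <- unet_config(2L, 3L, levels = 2L, base_filters = 2L)
  m <- build_unet(cfg, seed = 42L)
  nl <- length(m$layers)
  set.seed(3)
  m$layers[[nl]]$W[] <- rnorm(length(m$layers[[nl]]$W), 0, 0.1)
  x <- matrix(rnorm(2 * 64), 2L, 64L)
  y <- matrix(rnorm(3 * 64), 3L, 64L)
  fw <- hardigen:::.unet_forward(m, x, c(4L, 4L, 4L), keep_cache = TRUE)
  gr <- hardigen:::.unet_backward(m, fw$cache, 2 * (fw$y - y) / length(fw$y))
  loss <- function(mm)
    mean((hardigen:::.unet_forward(mm, x, c(4L, 4L, 4L))$y - y)^2)
  eps <- 1e-6
  for (li in seq_len(nl)) {
    set.seed(li)
    for (j in sample(length(m$layers[[li]]$W), 3L)) {
      mp <- m; mp$layers[[li]]$W[j] <- mp$layers[[li]]$W[j] + eps
      mm <- m; mm$layers[[li]]$W[j] <- mm$layers[[li]]$W[j] - eps
      num <- (loss(mp) - loss(mm)) / (2 * eps)
      expect_equal(gr[[li]]$dW[j], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  sc <- fixture_scheme64()
  ds <- generate_dataset(2L, list(scheme = sc,
                                  grid_shape = c(16L, 16L, 16L),
                                  partition = c(2, 0, 0)), seed = 31L)
  first <- which(sc$bvalues == 0 | sc$labels %in% 1:32)
  second <- setdiff(seq_along(sc$bvalues), first)
  xs <- lapply(ds$cases, function(cs)
    apply_normalization(cs$dwi)$data[, , , first])
  ys <- lapply(ds$cases, function(cs)
    apply_normalization(cs$dwi)$data[, , , second])
  m <- build_unet(unet_config(33L, 32L, levels = 2L, base_filters = 4L),
                  seed = 5L)
  tc <- train_config(minibatch_size = 2L, epochs = 5L,
                     learning_rate = 2e-3, seed = 6L)
  st <- train_unet(m, xs, ys, config = tc)
  expect_lt(st$train_mse[5L], st$train_mse[1L])
  expect_true(all(st$train_mse >= 0))
  st2 <- train_unet(m, xs, ys, config = tc)
  expect_identical(st$train_mse, st2$train_mse)
  # constant targets: MSE against the constant drops from its start
  zs <- lapply(ys, function(y) y * 0 + 0.2)
  stz <- train_unet(m, xs, zs, config = tc)
  expect_lt(stz$train_mse[5L], stz$train_mse[1L])
  # inference is deterministic
  p1 <- predict_unet(st, xs[[1L]])
  p2 <- predict_unet(st, xs[[1L]])
  expect_identical(p1, p2)
  expect_error(train_unet(m, xs, ys[1L], config = tc), "pair")
})

test_that("patch extraction indexes the same voxels as array slicing", {
  set.seed(21)
  arr <- array(rnorm(5 * 6 * 7 * 8 * 2), c(6L, 7L, 8L, 2L))
  st <- hardigen:::.to_cxn(arr)
  for (corner in list(c(0L, 0L, 0L), c(2L, 3L, 4L), c(2L, 0L, 1L))) {
    cols <- hardigen:::.patch_cols(st$dims, corner, c(4L, 4L, 4L))
    got <- st$x[, cols]
    want <- hardigen:::.to_cxn(
      arr[corner[1L] + 1:4, corner[2L] + 1:4, corner[3L] + 1:4, ,
          drop = FALSE])$x
    expect_identical(got, want)
  }
  # patch-mode training is deterministic and visits every voxel per epoch
  xs <- list(array(abs(rnorm(2 * 8^3)), c(8L, 8L, 8L, 2L)))
  ys <- list(array(abs(rnorm(3 * 8^3)), c(8L, 8L, 8L, 3L)))
  m <- build_unet(unet_config(2L, 3L, levels = 2L, base_filters = 2L),
                  seed = 4L)
  tc <- train_config(minibatch_size = 2L, epochs = 3L,
                     patch_shape = c(4L, 4L, 4L), seed = 5L)
  s1 <- train_unet(m, xs, ys, config = tc)
  s2 <- train_unet(m, xs, ys, config = tc)
  expect_identical(s1$train_mse, s2$train_mse)
})

test_that("the net can memorize a single phantom (capacity sanity)", {
  sc <- fixture_scheme64()
  sim <- fixture_crossing90()
  first <- which(sc$bvalues == 0 | sc$labels %in% 1:32)
  second <- setdiff(seq_along(sc$bvalues), first)
  d <- apply_normalization(sim$dwi)
  x <- d$data[, , , first]
  y <- d$data[, , , second]
  m <- build_unet(unet_config(33L, 32L, levels = 3L, base_filters = 16L),
                  seed = 9L)
  st <- train_unet(m, list(x), list(y),
                   config = train_config(minibatch_size = 2L, epochs = 120L,
                                         learning_rate = 3e-3,
                                         patch_shape = c(16L, 16L, 16L),
                                         seed = 10L))
  expect_gte(st$train_mse[1L] / min(st$train_mse), 100)
})

test_that("assemble_arms wires the three-arm comparison", {
  sc <- fixture_scheme64()
  sp <- split_scheme(sc, 32L)
  sim <- fixture_single_bundle()
  first <- which(sc$bvalues == 0 | sc$labels %in% 1:32)
  second <- setdiff(seq_along(sc$bvalues), first)
  input <- dwi_volume(sim$dwi$data[, , , first], sp$first)
  pred <- dwi_volume(sim$dwi$data[, , , second], sp$second)
  arms <- assemble_arms(input, pred, sim$dwi)
  expect_equal(dim(arms$b$data)[4L], 65L)
  expect_equal(dim(arms$c$data)[4L], 65L)
  expect_identical(arms$b$data[, , , 1:33], arms$a$data)
  expect_equal(length(arms$b$scheme$bvalues), 65L)
  expect_error(assemble_arms(input, input, sim$dwi), "mismatch")
})
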
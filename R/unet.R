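# 3D U-net for image-to-image MPG prediction, implemented on im2col/col2im
# primitives with BLAS matrix products. Volumes travel through the network
# as C x N matrices (channel-major, N = prod(spatial dims)).

#' U-net architecture configuration
#'
#' @param input_channels channels of the input stack (b0 + first-half MPG
#'   volumes; default 33).
#' @param output_channels predicted channels (second-half MPG; default 32).
#' @param levels number of resolution levels (>= 1).
#' @param base_filters filters at the finest level; doubled per level.
#' @param kernel_size odd convolution kernel extent (default 3).
#' @param downsample_stride stride of the downsampling convolutions.
#' @param activation activation name (only "relu" implemented).
#' @return list of class `unet_config`.
#' @export
unet_config <- function(input_channels = 33L, output_channels = 32L,
                        levels = 3L, base_filters = 16L, kernel_size = 3L,
                        downsample_stride = 2L, activation = "relu") {
  if (kernel_size %% 2 != 1) stop("`kernel_size` must be odd", call. = FALSE)
  if (levels < 1) stop("`levels` must be >= 1", call. = FALSE)
  if (input_channels < 1 || output_channels < 1)
    stop("channel counts must be >= 1", call. = FALSE)
  if (activation != "relu")
    stop("only the rectified linear unit activation is implemented",
         call. = FALSE)
  structure(list(input_channels = as.integer(input_channels),
                 output_channels = as.integer(output_channels),
                 levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 kernel_size = as.integer(kernel_size),
                 downsample_stride = as.integer(downsample_stride),
                 activation = activation),
            class = "unet_config")
}

# one conv layer descriptor; W is Cout x (k^3 * Cin) for conv layers and
# (k^3 * Cout) x Cin for transposed ("tconv") layers, matching im2col row
# order (offset-major, channel fastest)
.new_layer <- function(type, cin, cout, k, stride, pad, act) {
  list(type = type, cin = cin, cout = cout, k = k, stride = stride,
       pad = pad, act = act, W = NULL, b = NULL)
}

# layer topology for the configured depth; `skip_from` marks encoder taps,
# `concat_with` names the tap whose output is stacked onto a decoder input
.unet_topology <- function(config) {
  f <- config$base_filters * 2L^(0:(config$levels - 1L))
  k <- config$kernel_size
  pad <- (k - 1L) %/% 2L
  s <- config$downsample_stride
  layers <- list()
  add <- function(l, tag = NA_character_, concat = NA_character_) {
    l$tag <- tag; l$concat <- concat
    layers[[length(layers) + 1L]] <<- l
  }
  add(.new_layer("conv", config$input_channels, f[1L], k, 1L, pad, "relu"))
  add(.new_layer("conv", f[1L], f[1L], k, 1L, pad, "relu"), tag = "skip1")
  if (config$levels > 1L) {
    for (i in 2:config$levels) {
      add(.new_layer("conv", f[i - 1L], f[i], k, s, pad, "relu"))
      add(.new_layer("conv", f[i], f[i], k, 1L, pad, "relu"),
          tag = if (i < config$levels) paste0("skip", i) else NA_character_)
    }
    for (i in (config$levels - 1L):1L) {
      add(.new_layer("tconv", f[i + 1L], f[i], s, s, 0L, "relu"))
      add(.new_layer("conv", 2L * f[i], f[i], k, 1L, pad, "relu"),
          concat = paste0("skip", i))
    }
  }
  add(.new_layer("conv", f[1L], config$output_channels, 1L, 1L, 0L, "linear"))
  layers
}

#' Build a 3D U-net model
#'
#' Encoder-decoder with stride-2 convolutional downsampling, 2x2x2
#' transposed-convolution upsampling, skip connections by channel
#' concatenation and a final 1x1x1 linear projection. Weights use He
#' initialization; the final projection starts at zero so the untrained
#' model predicts zero signal.
#'
#' @param config a [unet_config()].
#' @param seed RNG seed for the initialization.
#' @return object of class `unet_model` (layers with weights, config,
#'   parameter count).
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  layers <- .unet_topology(config)
  n_layers <- length(layers)
  layers <- with_seed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      fan_in <- l$k^3 * l$cin
      sdev <- sqrt(2 / fan_in)
      nw <- l$k^3 * l$cin * l$cout
      if (i == n_layers) {
        w <- numeric(nw)
      } else {
        w <- rnorm(nw, 0, sdev)
      }
      l$W <- if (l$type == "conv") matrix(w, l$cout, l$k^3 * l$cin)
             else matrix(w, l$k^3 * l$cout, l$cin)
      l$b <- numeric(l$cout)
      layers[[i]] <- l
    }
    layers
  })
  structure(list(layers = layers, config = config, seed = as.integer(seed),
                 n_parameters = sum(vapply(layers, function(l)
                   length(l$W) + length(l$b), numeric(1L)))),
            class = "unet_model")
}

#' Trainable parameter count of a model
#' @param model a `unet_model`.
#' @return integer count.
#' @export
unet_param_count <- function(model) model$n_parameters

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %d levels, base %d, %d layers, %d parameters\n",
              x$config$levels, x$config$base_filters, length(x$layers),
              x$n_parameters))
  invisible(x)
}

.check_unet_dims <- function(dims, levels, stride) {
  div <- stride^(levels - 1L)
  bad <- which(dims %% div != 0L)
  if (length(bad) > 0L)
    stop(sprintf("spatial axis %d (extent %d) is not divisible by %d",
                 bad[1L], dims[bad[1L]], div), call. = FALSE)
  invisible(TRUE)
}

# forward pass; x is Cin x N, dims the spatial extents.
# Returns list(y, cache) where cache holds per-layer inputs/preactivations.
.unet_forward <- function(model, x, dims, keep_cache = FALSE) {
  .check_unet_dims(dims, model$config$levels, model$config$downsample_stride)
  skips <- list()
  cache <- if (keep_cache) vector("list", length(model$layers)) else NULL
  cur <- x
  cur_dims <- as.integer(dims)
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    concat_rows <- 0L
    if (!is.na(l$concat)) {
      sk <- skips[[l$concat]]
      concat_rows <- nrow(sk$x)
      cur <- rbind(cur, sk$x)
    }
    if (l$type == "conv") {
      out_dims <- (cur_dims + 2L * l$pad - l$k) %/% l$stride + 1L
      z <- .conv3_fwd(cur, l$W, l$b, cur_dims, l$k, l$stride, l$pad)
    } else {
      out_dims <- cur_dims * l$stride
      z <- .tconv3_fwd(cur, l$W, l$b, out_dims, l$k, l$stride, l$pad)
    }
    a <- if (l$act == "relu") pmax(z, 0) else z
    if (keep_cache)
      cache[[i]] <- list(x = cur, in_dims = cur_dims, z = z,
                         concat_rows = concat_rows)
    if (!is.na(l$tag)) skips[[l$tag]] <- list(x = a, dims = out_dims)
    cur <- a
    cur_dims <- out_dims
  }
  list(y = cur, dims = cur_dims, cache = cache)
}

# backward pass: returns per-layer gradients (dW, db) for loss gradient dY
.unet_backward <- function(model, cache, dY) {
  n <- length(model$layers)
  grads <- vector("list", n)
  d_skip <- list()   # gradients flowing back into encoder taps
  dcur <- dY
  for (i in seq(n, 1L)) {
    l <- model$layers[[i]]
    ca <- cache[[i]]
    if (!is.na(l$tag) && !is.null(d_skip[[l$tag]])) {
      dcur <- dcur + d_skip[[l$tag]]
    }
    if (l$act == "relu") dcur <- dcur * (ca$z > 0)
    if (l$type == "conv") {
      dW <- .conv3_bwd_weight(ca$x, dcur, ca$in_dims, l$k, l$stride, l$pad)
      db <- rowSums(dcur)
      dx <- .conv3_bwd_input(dcur, l$W, ca$in_dims, l$k, l$stride, l$pad)
    } else {
      out_dims <- ca$in_dims * l$stride
      dW <- .tconv3_bwd_weight(ca$x, dcur, out_dims, l$k, l$stride, l$pad)
      db <- rowSums(dcur)
      dx <- .tconv3_bwd_input(dcur, l$W, out_dims, l$k, l$stride, l$pad)
    }
    grads[[i]] <- list(dW = dW, db = db)
    if (ca$concat_rows > 0L) {
      main_rows <- nrow(dx) - ca$concat_rows
      d_skip[[l$concat]] <- dx[(main_rows + 1L):nrow(dx), , drop = FALSE]
      dx <- dx[seq_len(main_rows), , drop = FALSE]
    }
    dcur <- dx
  }
  grads
}

#' Train configuration
#'
#' @param minibatch_size volumes per optimizer step.
#' @param epochs training epochs (>= 1).
#' @param optimizer only "adam" is implemented.
#' @param learning_rate Adam step size (the peak rate under a schedule).
#' @param lr_schedule `"constant"`, or `"cosine"` for a linear warmup to
#'   `learning_rate` over `warmup_epochs` followed by a half-cosine decay
#'   to `learning_rate * lr_final_fraction`. The warmup is what keeps
#'   Adam stable at useful peak rates with the zero-initialized output
#'   projection; without it the first epochs overshoot.
#' @param lr_final_fraction floor of the cosine decay.
#' @param warmup_epochs linear warmup length (cosine schedule only).
#' @param patch_shape `NULL` for whole-volume training, or 3 integers: each
#'   epoch then visits randomly-offset patches of this shape tiling every
#'   volume (as many patches as tile the volume), which multiplies the
#'   optimizer steps per epoch at unchanged cost — the useful regime for
#'   small cohorts and for grids too large to fit whole.
#' @param seed RNG seed (shuffling and patch offsets).
#' @return list of class `train_config`.
#' @export
train_config <- function(minibatch_size = 2L, epochs = 40L,
                         optimizer = "adam", learning_rate = 3e-3,
                         lr_schedule = c("cosine", "constant"),
                         lr_final_fraction = 0.02, warmup_epochs = 5L,
                         patch_shape = NULL, seed = 1L) {
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (minibatch_size < 1) stop("`minibatch_size` must be >= 1", call. = FALSE)
  if (optimizer != "adam") stop("only Adam is implemented", call. = FALSE)
  if (!is.null(patch_shape) && (length(patch_shape) != 3L ||
                                any(patch_shape < 4)))
    stop("`patch_shape` must be NULL or 3 extents >= 4", call. = FALSE)
  structure(list(minibatch_size = as.integer(minibatch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 learning_rate = learning_rate,
                 lr_schedule = match.arg(lr_schedule),
                 lr_final_fraction = lr_final_fraction,
                 warmup_epochs = as.integer(warmup_epochs),
                 patch_shape = if (is.null(patch_shape)) NULL
                               else as.integer(patch_shape),
                 seed = as.integer(seed)),
            class = "train_config")
}

# column indices of the patch with 0-based corner `corner` and shape `ps`
.patch_cols <- function(dims, corner, ps) {
  ix <- corner[1L] + seq_len(ps[1L]) - 1L
  iy <- corner[2L] + seq_len(ps[2L]) - 1L
  iz <- corner[3L] + seq_len(ps[3L]) - 1L
  as.vector(outer(outer(ix + 1L, dims[1L] * iy, `+`),
                  dims[1L] * dims[2L] * iz, `+`))
}

# learning rate for a given epoch under the configured schedule
.lr_at <- function(config, epoch) {
  if (identical(config$lr_schedule, "constant") || config$epochs == 1L)
    return(config$learning_rate)
  w <- min(config$warmup_epochs, config$epochs - 1L)
  if (epoch <= w) return(config$learning_rate * epoch / (w + 1))
  lo <- config$learning_rate * config$lr_final_fraction
  frac <- (epoch - w - 1) / max(config$epochs - w - 1, 1L)
  lo + (config$learning_rate - lo) * (1 + cos(pi * frac)) / 2
}

# stack a dwi_volume (or plain 4D array) into the C x N layout
.to_cxn <- function(x) {
  arr <- if (inherits(x, "dwi_volume")) x$data else x
  d <- dim(arr)
  list(x = t(matrix(arr, prod(d[1:3]), d[4L])), dims = d[1:3])
}

#' Train the U-net with Adam on the MSE loss
#'
#' Minimizes the mean squared error between predicted and teaching
#' volumes. Per-epoch training MSE is the average of the minibatch losses
#' evaluated before each update; validation MSE is computed after each
#' epoch and the best-validation weights are kept.
#'
#' @param model a `unet_model`.
#' @param train_x,train_y lists of paired input/target volumes
#'   ([dwi_volume()]s or 4D arrays) with matching spatial shapes.
#' @param val_x,val_y validation pairs (may be empty lists).
#' @param config a [train_config()].
#' @return list of class `training_state`: `model` (best weights),
#'   `train_mse`, `val_mse` (per-epoch), `best_epoch`.
#' @export
train_unet <- function(model, train_x, train_y, val_x = list(),
                       val_y = list(), config = train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (length(train_x) != length(train_y))
    stop("training inputs and targets must pair up", call. = FALSE)
  tx <- lapply(train_x, .to_cxn)
  ty <- lapply(train_y, .to_cxn)
  for (i in seq_along(tx)) {
    if (!identical(tx[[i]]$dims, ty[[i]]$dims))
      stop(sprintf("shape mismatch in training pair %d", i), call. = FALSE)
    if (nrow(tx[[i]]$x) != model$config$input_channels)
      stop(sprintf("training input %d has %d channels, model expects %d",
                   i, nrow(tx[[i]]$x), model$config$input_channels),
           call. = FALSE)
  }
  vx <- lapply(val_x, .to_cxn)
  vy <- lapply(val_y, .to_cxn)
  n <- length(tx)
  layers <- model$layers
  mstate <- lapply(layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tstep <- 0L
  train_mse <- numeric(config$epochs)
  val_mse <- numeric(config$epochs)
  best <- list(epoch = 0L, mse = Inf, layers = layers)
  ps <- config$patch_shape
  # per-epoch task schedule: whole volumes, or the non-overlapping patch
  # tiling of every volume (so each epoch still visits every voxel exactly
  # once and the epoch-averaged patch MSE is a partition of the
  # whole-volume MSE), shuffled per epoch
  tile_corners <- function(d) {
    if (any(ps > d))
      stop("`patch_shape` exceeds the volume extents", call. = FALSE)
    starts <- lapply(1:3, function(ax)
      unique(pmin(seq(0L, d[ax] - 1L, by = ps[ax]), d[ax] - ps[ax])))
    as.matrix(expand.grid(starts))
  }
  order_seq <- with_seed(config$seed, {
    lapply(seq_len(config$epochs), function(e) {
      tasks <- list()
      for (i in seq_len(n)) {
        if (is.null(ps)) {
          tasks[[length(tasks) + 1L]] <- list(s = i, corner = NULL)
        } else {
          corners <- tile_corners(tx[[i]]$dims)
          for (t in seq_len(nrow(corners)))
            tasks[[length(tasks) + 1L]] <- list(s = i,
                                                corner = corners[t, ])
        }
      }
      tasks[sample.int(length(tasks))]
    })
  })
  mdl <- model
  eval_mse <- function(xs, ys) {
    if (length(xs) == 0L) return(NA_real_)
    tot <- 0; cnt <- 0
    for (i in seq_along(xs)) {
      fw <- .unet_forward(mdl, xs[[i]]$x, xs[[i]]$dims)
      tot <- tot + sum((fw$y - ys[[i]]$x)^2)
      cnt <- cnt + length(fw$y)
    }
    tot / cnt
  }
  for (epoch in seq_len(config$epochs)) {
    lr <- .lr_at(config, epoch)
    ord <- order_seq[[epoch]]
    batches <- split(ord, ceiling(seq_along(ord) / config$minibatch_size))
    epoch_losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      gacc <- NULL
      loss <- 0
      for (task in idx) {
        s <- task$s
        if (is.null(task$corner)) {
          xin <- tx[[s]]$x; yin <- ty[[s]]$x; din <- tx[[s]]$dims
        } else {
          cols <- .patch_cols(tx[[s]]$dims, task$corner, ps)
          xin <- tx[[s]]$x[, cols, drop = FALSE]
          yin <- ty[[s]]$x[, cols, drop = FALSE]
          din <- ps
        }
        fw <- .unet_forward(mdl, xin, din, keep_cache = TRUE)
        resid <- fw$y - yin
        loss <- loss + mean(resid^2)
        dY <- (2 / length(resid)) * resid
        g <- .unet_backward(mdl, fw$cache, dY)
        if (is.null(gacc)) gacc <- g
        else for (li in seq_along(g)) {
          gacc[[li]]$dW <- gacc[[li]]$dW + g[[li]]$dW
          gacc[[li]]$db <- gacc[[li]]$db + g[[li]]$db
        }
      }
      loss <- loss / length(idx)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      epoch_losses[bi] <- loss
      tstep <- tstep + 1L
      corr <- sqrt(1 - beta2^tstep) / (1 - beta1^tstep)
      for (li in seq_along(mdl$layers)) {
        st <- mstate[[li]]
        dW <- gacc[[li]]$dW / length(idx)
        db <- gacc[[li]]$db / length(idx)
        st$mW <- beta1 * st$mW + (1 - beta1) * dW
        st$vW <- beta2 * st$vW + (1 - beta2) * dW^2
        st$mb <- beta1 * st$mb + (1 - beta1) * db
        st$vb <- beta2 * st$vb + (1 - beta2) * db^2
        mdl$layers[[li]]$W <- mdl$layers[[li]]$W -
          lr * corr * st$mW / (sqrt(st$vW) + eps)
        mdl$layers[[li]]$b <- mdl$layers[[li]]$b -
          lr * corr * st$mb / (sqrt(st$vb) + eps)
        mstate[[li]] <- st
      }
    }
    train_mse[epoch] <- mean(epoch_losses)
    val_mse[epoch] <- eval_mse(vx, vy)
    track <- if (is.na(val_mse[epoch])) train_mse[epoch] else val_mse[epoch]
    if (track < best$mse)
      best <- list(epoch = epoch, mse = track, layers = mdl$layers)
  }
  mdl$layers <- best$layers
  structure(list(model = mdl, train_mse = train_mse, val_mse = val_mse,
                 best_epoch = best$epoch, config = config),
            class = "training_state")
}

#' @export
print.training_state <- function(x, ...) {
  cat(sprintf(paste0("<training_state> %d epochs, train MSE %.3g -> %.3g,",
                     " best epoch %d\n"),
              length(x$train_mse), x$train_mse[1L],
              x$train_mse[length(x$train_mse)], x$best_epoch))
  invisible(x)
}

#' Predict the second-half MPG volumes
#'
#' Applies the trained model to a b0 + first-half stack; outputs are
#' clamped to be nonnegative (DWI signals are magnitudes) and returned in
#' the order of the second-half scheme.
#'
#' @param model a `unet_model` (or `training_state`).
#' @param input a [dwi_volume()] (b0 + first half) or 4D array.
#' @param second_scheme [gradient_scheme()] of the predicted channels;
#'   required to return a `dwi_volume`, otherwise a 4D array is returned.
#' @return [dwi_volume()] (or array) of predicted channels.
#' @export
predict_unet <- function(model, input, second_scheme = NULL) {
  if (inherits(model, "training_state")) model <- model$model
  stopifnot(inherits(model, "unet_model"))
  st <- .to_cxn(input)
  if (nrow(st$x) != model$config$input_channels)
    stop(sprintf("input has %d channels, model expects %d",
                 nrow(st$x), model$config$input_channels), call. = FALSE)
  fw <- .unet_forward(model, st$x, st$dims)
  y <- pmax(fw$y, 0)
  arr <- array(t(y), dim = c(st$dims, nrow(y)))
  if (is.null(second_scheme)) return(arr)
  aff <- if (inherits(input, "dwi_volume")) input$affine
         else diag(c(2.5, 2.5, 2.5, 1))
  norm <- if (inherits(input, "dwi_volume")) input$normalization else NULL
  dwi_volume(arr, second_scheme, affine = aff, normalization = norm)
}

#' Assemble the three evaluation arms
#'
#' Arm (a): b0 + first-half measured volumes; arm (b): arm (a) plus the
#' predicted second half; arm (c): b0 + all measured volumes (reference).
#' Each arm carries its matching gradient scheme.
#'
#' @param input_dwi arm (a) [dwi_volume()] (b0 + first half).
#' @param predicted predicted second-half [dwi_volume()].
#' @param reference full measured [dwi_volume()].
#' @return named list of `dwi_volume`s `a`, `b`, `c`.
#' @export
assemble_arms <- function(input_dwi, predicted, reference) {
  stopifnot(inherits(input_dwi, "dwi_volume"),
            inherits(predicted, "dwi_volume"),
            inherits(reference, "dwi_volume"))
  na <- dim(input_dwi$data)[4L]
  np <- dim(predicted$data)[4L]
  nc <- dim(reference$data)[4L]
  if (na + np != nc)
    stop(sprintf("arm channel mismatch: %d + %d != %d", na, np, nc),
         call. = FALSE)
  if (!identical(dwi_dims(input_dwi), dwi_dims(reference)))
    stop("arm grids differ", call. = FALSE)
  b_scheme <- merge_schemes(input_dwi$scheme, predicted$scheme)
  b_data <- array(0, c(dwi_dims(input_dwi), na + np))
  b_data[, , , seq_len(na)] <- input_dwi$data
  b_data[, , , na + seq_len(np)] <- predicted$data
  list(a = input_dwi,
       b = dwi_volume(b_data, b_scheme, affine = input_dwi$affine),
       c = reference)
}
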
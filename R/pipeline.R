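#' Default experiment configuration
#'
#' Desk-scale profile of the full three-arm experiment: 32^3 phantom
#' grids, a 64-direction b = 3000 s/mm^2 scheme split 32 + 32, 20
#' training / 3 validation / 5 test phantoms, a levels = 3 U-net and at
#' most 50 epochs. Every random operation consumes a seed derived from
#' `seed`.
#'
#' @param seed master seed.
#' @param ... overrides for any top-level entry.
#' @return list of class `experiment_config`.
#' @export
default_experiment_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_train = 20L, n_val = 3L, n_test = 5L,
    grid_shape = c(32L, 32L, 32L),
    n_directions = 64L, k_split = 32L, bvalue = 3000,
    scheme_restarts = 20L, scheme_iterations = 150L,
    S0 = 100, noise_sigma = 0,
    angle_range = c(50, 90), radius_range = c(3, 4), offset_sd = 1,
    model = list(levels = 3L, base_filters = 16L, kernel_size = 3L),
    train = list(minibatch_size = 2L, epochs = 50L, learning_rate = 3e-3,
                 warmup_epochs = 6L, lr_final_fraction = 0.005,
                 patch_shape = c(16L, 16L, 16L)),
    gqi_sampling_ratio = 1.25,
    mask_fraction = 0.25,
    tracking = list(step_size = 0.5, max_angle = 45, min_length = 4),
    output_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("experiment_config", "list"))
}

# stable polynomial hash of the configuration serialization
.config_hash <- function(cfg) {
  cfg$output_dir <- NULL
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# voxelwise diffusion-profile comparison of one arm pair on QBI ODFs.
# Voxels whose reference-arm ODF has (numerically) no anisotropic energy
# carry no defined angular correlation -- on noiseless phantoms the
# isotropic background's l >= 1 coefficients are floating-point residue,
# and arms sharing raw measurements correlate that residue spuriously --
# so the comparison is restricted to voxels where the reference
# anisotropic fraction exceeds `min_anisotropy`.
.profile_metrics <- function(field_x, field_c, lmax_common = 8L,
                             min_anisotropy = 0.01) {
  pad <- function(f) {
    idx_full <- sh_index_table(lmax_common)
    coef <- matrix(0, nrow(idx_full), ncol(f$coef))
    idx_f <- sh_index_table(f$lmax)
    key_full <- paste(idx_full$l, idx_full$m)
    key_f <- paste(idx_f$l, idx_f$m)
    coef[match(key_f, key_full), ] <- f$coef
    coef
  }
  stopifnot(identical(field_x$voxels, field_c$voxels))
  U <- pad(field_x); V <- pad(field_c)
  fx <- field_x; fx$coef <- U; fx$lmax <- lmax_common
  fc <- field_c; fc$coef <- V; fc$lmax <- lmax_common
  P <- sample_odf(fx); Q <- sample_odf(fc)
  jsd_vox <- .jsd_rows(P, Q)
  ll <- sh_index_table(lmax_common)$l
  acc_vox <- .acc_cols(U, V, ll)
  aniso <- sqrt(colSums(V[ll >= 1, , drop = FALSE]^2)) /
    pmax(abs(V[1L, ]), 1e-300)
  ok <- !is.na(acc_vox) & aniso > min_anisotropy
  list(jsd_mean = mean(jsd_vox[ok]), acc_mean = mean(acc_vox[ok]),
       jsd_vox = jsd_vox, acc_vox = acc_vox, n = sum(ok))
}

#' Run the full three-arm experiment on synthetic phantoms
#'
#' Simulates a phantom cohort, trains the U-net to predict the second
#' half of the MPG volumes from the b0 plus first half, assembles the
#' three arms on held-out phantoms and evaluates: per-axis SSIM/PSNR of
#' the predictions, voxelwise JSD/ACC of QBI diffusion profiles (a vs c
#' and b vs c), three-arm FA/E1 ROI statistics, and QBI/GQI tractography
#' Dice vs the reference arm, with paired statistics.
#'
#' @param config an [default_experiment_config()] list.
#' @return object of class `metric_report` (nested list; see README). If
#'   `config$output_dir` is set, JSON and CSV reports and key volumes are
#'   written there.
#' @export
run_experiment <- function(config = default_experiment_config()) {
  t0 <- Sys.time()
  seed <- config$seed
  scheme <- design_scheme(config$n_directions, seed = seed + 101L,
                          n_restarts = config$scheme_restarts,
                          n_iterations = config$scheme_iterations,
                          bvalue = config$bvalue)
  n_all <- config$n_train + config$n_val + config$n_test
  ds <- generate_dataset(n_all, config = list(
    scheme = scheme, grid_shape = config$grid_shape, S0 = config$S0,
    noise_sigma = config$noise_sigma, angle_range = config$angle_range,
    radius_range = config$radius_range, offset_sd = config$offset_sd,
    partition = c(train = config$n_train, val = config$n_val,
                  test = config$n_test)),
    seed = seed + 202L)
  parts <- split(seq_len(n_all), ds$partition)
  halves <- split_scheme(scheme, config$k_split)
  first_idx <- which(scheme$bvalues == 0 |
                       scheme$labels %in% seq_len(config$k_split))
  second_idx <- setdiff(seq_along(scheme$bvalues), first_idx)

  prep <- function(i) {
    dwi <- apply_normalization(ds$cases[[i]]$dwi)
    list(x = dwi$data[, , , first_idx, drop = FALSE],
         y = dwi$data[, , , second_idx, drop = FALSE],
         norm = dwi$normalization)
  }
  pairs <- lapply(seq_len(n_all), prep)

  mcfg <- do.call(unet_config, c(
    list(input_channels = length(first_idx),
         output_channels = length(second_idx)),
    config$model))
  model <- build_unet(mcfg, seed = seed + 303L)
  tcfg <- do.call(train_config, c(config$train, list(seed = seed + 404L)))
  state <- train_unet(model,
                      lapply(parts$train, function(i) pairs[[i]]$x),
                      lapply(parts$train, function(i) pairs[[i]]$y),
                      lapply(parts$val, function(i) pairs[[i]]$x),
                      lapply(parts$val, function(i) pairs[[i]]$y),
                      tcfg)

  tracking <- do.call(track_params, config$tracking)
  per_case <- list()
  for (ti in seq_along(parts$test)) {
    i <- parts$test[[ti]]
    case <- ds$cases[[i]]
    norm <- pairs[[i]]$norm
    pred_n <- predict_unet(state, pairs[[i]]$x)
    pred <- dwi_volume(pred_n * norm$scale, halves$second,
                       affine = case$dwi$affine)
    input_dwi <- dwi_volume(case$dwi$data[, , , first_idx, drop = FALSE],
                            halves$first, affine = case$dwi$affine)
    arms <- assemble_arms(input_dwi, pred, case$dwi)
    mask <- compute_b0_mask(dwi_b0(arms$c), method = "fraction",
                            fraction = config$mask_fraction)

    ref_second <- case$dwi$data[, , , second_idx, drop = FALSE]
    ssim_axis <- psnr_axis <- numeric(length(second_idx))
    for (ax in seq_along(second_idx)) {
      ssim_axis[ax] <- ssim_volume(pred$data[, , , ax],
                                   ref_second[, , , ax], mask)
      psnr_axis[ax] <- psnr_volume(pred$data[, , , ax],
                                   ref_second[, , , ax], mask)
    }

    odf <- lapply(arms, qbi_odf, mask = mask)
    pm_a <- .profile_metrics(odf$a, odf$c)
    pm_b <- .profile_metrics(odf$b, odf$c)

    # single-fiber ROIs: each bundle minus the other's tube
    rois_fa <- list()
    for (k in seq_along(case$truth$bundle_masks)) {
      other <- Reduce(`|`, case$truth$bundle_masks[-k],
                      array(FALSE, dim(mask)))
      rois_fa[[paste0("bundle", k)]] <-
        case$truth$bundle_masks[[k]] & !other & mask
    }
    dti <- lapply(arms, function(arm) fit_dti(arm, mask = mask))
    fa_stats <- lapply(dti, function(tf) roi_statistics(tf$fa, rois_fa))
    e1_stats <- lapply(dti, function(tf) roi_statistics(tf$e1, rois_fa))

    dsc <- list(
      qbi = bundle_dsc_experiment(arms, case$rois, "qbi", mask = mask,
                                  params = tracking),
      gqi = bundle_dsc_experiment(arms, case$rois, "gqi", mask = mask,
                                  params = tracking))

    per_case[[ti]] <- list(
      case = i, angle = case$angle,
      ssim = ssim_axis, psnr = psnr_axis,
      jsd_a = pm_a$jsd_mean, jsd_b = pm_b$jsd_mean,
      acc_a = pm_a$acc_mean, acc_b = pm_b$acc_mean,
      n_profile_voxels = pm_a$n,
      fa = fa_stats, e1 = e1_stats,
      dsc_qbi = dsc$qbi[, c("bundle", "dsc_a", "dsc_b")],
      dsc_gqi = dsc$gqi[, c("bundle", "dsc_a", "dsc_b")])
  }

  agg <- function(fun) vapply(per_case, fun, numeric(1L))
  dsc_tab <- function(which) do.call(rbind, lapply(per_case, `[[`, which))
  dsc_qbi <- dsc_tab("dsc_qbi"); dsc_gqi <- dsc_tab("dsc_gqi")
  roi_mean <- function(stats_name, arm) {
    mean(unlist(lapply(per_case, function(pc) pc[[stats_name]][[arm]]$mean)))
  }
  comp <- list(
    jsd = paired_compare(agg(function(p) p$jsd_a), agg(function(p) p$jsd_b)),
    acc = paired_compare(agg(function(p) p$acc_a), agg(function(p) p$acc_b)),
    dsc_qbi = paired_compare(dsc_qbi$dsc_a, dsc_qbi$dsc_b),
    dsc_gqi = paired_compare(dsc_gqi$dsc_a, dsc_gqi$dsc_b),
    fa = lapply(c(a = "a", b = "b", c = "c"), function(arm) roi_mean("fa", arm)),
    e1 = lapply(c(a = "a", b = "b", c = "c"), function(arm) roi_mean("e1", arm)))

  report <- structure(list(
    config_hash = .config_hash(config),
    seed = seed,
    scheme = list(energy = attr(scheme, "energy"),
                  min_angle = min_folded_angle(diffusion_directions(scheme))),
    n_parameters = unet_param_count(state$model),
    train_mse = state$train_mse, val_mse = state$val_mse,
    best_epoch = state$best_epoch,
    mse_drop = state$train_mse[1L] / state$train_mse[length(state$train_mse)],
    summary = list(
      ssim_mean = mean(unlist(lapply(per_case, `[[`, "ssim"))),
      psnr_mean = mean(unlist(lapply(per_case, function(p)
        p$psnr[is.finite(p$psnr)]))),
      jsd_a = mean(agg(function(p) p$jsd_a)),
      jsd_b = mean(agg(function(p) p$jsd_b)),
      acc_a = mean(agg(function(p) p$acc_a)),
      acc_b = mean(agg(function(p) p$acc_b)),
      dsc_qbi_a = mean(dsc_qbi$dsc_a, na.rm = TRUE),
      dsc_qbi_b = mean(dsc_qbi$dsc_b, na.rm = TRUE),
      dsc_gqi_a = mean(dsc_gqi$dsc_a, na.rm = TRUE),
      dsc_gqi_b = mean(dsc_gqi$dsc_b, na.rm = TRUE),
      frac_dsc_improved_qbi = mean(dsc_qbi$dsc_b >= dsc_qbi$dsc_a,
                                   na.rm = TRUE),
      frac_dsc_improved_gqi = mean(dsc_gqi$dsc_b >= dsc_gqi$dsc_a,
                                   na.rm = TRUE),
      fa = comp$fa, e1 = comp$e1),
    comparisons = comp[c("jsd", "acc", "dsc_qbi", "dsc_gqi")],
    per_case = per_case,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "metric_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.metric_report <- function(x, ...) {
  s <- x$summary
  cat("<metric_report>\n")
  cat(sprintf("  training MSE: %.4g -> %.4g (drop %.0fx, best epoch %d)\n",
              x$train_mse[1L], x$train_mse[length(x$train_mse)],
              x$mse_drop, x$best_epoch))
  cat(sprintf("  prediction: SSIM %.4f, PSNR %.2f dB\n",
              s$ssim_mean, s$psnr_mean))
  cat(sprintf("  JSD  (a vs c) %.4g   (b vs c) %.4g\n", s$jsd_a, s$jsd_b))
  cat(sprintf("  ACC  (a vs c) %.6f (b vs c) %.6f\n", s$acc_a, s$acc_b))
  cat(sprintf("  DSC QBI a %.3f b %.3f | GQI a %.3f b %.3f\n",
              s$dsc_qbi_a, s$dsc_qbi_b, s$dsc_gqi_a, s$dsc_gqi_b))
  invisible(x)
}

#' Write a metric report as JSON + CSV tables
#'
#' `report.json` holds the full report (without timing, so identical runs
#' are byte-identical); `per_case.csv` one row per case x arm x metric.
#'
#' @param report a `metric_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- unclass(report)
  out$elapsed_s <- NULL
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  rows <- list()
  for (pc in report$per_case) {
    add <- function(metric, arm, value)
      rows[[length(rows) + 1L]] <<- data.frame(
        case = pc$case, metric = metric, arm = arm, value = value)
    add("jsd_vs_c", "a", pc$jsd_a); add("jsd_vs_c", "b", pc$jsd_b)
    add("acc_vs_c", "a", pc$acc_a); add("acc_vs_c", "b", pc$acc_b)
    add("ssim_mean", "b", mean(pc$ssim))
    add("psnr_mean", "b", mean(pc$psnr[is.finite(pc$psnr)]))
    for (k in seq_len(nrow(pc$dsc_qbi))) {
      add(paste0("dsc_qbi_bundle", k), "a", pc$dsc_qbi$dsc_a[k])
      add(paste0("dsc_qbi_bundle", k), "b", pc$dsc_qbi$dsc_b[k])
      add(paste0("dsc_gqi_bundle", k), "a", pc$dsc_gqi$dsc_a[k])
      add(paste0("dsc_gqi_bundle", k), "b", pc$dsc_gqi$dsc_b[k])
    }
  }
  write.csv(do.call(rbind, rows), file.path(dir, "per_case.csv"),
            row.names = FALSE)
  invisible(dir)
}
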
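#' Fiber bundle specification
#'
#' Describes one straight or polyline tubular white-matter-like bundle in
#' voxel units: its centerline, tube radius, single-tensor eigenvalues and
#' the volume fraction it occupies where present.
#'
#' @param centerline numeric matrix (>= 2 rows, 3 columns) of 3D points in
#'   0-based voxel coordinates.
#' @param radius tube radius (voxels, > 0).
#' @param eigenvalues three nonnegative diffusivities (mm^2/s), descending.
#' @param volume_fraction fraction in (0, 1].
#' @return an object of class `fiber_bundle_spec`.
#' @export
fiber_bundle_spec <- function(centerline, radius,
                              eigenvalues = c(1.7e-3, 0.3e-3, 0.3e-3),
                              volume_fraction = 1) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3L || nrow(centerline) < 2L)
    stop("`centerline` must be an m x 3 matrix with m >= 2", call. = FALSE)
  stopifnot_scalar(radius, "radius", positive = TRUE)
  if (length(eigenvalues) != 3L || any(eigenvalues < 0) ||
      is.unsorted(rev(eigenvalues)))
    stop("`eigenvalues` must be 3 nonnegative values, sorted descending",
         call. = FALSE)
  if (volume_fraction <= 0 || volume_fraction > 1)
    stop("`volume_fraction` must be in (0, 1]", call. = FALSE)
  structure(list(centerline = centerline, radius = radius,
                 eigenvalues = as.numeric(eigenvalues),
                 volume_fraction = volume_fraction),
            class = "fiber_bundle_spec")
}

# unit direction of (the first segment of) a bundle centerline
bundle_direction <- function(bundle) {
  d <- bundle$centerline[nrow(bundle$centerline), ] - bundle$centerline[1L, ]
  d / vnorm(d)
}

# distance from each row of `pts` to the segment chain of `centerline`;
# straight bundles have a 2-point centerline so this is a single segment
.dist_to_polyline <- function(pts, centerline) {
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(centerline) - 1L)) {
    a <- centerline[s, ]; b <- centerline[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L] +
          (pts[, 3L] - a[3L]) * ab[3L]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1L] - (a[1L] + t * ab[1L])
    dy <- pts[, 2L] - (a[2L] + t * ab[2L])
    dz <- pts[, 3L] - (a[3L] + t * ab[3L])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2 + dz^2))
  }
  dmin
}

#' Build a two-bundle crossing-fiber phantom geometry
#'
#' Two straight tubular bundles intersect at the grid center at the
#' requested angle, lying in a plane whose azimuth can be rotated. In the
#' overlap both bundles carry equal volume fractions of 0.5.
#'
#' @param angle_degrees crossing angle, strictly between 0 and 180.
#' @param grid_shape integer vector of 3 positive extents.
#' @param radius tube radius in voxels.
#' @param azimuth_degrees rotation of the crossing plane about the z axis.
#' @param eigenvalues per-bundle tensor eigenvalues (mm^2/s, descending).
#' @param center optional crossing point (default grid center).
#' @return list of two [fiber_bundle_spec()]s.
#' @export
make_crossing_phantom <- function(angle_degrees, grid_shape, radius = 3.5,
                                  azimuth_degrees = 0,
                                  eigenvalues = c(1.7e-3, 0.3e-3, 0.3e-3),
                                  center = NULL) {
  stopifnot_scalar(angle_degrees, "angle_degrees")
  if (angle_degrees <= 0 || angle_degrees >= 180)
    stop("`angle_degrees` must be strictly between 0 and 180", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be 3 positive integers", call. = FALSE)
  if (is.null(center)) center <- (grid_shape - 1) / 2
  half <- angle_degrees * pi / 360    # angle/2 in radians
  az <- azimuth_degrees * pi / 180
  rot <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3L, 3L)
  d1 <- as.numeric(rot %*% c(cos(half), sin(half), 0))
  d2 <- as.numeric(rot %*% c(cos(half), -sin(half), 0))
  span <- sqrt(sum(grid_shape^2))
  mk <- function(d) fiber_bundle_spec(rbind(center - span * d, center + span * d),
                                      radius = radius, eigenvalues = eigenvalues,
                                      volume_fraction = 1)
  list(mk(d1), mk(d2))
}

# single-tensor attenuation exp(-b g' D g) for every scheme entry, where D
# has principal axis `u` and the given eigenvalues
.tensor_attenuation <- function(scheme, u, eigenvalues) {
  R <- rotation_between(c(1, 0, 0), u)
  D <- R %*% diag(eigenvalues) %*% t(R)
  g <- scheme$directions
  quad <- rowSums((g %*% D) * g)
  exp(-scheme$bvalues * quad)
}

#' Simulate a multi-tensor DWI phantom
#'
#' Per voxel the noiseless signal is
#' \deqn{S(g, b) = S_0 [\sum_k f_k e^{-b g^T D_k g} + f_{bg} e^{-b d_{iso}}]}
#' with an isotropic background compartment inside a spherical "tissue"
#' region and zero signal outside it. Rician noise is applied as
#' \eqn{\sqrt{(S + n_1)^2 + n_2^2}} with \eqn{n_1, n_2 \sim N(0, \sigma^2)}.
#'
#' @param bundles list of [fiber_bundle_spec()]s.
#' @param scheme a [gradient_scheme()].
#' @param grid_shape 3 positive integers.
#' @param S0 reference (b0) signal.
#' @param noise_sigma Rician noise level (>= 0), on the scale of `S0`.
#' @param seed RNG seed for the noise draws.
#' @param d_iso isotropic background diffusivity (mm^2/s).
#' @param tissue_radius_frac tissue sphere radius as a fraction of the
#'   smallest grid extent.
#' @return list with elements `dwi` (a [dwi_volume()]) and `truth` (class
#'   `phantom_truth`: bundle masks, per-bundle directions and eigenvalues,
#'   fraction volumes, tissue mask, `S0`, `d_iso`).
#' @export
simulate_signal <- function(bundles, scheme, grid_shape, S0 = 100,
                            noise_sigma = 0, seed = 1L, d_iso = 0.8e-3,
                            tissue_radius_frac = 0.45) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (length(scheme$bvalues) < 1L) stop("empty scheme", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be 3 positive integers", call. = FALSE)
  stopifnot_scalar(S0, "S0", positive = TRUE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  nvox <- prod(grid_shape)
  pts <- voxel_grid(grid_shape)
  center <- (grid_shape - 1) / 2
  rad <- tissue_radius_frac * min(grid_shape)
  tissue <- sqrt(rowSums((pts - matrix(center, nvox, 3L, byrow = TRUE))^2)) <= rad

  nb <- length(bundles)
  frac <- matrix(0, nvox, nb)
  masks <- vector("list", nb)
  dirs <- matrix(0, nb, 3L)
  for (k in seq_len(nb)) {
    b <- bundles[[k]]
    stopifnot(inherits(b, "fiber_bundle_spec"))
    inside <- .dist_to_polyline(pts, b$centerline) <= b$radius & tissue
    masks[[k]] <- array(inside, dim = grid_shape)
    frac[inside, k] <- b$volume_fraction
    dirs[k, ] <- bundle_direction(b)
  }
  tot <- rowSums(frac)
  over <- tot > 1
  if (any(over)) frac[over, ] <- frac[over, , drop = FALSE] / tot[over]
  f_bg <- ifelse(tissue, pmax(1 - pmin(tot, 1), 0), 0)

  n_ch <- length(scheme$bvalues)
  att <- matrix(0, n_ch, nb)
  for (k in seq_len(nb))
    att[, k] <- .tensor_attenuation(scheme, dirs[k, ], bundles[[k]]$eigenvalues)
  att_bg <- exp(-scheme$bvalues * d_iso)
  # signal: nvox x n_ch = frac %*% t(att) + f_bg %*% t(att_bg)
  sig <- S0 * (frac %*% t(att) + outer(f_bg, att_bg))
  if (noise_sigma > 0) {
    sig <- with_seed(seed, {
      n1 <- matrix(rnorm(length(sig), 0, noise_sigma), nrow(sig))
      n2 <- matrix(rnorm(length(sig), 0, noise_sigma), nrow(sig))
      sqrt((sig + n1)^2 + n2^2)
    })
  }
  data <- array(sig, dim = c(grid_shape, n_ch))
  truth <- structure(list(
    bundle_masks = masks,
    directions = dirs,
    eigenvalues = lapply(bundles, `[[`, "eigenvalues"),
    fractions = frac,
    f_bg = array(f_bg, dim = grid_shape),
    tissue_mask = array(tissue, dim = grid_shape),
    S0 = S0, d_iso = d_iso, noise_sigma = noise_sigma
  ), class = "phantom_truth")
  list(dwi = dwi_volume(data, scheme), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d bundles, tissue %d voxels, sigma = %g\n",
              length(x$bundle_masks), sum(x$tissue_mask), x$noise_sigma))
  invisible(x)
}

#' Seed/target(/avoid) ROI set for one phantom bundle
#'
#' The seed is a slab at one end of the bundle (lowest extent along the
#' bundle axis), the target a slab at the opposite end — the phantom
#' analogue of seeding in one anatomical end-region and targeting the
#' other. An optional avoidance plane orthogonal to a coordinate axis can
#' be added.
#'
#' @param truth a `phantom_truth`.
#' @param bundle_index which bundle.
#' @param slab_fraction fraction of the bundle extent used for each slab.
#' @param avoid_axis optional axis (1-3) for a mid-plane avoidance ROI.
#' @param avoid_position plane position (0-based voxel units) along
#'   `avoid_axis`; default mid-grid.
#' @return an object of class `roi_set` with logical arrays `seed_mask`,
#'   `target_mask`, `avoid_mask`.
#' @export
make_roi_set <- function(truth, bundle_index, slab_fraction = 0.15,
                         avoid_axis = NULL, avoid_position = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (bundle_index < 1 || bundle_index > length(truth$bundle_masks))
    stop("no such bundle", call. = FALSE)
  mask <- truth$bundle_masks[[bundle_index]]
  if (!any(mask)) stop("empty bundle mask", call. = FALSE)
  dims <- dim(mask)
  u <- truth$directions[bundle_index, ]
  vox <- index_to_voxel(which(mask), dims)
  proj <- as.numeric(vox %*% u)
  lo <- min(proj); hi <- max(proj)
  slab <- (hi - lo) * slab_fraction
  seed <- target <- array(FALSE, dims)
  seed[which(mask)[proj <= lo + slab]] <- TRUE
  target[which(mask)[proj >= hi - slab]] <- TRUE
  avoid <- array(FALSE, dims)
  if (!is.null(avoid_axis)) {
    if (is.null(avoid_position)) avoid_position <- (dims[avoid_axis] - 1) / 2
    coord <- index_to_voxel(seq_len(prod(dims)), dims)[, avoid_axis]
    avoid[abs(coord - avoid_position) <= 0.5] <- TRUE
  }
  if (any(seed & target))
    stop("seed and target slabs overlap; reduce `slab_fraction`", call. = FALSE)
  structure(list(seed_mask = seed, target_mask = target, avoid_mask = avoid),
            class = "roi_set")
}

#' Generate a reproducible phantom dataset with train/val/test partition
#'
#' Each phantom is a two-bundle crossing with randomized crossing angle,
#' in-plane azimuth, tube radius and center offset; the acquisition scheme,
#' grid and noise level are fixed by `config`. Reproducible per seed.
#'
#' @param n_phantoms number of phantoms (>= 1).
#' @param config list; recognized entries (with defaults):
#'   `scheme` (a 64-direction b=3000 design), `grid_shape` (c(32,32,32)),
#'   `S0` (100), `noise_sigma` (0), `angle_range` (c(50, 90)),
#'   `radius_range` (c(3, 4)), `offset_sd` (1), `partition`
#'   (c(train = .7, val = .15, test = .15)).
#' @param seed integer seed; phantom i uses sub-seed `seed * 1000 + i`.
#' @return list with `cases` (each: `dwi`, `truth`, `rois` per bundle,
#'   `angle`), `partition` (factor), `scheme` and `config`.
#' @export
generate_dataset <- function(n_phantoms, config = list(), seed = 1L) {
  stopifnot_scalar(n_phantoms, "n_phantoms", positive = TRUE, integerish = TRUE)
  defaults <- list(scheme = NULL, grid_shape = c(32L, 32L, 32L), S0 = 100,
                   noise_sigma = 0, angle_range = c(50, 90),
                   radius_range = c(3, 4), offset_sd = 1,
                   partition = c(train = 0.7, val = 0.15, test = 0.15))
  config <- utils::modifyList(defaults, config)
  scheme <- config$scheme
  if (is.null(scheme))
    scheme <- design_scheme(64L, seed = 20L, n_restarts = 20L, n_iterations = 150L)
  params <- with_seed(seed, {
    lapply(seq_len(n_phantoms), function(i) list(
      angle = runif(1, config$angle_range[1L], config$angle_range[2L]),
      azimuth = runif(1, 0, 180),
      radius = runif(1, config$radius_range[1L], config$radius_range[2L]),
      offset = rnorm(3, 0, config$offset_sd)
    ))
  })
  cases <- lapply(seq_len(n_phantoms), function(i) {
    p <- params[[i]]
    center <- (config$grid_shape - 1) / 2 + p$offset
    bundles <- make_crossing_phantom(p$angle, config$grid_shape,
                                     radius = p$radius,
                                     azimuth_degrees = p$azimuth,
                                     center = center)
    sim <- simulate_signal(bundles, scheme, config$grid_shape, S0 = config$S0,
                           noise_sigma = config$noise_sigma,
                           seed = seed * 1000L + i)
    rois <- lapply(seq_along(bundles), function(k) make_roi_set(sim$truth, k))
    list(dwi = sim$dwi, truth = sim$truth, rois = rois, angle = p$angle)
  })
  fr <- config$partition / sum(config$partition)
  n_train <- round(fr[[1L]] * n_phantoms)
  n_val <- round(fr[[2L]] * n_phantoms)
  n_test <- n_phantoms - n_train - n_val
  part <- factor(rep(c("train", "val", "test"), c(n_train, n_val, n_test)),
                 levels = c("train", "val", "test"))
  list(cases = cases, partition = part, scheme = scheme, config = config)
}
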
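#' Maximum SH order supported by a direction count
#'
#' The largest even l with (l+1)(l+2)/2 coefficients not exceeding the
#' number of diffusion directions, capped (default 8). A 32-direction arm
#' therefore uses lmax 6; 64-direction arms use lmax 8.
#'
#' @param n_directions number of diffusion directions.
#' @param cap maximum allowed order.
#' @return even integer order.
#' @export
lmax_for <- function(n_directions, cap = 8L) {
  l <- 0L
  while ((l + 3L) * (l + 4L) / 2L <= n_directions && l + 2L <= cap) l <- l + 2L
  l
}

#' Fit the diffusion tensor per voxel
#'
#' Weighted log-linear least squares: the log-signal is regressed on the
#' b-matrix design with per-voxel weights equal to the squared (noiseless
#' predicted) signal, the standard WLS scheme for DTI. Negative eigenvalues
#' are clamped to zero and counted. Derived maps: FA, E1 (= largest
#' eigenvalue), color FA (FA times |principal eigenvector|).
#'
#' @param dwi a [dwi_volume()].
#' @param scheme optional [gradient_scheme()] (default: the volume's).
#' @param mask logical 3D array; default: all voxels with positive b0.
#' @param weighted use WLS (default) or plain OLS on the log signal.
#' @return object of class `tensor_field`: arrays `lambda1-3`, `fa`, `e1`,
#'   `v1` (x,y,z channels), `color_fa`, `mask`, and counters
#'   `n_clamped`, `n_excluded`.
#' @export
fit_dti <- function(dwi, scheme = NULL, mask = NULL, weighted = TRUE) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (is.null(scheme)) scheme <- dwi$scheme
  dims <- dwi_dims(dwi)
  nd <- n_diffusion_directions(scheme)
  if (nd < 6L) stop("DTI fit needs >= 6 diffusion directions", call. = FALSE)
  if (sum(scheme$bvalues == 0) < 1L) stop("DTI fit needs a b0 volume", call. = FALSE)
  g <- scheme$directions
  b <- scheme$bvalues
  # design: log S = log S0 - b g' D g, D packed as (xx, yy, zz, xy, xz, yz)
  X <- cbind(1,
             -b * g[, 1L]^2, -b * g[, 2L]^2, -b * g[, 3L]^2,
             -2 * b * g[, 1L] * g[, 2L], -2 * b * g[, 1L] * g[, 3L],
             -2 * b * g[, 2L] * g[, 3L])
  sig <- matrix(dwi$data, prod(dims), length(b))   # voxels x channels
  if (is.null(mask)) {
    b0 <- rowMeans(sig[, b == 0, drop = FALSE])
    mask <- array(b0 > 0, dims)
  }
  vox <- which(mask)
  excluded <- rowSums(sig[vox, , drop = FALSE]) == 0
  vox <- vox[!excluded]
  floor_sig <- pmax(sig[vox, , drop = FALSE], 1e-10)
  logs <- log(floor_sig)
  # OLS pass (shared operator); WLS refinement per voxel
  beta <- t(solve(crossprod(X), t(X) %*% t(logs)))
  if (weighted) {
    for (i in seq_len(length(vox))) {
      w <- floor_sig[i, ]^2
      Xw <- X * w
      beta[i, ] <- solve(crossprod(Xw, X), crossprod(Xw, logs[i, ]))
    }
  }
  n <- length(vox)
  l1 <- l2 <- l3 <- fa <- numeric(n)
  v1 <- matrix(0, n, 3L)
  n_clamped <- 0L
  for (i in seq_len(n)) {
    D <- matrix(c(beta[i, 2L], beta[i, 5L], beta[i, 6L],
                  beta[i, 5L], beta[i, 3L], beta[i, 7L],
                  beta[i, 6L], beta[i, 7L], beta[i, 4L]), 3L, 3L)
    e <- eigen(D, symmetric = TRUE)
    ev <- e$values
    if (any(ev < 0)) { n_clamped <- n_clamped + 1L; ev <- pmax(ev, 0) }
    l1[i] <- ev[1L]; l2[i] <- ev[2L]; l3[i] <- ev[3L]
    v1[i, ] <- e$vectors[, 1L]
    den <- ev[1L]^2 + ev[2L]^2 + ev[3L]^2
    fa[i] <- if (den > 0)
      sqrt(0.5 * ((ev[1L] - ev[2L])^2 + (ev[2L] - ev[3L])^2 +
                  (ev[1L] - ev[3L])^2) / den) else 0
  }
  put <- function(vals) { a <- array(0, dims); a[vox] <- vals; a }
  cfa <- array(0, c(dims, 3L))
  for (ch in 1:3) {
    a <- array(0, dims); a[vox] <- fa * abs(v1[, ch]); cfa[, , , ch] <- a
  }
  structure(list(lambda1 = put(l1), lambda2 = put(l2), lambda3 = put(l3),
                 fa = put(fa), e1 = put(l1), v1 = v1, voxels = vox,
                 color_fa = cfa, mask = mask, dims = dims,
                 n_clamped = n_clamped, n_excluded = sum(excluded)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d fitted voxels (%d clamped, %d flagged)\n",
              length(x$voxels), x$n_clamped, x$n_excluded))
  invisible(x)
}

# shared container for SH-expanded spherical functions
new_odf_field <- function(coef, voxels, dims, lmax, method) {
  structure(list(coef = coef, voxels = voxels, dims = dims, lmax = lmax,
                 basis = "real-even", method = method),
            class = "odf_field")
}

#' @export
print.odf_field <- function(x, ...) {
  cat(sprintf("<odf_field> %s, lmax %d, %d voxels\n",
              x$method, x$lmax, length(x$voxels)))
  invisible(x)
}

#' Analytic Q-ball ODF reconstruction
#'
#' Least-squares SH fit of the normalized single-shell signal S/S0 with
#' Laplace-Beltrami regularization, followed by the Funk-Radon transform
#' via the Legendre diagonal: \eqn{c_{lm} = 2\pi P_l(0) s_{lm}}. Raw
#' (unnormalized) ODF amplitudes are kept; sampling clamps negatives.
#'
#' @param dwi a [dwi_volume()].
#' @param scheme optional scheme override.
#' @param mask logical 3D array (default: positive-b0 voxels).
#' @param lmax SH order; default from [lmax_for()] of the direction count.
#' @param reg Laplace-Beltrami weight (standard 0.006).
#' @return an `odf_field` (SH coefficients per masked voxel).
#' @export
qbi_odf <- function(dwi, scheme = NULL, mask = NULL, lmax = NULL, reg = 0.006) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (is.null(scheme)) scheme <- dwi$scheme
  dims <- dwi_dims(dwi)
  gd <- diffusion_directions(scheme)
  nd <- nrow(gd)
  if (is.null(lmax)) lmax <- lmax_for(nd)
  ncoef <- (lmax + 1) * (lmax + 2) / 2
  if (ncoef > nd)
    stop(sprintf("lmax %d needs %d coefficients but only %d directions given",
                 lmax, ncoef, nd), call. = FALSE)
  bvals <- unique(scheme$bvalues[scheme$bvalues > 0])
  if (length(bvals) > 1L)
    stop("analytic Q-ball requires a single-shell scheme", call. = FALSE)
  sig <- matrix(dwi$data, prod(dims), length(scheme$bvalues))
  b0 <- rowMeans(sig[, scheme$bvalues == 0, drop = FALSE])
  if (is.null(mask)) mask <- array(b0 > 0, dims)
  vox <- which(mask & array(b0 > 0, dims))
  E <- sig[vox, scheme$bvalues > 0, drop = FALSE] / b0[vox]
  fit <- .sh_fit_operator(gd, lmax, reg)
  s_lm <- fit %*% t(E)                     # ncoef x nvox
  ll <- sh_index_table(lmax)$l
  # P_l(0) = (-1)^(l/2) (l-1)!! / l!!
  pl0 <- vapply(ll, function(l) {
    if (l == 0) return(1)
    (-1)^(l / 2) * prod(seq(1, l - 1, by = 2)) / prod(seq(2, l, by = 2))
  }, numeric(1L))
  coef <- (2 * pi * pl0) * s_lm
  new_odf_field(coef, vox, dims, lmax, "qbi")
}

#' Generalized q-sampling spin distribution function
#'
#' The SDF is the kernel sum \eqn{\psi(u) = \sum_i S_i\,
#' \mathrm{sinc}(\sigma \sqrt{6 D_0 b_i}\; g_i \cdot u)} over all acquired
#' volumes (b0 included) with the free-water diffusivity constant
#' \eqn{6 D_0 = 0.01506} and sampling-length ratio \eqn{\sigma}; it is
#' evaluated on the 181-point hemisphere and projected to the SH basis for
#' downstream metrics and peak finding.
#'
#' @param dwi a [dwi_volume()].
#' @param scheme optional scheme override.
#' @param mask logical 3D array (default: positive-b0 voxels).
#' @param sampling_ratio sampling-length ratio (default 1.25).
#' @param lmax SH order for the projection (default [lmax_for()]).
#' @return an `odf_field`.
#' @export
gqi_sdf <- function(dwi, scheme = NULL, mask = NULL, sampling_ratio = 1.25,
                    lmax = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (sampling_ratio <= 0) stop("`sampling_ratio` must be > 0", call. = FALSE)
  if (is.null(scheme)) scheme <- dwi$scheme
  dims <- dwi_dims(dwi)
  nd <- n_diffusion_directions(scheme)
  if (is.null(lmax)) lmax <- lmax_for(nd)
  sphere <- hemisphere181()
  # kernel argument sigma * sqrt(6 D0 b) * (g . u); sinc(x) = sin(x)/x
  lvals <- sqrt(0.01506 * scheme$bvalues)
  A <- sphere %*% t(scheme$directions)     # 181 x nchan of g.u
  A <- sweep(A, 2L, sampling_ratio * lvals, `*`)
  K <- ifelse(abs(A) < 1e-12, 1, sin(A) / ifelse(A == 0, 1, A))
  sig <- matrix(dwi$data, prod(dims), length(scheme$bvalues))
  b0 <- rowMeans(sig[, scheme$bvalues == 0, drop = FALSE])
  if (is.null(mask)) mask <- array(b0 > 0, dims)
  vox <- which(mask)
  psi <- K %*% t(sig[vox, , drop = FALSE]) # 181 x nvox
  fit <- .sh_fit_operator(sphere, lmax, 0)
  coef <- fit %*% psi
  new_odf_field(coef, vox, dims, lmax, "gqi")
}

#' Sample an SH field on the 181-point hemisphere
#'
#' Evaluates each voxel's spherical function at the 181 directions, clamps
#' negatives to zero and normalizes to a probability vector (sum 1) for
#' divergence computations. All-zero functions become uniform and are
#' counted in the `n_flagged` attribute.
#'
#' @param field an `odf_field`.
#' @param sphere direction matrix (default [hemisphere181()]).
#' @return matrix nvox x 181 of probabilities; attributes `voxels`,
#'   `n_flagged`.
#' @export
sample_odf <- function(field, sphere = hemisphere181()) {
  stopifnot(inherits(field, "odf_field"))
  B <- sh_basis(sphere, field$lmax)
  P <- t(B %*% field$coef)                 # nvox x 181
  P[P < 0] <- 0
  s <- rowSums(P)
  flagged <- s <= 0
  if (any(flagged)) P[flagged, ] <- 1
  s[flagged] <- ncol(P)
  P <- P / s
  attr(P, "voxels") <- field$voxels
  attr(P, "n_flagged") <- sum(flagged)
  P
}

# vectorized local refinement of peak directions on the continuous SH
# function: shrinking-cap hill climb, 8 tangent candidates per round
.refine_peaks <- function(coef, u, lmax, rounds = 5L, start_deg = 6) {
  npk <- nrow(u)
  ang <- c(0, pi / 4, pi / 2, 3 * pi / 4, pi, 5 * pi / 4, 3 * pi / 2, 7 * pi / 4)
  for (r in seq_len(rounds)) {
    delta <- (start_deg / 2^(r - 1)) * pi / 180
    ref <- matrix(c(1, 0, 0), npk, 3L, byrow = TRUE)
    swap <- abs(u[, 1L]) > 0.9
    if (any(swap))
      ref[swap, ] <- matrix(c(0, 1, 0), sum(swap), 3L, byrow = TRUE)
    e1 <- ref - u * rowSums(ref * u)
    e1 <- normalize_rows(e1)
    e2 <- cbind(u[, 2L] * e1[, 3L] - u[, 3L] * e1[, 2L],
                u[, 3L] * e1[, 1L] - u[, 1L] * e1[, 3L],
                u[, 1L] * e1[, 2L] - u[, 2L] * e1[, 1L])
    cand <- vector("list", length(ang) + 1L)
    cand[[1L]] <- u
    for (a in seq_along(ang))
      cand[[a + 1L]] <- normalize_rows(
        u + tan(delta) * (cos(ang[a]) * e1 + sin(ang[a]) * e2))
    vals <- vapply(cand, function(cc)
      rowSums(sh_basis(cc, lmax) * t(coef)), numeric(npk))
    best <- max.col(vals, ties.method = "first")
    u <- do.call(rbind, lapply(seq_len(npk),
                               function(i) cand[[best[i]]][i, ]))
  }
  u
}

#' Locate per-voxel fiber peaks of an SH field
#'
#' Local maxima on the sampled 181-point hemisphere (a point is a maximum
#' when it dominates every sample within `neighbor_angle`), thresholded
#' relative to the per-voxel global maximum, greedily deduplicated so that
#' retained peaks are at least `min_separation_angle` apart (after
#' antipodal folding), sorted by amplitude and optionally refined on the
#' continuous function by a shrinking-cap search.
#'
#' @param field an `odf_field`.
#' @param sphere direction matrix (default [hemisphere181()]).
#' @param min_separation_angle minimum angle (deg) between retained peaks.
#' @param relative_threshold keep peaks >= this fraction of the voxel max.
#' @param max_peaks maximum peaks kept per voxel.
#' @param neighbor_angle angular radius (deg) defining the local
#'   neighborhood on the sampled sphere.
#' @param refine refine peak directions beyond the grid resolution?
#' @return object of class `peak_field`: `dirs` array (nvox_total x
#'   max_peaks x 3), `npeaks` (integer vector over the full grid), `dims`.
#' @export
find_peaks <- function(field, sphere = hemisphere181(),
                       min_separation_angle = 25, relative_threshold = 0.3,
                       max_peaks = 3L, neighbor_angle = 16, refine = TRUE) {
  stopifnot(inherits(field, "odf_field"))
  B <- sh_basis(sphere, field$lmax)
  vals <- t(B %*% field$coef)              # nvox x 181
  cosang <- abs(tcrossprod(sphere))
  cosang <- pmin(cosang, 1)
  neigh <- cosang >= cos(neighbor_angle * pi / 180)
  diag(neigh) <- FALSE
  nvox <- nrow(vals)
  n_total <- prod(field$dims)
  dirs <- array(0, c(n_total, max_peaks, 3L))
  npeaks <- integer(n_total)
  sep_cos <- cos(min_separation_angle * pi / 180)
  # neighbor max per sample: vals %*% indicator, using max via loop over 181
  nb_idx <- lapply(seq_len(ncol(vals)), function(i) which(neigh[i, ]))
  nbmax <- vapply(seq_len(ncol(vals)), function(i)
    do.call(pmax, as.data.frame(vals[, nb_idx[[i]], drop = FALSE])),
    numeric(nvox))
  if (is.null(dim(nbmax))) nbmax <- matrix(nbmax, nrow = nvox)
  ispeak <- vals > nbmax
  gmax <- do.call(pmax, as.data.frame(vals))
  refine_list_u <- list(); refine_list_c <- list(); refine_map <- list()
  for (i in seq_len(nvox)) {
    cand <- which(ispeak[i, ] & vals[i, ] >= relative_threshold * gmax[i] &
                  vals[i, ] > 0)
    if (length(cand) == 0L) next
    cand <- cand[order(vals[i, cand], decreasing = TRUE)]
    kept <- integer(0L)
    for (ci in cand) {
      if (length(kept) == max_peaks) break
      if (all(cosang[ci, kept] < sep_cos)) kept <- c(kept, ci)
    }
    v <- field$voxels[i]
    npeaks[v] <- length(kept)
    dirs[v, seq_along(kept), ] <- sphere[kept, , drop = FALSE]
    if (refine) {
      refine_list_u[[length(refine_list_u) + 1L]] <-
        sphere[kept, , drop = FALSE]
      refine_list_c[[length(refine_list_c) + 1L]] <-
        matrix(field$coef[, i], length(kept), nrow(field$coef), byrow = TRUE)
      refine_map[[length(refine_map) + 1L]] <-
        cbind(v, seq_along(kept))
    }
  }
  if (refine && length(refine_list_u) > 0L) {
    u <- do.call(rbind, refine_list_u)
    cf <- t(do.call(rbind, refine_list_c))
    mp <- do.call(rbind, refine_map)
    u <- .refine_peaks(cf, u, field$lmax)
    for (j in seq_len(nrow(mp))) dirs[mp[j, 1L], mp[j, 2L], ] <- u[j, ]
  }
  structure(list(dirs = dirs, npeaks = npeaks, dims = field$dims,
                 max_peaks = max_peaks),
            class = "peak_field")
}

#' Per-ROI mean and standard deviation of a scalar map
#'
#' @param map numeric 3D array (e.g. FA or E1).
#' @param roi_masks named list of logical arrays.
#' @return data.frame with columns `roi`, `mean`, `sd` (sample SD,
#'   denominator n-1), `n`; empty ROIs are excluded and flagged in the
#'   `excluded` attribute.
#' @export
roi_statistics <- function(map, roi_masks) {
  if (is.null(names(roi_masks)))
    names(roi_masks) <- paste0("roi", seq_along(roi_masks))
  rows <- list(); excluded <- character(0L)
  for (nm in names(roi_masks)) {
    m <- roi_masks[[nm]]
    if (!any(m)) { excluded <- c(excluded, nm); next }
    v <- map[m]
    rows[[nm]] <- data.frame(roi = nm, mean = mean(v),
                             sd = if (length(v) > 1L) sd(v) else 0,
                             n = length(v))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
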
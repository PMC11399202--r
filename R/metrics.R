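#' Kullback-Leibler divergence between probability vectors
#'
#' \eqn{D_{KL}(P, Q) = \sum_i P(i) \log(P(i)/Q(i))} in nats, with
#' \eqn{0 \log(0/q) = 0}; zeros in Q facing positive P are floored at
#' 1e-12 (clamped ODF samples can be exactly zero).
#'
#' @param P,Q nonnegative vectors of equal length summing to 1.
#' @param eps flooring constant for zero denominators.
#' @return scalar divergence (nats).
#' @export
kl_divergence <- function(P, Q, eps = 1e-12) {
  if (length(P) != length(Q))
    stop("`P` and `Q` must have equal length", call. = FALSE)
  if (abs(sum(P) - 1) > 1e-6 || abs(sum(Q) - 1) > 1e-6)
    stop("`P` and `Q` must each sum to 1", call. = FALSE)
  pos <- P > 0
  sum(P[pos] * log(P[pos] / pmax(Q[pos], eps)))
}

#' Jensen-Shannon divergence
#'
#' \eqn{JSD(P, Q) = [D_{KL}(P, M) + D_{KL}(Q, M)]/2} with
#' \eqn{M = (P + Q)/2}; symmetric, bounded by \eqn{\ln 2}, zero iff P = Q.
#'
#' @inheritParams kl_divergence
#' @return scalar divergence (nats).
#' @export
jsd <- function(P, Q) {
  M <- (P + Q) / 2
  (kl_divergence(P, M) + kl_divergence(Q, M)) / 2
}

# row-wise JSD for matrices of probability rows (voxelwise pipelines)
.jsd_rows <- function(P, Q) {
  M <- (P + Q) / 2
  t1 <- ifelse(P > 0, P * log(P / pmax(M, 1e-300)), 0)
  t2 <- ifelse(Q > 0, Q * log(Q / pmax(M, 1e-300)), 0)
  (rowSums(t1) + rowSums(t2)) / 2
}

#' Angular correlation coefficient of two SH expansions
#'
#' Normalized inner product of the coefficient vectors excluding the
#' isotropic l = 0 term:
#' \deqn{ACC = \frac{\sum_{l \ge 1, m} u_{lm} v_{lm}}
#'   {\|u\|_{l \ge 1} \, \|v\|_{l \ge 1}}.}
#' With the real orthonormal basis the complex-conjugate products reduce
#' to real products. When either function has no anisotropic energy the
#' ACC is undefined and `NA` is returned with attribute `undefined`.
#'
#' @param u,v coefficient vectors over the same basis and order.
#' @param l vector of SH orders per coefficient (default: inferred from
#'   the common length via [sh_index_table()]).
#' @return scalar in \[-1, 1\], or flagged `NA`.
#' @export
acc <- function(u, v, l = NULL) {
  if (length(u) != length(v))
    stop("`u` and `v` must have equal length", call. = FALSE)
  if (is.null(l)) {
    lmax <- (sqrt(8 * length(u) + 1) - 3) / 2
    if (abs(lmax - round(lmax)) > 1e-9)
      stop("cannot infer lmax from coefficient count; supply `l`",
           call. = FALSE)
    l <- sh_index_table(as.integer(round(lmax)))$l
  }
  keep <- l >= 1
  u1 <- u[keep]; v1 <- v[keep]
  nu <- sqrt(sum(u1^2)); nv <- sqrt(sum(v1^2))
  if (nu == 0 || nv == 0)
    return(structure(NA_real_, undefined = TRUE))
  sum(u1 * v1) / (nu * nv)
}

# voxelwise ACC for coefficient matrices (ncoef x nvox); NA where undefined
.acc_cols <- function(U, V, l) {
  keep <- l >= 1
  U1 <- U[keep, , drop = FALSE]; V1 <- V[keep, , drop = FALSE]
  nu <- sqrt(colSums(U1^2)); nv <- sqrt(colSums(V1^2))
  out <- colSums(U1 * V1) / (nu * nv)
  out[nu == 0 | nv == 0] <- NA_real_
  out
}

# normalized 3D Gaussian window, applied separably with replicate padding
.gauss_kernel <- function(win, sigma) {
  half <- (win - 1) / 2
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

.blur3 <- function(x, dims, kernel) {
  v <- as.numeric(x)
  for (ax in 0:2) v <- .sepconv_axis(v, as.integer(dims), kernel, ax)
  array(v, dim = dims)
}

#' Volumetric structural similarity (SSIM)
#'
#' Standard SSIM with a 3D Gaussian window (11^3 support, sigma 1.5,
#' applied separably with replicate padding), constants k1 = 0.01,
#' k2 = 0.03 and dynamic range max(ref over mask). The SSIM map is
#' averaged over the mask restricted to the interior (window half-width
#' cropped at each face), so border voxels with partially synthetic
#' windows do not contribute.
#'
#' @param pred,ref numeric 3D arrays of equal shape.
#' @param mask logical array (default: everywhere).
#' @param win window extent (odd).
#' @param sigma Gaussian window sigma.
#' @param k1,k2 stabilization constants.
#' @return scalar SSIM in \[-1, 1\].
#' @export
ssim_volume <- function(pred, ref, mask = NULL, win = 11L, sigma = 1.5,
                        k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(pred), dim(ref)))
    stop("`pred` and `ref` shapes differ", call. = FALSE)
  dims <- dim(pred)
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  L <- max(ref[mask])
  if (L <= 0) stop("reference has no positive dynamic range in mask",
                   call. = FALSE)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  ker <- .gauss_kernel(win, sigma)
  mu1 <- .blur3(pred, dims, ker)
  mu2 <- .blur3(ref, dims, ker)
  s11 <- .blur3(pred * pred, dims, ker) - mu1^2
  s22 <- .blur3(ref * ref, dims, ker) - mu2^2
  s12 <- .blur3(pred * ref, dims, ker) - mu1 * mu2
  ssim_map <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  half <- (win - 1) / 2
  interior <- array(FALSE, dims)
  interior[(half + 1):(dims[1L] - half), (half + 1):(dims[2L] - half),
           (half + 1):(dims[3L] - half)] <- TRUE
  sel <- mask & interior
  if (!any(sel)) sel <- mask
  mean(ssim_map[sel])
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(MAX^2 / MSE)} with MAX the reference maximum over the
#' mask and MSE over masked voxels; identical volumes return `Inf`.
#'
#' @inheritParams ssim_volume
#' @return scalar PSNR in dB (possibly `Inf`).
#' @export
psnr_volume <- function(pred, ref, mask = NULL) {
  if (!identical(dim(pred), dim(ref)))
    stop("`pred` and `ref` shapes differ", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(ref))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  mse <- mean((pred[mask] - ref[mask])^2)
  if (mse == 0) return(Inf)
  10 * log10(max(ref[mask])^2 / mse)
}

#' Dice similarity coefficient of two voxel sets
#'
#' \eqn{DSC = 2 V(x \cap y) / (V(x) + V(y))}. Two empty masks give a
#' flagged `NA` (undefined).
#'
#' @param x,y logical arrays on the same grid.
#' @return scalar in \[0, 1\] or flagged `NA`.
#' @export
dice <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("masks are on different grids", call. = FALSE)
  vx <- sum(x != 0); vy <- sum(y != 0)
  if (vx + vy == 0) return(structure(NA_real_, undefined = TRUE))
  2 * sum(x != 0 & y != 0) / (vx + vy)
}

#' Paired statistical comparison of metric values
#'
#' `"wilcoxon"`: Wilcoxon signed-rank test on paired values (zero
#' differences dropped; exact enumeration for n <= 12 without ties, normal
#' approximation otherwise) with effect size r = |Z|/sqrt(N) over the N
#' retained pairs. `"friedman_bonferroni"`: Friedman test across the three
#' arms followed by pairwise Wilcoxon tests judged against the
#' Bonferroni-adjusted threshold p < 0.0167.
#'
#' @param values_a,values_b paired metric vectors (equal length >= 5 for
#'   the asymptotic mode). Pairs with `NA` in any arm are excluded
#'   pairwise (non-visualized bundles) and counted in `n_excluded`.
#' @param values_c third arm, required for `"friedman_bonferroni"`.
#' @param method comparison method.
#' @return list with `statistic`, `p`, `effect_size`, `method`,
#'   `degenerate` flag, `n_excluded`, and for the Friedman route
#'   `pairwise` (data.frame) and `bonferroni_threshold`.
#' @export
paired_compare <- function(values_a, values_b, values_c = NULL,
                           method = c("wilcoxon", "friedman_bonferroni")) {
  method <- match.arg(method)
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  # pairwise exclusion of incomplete pairs (e.g. non-visualized bundles)
  ok <- !is.na(values_a) & !is.na(values_b)
  if (!is.null(values_c)) ok <- ok & !is.na(values_c)
  n_excluded <- sum(!ok)
  values_a <- values_a[ok]; values_b <- values_b[ok]
  if (!is.null(values_c)) values_c <- values_c[ok]
  if (length(values_a) == 0L)
    return(list(statistic = NA_real_, p = NA_real_,
                effect_size = NA_real_, method = method, degenerate = TRUE,
                n_excluded = n_excluded))
  if (method == "wilcoxon") {
    d <- values_b - values_a
    keep <- d != 0
    n <- sum(keep)
    if (n == 0L)
      return(list(statistic = 0, p = 1, effect_size = 0, method = method,
                  degenerate = TRUE, n_excluded = n_excluded))
    dk <- d[keep]
    r <- rank(abs(dk))
    V <- sum(r[dk > 0])
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                sum(tie_tab^3 - tie_tab) / 48)
    z <- if (sig > 0) (V - mu) / sig else 0
    if (n <= 12L) {
      # exact two-sided p by enumeration of all 2^n sign assignments,
      # valid with tied |differences| (permutation null on the signed ranks)
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      vall <- as.numeric(signs %*% r)
      p <- mean(abs(vall - mu) >= abs(V - mu) - 1e-12)
    } else {
      p <- 2 * (1 - stats::pnorm(abs(z)))
    }
    list(statistic = V, p = min(p, 1), effect_size = abs(z) / sqrt(n),
         method = method, degenerate = FALSE, n_excluded = n_excluded)
  } else {
    if (is.null(values_c))
      stop("`values_c` is required for the Friedman route", call. = FALSE)
    m <- cbind(a = values_a, b = values_b, c = values_c)
    ft <- friedman.test(m)
    pairs <- list(c("a", "b"), c("a", "c"), c("b", "c"))
    pw <- do.call(rbind, lapply(pairs, function(pr) {
      res <- paired_compare(m[, pr[1L]], m[, pr[2L]], method = "wilcoxon")
      data.frame(pair = paste(pr, collapse = "-"), statistic = res$statistic,
                 p = res$p, effect_size = res$effect_size,
                 significant = is.finite(res$p) && res$p < 1 / 60)
    }))
    list(statistic = unname(ft$statistic), p = ft$p.value,
         effect_size = unname(ft$statistic) /
           (length(values_a) * (ncol(m) - 1)),
         method = method, degenerate = FALSE, pairwise = pw,
         bonferroni_threshold = 1 / 60, n_excluded = n_excluded)
  }
}
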
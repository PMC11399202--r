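#' 4D diffusion-weighted volume container
#'
#' A `dwi_volume` couples a 4D intensity array (x, y, z, channel) with the
#' [gradient_scheme()] describing its channels and an affine mapping voxel
#' centers to mm. Voxel coordinates are 0-based with half-open voxel
#' extents; the affine maps voxel centers — this convention is used by every
#' module in the package.
#'
#' @param data numeric 4D array; 4th dimension indexes MPG channels.
#' @param scheme a [gradient_scheme()] with one entry per channel.
#' @param affine 4x4 voxel-to-mm affine (default: 2.5 mm isotropic).
#' @param normalization optional record from [apply_normalization()].
#' @return an object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, scheme, affine = diag(c(2.5, 2.5, 2.5, 1)),
                       normalization = NULL) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array", call. = FALSE)
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (dim(data)[4L] != length(scheme$bvalues))
    stop(sprintf("channel count (%d) does not match scheme length (%d)",
                 dim(data)[4L], length(scheme$bvalues)), call. = FALSE)
  if (any(data < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible", call. = FALSE)
  structure(list(data = data, scheme = scheme, affine = affine,
                 normalization = normalization),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_volume> %dx%dx%d voxels, %d channels (%d b0)\n",
              d[1L], d[2L], d[3L], d[4L], sum(x$scheme$bvalues == 0)))
  invisible(x)
}

#' Spatial dimensions of a dwi_volume
#' @param dwi a [dwi_volume()].
#' @return integer vector length 3.
#' @export
dwi_dims <- function(dwi) dim(dwi$data)[1:3]

#' Mean b0 channel of a dwi_volume
#' @param dwi a [dwi_volume()].
#' @return 3D array (mean over b0 channels).
#' @export
dwi_b0 <- function(dwi) {
  idx <- which(dwi$scheme$bvalues == 0)
  if (length(idx) == 0L) stop("volume has no b0 channel", call. = FALSE)
  if (length(idx) == 1L) return(dwi$data[, , , idx])
  apply(dwi$data[, , , idx, drop = FALSE], 1:3, mean)
}

#' Read a 4D NIfTI DWI volume with its gradient table
#'
#' @param path_nifti NIfTI-1 file (.nii or .nii.gz).
#' @param path_bvec,path_bval FSL gradient table paths.
#' @return a [dwi_volume()].
#' @export
read_dwi <- function(path_nifti, path_bvec, path_bval) {
  img <- RNifti::readNifti(path_nifti)
  scheme <- read_bvec_bval(path_bvec, path_bval)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (dim(arr)[4L] != length(scheme$bvalues))
    stop(sprintf("format error: %d channels in %s but %d scheme entries",
                 dim(arr)[4L], path_nifti, length(scheme$bvalues)), call. = FALSE)
  arr[arr < 0] <- 0
  affine <- structure(RNifti::xform(img), class = "matrix")
  norm <- NULL
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path_nifti)
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$normalization)) norm <- side$normalization
  }
  dwi_volume(arr, scheme, affine = unclass(affine), normalization = norm)
}

#' Write a dwi_volume as NIfTI + bvec/bval (+ JSON sidecar)
#'
#' @param dwi a [dwi_volume()].
#' @param path_nifti output NIfTI path (.nii or .nii.gz).
#' @param path_bvec,path_bval gradient table output paths (default: derived
#'   from `path_nifti`).
#' @return invisibly, the NIfTI path.
#' @export
write_dwi <- function(dwi, path_nifti,
                      path_bvec = sub("\\.nii(\\.gz)?$", ".bvec", path_nifti),
                      path_bval = sub("\\.nii(\\.gz)?$", ".bval", path_nifti)) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- RNifti::asNifti(dwi$data)
  img <- RNifti::`sform<-`(img, structure(dwi$affine, code = 2L))
  RNifti::writeNifti(img, path_nifti)
  write_bvec_bval(dwi$scheme, path_bvec, path_bval)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path_nifti)
  jsonlite::write_json(list(normalization = dwi$normalization),
                       sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path_nifti)
}

#' Write a binary mask as uint8 NIfTI
#' @param mask logical/numeric 3D array.
#' @param path output path.
#' @param affine 4x4 affine.
#' @return invisibly, `path`.
#' @export
write_mask <- function(mask, path, affine = diag(c(2.5, 2.5, 2.5, 1))) {
  img <- RNifti::asNifti(array(as.integer(mask != 0), dim = dim(mask)),
                         datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Otsu threshold of a nonnegative volume (256-bin histogram)
.otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (r[1L] == r[2L]) return(r[1L])
  br <- seq(r[1L], r[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# one step of 6-neighborhood binary dilation / erosion via array shifts
.shift6 <- function(m, op = max) {
  d <- dim(m)
  out <- m
  pad <- function(a) a
  sh <- function(ax, by) {
    idx <- list(seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L]))
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    m[src[[1L]], src[[2L]], src[[3L]]]
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- op(out, sh(ax, by))
  out
}

.dilate6 <- function(m) .shift6(m, pmax)
.erode6 <- function(m) .shift6(m, pmin)

#' Derive the b0 analysis mask
#'
#' Default: Otsu threshold on the b0 image, keep the largest 6-connected
#' component, then one-voxel morphological closing. `"fraction"` mode
#' thresholds at `fraction * max(b0)` instead (no component/closing steps),
#' which is appropriate for clean phantoms.
#'
#' @param b0 nonnegative 3D array.
#' @param method `"otsu"` (default) or `"fraction"`.
#' @param fraction threshold fraction of max(b0) for `"fraction"` mode.
#' @return logical 3D array with attribute `provenance` (method, threshold).
#' @export
compute_b0_mask <- function(b0, method = c("otsu", "fraction"), fraction = 0.25) {
  method <- match.arg(method)
  if (any(b0 < 0)) stop("`b0` must be nonnegative", call. = FALSE)
  if (all(b0 == 0)) stop("all-zero b0: cannot derive a mask", call. = FALSE)
  d <- dim(b0)
  if (method == "fraction") {
    thr <- fraction * max(b0)
    mask <- b0 > thr
  } else {
    thr <- .otsu_threshold(as.numeric(b0))
    mask <- b0 > thr
    lab <- .label_components6(as.logical(mask), as.integer(d))
    nl <- attr(lab, "n_labels")
    if (nl > 1L) {
      sizes <- tabulate(lab[lab > 0L], nl)
      mask <- array(lab == which.max(sizes), dim = d)
    }
    mask <- array(as.logical(mask), dim = d)
    mask <- .erode6(.dilate6(mask * 1)) > 0   # closing, 1 voxel
  }
  if (!any(mask)) stop("empty mask after thresholding", call. = FALSE)
  structure(array(as.logical(mask), dim = d),
            provenance = list(method = method, threshold = thr))
}

#' Normalize DWI intensities for training
#'
#' Divides all channels by a robust b0 maximum (99th percentile of the b0
#' channel) and records the scale so [invert_normalization()] restores the
#' original intensities before metric computation.
#'
#' @param dwi a [dwi_volume()].
#' @param probs quantile of the b0 intensities used as the scale.
#' @return a normalized [dwi_volume()] carrying a `normalization` record.
#' @export
apply_normalization <- function(dwi, probs = 0.99) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (!is.null(dwi$normalization))
    stop("volume is already normalized", call. = FALSE)
  b0 <- dwi_b0(dwi)
  scale <- as.numeric(quantile(b0[b0 > 0], probs = probs, names = FALSE))
  if (!is.finite(scale) || scale <= 0) scale <- max(b0)
  out <- dwi
  out$data <- dwi$data / scale
  out$normalization <- list(method = "b0_robust_max", scale = scale,
                            probs = probs)
  out
}

#' Undo [apply_normalization()]
#' @param dwi a normalized [dwi_volume()].
#' @return the volume on its original intensity scale.
#' @export
invert_normalization <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (is.null(dwi$normalization))
    stop("no normalization record present", call. = FALSE)
  out <- dwi
  out$data <- dwi$data * dwi$normalization$scale
  out$normalization <- NULL
  out
}
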
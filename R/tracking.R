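# Deterministic streamline tractography over per-voxel peak directions,
# ROI filtering and bundle voxelization. All geometry is in 0-based voxel
# coordinates (voxel centers at integers); affines apply only at export.

#' Tracking parameter set
#'
#' Explicit deterministic defaults: Euler steps of 0.5 voxel, turning
#' angle limit 45 degrees, minimum streamline length 4 voxels, one seed at
#' each seed-voxel center, nearest-voxel peak lookup.
#'
#' @param step_size Euler step (voxels, > 0).
#' @param max_angle maximum turning angle per step (degrees).
#' @param min_length minimum streamline length (voxels).
#' @param max_steps hard cap on steps per direction.
#' @return list of class `track_params`.
#' @export
track_params <- function(step_size = 0.5, max_angle = 45, min_length = 4,
                         max_steps = 1000L) {
  if (step_size <= 0) stop("`step_size` must be > 0", call. = FALSE)
  structure(list(step_size = step_size, max_angle = max_angle,
                 min_length = min_length, max_steps = as.integer(max_steps)),
            class = "track_params")
}

# peaks at the nearest voxel of `pos`, or NULL outside the grid / mask
.peaks_at <- function(peaks, pos, stop_mask) {
  v <- round(pos)
  d <- peaks$dims
  if (any(v < 0) || any(v >= d)) return(NULL)
  li <- 1L + v[1L] + d[1L] * (v[2L] + d[2L] * v[3L])
  if (!stop_mask[li]) return(NULL)
  np <- peaks$npeaks[li]
  if (np == 0L) return(NULL)
  matrix(peaks$dirs[li, seq_len(np), ], np, 3L)
}

# walk from `pos0` along `dir0`; returns list(points, reason)
.walk <- function(peaks, pos0, dir0, stop_mask, params) {
  pts <- matrix(0, params$max_steps + 1L, 3L)
  pts[1L, ] <- pos0
  pos <- pos0
  dir <- dir0
  cos_lim <- cos(params$max_angle * pi / 180)
  n <- 1L
  reason <- "max_steps"
  for (s in seq_len(params$max_steps)) {
    pos_new <- pos + params$step_size * dir
    pk <- .peaks_at(peaks, pos_new, stop_mask)
    if (is.null(pk)) { reason <- "left_mask_or_no_peak"; break }
    al <- pk %*% dir
    best <- which.max(abs(al))
    new_dir <- pk[best, ] * sign(al[best])
    if (sum(new_dir * dir) < cos_lim) { reason <- "angle"; break }
    pos <- pos_new
    dir <- new_dir
    n <- n + 1L
    pts[n, ] <- pos
  }
  list(points = pts[seq_len(n), , drop = FALSE], reason = reason)
}

#' Deterministic streamline tracking
#'
#' Euler integration from the center of every seed voxel, in both
#' directions along the locally best-aligned peak (after antipodal
#' folding). A step terminates on leaving the stop mask, finding no peak,
#' or turning by more than `max_angle`. Streamlines shorter than
#' `min_length` are discarded.
#'
#' @param peaks a `peak_field` from [find_peaks()].
#' @param seed_mask logical array of seed voxels (nonempty).
#' @param stop_mask logical array; tracking stops outside it (default:
#'   voxels with at least one peak).
#' @param params a [track_params()].
#' @return object of class `streamline_set`: `lines` (list of point
#'   matrices), `seeds` (seed voxel index per line), `reasons` (two
#'   termination reasons per line), `dims`.
#' @export
track <- function(peaks, seed_mask, stop_mask = NULL,
                  params = track_params()) {
  stopifnot(inherits(peaks, "peak_field"))
  if (!any(seed_mask)) stop("empty seed mask", call. = FALSE)
  if (!identical(dim(seed_mask), as.integer(peaks$dims)) &&
      !identical(dim(seed_mask), peaks$dims))
    stop("seed mask grid does not match the peak field", call. = FALSE)
  if (is.null(stop_mask)) stop_mask <- array(peaks$npeaks > 0, peaks$dims)
  seeds <- which(seed_mask)
  lines <- list(); seed_ids <- integer(0L); reasons <- list()
  for (sv in seeds) {
    if (peaks$npeaks[sv] == 0L) next
    v <- index_to_voxel(sv, peaks$dims)[1L, ]
    dir0 <- peaks$dirs[sv, 1L, ]
    fwd <- .walk(peaks, as.numeric(v), dir0, stop_mask, params)
    bwd <- .walk(peaks, as.numeric(v), -dir0, stop_mask, params)
    pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
                 fwd$points[-1L, , drop = FALSE])
    if (nrow(pts) < 2L) next
    len <- (nrow(pts) - 1L) * params$step_size
    if (len < params$min_length) next
    lines[[length(lines) + 1L]] <- pts
    seed_ids <- c(seed_ids, sv)
    reasons[[length(reasons) + 1L]] <- c(backward = bwd$reason,
                                         forward = fwd$reason)
  }
  structure(list(lines = lines, seeds = seed_ids, reasons = reasons,
                 dims = peaks$dims, params = params),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines on a %s grid\n",
              length(x$lines), paste(x$dims, collapse = "x")))
  invisible(x)
}

# voxels (rounded) visited by a polyline
.line_voxels <- function(pts, dims) {
  v <- round(pts)
  keep <- v[, 1L] >= 0 & v[, 1L] < dims[1L] &
          v[, 2L] >= 0 & v[, 2L] < dims[2L] &
          v[, 3L] >= 0 & v[, 3L] < dims[3L]
  unique(voxel_to_index(v[keep, , drop = FALSE], dims))
}

#' Filter streamlines by target/avoidance ROIs
#'
#' Keeps streamlines that intersect the target mask and removes any that
#' touch the avoidance mask. Counts per rule are attached; an empty result
#' is allowed and flagged as a non-visualized bundle.
#'
#' @param streamlines a `streamline_set`.
#' @param rois an `roi_set` (see [make_roi_set()]).
#' @return filtered `streamline_set` with attributes `n_kept`,
#'   `n_removed_no_target`, `n_removed_avoid`, `not_visualized`.
#' @export
filter_by_rois <- function(streamlines, rois) {
  stopifnot(inherits(streamlines, "streamline_set"),
            inherits(rois, "roi_set"))
  dims <- streamlines$dims
  tgt <- which(rois$target_mask)
  avd <- which(rois$avoid_mask)
  keep <- logical(length(streamlines$lines))
  n_no_target <- 0L; n_avoid <- 0L
  for (i in seq_along(streamlines$lines)) {
    vis <- .line_voxels(streamlines$lines[[i]], dims)
    if (length(avd) > 0L && any(vis %in% avd)) { n_avoid <- n_avoid + 1L; next }
    if (!any(vis %in% tgt)) { n_no_target <- n_no_target + 1L; next }
    keep[i] <- TRUE
  }
  out <- streamlines
  out$lines <- streamlines$lines[keep]
  out$seeds <- streamlines$seeds[keep]
  out$reasons <- streamlines$reasons[keep]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed_no_target") <- n_no_target
  attr(out, "n_removed_avoid") <- n_avoid
  attr(out, "not_visualized") <- sum(keep) == 0L
  out
}

# voxels with positive-length intersection with segment a->b (DDA
# traversal in shifted coordinates where voxel v spans [v, v+1))
.segment_voxels <- function(a, b, dims) {
  q0 <- a + 0.5; q1 <- b + 0.5
  d <- q1 - q0
  v <- floor(q0)
  if (all(abs(d) < 1e-12)) return(matrix(v, 1L, 3L))
  step <- ifelse(d > 0, 1, ifelse(d < 0, -1, 0))
  tdelta <- ifelse(d != 0, abs(1 / d), Inf)
  nextb <- v + ifelse(d > 0, 1, 0)
  tmax <- ifelse(d != 0, (nextb - q0) / d, Inf)
  out <- matrix(v, 1L, 3L)
  repeat {
    tm <- min(tmax)
    if (tm >= 1) break
    ax <- which(tmax - tm < 1e-12)   # simultaneous crossings step together
    v[ax] <- v[ax] + step[ax]
    tmax[ax] <- tmax[ax] + tdelta[ax]
    out <- rbind(out, v)
  }
  out
}

#' Voxelize a streamline set
#'
#' A voxel is set iff at least one streamline segment passes through it
#' with positive intersection length (grid traversal, not vertex
#' rounding).
#'
#' @param streamlines a `streamline_set`.
#' @param dims grid extents (default: the tracking grid).
#' @return logical array (class `bundle_mask`) with attribute `V` (voxel
#'   count) and `empty` flag.
#' @export
voxelize <- function(streamlines, dims = NULL) {
  stopifnot(inherits(streamlines, "streamline_set"))
  if (is.null(dims)) dims <- streamlines$dims
  mask <- array(FALSE, dims)
  for (ln in streamlines$lines) {
    for (s in seq_len(nrow(ln) - 1L)) {
      vox <- .segment_voxels(ln[s, ], ln[s + 1L, ], dims)
      keep <- vox[, 1L] >= 0 & vox[, 1L] < dims[1L] &
              vox[, 2L] >= 0 & vox[, 2L] < dims[2L] &
              vox[, 3L] >= 0 & vox[, 3L] < dims[3L]
      if (any(keep))
        mask[voxel_to_index(vox[keep, , drop = FALSE], dims)] <- TRUE
    }
  }
  structure(mask, class = c("bundle_mask", class(mask)), V = sum(mask),
            empty = length(streamlines$lines) == 0L)
}

#' Three-arm tractography Dice experiment for one phantom
#'
#' Reconstructs each arm with the requested model (analytic Q-ball or
#' GQI), finds peaks, tracks every bundle from its seed ROI, filters by
#' target/avoidance ROIs, voxelizes and scores Dice overlap against the
#' reference arm (c). A bundle not visualized in the reference arm voids
#' its comparison and is excluded, with bookkeeping; a test arm that
#' fails to visualize a bundle scores Dice 0 against the nonempty
#' reference (the formula is defined there).
#'
#' @param arms named list of [dwi_volume()]s `a`, `b`, `c` (see
#'   [assemble_arms()]).
#' @param rois list of `roi_set`s, one per bundle.
#' @param method `"qbi"` or `"gqi"`.
#' @param mask analysis mask (default: b0 mask of arm (c), fraction mode).
#' @param params a [track_params()].
#' @param find_peaks_args extra arguments for [find_peaks()].
#' @return data.frame with one row per bundle: `bundle`, `dsc_a`, `dsc_b`
#'   (each vs arm c), `visualized_a/b/c`, plus attributes `masks` (per
#'   arm/bundle), `n_compared`, `n_not_visualized`, `failed` (arm c empty).
#' @export
bundle_dsc_experiment <- function(arms, rois, method = c("qbi", "gqi"),
                                  mask = NULL, params = track_params(),
                                  find_peaks_args = list()) {
  method <- match.arg(method)
  stopifnot(all(c("a", "b", "c") %in% names(arms)))
  if (is.null(mask))
    mask <- compute_b0_mask(dwi_b0(arms$c), method = "fraction")
  recon_fun <- if (method == "qbi") qbi_odf else gqi_sdf
  peak_fields <- lapply(arms, function(arm) {
    field <- recon_fun(arm, mask = mask)
    do.call(find_peaks, c(list(field), find_peaks_args))
  })
  res <- list(); masks <- list(a = list(), b = list(), c = list())
  n_not_vis <- 0L
  for (k in seq_along(rois)) {
    row <- list(bundle = k)
    for (arm in c("a", "b", "c")) {
      sl <- track(peak_fields[[arm]], rois[[k]]$seed_mask, params = params)
      sl <- filter_by_rois(sl, rois[[k]])
      bm <- voxelize(sl)
      masks[[arm]][[k]] <- bm
      row[[paste0("visualized_", arm)]] <- !attr(bm, "empty") && attr(bm, "V") > 0
    }
    # Dice is defined (0) for an empty test mask against a nonempty
    # reference; only a non-visualized reference bundle voids the
    # comparison and is excluded
    row$dsc_a <- if (row$visualized_c)
      as.numeric(dice(masks$a[[k]], masks$c[[k]])) else NA_real_
    row$dsc_b <- if (row$visualized_c)
      as.numeric(dice(masks$b[[k]], masks$c[[k]])) else NA_real_
    if (!row$visualized_a || !row$visualized_b || !row$visualized_c)
      n_not_vis <- n_not_vis + 1L
    res[[k]] <- as.data.frame(row)
  }
  out <- do.call(rbind, res)
  attr(out, "masks") <- masks
  attr(out, "n_compared") <- sum(!is.na(out$dsc_a) & !is.na(out$dsc_b))
  attr(out, "n_not_visualized") <- n_not_vis
  attr(out, "failed") <- any(!out$visualized_c)
  out
}

#' Export streamlines as JSON lines
#'
#' One JSON object per line: streamline id, seed voxel, termination
#' reasons and the point list (voxel coordinates).
#'
#' @param streamlines a `streamline_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_streamlines_jsonl <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(streamlines$lines)) {
    obj <- list(id = i, seed = streamlines$seeds[i],
                reasons = as.list(streamlines$reasons[[i]]),
                points = unname(as.matrix(streamlines$lines[[i]])))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Export streamlines in TrackVis .trk format
#'
#' Writes the little-endian .trk header (version 2) and one track per
#' streamline. Point coordinates follow the TrackVis voxel-mm convention:
#' voxel coordinates are scaled by the voxel size (corner-based origin),
#' i.e. `(v + 0.5) * voxel_size`.
#'
#' @param streamlines a `streamline_set`.
#' @param path output path.
#' @param voxel_size numeric length-3 voxel extents in mm.
#' @return invisibly, `path`.
#' @export
write_trk <- function(streamlines, path, voxel_size = c(2.5, 2.5, 2.5)) {
  con <- file(path, "wb")
  on.exit(close(con))
  put_chars <- function(s, n) {           # zero-padded fixed-width field
    r <- raw(n)
    b <- charToRaw(s)
    r[seq_along(b)] <- b
    writeBin(r, con)
  }
  put_chars("TRACK", 6L)
  writeBin(as.integer(streamlines$dims), con, size = 2L, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")   # origin
  writeBin(integer(1L), con, size = 2L, endian = "little")   # n_scalars
  put_chars("", 200L)                                        # scalar names
  writeBin(integer(1L), con, size = 2L, endian = "little")   # n_properties
  put_chars("", 200L)                                        # property names
  m <- diag(4); m[1, 1] <- voxel_size[1L]; m[2, 2] <- voxel_size[2L]
  m[3, 3] <- voxel_size[3L]
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  put_chars("", 444L)                                        # reserved
  put_chars("LPS", 4L)                                       # voxel_order
  put_chars("", 4L)                                          # pad2
  writeBin(numeric(6L), con, size = 4L, endian = "little")   # image orient
  put_chars("", 8L)                                          # pad1 + flags
  writeBin(c(length(streamlines$lines), 2L, 1000L), con, size = 4L,
           endian = "little")
  for (ln in streamlines$lines) {
    writeBin(nrow(ln), con, size = 4L, endian = "little")
    pts <- sweep(ln + 0.5, 2L, voxel_size, `*`)
    writeBin(as.numeric(t(pts)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
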
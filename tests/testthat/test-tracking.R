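# exhaustive segment-box intersection oracle (Liang-Barsky clipping per
# voxel; a voxel counts when the clipped parameter interval has positive
# length)
segment_box_oracle <- function(a, b, dims) {
  hits <- NULL
  for (ix in 0:(dims[1L] - 1L)) for (iy in 0:(dims[2L] - 1L))
    for (iz in 0:(dims[3L] - 1L)) {
      lo <- c(ix, iy, iz) - 0.5; hi <- c(ix, iy, iz) + 0.5
      t0 <- 0; t1 <- 1; ok <- TRUE
      for (ax in 1:3) {
        d <- b[ax] - a[ax]
        if (abs(d) < 1e-15) {
          if (a[ax] < lo[ax] || a[ax] > hi[ax]) { ok <- FALSE; break }
        } else {
          ta <- (lo[ax] - a[ax]) / d; tb <- (hi[ax] - a[ax]) / d
          if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
          t0 <- max(t0, ta); t1 <- min(t1, tb)
          if (t0 >= t1) { ok <- FALSE; break }
        }
      }
      if (ok && t1 - t0 > 1e-12) hits <- rbind(hits, c(ix, iy, iz))
    }
  hits[order(hits[, 1L], hits[, 2L], hits[, 3L]), , drop = FALSE]
}

test_that("tracking follows a uniform +x field straight across the mask", {
  dims <- c(11L, 11L, 11L)
  n <- prod(dims)
  dirs <- array(0, c(n, 3L, 3L))
  dirs[, 1L, 1L] <- 1   # every voxel: single +x peak
  pk <- structure(list(dirs = dirs, npeaks = rep(1L, n), dims = dims,
                       max_peaks = 3L), class = "peak_field")
  seed <- array(FALSE, dims); seed[6, 6, 6] <- TRUE
  stop_mask <- array(TRUE, dims)
  sl <- track(pk, seed, stop_mask, track_params(step_size = 0.5))
  expect_equal(length(sl$lines), 1L)
  pts <- sl$lines[[1L]]
  expect_lt(max(abs(pts[, 2L] - 5)), 1e-6)
  expect_lt(max(abs(pts[, 3L] - 5)), 1e-6)
  expect_equal(range(pts[, 1L]), c(0, 10), tolerance = 0.51)
  # determinism
  sl2 <- track(pk, seed, stop_mask, track_params(step_size = 0.5))
  expect_identical(sl$lines, sl2$lines)
  expect_error(track(pk, array(FALSE, dims)), "empty seed")
})

test_that("max_angle = 0 in a curved field terminates with reason angle", {
  dims <- c(9L, 9L, 9L)
  n <- prod(dims)
  dirs <- array(0, c(n, 3L, 3L))
  # rotating field: direction varies with x so any step turns
  vox <- hardigen:::index_to_voxel(seq_len(n), dims)
  th <- vox[, 1L] * 0.2
  dirs[, 1L, 1L] <- cos(th); dirs[, 1L, 2L] <- sin(th)
  pk <- structure(list(dirs = dirs, npeaks = rep(1L, n), dims = dims,
                       max_peaks = 3L), class = "peak_field")
  seed <- array(FALSE, dims); seed[5, 5, 5] <- TRUE
  sl <- track(pk, seed, array(TRUE, dims),
              track_params(step_size = 0.5, max_angle = 0, min_length = 0))
  expect_equal(length(sl$lines), 1L)
  expect_true(all(unlist(sl$reasons) == "angle"))
})

test_that("streamlines respect the minimum length", {
  dims <- c(9L, 9L, 9L)
  n <- prod(dims)
  dirs <- array(0, c(n, 3L, 3L))
  dirs[, 1L, 1L] <- 1
  pk <- structure(list(dirs = dirs, npeaks = rep(1L, n), dims = dims,
                       max_peaks = 3L), class = "peak_field")
  seed <- array(FALSE, dims); seed[5, 5, 5] <- TRUE
  stop_small <- array(FALSE, dims); stop_small[4:6, 4:6, 4:6] <- TRUE
  sl <- track(pk, seed, stop_small, track_params(min_length = 4))
  expect_equal(length(sl$lines), 0L)
  sl2 <- track(pk, seed, stop_small, track_params(min_length = 1))
  expect_gte(length(sl2$lines), 1L)
  for (ln in sl2$lines)
    expect_gte((nrow(ln) - 1L) * 0.5, 1)
})

test_that("ROI filtering keeps target hitters and drops avoid hitters", {
  dims <- c(8L, 8L, 8L)
  mk_line <- function(...) matrix(c(...), ncol = 3L, byrow = TRUE)
  sl <- structure(list(lines = list(
    mk_line(1, 4, 4, 3, 4, 4, 6, 4, 4),            # reaches target
    mk_line(1, 1, 1, 1, 2, 1),                     # misses target
    mk_line(1, 4, 4, 4, 4, 6, 6, 4, 4)),           # target but via avoid
    seeds = c(1L, 2L, 3L),
    reasons = list(c("a", "b"), c("a", "b"), c("a", "b")),
    dims = dims), class = "streamline_set")
  tgt <- array(FALSE, dims); tgt[7, 5, 5] <- TRUE
  avd <- array(FALSE, dims); avd[5, 5, 7] <- TRUE
  rois <- structure(list(seed_mask = tgt, target_mask = tgt,
                         avoid_mask = avd), class = "roi_set")
  out <- filter_by_rois(sl, rois)
  expect_equal(length(out$lines), 1L)
  expect_equal(attr(out, "n_removed_no_target"), 1L)
  expect_equal(attr(out, "n_removed_avoid"), 1L)
  expect_false(attr(out, "not_visualized"))
  # empty result is allowed and flagged as non-visualized
  far <- array(FALSE, dims); far[8, 8, 8] <- TRUE
  rois2 <- structure(list(seed_mask = far, target_mask = far,
                          avoid_mask = array(FALSE, dims)),
                     class = "roi_set")
  out2 <- filter_by_rois(sl, rois2)
  expect_true(attr(out2, "not_visualized"))
})

test_that("voxelization matches the exhaustive segment-box oracle", {
  dims <- c(8L, 8L, 8L)
  segs <- list(
    list(a = c(0.1, 0.2, 0.05), b = c(7.7, 7.9, 7.3)),   # long diagonal
    list(a = c(2.3, 1.1, 6.2), b = c(5.9, 6.8, 0.4)),
    list(a = c(3.2, 3.2, 3.2), b = c(3.4, 3.3, 3.1)))    # within one voxel
  clip <- function(v) v[v[, 1L] >= 0 & v[, 1L] < dims[1L] &
                          v[, 2L] >= 0 & v[, 2L] < dims[2L] &
                          v[, 3L] >= 0 & v[, 3L] < dims[3L], , drop = FALSE]
  for (sg in segs) {
    got <- clip(hardigen:::.segment_voxels(sg$a, sg$b, dims))
    got <- got[order(got[, 1L], got[, 2L], got[, 3L]), , drop = FALSE]
    expect_equal(unname(got), unname(segment_box_oracle(sg$a, sg$b, dims)))
  }
  # random short segments (tracking-step scale)
  set.seed(17)
  for (i in 1:25) {
    a <- runif(3, 0.6, 6.4)
    b <- a + runif(3, -0.9, 0.9)
    got <- clip(unique(hardigen:::.segment_voxels(a, b, dims)))
    got <- got[order(got[, 1L], got[, 2L], got[, 3L]), , drop = FALSE]
    expect_equal(unname(got), unname(segment_box_oracle(a, b, dims)))
  }
})

test_that("voxelize sets exactly the traversed voxels", {
  dims <- c(8L, 8L, 8L)
  inner <- matrix(c(3.2, 3.2, 3.2, 3.4, 3.3, 3.1), 2L, 3L, byrow = TRUE)
  sl <- structure(list(lines = list(inner), seeds = 1L,
                       reasons = list(c("a", "b")), dims = dims),
                  class = "streamline_set")
  bm <- voxelize(sl)
  expect_equal(attr(bm, "V"), 1L)
  expect_true(bm[4, 4, 4])   # voxel (3,3,3) 0-based
  # invariance to point-order reversal
  slr <- sl; slr$lines[[1L]] <- inner[2:1, ]
  expect_equal(unclass(voxelize(slr)), unclass(bm), ignore_attr = TRUE)
  # empty set: empty mask with flag
  sle <- sl; sle$lines <- list(); sle$seeds <- integer(0L)
  bme <- voxelize(sle)
  expect_true(attr(bme, "empty"))
  expect_equal(attr(bme, "V"), 0L)
})

test_that("streamline exports produce readable files", {
  dims <- c(8L, 8L, 8L)
  ln <- matrix(c(1, 1, 1, 2, 1, 1, 3, 1.2, 1), 3L, 3L, byrow = TRUE)
  sl <- structure(list(lines = list(ln), seeds = 1L,
                       reasons = list(c(backward = "x", forward = "y")),
                       dims = dims), class = "streamline_set")
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_streamlines_jsonl(sl, jl)
  rec <- jsonlite::fromJSON(readLines(jl)[1L])
  expect_equal(rec$points, unname(ln))
  trk <- withr::local_tempfile(fileext = ".trk")
  write_trk(sl, trk)
  expect_equal(file.size(trk), 1000 + 4 + 3 * 3 * 4)
  con <- file(trk, "rb")
  id <- readChar(con, 5L)
  seek(con, 996)
  hdr_size <- readBin(con, integer(), size = 4L, endian = "little")
  close(con)
  expect_equal(id, "TRACK")
  expect_equal(hdr_size, 1000L)
})
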
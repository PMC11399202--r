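#' Gradient scheme container
#'
#' A `gradient_scheme` stores the motion-probing-gradient (MPG) table of a
#' single-shell HARDI acquisition: one unit direction and one b-value per
#' volume. b0 volumes are stored with a zero direction and b-value 0; by
#' convention a single b0 is stored first (MPG index 0).
#'
#' @param directions numeric matrix, one row per volume, 3 columns. Rows for
#'   b0 volumes are all-zero; diffusion rows must have unit norm.
#' @param bvalues numeric vector of b-values (s/mm^2), same length as rows.
#' @return an object of class `gradient_scheme` with elements `directions`,
#'   `bvalues` and `labels` (ordinal MPG indices; 0 marks b0).
#' @export
gradient_scheme <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stop("`directions` must have 3 columns", call. = FALSE)
  bvalues <- as.numeric(bvalues)
  if (nrow(directions) != length(bvalues))
    stop("length(directions) must equal length(bvalues)", call. = FALSE)
  if (any(bvalues < 0)) stop("bvalues must be >= 0", call. = FALSE)
  nrm <- sqrt(rowSums(directions^2))
  b0 <- bvalues == 0
  if (any(abs(nrm[!b0] - 1) > 1e-9))
    stop("diffusion directions must be unit vectors (|norm - 1| <= 1e-9)",
         call. = FALSE)
  if (any(nrm[b0] > 1e-9))
    stop("b0 entries must have zero direction", call. = FALSE)
  labels <- integer(length(bvalues))
  labels[!b0] <- seq_len(sum(!b0))
  structure(list(directions = directions, bvalues = bvalues, labels = labels),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d volumes: %d b0 + %d diffusion (b = %s)\n",
              length(x$bvalues), sum(x$bvalues == 0), sum(x$bvalues > 0),
              paste(unique(x$bvalues[x$bvalues > 0]), collapse = ", ")))
  invisible(x)
}

#' Number of diffusion (b > 0) directions in a scheme
#' @param scheme a [gradient_scheme()].
#' @return integer count.
#' @export
n_diffusion_directions <- function(scheme) sum(scheme$bvalues > 0)

#' Rows of the direction matrix with b > 0
#' @param scheme a [gradient_scheme()].
#' @return numeric matrix of unit diffusion directions.
#' @export
diffusion_directions <- function(scheme) {
  scheme$directions[scheme$bvalues > 0, , drop = FALSE]
}

#' Electrostatic-repulsion energy of a direction set
#'
#' The antipodal Coulomb energy
#' \deqn{E = \sum_{i<j} \left( 1/\|d_i - d_j\| + 1/\|d_i + d_j\| \right)}
#' used as the design criterion for MPG schemes. Coincident or antipodal
#' pairs give `Inf` (documented sentinel).
#'
#' @param directions numeric matrix of unit 3-vectors (>= 2 rows).
#' @return scalar energy; `Inf` when two directions coincide up to sign.
#' @export
scheme_energy <- function(directions) {
  directions <- as.matrix(directions)
  n <- nrow(directions)
  if (n < 2L) stop("need at least 2 directions", call. = FALSE)
  if (any(abs(sqrt(rowSums(directions^2)) - 1) > 1e-6))
    stop("directions must be unit vectors", call. = FALSE)
  g <- tcrossprod(directions)
  d2 <- pmax(2 - 2 * g, 0)
  s2 <- pmax(2 + 2 * g, 0)
  ut <- upper.tri(d2)
  dd <- sqrt(d2[ut]); ss <- sqrt(s2[ut])
  if (any(dd < 1e-12) || any(ss < 1e-12)) return(Inf)
  sum(1 / dd + 1 / ss)
}

# energy and Riemannian gradient for the projected-gradient optimizer
.energy_grad <- function(d) {
  n <- nrow(d)
  g <- tcrossprod(d)
  dm <- sqrt(pmax(2 - 2 * g, 1e-300))
  sm <- sqrt(pmax(2 + 2 * g, 1e-300))
  diag(dm) <- Inf
  a <- 1 / dm^3
  b <- 1 / sm^3
  diag(a) <- 0; diag(b) <- 0
  # dE/dd_i = -sum_j (d_i - d_j)/r-^3 - sum_j (d_i + d_j)/r+^3
  grad <- -(d * rowSums(a) - a %*% d) - (d * rowSums(b) + b %*% d)
  ut <- upper.tri(g)
  e <- sum(1 / dm[ut] + 1 / sm[ut])
  # project onto tangent space of the sphere
  grad <- grad - d * rowSums(grad * d)
  list(energy = e, grad = grad)
}

.optimize_directions <- function(d0, n_iterations) {
  d <- normalize_rows(d0)
  eg <- .energy_grad(d)
  e <- eg$energy
  trace <- e
  step <- 0.1
  for (it in seq_len(n_iterations)) {
    gmax <- max(abs(eg$grad))
    if (gmax < 1e-10) break
    improved <- FALSE
    while (step > 1e-12) {
      cand <- normalize_rows(d - step * eg$grad / gmax)
      ec <- scheme_energy(cand)
      if (ec < e) {
        d <- cand; e <- ec
        eg <- .energy_grad(d)
        step <- step * 1.3
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    trace <- c(trace, e)
    if (!improved) break
  }
  list(directions = d, energy = e, trace = trace)
}

#' Design an MPG scheme by electrostatic repulsion
#'
#' Places `n_directions` unit vectors on the sphere by minimizing the
#' antipodal Coulomb energy (see [scheme_energy()]) with projected gradient
#' descent and step-halving line search from random restarts. Deterministic
#' for a fixed seed; the energy is non-increasing over iterations.
#'
#' @param n_directions number of diffusion directions (>= 1).
#' @param seed integer RNG seed.
#' @param n_iterations optimizer iterations per restart.
#' @param n_restarts number of random restarts; the best final energy wins.
#' @param bvalue b-value (s/mm^2) assigned to the designed directions.
#' @param include_b0 prepend a single b0 entry (MPG index 0)?
#' @return a [gradient_scheme()]; attributes `energy` and `seed` record the
#'   achieved design energy and the seed used.
#' @export
design_scheme <- function(n_directions, seed = 1L, n_iterations = 200L,
                          n_restarts = 100L, bvalue = 3000, include_b0 = TRUE) {
  stopifnot_scalar(n_directions, "n_directions", integerish = TRUE)
  if (n_directions < 1) stop("`n_directions` must be >= 1", call. = FALSE)
  n <- as.integer(n_directions)
  if (n == 1L) {
    best <- list(directions = matrix(c(0, 0, 1), 1L, 3L), energy = 0)
  } else {
    best <- with_seed(seed, {
      res <- NULL
      for (r in seq_len(n_restarts)) {
        d0 <- matrix(rnorm(3L * n), n, 3L)
        cand <- .optimize_directions(d0, n_iterations)
        if (is.null(res) || cand$energy < res$energy) res <- cand
      }
      res
    })
  }
  dirs <- best$directions
  bv <- rep(bvalue, n)
  if (include_b0) {
    dirs <- rbind(c(0, 0, 0), dirs)
    bv <- c(0, bv)
  }
  out <- gradient_scheme(dirs, bv)
  attr(out, "energy") <- best$energy
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Split a scheme into input and complement halves
#'
#' The first part keeps every b0 entry plus the first `k` diffusion
#' directions in stored order; the second part holds the remaining
#' diffusion directions. [merge_schemes()] restores the original.
#'
#' @param scheme a [gradient_scheme()].
#' @param k number of diffusion directions kept in the first part
#'   (0 < k < number of diffusion directions).
#' @return list with elements `first` and `second`, both `gradient_scheme`s.
#' @export
split_scheme <- function(scheme, k) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  nd <- n_diffusion_directions(scheme)
  stopifnot_scalar(k, "k", integerish = TRUE)
  if (k <= 0 || k >= nd)
    stop(sprintf("`k` must satisfy 0 < k < %d", nd), call. = FALSE)
  diff_idx <- which(scheme$bvalues > 0)
  b0_idx <- which(scheme$bvalues == 0)
  first_idx <- sort(c(b0_idx, diff_idx[seq_len(k)]))
  second_idx <- diff_idx[(k + 1L):nd]
  list(
    first = gradient_scheme(scheme$directions[first_idx, , drop = FALSE],
                            scheme$bvalues[first_idx]),
    second = gradient_scheme(scheme$directions[second_idx, , drop = FALSE],
                             scheme$bvalues[second_idx])
  )
}

#' Merge two schemes by concatenation
#'
#' Duplicated b0 entries are not collapsed unless `drop_duplicate_b0` is
#' set; with the output of [split_scheme()] the default restores the input.
#'
#' @param first,second [gradient_scheme()]s.
#' @param drop_duplicate_b0 drop b0 rows of `second` when `first` has b0s?
#' @return a [gradient_scheme()].
#' @export
merge_schemes <- function(first, second, drop_duplicate_b0 = TRUE) {
  stopifnot(inherits(first, "gradient_scheme"),
            inherits(second, "gradient_scheme"))
  keep2 <- rep(TRUE, length(second$bvalues))
  if (drop_duplicate_b0 && any(first$bvalues == 0))
    keep2 <- second$bvalues > 0
  gradient_scheme(rbind(first$directions, second$directions[keep2, , drop = FALSE]),
                  c(first$bvalues, second$bvalues[keep2]))
}

#' Read an FSL-dialect bvec/bval pair
#'
#' bvec: three whitespace-separated rows (x, y, z components); bval: one
#' row. Zero-norm columns are interpreted as b0 axes.
#'
#' @param path_bvec,path_bval file paths.
#' @return a [gradient_scheme()].
#' @export
read_bvec_bval <- function(path_bvec, path_bval) {
  bvec_lines <- readLines(path_bvec, warn = FALSE)
  bvec_lines <- bvec_lines[nzchar(trimws(bvec_lines))]
  if (length(bvec_lines) != 3L)
    stop(sprintf("format error in %s: expected 3 rows, found %d",
                 path_bvec, length(bvec_lines)), call. = FALSE)
  rows <- lapply(bvec_lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  ncols <- vapply(rows, length, integer(1L))
  if (length(unique(ncols)) != 1L)
    stop(sprintf("format error in %s: rows have %s columns",
                 path_bvec, paste(ncols, collapse = "/")), call. = FALSE)
  bval_lines <- readLines(path_bval, warn = FALSE)
  bval_lines <- bval_lines[nzchar(trimws(bval_lines))]
  bval <- as.numeric(strsplit(trimws(paste(bval_lines, collapse = " ")), "\\s+")[[1L]])
  if (length(bval) != ncols[1L])
    stop(sprintf("format error: %s has %d columns but %s has %d entries",
                 path_bvec, ncols[1L], path_bval, length(bval)), call. = FALSE)
  dirs <- t(do.call(rbind, rows))
  nrm <- sqrt(rowSums(dirs^2))
  b0 <- nrm < 1e-8 | bval == 0
  bval[b0] <- 0
  dirs[b0, ] <- 0
  dirs[!b0, ] <- dirs[!b0, , drop = FALSE] / nrm[!b0]
  gradient_scheme(dirs, bval)
}

#' Write a scheme as FSL bvec/bval files
#'
#' Values are written with six significant digits; write-read round trips
#' reproduce directions within 1e-6.
#'
#' @param scheme a [gradient_scheme()].
#' @param path_bvec,path_bval output file paths.
#' @return invisibly, the two paths.
#' @export
write_bvec_bval <- function(scheme, path_bvec, path_bval) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  fmt <- function(v) paste(sprintf("%.6g", v), collapse = " ")
  writeLines(c(fmt(scheme$directions[, 1L]),
               fmt(scheme$directions[, 2L]),
               fmt(scheme$directions[, 3L])), path_bvec)
  writeLines(fmt(scheme$bvalues), path_bval)
  invisible(c(path_bvec, path_bval))
}

#' Serialize a scheme to JSON
#'
#' Records directions, b-values and, when present, the design seed and
#' energy, so a designed scheme is reproducible from its serialization.
#'
#' @param scheme a [gradient_scheme()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_scheme_json <- function(scheme, path) {
  obj <- list(directions = unname(as.matrix(scheme$directions)),
              bvalues = scheme$bvalues)
  if (!is.null(attr(scheme, "seed"))) obj$seed <- attr(scheme, "seed")
  if (!is.null(attr(scheme, "energy"))) obj$energy <- attr(scheme, "energy")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Minimum antipodally-folded pairwise angle of a direction set
#' @param directions matrix of unit vectors.
#' @return smallest pairwise angle in degrees after folding d and -d.
#' @export
min_folded_angle <- function(directions) {
  g <- abs(tcrossprod(as.matrix(directions)))
  g <- pmin(g, 1)
  diag(g) <- -Inf
  acos(max(g[upper.tri(g)])) * 180 / pi
}
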
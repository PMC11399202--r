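#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' operations do not perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  if (integerish && abs(x - round(x)) > 1e-8)
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(x)
}

#' @keywords internal
vnorm <- function(x) sqrt(sum(x^2))

#' Normalize rows of a matrix to unit Euclidean norm
#' @keywords internal
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# linear index <-> voxel coordinate helpers (0-based voxel coordinates,
# affine maps voxel centers; documented once in dwi_io)
voxel_to_index <- function(v, dims) {
  1L + v[, 1L] + dims[1L] * (v[, 2L] + dims[2L] * v[, 3L])
}

index_to_voxel <- function(i, dims) {
  i0 <- i - 1L
  cbind(i0 %% dims[1L],
        (i0 %/% dims[1L]) %% dims[2L],
        i0 %/% (dims[1L] * dims[2L]))
}

# grid of all voxel coordinates (0-based), rows in linear-index order
voxel_grid <- function(dims) {
  as.matrix(expand.grid(x = 0:(dims[1L] - 1L),
                        y = 0:(dims[2L] - 1L),
                        z = 0:(dims[3L] - 1L)))
}

# rotation taking unit vector `from` onto unit vector `to`
rotation_between <- function(from, to) {
  v <- c(from[2L] * to[3L] - from[3L] * to[2L],
         from[3L] * to[1L] - from[1L] * to[3L],
         from[1L] * to[2L] - from[2L] * to[1L])
  c_ <- sum(from * to)
  if (c_ < -1 + 1e-12) {
    # antipodal: rotate pi about any axis orthogonal to `from`
    ax <- if (abs(from[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * from) * from
    ax <- ax / vnorm(ax)
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + vx + vx %*% vx / (1 + c_)
}
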
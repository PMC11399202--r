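# Sphere sampling and the real spherical-harmonic basis used by the
# reconstruction and metric modules.

.hardigen_env <- new.env(parent = emptyenv())

.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# vertices of the icosahedron subdivided `freq` times per edge, projected
# to the unit sphere and deduplicated
.icosphere_vertices <- function(freq) {
  ico <- .icosahedron()
  pts <- ico$vertices
  for (fi in seq_len(nrow(ico$faces))) {
    tri <- ico$vertices[ico$faces[fi, ], ]
    for (i in 0:freq) for (j in 0:(freq - i)) {
      k <- freq - i - j
      pts <- rbind(pts, (i * tri[1L, ] + j * tri[2L, ] + k * tri[3L, ]) / freq)
    }
  }
  pts <- normalize_rows(pts)
  key <- apply(round(pts, 8L), 1L, paste, collapse = ",")
  pts[!duplicated(key), , drop = FALSE]
}

#' The 181-point hemisphere sampling
#'
#' Vertices of a frequency-6 subdivided icosahedron (362 points,
#' antipodally symmetric) folded to one hemisphere, giving exactly 181
#' near-uniformly spread directions. The folding keeps the representative
#' with z > 0 (ties broken by y, then x). The result is cached.
#'
#' @return numeric 181 x 3 matrix of unit vectors; attribute `min_angle`
#'   records the minimum pairwise (folded) angle in degrees.
#' @export
hemisphere181 <- function() {
  if (!is.null(.hardigen_env$sphere181)) return(.hardigen_env$sphere181)
  pts <- .icosphere_vertices(6L)
  eps <- 1e-9
  keep <- pts[, 3L] > eps |
    (abs(pts[, 3L]) <= eps & (pts[, 2L] > eps |
      (abs(pts[, 2L]) <= eps & pts[, 1L] > 0)))
  hemi <- pts[keep, , drop = FALSE]
  if (nrow(hemi) != 181L)
    stop(sprintf("internal error: hemisphere has %d points, expected 181",
                 nrow(hemi)))
  attr(hemi, "min_angle") <- min_folded_angle(hemi)
  .hardigen_env$sphere181 <- hemi
  hemi
}

#' (l, m) index table of the even-order real SH basis
#' @param lmax maximum (even) order.
#' @return data.frame with columns `l` and `m`, one row per coefficient,
#'   ordered by l then m = -l..l; `(lmax+1)(lmax+2)/2` rows.
#' @export
sh_index_table <- function(lmax) {
  if (lmax %% 2 != 0 || lmax < 0) stop("`lmax` must be even and >= 0", call. = FALSE)
  do.call(rbind, lapply(seq(0L, lmax, by = 2L), function(l)
    data.frame(l = l, m = seq(-l, l))))
}

# associated Legendre functions P_l^m (Condon-Shortley phase) for all
# l = 0..lmax, m = 0..l, vectorized over x via the standard recurrences;
# returns a list keyed "l,m" of numeric vectors
.assoc_legendre <- function(lmax, x) {
  s <- sqrt(pmax(1 - x^2, 0))
  P <- vector("list", (lmax + 1L) * (lmax + 2L) / 2L)
  key <- function(l, m) l * (l + 1L) / 2L + m + 1L
  pmm <- rep(1, length(x))
  for (m in 0:lmax) {
    if (m > 0) pmm <- -pmm * (2 * m - 1) * s
    P[[key(m, m)]] <- pmm
    if (m < lmax) P[[key(m + 1L, m)]] <- x * (2 * m + 1) * pmm
    if (m + 2L <= lmax) {
      for (l in (m + 2L):lmax) {
        P[[key(l, m)]] <- ((2 * l - 1) * x * P[[key(l - 1L, m)]] -
                             (l + m - 1) * P[[key(l - 2L, m)]]) / (l - m)
      }
    }
  }
  list(get = function(l, m) P[[key(l, m)]])
}

#' Real even-order spherical-harmonic basis matrix
#'
#' Orthonormal real basis built from associated Legendre functions
#' (evaluated by the standard stable recurrences):
#' m = 0 gives \eqn{N_{l0} P_l^0(\cos\theta)}; m > 0 gives
#' \eqn{\sqrt{2} N_{lm} P_l^m(\cos\theta)\cos(m\varphi)}; m < 0 the sine
#' counterpart. Only even l appear (antipodally symmetric functions).
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param lmax maximum even order.
#' @return n x ncoef matrix; column order matches [sh_index_table()].
#' @export
sh_basis <- function(dirs, lmax) {
  dirs <- as.matrix(dirs)
  idx <- sh_index_table(lmax)
  n <- nrow(dirs)
  ct <- pmin(pmax(dirs[, 3L], -1), 1)       # cos(theta)
  phi <- atan2(dirs[, 2L], dirs[, 1L])
  leg <- .assoc_legendre(lmax, ct)
  out <- matrix(0, n, nrow(idx))
  cosphi <- sinphi <- vector("list", lmax)
  for (m in seq_len(lmax)) {
    cosphi[[m]] <- cos(m * phi)
    sinphi[[m]] <- sin(m * phi)
  }
  col <- 1L
  for (l in seq(0L, lmax, by = 2L)) {
    for (m in seq(-l, l)) {
      am <- abs(m)
      nlm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- nlm * leg$get(l, am)
      out[, col] <- if (m == 0) base
        else if (m > 0) sqrt(2) * base * cosphi[[m]]
        else sqrt(2) * base * sinphi[[am]]
      col <- col + 1L
    }
  }
  out
}

# least-squares SH fit operator with optional Laplace-Beltrami
# regularization: coef = (B'B + reg * L^2)^-1 B'  (L = diag(l(l+1)))
.sh_fit_operator <- function(dirs, lmax, reg = 0) {
  B <- sh_basis(dirs, lmax)
  ll <- sh_index_table(lmax)$l
  lb <- diag((ll * (ll + 1))^2, nrow = length(ll))
  solve(crossprod(B) + reg * lb, t(B))
}
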
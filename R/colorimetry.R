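# chromaticity, correlated colour temperature and Duv

# second radiation constant used throughout, nm K
C2_NMK <- 1.4388e7

# relative Planckian spectral exitance on a wavelength grid, peak-normalized
planck_rel <- function(grid, TK) {
  e <- grid^-5 / (exp(C2_NMK / (grid * TK)) - 1)
  e / max(e)
}

uv1960 <- function(X, Y, Z) {
  d <- X + 15 * Y + 3 * Z
  c(u = 4 * X / d, v = 6 * Y / d)
}

# Planckian locus table in CIE 1960 (u, v), log-spaced in T; resolution is
# refined below 1 K by the local minimization in cct_duv()
planck_locus <- function(grid, xbar, ybar, zbar, n = 1201,
                         t_range = c(1000, 30000)) {
  TK <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n))
  w <- trapz_weights(grid)
  wx <- w * xbar; wy <- w * ybar; wz <- w * zbar
  u <- v <- numeric(n)
  for (i in seq_len(n)) {
    e <- planck_rel(grid, TK[i])
    uvi <- uv1960(sum(wx * e), sum(wy * e), sum(wz * e))
    u[i] <- uvi[1]; v[i] <- uvi[2]
  }
  list(TK = TK, u = u, v = v,
       uv_of_T = function(TT) {
         e <- planck_rel(grid, TT)
         uv1960(sum(wx * e), sum(wy * e), sum(wz * e))
       })
}

#' Chromaticity coordinates of a spectrum
#'
#' CIE 1931 (x, y, z) from the bundled 2-degree colour-matching functions;
#' z = 1 - x - y. Invariant under positive scaling of the spectrum.
#'
#' @param s an [spd()].
#' @param bundle an [load_bundle()] observer bundle.
#' @return Named numeric vector `c(x, y, z)`.
#' @export
chromaticity <- function(s, bundle) {
  e <- on_bundle_grid(s, bundle)
  w <- trapz_weights(bundle$grid)
  X <- sum(w * e * bundle$cmf$xbar)
  Y <- sum(w * e * bundle$cmf$ybar)
  Z <- sum(w * e * bundle$cmf$zbar)
  if (Y <= 0) stop("spectrum has zero luminance; chromaticity undefined")
  tot <- X + Y + Z
  c(x = X / tot, y = Y / tot, z = Z / tot)
}

#' Correlated colour temperature and Duv
#'
#' Ohno-style Planckian locus search: the bundled locus table (log-spaced,
#' 1000--30000 K) brackets the nearest point, which a local distance
#' minimization then refines well below 1 K. Duv is the signed distance from
#' the locus in the CIE 1960 (u, v) diagram, positive above the locus
#' (v above the Planckian v). When |Duv| > 0.05 the CCT is flagged as not
#' meaningful rather than silently reported.
#'
#' @inheritParams chromaticity
#' @return List with `cct` (K), `duv`, `cct_valid` (FALSE when |Duv| > 0.05),
#'   and the (x, y) chromaticity.
#' @export
cct_duv <- function(s, bundle) {
  xy <- chromaticity(s, bundle)
  X <- xy[["x"]]; Y <- xy[["y"]]; Z <- xy[["z"]]
  uv <- uv1960(X, Y, Z)
  loc <- bundle$locus
  d2 <- (loc$u - uv[1])^2 + (loc$v - uv[2])^2
  i <- which.min(d2)
  lo <- loc$TK[max(i - 1L, 1L)]; hi <- loc$TK[min(i + 1L, length(loc$TK))]
  f <- function(TT) { p <- loc$uv_of_T(TT); (p[1] - uv[1])^2 + (p[2] - uv[2])^2 }
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-2)
  cct <- opt$minimum
  pl <- loc$uv_of_T(cct)
  duv <- sqrt(opt$objective) * sign(uv[2] - pl[2])
  list(cct = cct, duv = duv, cct_valid = abs(duv) <= 0.05,
       x = unname(xy["x"]), y = unname(xy["y"]))
}
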
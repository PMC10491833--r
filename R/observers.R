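#' Spectral sensitivity functions
#'
#' A `sensitivity_function` is a tabulated spectral weighting function on a
#' strictly increasing wavelength grid (nm): a luminous efficiency function,
#' a cone fundamental, an opsin action spectrum, or a pre-receptoral
#' transmittance. Values are dimensionless and non-negative. Functions with
#' `normalization = "peak-1"` have maximum exactly 1 on their grid.
#'
#' @param name identifier, e.g. `"V"` or `"s_mel"`.
#' @param grid wavelengths in nm, strictly increasing, covering at least
#'   380--780 nm.
#' @param values non-negative weights, same length as `grid`.
#' @param normalization `"peak-1"` or `"as-published"`.
#' @return An object of class `sensitivity_function`.
#' @export
sensitivity_function <- function(name, grid, values,
                                 normalization = c("peak-1", "as-published")) {
  normalization <- match.arg(normalization)
  if (any(diff(grid) <= 0)) stop("wavelength grid must be strictly increasing")
  if (length(values) != length(grid)) stop("grid/values length mismatch")
  if (any(values < 0)) stop(sprintf("'%s' has negative values", name))
  if (min(grid) > 380 || max(grid) < 780)
    stop(sprintf("'%s' must cover at least 380-780 nm", name))
  if (normalization == "peak-1" && abs(max(values) - 1) > 1e-9)
    stop(sprintf("'%s' declared peak-1 but max(values) = %.12g", name, max(values)))
  structure(list(name = name, grid = as.numeric(grid),
                 values = as.numeric(values), normalization = normalization),
            class = "sensitivity_function")
}

#' @export
print.sensitivity_function <- function(x, ...) {
  cat(sprintf("<sensitivity_function> %s: %g-%g nm (%d points), %s, peak %.4g at %g nm\n",
              x$name, min(x$grid), max(x$grid), length(x$grid),
              x$normalization, max(x$values), x$grid[which.max(x$values)]))
  invisible(x)
}

observer_dir <- function() {
  d <- system.file("extdata", "observers", package = "circlight")
  if (!nzchar(d)) stop("bundled observer tables not found; broken installation")
  d
}

read_observer_table <- function(file) {
  path <- file.path(observer_dir(), file)
  if (!file.exists(path))
    stop(sprintf("missing bundled observer table '%s'", file), call. = FALSE)
  tab <- utils::read.table(path, comment.char = "#")
  provenance <- sub("^#\\s*", "", readLines(path, n = 1L))
  list(table = tab, provenance = provenance)
}

# linear resample of a tabulated function onto `grid`; outside the tabulated
# range observer functions are extended with `fill` (0 for sensitivities,
# nearest value for transmittances, which must stay positive)
resample_table <- function(wl, val, grid, fill = 0) {
  if (identical(fill, "nearest")) {
    stats::approx(wl, val, xout = grid, rule = 2)$y
  } else {
    y <- stats::approx(wl, val, xout = grid, rule = 1)$y
    y[is.na(y)] <- fill
    y
  }
}

#' Load the observer bundle
#'
#' Reads the bundled sensitivity and transmittance tables, resamples all of
#' them to one common wavelength grid by linear interpolation, renormalizes
#' the peak-1 functions on that grid, and precomputes everything the metric
#' stack needs: the macular-corrected peak-normalized cone functions
#' \eqn{V_c} and \eqn{S_c}, the Planckian locus used for CCT/Duv, the
#' equal-energy signal ratios used as normalization conventions by the
#' brightness metrics, and the melanopic irradiance of D65 at 1 photopic lux
#' (the self-calibrated mEDI divisor).
#'
#' Members: `V` (CIE 1924 photopic), `Vprime` (CIE 1951 scotopic), `S_cone`
#' (Smith--Pokorny-type S fundamental), `M_c` (lens-corrected melanopsin),
#' `mp` (macular pigment transmittance), `s_mel` (melanopic action spectrum),
#' and the CIE 1931 2-degree colour-matching functions. The CMF x-bar and
#' z-bar are rescaled so their trapezoidal integrals equal y-bar's, which
#' makes the chromaticity of the equal-energy spectrum exactly (1/3, 1/3).
#'
#' @param grid target wavelength grid in nm, within 360--830 nm, step at
#'   most 5 nm. Default 380:780 (1 nm).
#' @return An object of class `observer_bundle`.
#' @examples
#' b <- load_bundle()
#' b$V
#' @export
load_bundle <- function(grid = 380:780) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (min(grid) < 360 || max(grid) > 830) stop("grid must lie within 360-830 nm")
  if (max(diff(grid)) > 5 + 1e-12) stop("grid step must be at most 5 nm")

  files <- c(V      = "vlambda_photopic_1924.txt",
             Vprime = "vprime_scotopic_1951.txt",
             S_cone = "scone_zbar_based.txt",
             M_c    = "melanopsin_lens_corrected.txt",
             s_mel  = "melanopic_s026_type.txt",
             mp     = "macular_transmittance_snodderly_type.txt",
             xbar   = "cmf_xbar_1931.txt",
             ybar   = "cmf_ybar_1931.txt",
             zbar   = "cmf_zbar_1931.txt")
  raw <- lapply(files, read_observer_table)
  meta <- lapply(raw, `[[`, "provenance")

  rs <- function(nm, fill = 0, renorm = TRUE) {
    tab <- raw[[nm]]$table
    v <- resample_table(tab[[1]], tab[[2]], grid, fill)
    if (renorm && max(v) > 0) v <- v / max(v)
    v
  }
  V      <- rs("V")
  Vprime <- rs("Vprime")
  S_cone <- rs("S_cone")
  M_c    <- rs("M_c")
  s_mel  <- rs("s_mel")
  mp     <- rs("mp", fill = "nearest", renorm = FALSE)
  xbar   <- rs("xbar", renorm = FALSE)
  ybar   <- rs("ybar", renorm = FALSE)
  zbar   <- rs("zbar", renorm = FALSE)
  if (any(mp <= 0) || any(mp > 1))
    stop("macular transmittance must lie in (0, 1]")

  w <- trapz_weights(grid)
  # equal-sum rescale of x-bar / z-bar (CIE construction; exact EE white point)
  xbar <- xbar * sum(w * ybar) / sum(w * xbar)
  zbar <- zbar * sum(w * ybar) / sum(w * zbar)

  sf <- function(name, values, norm = "peak-1")
    sensitivity_function(name, grid, values, norm)

  bundle <- list(
    grid   = grid,
    V      = sf("V", V),
    Vprime = sf("Vprime", Vprime),
    S_cone = sf("S_cone", S_cone),
    M_c    = sf("M_c", M_c),
    s_mel  = sf("s_mel", s_mel),
    mp     = sf("mp", mp, "as-published"),
    cmf    = list(xbar = xbar, ybar = ybar, zbar = zbar),
    meta   = meta
  )
  bundle$V_c <- corrected_function(bundle$V, bundle$mp)
  bundle$S_c <- corrected_function(bundle$S_cone, bundle$mp)
  bundle$V_c$name <- "V_c"; bundle$S_c$name <- "S_c"

  # equal-energy normalization constants for the brightness-metric ratios
  bundle$sv_ee  <- sum(w * S_cone) / sum(w * V)
  bundle$mel_ee <- sum(w * s_mel) / sum(w * V)

  bundle$locus <- planck_locus(grid, xbar, ybar, zbar)
  class(bundle) <- "observer_bundle"

  # self-calibrated mEDI divisor: melanopic irradiance of D65 at 1 lx
  d65 <- daylight_spd(6500 * 1.4388 / 1.4380, grid = grid)
  e <- d65$irradiance / (683 * sum(w * d65$irradiance * V))
  bundle$d65_mel_per_lx <- sum(w * e * s_mel)
  bundle
}

#' @export
print.observer_bundle <- function(x, ...) {
  cat(sprintf("<observer_bundle> grid %g-%g nm, step %g nm (%d points)\n",
              min(x$grid), max(x$grid), x$grid[2] - x$grid[1], length(x$grid)))
  cat(sprintf("  members: V, Vprime, S_cone, M_c, mp, s_mel, V_c, S_c, 2-deg CMFs\n"))
  cat(sprintf("  melanopic irradiance of D65 at 1 lx: %.4g W m-2\n", x$d65_mel_per_lx))
  invisible(x)
}

#' Macular-corrected, peak-normalized sensitivity function
#'
#' Divides a sensitivity function by the macular pigment transmittance and
#' renormalizes the result to peak 1: \eqn{f_c = (f/mp) / max(f/mp)}. This is
#' how the corrected cone functions \eqn{V_c} and \eqn{S_c} of the 2021
#' circadian-light model are built. Applying the operation twice gives the
#' same result as applying it once (idempotent up to scale).
#'
#' @param f a [sensitivity_function()].
#' @param mp the macular pigment transmittance on the same grid, values in
#'   (0, 1].
#' @return A peak-1 `sensitivity_function`.
#' @export
corrected_function <- function(f, mp) {
  stopifnot(inherits(f, "sensitivity_function"),
            inherits(mp, "sensitivity_function"))
  if (!isTRUE(all.equal(f$grid, mp$grid)))
    stop("`f` and `mp` must be tabulated on identical grids")
  if (any(mp$values == 0))
    stop("macular transmittance contains zeros; corrected function undefined")
  v <- f$values / mp$values
  sensitivity_function(paste0(f$name, "_c"), f$grid, v / max(v), "peak-1")
}

# trapezoidal integral of spectrum irradiance against a bundle member
spectral_integral <- function(e, weights_fun, w) sum(w * e * weights_fun)
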
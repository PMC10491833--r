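# parametric spectral families used by the synthetic ensemble

gaussian_band <- function(grid, center, fwhm)
  exp(-4 * log(2) * ((grid - center) / fwhm)^2)

#' Reference and parametric spectra
#'
#' `planckian_spd()` evaluates Planck's law (second radiation constant
#' 1.4388e7 nm K) as a relative spectrum; `daylight_spd()` reconstructs a
#' CIE D-series daylight phase from the bundled S0/S1/S2 components (valid
#' for 4000--25000 K); `equal_energy_spd()` is the constant spectrum.
#' Returned spectra are relative (peak 1); use [scale_to_illuminance()] to
#' make them absolute.
#'
#' @param TK Planckian temperature in K (> 0).
#' @param cct daylight correlated colour temperature in K, 4000--25000.
#' @param grid wavelength grid in nm.
#' @return An [spd()].
#' @export
planckian_spd <- function(TK, grid = 380:780) {
  stop_if_not_scalar_number(TK, "TK")
  if (TK <= 0) stop("Planckian temperature must be positive")
  spd(grid, planck_rel(grid, TK), id = sprintf("planckian_%.0fK", TK),
      source_class = "incandescent", metadata = list(family = "planckian", T = TK))
}

#' @rdname planckian_spd
#' @export
daylight_spd <- function(cct, grid = 380:780) {
  stop_if_not_scalar_number(cct, "cct")
  if (cct < 4000 || cct > 25000)
    stop("daylight reconstruction is defined for 4000-25000 K")
  x <- if (cct <= 7000)
    0.244063 + 0.09911e3 / cct + 2.9678e6 / cct^2 - 4.6070e9 / cct^3
  else
    0.237040 + 0.24748e3 / cct + 1.9018e6 / cct^2 - 2.0064e9 / cct^3
  y <- -3.000 * x^2 + 2.870 * x - 0.275
  den <- 0.0241 + 0.2562 * x - 0.7341 * y
  M1 <- (-1.3515 - 1.7703 * x + 5.9114 * y) / den
  M2 <- (0.0300 - 31.4424 * x + 30.0717 * y) / den
  comp <- read_observer_table("daylight_components_cie.txt")$table
  rs <- function(col) resample_table(comp[[1]], comp[[col]], grid, fill = 0)
  e <- rs(2) + M1 * rs(3) + M2 * rs(4)
  e[e < 0] <- 0
  spd(grid, e / max(e), id = sprintf("daylight_%.0fK", cct),
      source_class = "daylight", metadata = list(family = "daylight", cct = cct))
}

#' @rdname planckian_spd
#' @export
equal_energy_spd <- function(grid = 380:780)
  spd(grid, rep(1, length(grid)), id = "equal_energy")

#' Synthesize a parametric light-source spectrum
#'
#' Parametric stand-ins for the four light-source technology classes of the
#' analysed corpus:
#' \describe{
#'   \item{planckian}{Planck's law at `params$T`; optionally multiplied by a
#'     smooth logistic long-/short-pass transmittance (`params$filter` with
#'     `cutoff` nm, `width` nm, `floor` in \[0,1\], `direction` "longpass" or
#'     "shortpass") to emulate filtered incandescent lamps.}
#'   \item{daylight}{CIE D-series at `params$cct` (4000--25000 K).}
#'   \item{led}{blue pump Gaussian (`blue_peak`, `blue_fwhm`) plus phosphor
#'     Gaussian (`phos_center`, `phos_fwhm`) with amplitude `ratio`
#'     (phosphor/pump).}
#'   \item{fluorescent}{mercury lines at 405/436/546/578 nm (Gaussian,
#'     sd 2 nm, weights `line_weights`) over 1--3 phosphor bands
#'     (`bands`: data.frame with `center`, `fwhm`, `weight`).}
#' }
#'
#' @param family one of `"planckian"`, `"daylight"`, `"led"`, `"fluorescent"`.
#' @param params named list of family parameters (above).
#' @param grid wavelength grid in nm.
#' @return A relative [spd()] with `source_class` recording the family
#'   (planckian maps to `"incandescent"`).
#' @export
synth_spd <- function(family = c("planckian", "daylight", "led", "fluorescent"),
                      params = list(), grid = 380:780) {
  family <- match.arg(family)
  e <- switch(family,
    planckian = {
      if (is.null(params$T)) stop("planckian family needs params$T")
      v <- planck_rel(grid, params$T)
      if (!is.null(params$filter)) {
        fl <- params$filter
        tr <- fl$floor + (1 - fl$floor) /
          (1 + exp(-(grid - fl$cutoff) / fl$width))
        if (identical(fl$direction, "shortpass")) tr <- fl$floor + (1 - fl$floor) /
          (1 + exp((grid - fl$cutoff) / fl$width))
        v <- v * tr
      }
      v
    },
    daylight = {
      if (is.null(params$cct)) stop("daylight family needs params$cct")
      daylight_spd(params$cct, grid)$irradiance
    },
    led = {
      p <- params
      gaussian_band(grid, p$blue_peak, p$blue_fwhm) +
        p$ratio * gaussian_band(grid, p$phos_center, p$phos_fwhm)
    },
    fluorescent = {
      p <- params
      lines <- c(405, 436, 546, 578)
      v <- numeric(length(grid))
      for (i in seq_along(lines))
        v <- v + p$line_weights[i] * exp(-((grid - lines[i]) / 2)^2 / 2)
      if (!is.null(p$bands))
        for (j in seq_len(nrow(p$bands)))
          v <- v + p$bands$weight[j] *
            gaussian_band(grid, p$bands$center[j], p$bands$fwhm[j])
      v
    })
  cls <- switch(family, planckian = "incandescent", daylight = "daylight",
                led = "led", fluorescent = "fluorescent")
  spd(grid, e / max(e), id = family, source_class = cls,
      metadata = c(list(family = family), params[!vapply(params, is.list, TRUE)]))
}
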
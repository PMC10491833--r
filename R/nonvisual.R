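# circadian light (CL_A 1.0 / 2.0), circadian stimulus, mEDI, and the
# as-printed melatonin-suppression conversion

#' Constants of the circadian light / circadian stimulus models
#'
#' The printed model constants: the illuminant-A normalization `norm = 1548`,
#' the opponent-channel constant `k = 0.2616`, the 2018 weights
#' (`a_by_2018 = 0.7`, `a_rod_2018 = 3.3`), the 2021 weights
#' (`a_by_2021 = 0.21`, `a_rod1 = 2.3`, `a_rod2 = 1.60`, `g1 = 1.00`,
#' `g2 = 0.16`), the rod saturation constant `rod_sat = 6.5` W m-2 (scotopic
#' irradiance), and the logistic conversion parameters
#' (`cs_halfsat = 355.7`, `cs_exponent = 1.1026`, `cs_max = 0.7`).
#' Any override is reported with a message so non-standard runs are visible.
#'
#' @param ... named overrides of individual constants.
#' @return Named list of class `cla_constants`.
#' @export
cla_constants <- function(...) {
  const <- list(norm = 1548, k = 0.2616,
                a_by_2018 = 0.7, a_rod_2018 = 3.3,
                a_by_2021 = 0.21, a_rod1 = 2.3, a_rod2 = 1.60,
                g1 = 1.00, g2 = 0.16, rod_sat = 6.5,
                cs_halfsat = 355.7, cs_exponent = 1.1026, cs_max = 0.7)
  ov <- list(...)
  bad <- setdiff(names(ov), names(const))
  if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
  if (length(ov))
    message("cla_constants: overriding ", paste(
      sprintf("%s = %g (default %g)", names(ov), unlist(ov),
              unlist(const[names(ov)])), collapse = ", "))
  const[names(ov)] <- ov
  structure(const, class = "cla_constants")
}

# all spectral integrals the circadian / brightness metrics need, from one
# pass over the bundle grid
circadian_integrals <- function(e, bundle) {
  w <- trapz_weights(bundle$grid)
  mpv <- bundle$mp$values
  list(
    iv    = sum(w * e * bundle$V$values),
    ivp   = sum(w * e * bundle$Vprime$values),
    is    = sum(w * e * bundle$S_cone$values),
    imc   = sum(w * e * bundle$M_c$values),
    ismel = sum(w * e * bundle$s_mel$values),
    ivmp  = sum(w * e * bundle$V$values / mpv),
    ismp  = sum(w * e * bundle$S_cone$values / mpv),
    ivc   = sum(w * e * bundle$V_c$values),
    isc   = sum(w * e * bundle$S_c$values)
  )
}

#' Blue-versus-yellow opponent signal
#'
#' The signed b-y opponent value whose sign selects the warm/cold branch of
#' the circadian light formulas. The 2021 form uses the macular-corrected,
#' peak-normalized cone functions,
#' \eqn{b-y = \int S_c E d\lambda - k \int V_c E d\lambda}; the 2018 form
#' uses the macular-divided but unnormalized functions,
#' \eqn{\int (S/mp) E d\lambda - k \int (V/mp) E d\lambda}. `k = 0.2616` in
#' both.
#'
#' @param s an absolute [spd()].
#' @param bundle an [load_bundle()] observer bundle.
#' @param version `"2021"` or `"2018"`.
#' @param constants a [cla_constants()] list.
#' @return Signed opponent value (W m-2 scale; only the sign is interpreted).
#' @export
opponent_by <- function(s, bundle, version = c("2021", "2018"),
                        constants = cla_constants()) {
  version <- match.arg(version)
  ii <- circadian_integrals(on_bundle_grid(s, bundle), bundle)
  opponent_by_from_integrals(ii, version, constants)
}

opponent_by_from_integrals <- function(ii, version, constants) {
  if (version == "2021") ii$isc - constants$k * ii$ivc
  else ii$ismp - constants$k * ii$ivmp
}

cla_result <- function(value, version, branch, by_signal, terms, constants) {
  structure(list(value = value, version = version, branch = branch,
                 by_signal = by_signal, terms = terms, constants = constants),
            class = "cla_result")
}

#' @export
print.cla_result <- function(x, ...) {
  cat(sprintf("<cla_result> CL_A %s = %.4g  [%s branch, b-y = %.4g]\n",
              x$version, x$value, x$branch, x$by_signal))
  cat("  terms (x norm):",
      paste(sprintf("%s = %.4g", names(x$terms), unlist(x$terms)), collapse = ", "),
      "\n")
  invisible(x)
}

cla_2018_from_integrals <- function(ii, constants) {
  cst <- constants
  by18 <- opponent_by_from_integrals(ii, "2018", cst)
  if (by18 > 0) {
    terms <- list(melanopsin = ii$imc,
                  opponent = cst$a_by_2018 * by18,
                  rod = -cst$a_rod_2018 * (1 - exp(-ii$ivp / cst$rod_sat)))
    branch <- "cold"
  } else {
    terms <- list(melanopsin = ii$imc, opponent = 0, rod = 0)
    branch <- "warm"
  }
  cla_result(cst$norm * sum(unlist(terms)), "2018", branch, by18, terms, cst)
}

cla_2021_from_integrals <- function(ii, constants) {
  cst <- constants
  by21 <- opponent_by_from_integrals(ii, "2021", cst)
  rod_term <- function(g) {
    den <- ii$ivc + g * ii$isc
    if (den <= 0) return(0)
    (ii$ivp / den) * (1 - exp(-ii$ivp / cst$rod_sat))
  }
  terms <- list(melanopsin = ii$imc, rod1 = -cst$a_rod1 * rod_term(cst$g1),
                opponent = 0, rod2 = 0)
  branch <- "warm"
  if (by21 > 0) {
    # as printed, the cold-branch opponent term pairs the corrected S_c with
    # the unnormalized V/mp; numerically max(V/mp) = 1 on the bundled tables,
    # so the two V forms coincide and the term vanishes at the branch point
    terms$opponent <- cst$a_by_2021 * (ii$isc - cst$k * ii$ivmp)
    terms$rod2 <- -cst$a_rod2 * rod_term(cst$g2)
    branch <- "cold"
  }
  cla_result(cst$norm * sum(unlist(terms)), "2021", branch, by21, terms, cst)
}

#' Circadian light, 2018 model (CL_A 1.0)
#'
#' Warm branch (b-y <= 0): \eqn{CL_A = 1548 \int M_c E d\lambda}. Cold
#' branch adds the macular-divided opponent term weighted by 0.7 and
#' subtracts the rod saturation term \eqn{3.3 (1 - e^{-\int V' E / 6.5})}.
#' The spectrum must be absolute (W m-2 nm-1): the rod term depends on the
#' absolute scotopic irradiance. A zero spectrum returns 0 on the warm
#' branch.
#'
#' @inheritParams opponent_by
#' @return A `cla_result` with value, version, branch, signed opponent value
#'   and the per-term breakdown (`value = norm * sum(terms)`).
#' @export
cla_2018 <- function(s, bundle, constants = cla_constants()) {
  ii <- circadian_integrals(on_bundle_grid(s, bundle), bundle)
  cla_2018_from_integrals(ii, constants)
}

#' Circadian light, 2021 model (CL_A 2.0)
#'
#' Both branches start from the melanopsin integral and subtract a rod term
#' whose denominator is the weighted corrected-cone sum
#' \eqn{\int V_c E + g \int S_c E} and whose saturation factor uses the raw
#' scotopic irradiance \eqn{\int V' E} against RodSat = 6.5 W m-2; the cold
#' branch (b-y > 0 under the 2021 opponent) additionally adds the opponent
#' term weighted by 0.21 and subtracts a second rod term with g2 = 0.16.
#'
#' @inheritParams opponent_by
#' @return A `cla_result`; see [cla_2018()].
#' @export
cla_2021 <- function(s, bundle, constants = cla_constants()) {
  ii <- circadian_integrals(on_bundle_grid(s, bundle), bundle)
  cla_2021_from_integrals(ii, constants)
}

#' Circadian stimulus (CS) from circadian light
#'
#' The saturating logistic conversion
#' \deqn{CS = 0.7 - 0.7 / (1 + (CL_A t f / 355.7)^{1.1026})}
#' predicting fractional nocturnal melatonin suppression (0.35 exactly at
#' the half-saturation value, asymptote 0.7). `t` is exposure time in hours;
#' `f` describes the visual field (0.5 superior field, 1.0 central field,
#' 2.0 Ganzfeld); other positive values are accepted with a warning.
#' Strictly increasing in `cla * t * f`. Vectorized over `cla`.
#'
#' @param cla non-negative circadian light value(s); a `cla_result` is
#'   accepted.
#' @param t exposure time in hours (> 0), default 1.
#' @param f visual-field factor (> 0), default 1.0.
#' @param constants a [cla_constants()] list.
#' @return CS fraction(s) in \[0, 0.7).
#' @export
circadian_stimulus <- function(cla, t = 1, f = 1.0, constants = cla_constants()) {
  if (inherits(cla, "cla_result")) cla <- cla$value
  if (any(cla < 0)) stop("negative circadian light value")
  if (t <= 0) stop("`t` must be positive")
  if (f <= 0) stop("`f` must be positive")
  if (!f %in% c(0.5, 1.0, 2.0))
    warning(sprintf("f = %g is outside the documented set {0.5, 1, 2}", f))
  dose <- cla * t * f / constants$cs_halfsat
  constants$cs_max - constants$cs_max / (1 + dose^constants$cs_exponent)
}

#' Melanopic equivalent daylight illuminance (mEDI)
#'
#' The illuminance of D65 daylight producing the same melanopic irradiance
#' as the test spectrum: \eqn{\int E s_{mel} d\lambda} divided by the
#' melanopic irradiance of D65 at 1 photopic lux. The divisor is computed at
#' bundle load from the bundled D65 reconstruction with the same quadrature,
#' so mEDI(D65 at E lx) = E holds to numerical precision by construction.
#'
#' @inheritParams opponent_by
#' @return mEDI in lx.
#' @export
medi <- function(s, bundle) {
  e <- on_bundle_grid(s, bundle)
  sum(trapz_weights(bundle$grid) * e * bundle$s_mel$values) / bundle$d65_mel_per_lx
}

#' Nocturnal melatonin suppression from mEDI (as-printed formula)
#'
#' Evaluates, verbatim, the published logistic conversion
#' \deqn{(0 - 100) / (1 + log10(mEDI \cdot 10^6) / (9.002 - 0.008 \Delta t -
#' 0.462 \, dil))}
#' with exposure duration \eqn{\Delta t} in minutes and pupil dilation 0/1.
#' Both the signed value and its magnitude are returned.
#'
#' Caveat (`formula = "as-printed"`): as printed, the expression tends to 0
#' (not -100) as mEDI grows, and its magnitude decreases with mEDI over the
#' usual indoor range — both at odds with the increasing suppression the
#' source model describes, so the transcription is most likely garbled. The
#' formula is therefore reproduced exactly as printed, flagged, and excluded
#' from the headline correlation orderings; no corrected form is guessed.
#'
#' @param medi melanopic equivalent daylight illuminance in lx (> 0);
#'   vectorized.
#' @param duration exposure duration in minutes (> 0), default 60.
#' @param pupil_dilated 0 (natural pupil) or 1 (dilated).
#' @return Object of class `gimenez_suppression`: list with `value` (signed
#'   %, as printed), `magnitude` (%), `duration`, `pupil_dilated`, `formula`.
#' @export
gimenez_suppression <- function(medi, duration = 60, pupil_dilated = 0) {
  if (any(medi <= 0)) stop("mEDI must be positive")
  if (duration <= 0) stop("`duration` must be positive")
  if (!pupil_dilated %in% c(0, 1)) stop("`pupil_dilated` must be 0 or 1")
  divisor <- 9.002 - 0.008 * duration - 0.462 * pupil_dilated
  value <- (0 - 100) / (1 + log10(medi * 1e6) / divisor)
  structure(list(value = value, magnitude = abs(value), duration = duration,
                 pupil_dilated = pupil_dilated, divisor = divisor,
                 formula = "as-printed"),
            class = "gimenez_suppression")
}

#' @export
print.gimenez_suppression <- function(x, ...) {
  cat(sprintf("<gimenez_suppression> %s%% (magnitude %s) at %g min, dilation %d [formula as-printed; see ?gimenez_suppression]\n",
              paste(sprintf("%.2f", x$value), collapse = ", "),
              paste(sprintf("%.2f", x$magnitude), collapse = ", "),
              x$duration, x$pupil_dilated))
  invisible(x)
}
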
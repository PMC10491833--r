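# spectral brightness metrics: equivalent luminance, B2, and the TU
# Darmstadt brightness model

#' Constants of the brightness models
#'
#' Printed values: the S/V exponent 0.24 of the equivalent-luminance model;
#' the B2 weights 0.6 (S-cone, times the adaptation factor g) and 0.5
#' (melanopsin); and the TUD model coefficients
#' \eqn{M = 8.9974 [E_v^{0.2629} (S^{0.074} + 0.5 G^{0.0424})] - 1.3307}.
#' Overrides are reported with a message.
#'
#' @param ... named overrides.
#' @export
brightness_constants <- function(...) {
  const <- list(fotios_exponent = 0.24, b2_s_weight = 0.6, b2_mel_weight = 0.5,
                tud_scale = 8.9974, tud_ev_exp = 0.2629, tud_s_exp = 0.074,
                tud_g_exp = 0.0424, tud_g_weight = 0.5, tud_offset = 1.3307)
  ov <- list(...)
  bad <- setdiff(names(ov), names(const))
  if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
  if (length(ov))
    message("brightness_constants: overriding ",
            paste(sprintf("%s = %g", names(ov), unlist(ov)), collapse = ", "))
  const[names(ov)] <- ov
  structure(const, class = "brightness_constants")
}

# S/V and melanopsin/V signal ratios under the equal-energy convention
# (ratio = 1 for a constant spectrum)
signal_ratios <- function(e, bundle) {
  w <- trapz_weights(bundle$grid)
  iv <- sum(w * e * bundle$V$values)
  if (iv <= 0) stop("spectrum has zero luminance")
  list(sv = (sum(w * e * bundle$S_cone$values) / iv) / bundle$sv_ee,
       mel = (sum(w * e * bundle$s_mel$values) / iv) / bundle$mel_ee)
}

#' Equivalent luminance (Fotios--Levermore)
#'
#' \eqn{L_{eq} = L_v (S/V)^{0.24}}, the brightness metric in which the
#' photopic signal stays uncompressed and the S-cone/photopic ratio carries
#' the spectral correction. When the input is an irradiance spectrum, the
#' photopic illuminance stands in for \eqn{L_v}, and the S/V ratio is scaled
#' so that S/V = 1 for the equal-energy spectrum (documented convention; any
#' other global ratio scaling multiplies L_eq by a constant and leaves all
#' correlations unchanged).
#'
#' @param s an absolute [spd()] with positive luminance.
#' @param bundle an [load_bundle()] observer bundle.
#' @param constants a [brightness_constants()] list.
#' @return Equivalent luminance, same unit as the luminance proxy (lx here).
#' @export
leq_fotios <- function(s, bundle, constants = brightness_constants()) {
  e <- on_bundle_grid(s, bundle)
  r <- signal_ratios(e, bundle)
  photopic_illuminance(s, bundle) * r$sv^constants$fotios_exponent
}

#' B2 brightness signal (Bullough)
#'
#' \eqn{B_2 = V + 0.6 g S + 0.5 Mel}: a linear combination of the photopic,
#' S-cone and melanopsin signals, each a trapezoidal integral of the
#' absolute spectrum against the peak-normalized function. The adaptation
#' factor `g` depends on light level and is supplied by the caller
#' (default 1); it is not calibrated here.
#'
#' @inheritParams leq_fotios
#' @param g adaptation factor, >= 0.
#' @export
b2_bullough <- function(s, bundle, g = 1, constants = brightness_constants()) {
  if (g < 0) stop("adaptation factor `g` must be non-negative")
  e <- on_bundle_grid(s, bundle)
  w <- trapz_weights(bundle$grid)
  sum(w * e * bundle$V$values) +
    constants$b2_s_weight * g * sum(w * e * bundle$S_cone$values) +
    constants$b2_mel_weight * sum(w * e * bundle$s_mel$values)
}

#' TU Darmstadt brightness model
#'
#' \deqn{M = 8.9974 [E_v^{0.2629} (S^{0.074} + 0.5 G^{0.0424})] - 1.3307}
#' with S-cone signal \eqn{S = s_{ratio} E_v} and melanopsin signal
#' \eqn{G = mel_{ratio} E_v}. This ratio entry path reproduces the published
#' worked examples directly from the printed S-cone/photopic and
#' melanopsin/photopic ratios; [m_tud_from_spectrum()] derives the two
#' ratios from a spectrum under the equal-energy convention.
#' Strictly increasing in each argument; the zero-illuminance limit is
#' `-1.3307`.
#'
#' @param E_v photopic illuminance in lx, >= 0. Vectorized.
#' @param s_ratio S-cone/photopic ratio (> 0 when `E_v` > 0).
#' @param mel_ratio melanopsin/photopic ratio (> 0 when `E_v` > 0).
#' @param constants a [brightness_constants()] list.
#' @return Brightness M (model units).
#' @export
m_tud <- function(E_v, s_ratio, mel_ratio, constants = brightness_constants()) {
  if (any(E_v < 0)) stop("`E_v` must be non-negative")
  if (any(E_v > 0 & (s_ratio <= 0 | mel_ratio <= 0)))
    stop("signal ratios must be positive when E_v > 0")
  S <- s_ratio * E_v
  G <- mel_ratio * E_v
  cst <- constants
  cst$tud_scale * (E_v^cst$tud_ev_exp *
    (S^cst$tud_s_exp + cst$tud_g_weight * G^cst$tud_g_exp)) - cst$tud_offset
}

#' @rdname m_tud
#' @param s an absolute [spd()].
#' @param bundle an [load_bundle()] observer bundle.
#' @export
m_tud_from_spectrum <- function(s, bundle, constants = brightness_constants()) {
  e <- on_bundle_grid(s, bundle)
  r <- signal_ratios(e, bundle)
  m_tud(photopic_illuminance(s, bundle), r$sv, r$mel, constants)
}
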
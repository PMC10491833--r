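# shared fixtures: one observer bundle, cached ensembles, reference spectra

.fixtures <- new.env(parent = emptyenv())

the_bundle <- function() {
  if (is.null(.fixtures$bundle)) .fixtures$bundle <- load_bundle()
  .fixtures$bundle
}

# small ensemble for unit tests
small_ensemble <- function(seed = 11) {
  key <- paste0("small_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_ensemble(
      ensemble_config(seed = seed, n_incandescent = 4, n_fluorescent = 6,
                      n_led = 6, n_daylight = 4),
      the_bundle())
  .fixtures[[key]]
}

# the default 884-spectrum study ensemble + pooled metric table (cached; the
# acceptance checks all run on this one realization, seed 1)
default_run <- function() {
  if (is.null(.fixtures$default_run)) {
    t0 <- proc.time()[["elapsed"]]
    ens <- generate_ensemble(ensemble_config(seed = 1), the_bundle())
    tab <- compute_metric_table(ens$spectra, bundle = the_bundle())
    .fixtures$default_run <- list(ensemble = ens, table = tab,
                                  elapsed = proc.time()[["elapsed"]] - t0)
  }
  .fixtures$default_run
}

d65_spd <- function() daylight_spd(6500 * 1.4388 / 1.4380)

gaussian_band_for_tests <- function(grid, center, fwhm)
  exp(-4 * log(2) * ((grid - center) / fwhm)^2)

circlight_trapz_weights_for_tests <- function(x) {
  n <- length(x); dx <- diff(x)
  c(dx[1], dx[-1] + dx[-(n - 1)], dx[n - 1]) / 2
}

# trapezoidal integral of a spectrum against a bundle member
attr_integral <- function(s, member, bundle) {
  e <- resample_spd(s, bundle$grid)$irradiance
  sum(circlight_trapz_weights_for_tests(bundle$grid) * e * bundle[[member]]$values)
}

illuminant_a <- function(lux, bundle = the_bundle())
  scale_to_illuminance(planckian_spd(2856), lux, bundle)
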
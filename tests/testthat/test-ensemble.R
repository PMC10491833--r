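test_that("parametric families produce valid spectra", {
  b <- the_bundle()
  led <- synth_spd("led", list(blue_peak = 450, blue_fwhm = 20,
                               phos_center = 570, phos_fwhm = 100, ratio = 2))
  expect_true(all(led$irradiance >= 0))
  # two local maxima: blue pump and phosphor hump
  y <- led$irradiance
  ismax <- which(diff(sign(diff(y))) == -2) + 1
  expect_equal(length(ismax), 2)
  expect_equal(led$source_class, "led")

  expect_error(synth_spd("daylight", list(cct = 3500)), "4000")
  dd <- synth_spd("daylight", list(cct = 6504))
  xy <- chromaticity(dd, b)
  expect_equal(unname(xy["x"]), 0.3127, tolerance = 1e-3)
  expect_equal(unname(xy["y"]), 0.3290, tolerance = 1e-3)

  fl <- synth_spd("fluorescent",
                  list(line_weights = c(0.1, 0.6, 0.7, 0.4),
                       bands = data.frame(center = 570, fwhm = 110, weight = 1)))
  expect_true(all(fl$irradiance >= 0))
  # the 546 nm mercury line sits on top of the phosphor band
  expect_gt(fl$irradiance[fl$grid == 546], fl$irradiance[fl$grid == 530])

  filt <- synth_spd("planckian",
                    list(T = 2856, filter = list(cutoff = 550, width = 30,
                                                 floor = 0.4, direction = "longpass")))
  plain <- synth_spd("planckian", list(T = 2856))
  expect_gt(cct_duv(plain, b)$cct / cct_duv(filt, b)$cct, 1)  # longpass reddens
})

test_that("the generator honours counts, ranges, Duv bound and the seed", {
  b <- the_bundle()
  ens <- small_ensemble()
  m <- ens$manifest
  expect_equal(as.vector(table(factor(m$source_class,
    c("incandescent", "fluorescent", "led", "daylight")))), c(4, 6, 6, 4))
  expect_equal(length(ens$spectra), 20)
  cfg <- ensemble_config(seed = 11, n_incandescent = 4, n_fluorescent = 6,
                         n_led = 6, n_daylight = 4)
  for (cl in unique(m$source_class)) {
    r <- cfg$cct_ranges[[cl]]
    expect_true(all(m$cct[m$source_class == cl] >= r[1] &
                    m$cct[m$source_class == cl] <= r[2]))
  }
  expect_true(all(m$cct >= 2201 & m$cct <= 17815))
  expect_true(all(abs(m$duv) <= cfg$duv_max))
  # same seed, same ensemble, bit for bit
  again <- generate_ensemble(cfg, b)
  expect_identical(again$manifest, m)
  expect_identical(again$spectra[[5]]$irradiance, ens$spectra[[5]]$irradiance)
  # different seed, different draws
  other <- generate_ensemble(ensemble_config(seed = 12, n_incandescent = 4,
                                             n_fluorescent = 6, n_led = 6,
                                             n_daylight = 4), b)
  expect_false(identical(other$manifest$cct, m$cct))
})

test_that("config validation rejects impossible requests", {
  expect_error(ensemble_config(seed = 1, n_led = -3), "non-negative")
  expect_error(ensemble_config(seed = 1,
    cct_ranges = list(incandescent = c(1500, 3000), fluorescent = c(2500, 7500),
                      led = c(2201, 10000), daylight = c(4000, 17815))),
    "global")
  expect_error(ensemble_config(seed = "a"), "number")
})

test_that("generated spectra cover both opponent-channel signs", {
  b <- the_bundle()
  ens <- small_ensemble()
  signs <- vapply(ens$spectra, function(s)
    sign(opponent_by(scale_to_illuminance(s, 500, b), b, "2021")), 0)
  expect_true(any(signs < 0) && any(signs > 0))
})
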
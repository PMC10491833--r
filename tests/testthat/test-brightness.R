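test_that("the ratio entry path reproduces the published equiluminance table", {
  # reference condition 108 lx and the two test conditions
  expect_equal(m_tud(108, 0.27, 0.14), 55.32, tolerance = 0.01)
  expect_equal(m_tud(94, 3.29, 1.13), 62.15, tolerance = 0.01)
  expect_equal(m_tud(125, 0.27, 0.14), 58.27, tolerance = 0.01)
  # relative brightness differences of the two equiluminant pairs
  d1 <- 100 * (m_tud(94, 3.29, 1.13) / m_tud(108, 0.27, 0.14) - 1)
  d2 <- 100 * (m_tud(125, 0.27, 0.14) / m_tud(108, 3.29, 1.13) - 1)
  expect_equal(d1, 12.3, tolerance = 0.5 / 12.3)
  expect_equal(d2, -10.5, tolerance = 0.5 / 10.5)
})

test_that("the TUD model is monotone with the printed zero-light limit", {
  expect_equal(m_tud(0, 0.27, 0.14), -1.3307)
  ev <- c(10, 50, 100, 500, 1000)
  expect_true(all(diff(m_tud(ev, 0.5, 0.5)) > 0))
  rs <- seq(0.1, 3, length.out = 20)
  expect_true(all(diff(m_tud(200, rs, 0.5)) > 0))
  expect_true(all(diff(m_tud(200, 0.5, rs)) > 0))
  expect_error(m_tud(100, 0, 0.5), "positive")
  expect_error(m_tud(-5, 0.5, 0.5), "non-negative")
})

test_that("B2 is a linear brightness signal", {
  b <- the_bundle()
  s1 <- scale_to_illuminance(daylight_spd(6504), 300, b)
  s2 <- illuminant_a(200)
  expect_equal(b2_bullough(spd(380:780, rep(0, 401)), b), 0)
  both <- spd(380:780, s1$irradiance + s2$irradiance)
  expect_equal(b2_bullough(both, b),
               b2_bullough(s1, b) + b2_bullough(s2, b), tolerance = 1e-12)
  # g = 0 drops exactly the S-cone term
  w <- 0.6 * 1 * attr_integral(s1, "S_cone", b)
  expect_equal(b2_bullough(s1, b, g = 0), b2_bullough(s1, b, g = 1) - w,
               tolerance = 1e-9)
  expect_error(b2_bullough(s1, b, g = -1), "non-negative")
})

test_that("equivalent luminance reduces to illuminance for equal-energy light", {
  b <- the_bundle()
  ee <- scale_to_illuminance(equal_energy_spd(), 400, b)
  expect_equal(leq_fotios(ee, b), 400, tolerance = 1e-9)
  d65 <- scale_to_illuminance(daylight_spd(6504), 500, b)
  expect_equal(leq_fotios(spd(d65$grid, 2 * d65$irradiance), b),
               2 * leq_fotios(d65, b), tolerance = 1e-12)
  # blue-rich daylight appears brighter than warm incandescent at equal E_v
  expect_gt(leq_fotios(d65, b), leq_fotios(illuminant_a(500), b))
  expect_error(leq_fotios(spd(380:780, rep(0, 401)), b), "zero")
})

test_that("equivalent luminance is perfectly correlated with E_v at fixed spectrum", {
  b <- the_bundle()
  s <- daylight_spd(5000)
  lv <- c(125, 300, 500, 750, 1000)
  leq <- vapply(lv, function(x) leq_fotios(scale_to_illuminance(s, x, b), b), 0)
  expect_equal(stats::cor(lv, leq)^2, 1, tolerance = 1e-12)
})

test_that("the spectrum entry path agrees with the ratio entry path", {
  b <- the_bundle()
  ee <- scale_to_illuminance(equal_energy_spd(), 300, b)
  # equal-energy light has unit ratios by convention
  expect_equal(m_tud_from_spectrum(ee, b), m_tud(300, 1, 1), tolerance = 1e-9)
  a <- illuminant_a(200)
  e <- a$irradiance
  w <- circlight_trapz_weights_for_tests(380:780)
  sv <- (sum(w * e * b$S_cone$values) / sum(w * e * b$V$values)) / b$sv_ee
  mel <- (sum(w * e * b$s_mel$values) / sum(w * e * b$V$values)) / b$mel_ee
  expect_equal(m_tud_from_spectrum(a, b),
               m_tud(photopic_illuminance(a, b), sv, mel), tolerance = 1e-9)
})
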
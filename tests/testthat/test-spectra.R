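test_that("SPD files round-trip and reject malformed input", {
  b <- the_bundle()
  path <- withr::local_tempfile(fileext = ".spd")
  s <- scale_to_illuminance(daylight_spd(5500), 300, b)
  write_spd(s, path)
  s2 <- read_spd(path)
  expect_equal(s2$grid, s$grid)
  expect_equal(s2$irradiance, s$irradiance, tolerance = 1e-6)
  expect_equal(s2$source_class, "daylight")

  zero <- withr::local_tempfile()
  writeLines(sprintf("%d\t0.0", 380:780), zero)
  z <- read_spd(zero)   # parser accepts the degenerate all-zero spectrum
  expect_true(all(z$irradiance == 0))
  expect_error(photopic_illuminance(z, b), NA)  # metrics reject it later where needed
  expect_error(scale_to_illuminance(z, 125, b), "zero")

  bad <- withr::local_tempfile()
  writeLines(c("400 1.0", "395 1.0", "410 1.0"), bad)
  expect_error(read_spd(bad), "increasing")

  neg <- withr::local_tempfile()
  writeLines(c("400 1.0", "405 -0.2", "410 1.0"), neg)
  expect_error(read_spd(neg), "row 2")
})

test_that("resampling is an identity on its own grid and preserves constants", {
  s <- planckian_spd(2856)
  expect_equal(resample_spd(s, s$grid)$irradiance, s$irradiance)
  const <- spd(seq(380, 780, 5), rep(2.5, 81))
  expect_equal(resample_spd(const, 400:700)$irradiance, rep(2.5, 301))
  expect_error(resample_spd(s, numeric(0)), "empty")
  # outside the source support the spectrum carries no energy
  wide <- resample_spd(spd(500:600, rep(1, 101)), 380:780)
  expect_true(all(wide$irradiance[wide$grid < 500 | wide$grid > 600] == 0))
  b <- the_bundle()
  e1 <- photopic_illuminance(planckian_spd(2856, 380:780), b)
  e5 <- photopic_illuminance(planckian_spd(2856, seq(380, 780, 5)), b)
  expect_lt(abs(e1 - e5) / e1, 5e-3)
})

test_that("photopic illuminance is the 683 lm/W weighted integral", {
  b <- the_bundle()
  expect_equal(photopic_illuminance(spd(380:780, rep(0, 401)), b), 0)
  s <- daylight_spd(6504)
  expect_equal(photopic_illuminance(spd(s$grid, 2 * s$irradiance), b),
               2 * photopic_illuminance(s, b))
  # 1 W m-2 nm-1 in a single 1 nm bin at the V peak
  spike <- spd(380:780, as.numeric(380:780 == 555))
  expect_equal(photopic_illuminance(spike, b), 683, tolerance = 1e-6)
})

test_that("scale_to_illuminance hits its target and is idempotent", {
  b <- the_bundle()
  s <- daylight_spd(8000)
  out <- scale_to_illuminance(s, 500, b)
  expect_equal(photopic_illuminance(out, b), 500, tolerance = 1e-9)
  expect_equal(out$irradiance,
               s$irradiance * (500 / photopic_illuminance(s, b)))
  twice <- scale_to_illuminance(out, 500, b)
  expect_equal(twice$irradiance, out$irradiance, tolerance = 1e-12)
  expect_error(scale_to_illuminance(s, -10, b), "positive")
})

test_that("chromaticity is scale-invariant", {
  b <- the_bundle()
  s <- daylight_spd(6504)
  expect_equal(chromaticity(s, b),
               chromaticity(spd(s$grid, 37.5 * s$irradiance), b),
               tolerance = 1e-12)
})
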
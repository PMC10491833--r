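test_that("bundle members have the documented peaks and ranges", {
  b <- the_bundle()
  expect_equal(max(b$V$values), 1, tolerance = 1e-12)
  expect_equal(b$grid[which.max(b$V$values)], 555)
  expect_equal(b$grid[which.max(b$Vprime$values)], 507)
  expect_equal(b$grid[which.max(b$s_mel$values)], 490)
  expect_equal(b$grid[which.max(b$S_cone$values)], 445)
  expect_true(all(b$mp$values > 0 & b$mp$values <= 1))
  # macular pigment absorbs short wavelengths, is transparent in the red
  mp460 <- b$mp$values[b$grid == 460]
  mp700 <- b$mp$values[b$grid == 700]
  expect_lt(mp460, mp700)
  expect_equal(mp700, 1)
  for (f in list(b$V, b$Vprime, b$S_cone, b$M_c, b$s_mel))
    expect_true(all(f$values >= 0))
})

test_that("bundle construction validates its grid", {
  expect_error(load_bundle(seq(300, 780, 5)), "360-830")
  expect_error(load_bundle(seq(380, 780, 10)), "at most 5")
  expect_error(load_bundle(c(400, 390, 410)), "increasing")
})

test_that("corrected_function divides by mp and renormalizes to peak 1", {
  b <- the_bundle()
  vc <- corrected_function(b$V, b$mp)
  expect_equal(max(vc$values), 1, tolerance = 1e-12)
  # identity transmittance: result is just the peak-normalized input
  one <- sensitivity_function("one", b$grid, rep(1, length(b$grid)), "as-published")
  expect_equal(corrected_function(b$V, one)$values, b$V$values / max(b$V$values))
  # mp < 1 at short wavelengths boosts the ratio relative to long wavelengths
  i460 <- which(b$grid == 460); i650 <- which(b$grid == 650)
  expect_gt(vc$values[i460] / b$V$values[i460],
            vc$values[i650] / b$V$values[i650])
  # idempotent up to scale: correcting an already-corrected function with
  # identity mp reproduces it
  expect_equal(corrected_function(vc, one)$values, vc$values)
  # applying the mp correction twice equals correcting by mp^2
  vcc <- corrected_function(vc, b$mp)
  mp2 <- sensitivity_function("mp2", b$grid, b$mp$values^2, "as-published")
  expect_equal(vcc$values, corrected_function(b$V, mp2)$values, tolerance = 1e-12)
  zeromp <- sensitivity_function("z", b$grid,
                                 c(0, rep(0.5, length(b$grid) - 1)), "as-published")
  expect_error(corrected_function(b$V, zeromp), "zero")
})

test_that("1 nm and 5 nm bundles agree to < 0.5 % for smooth spectra", {
  b1 <- the_bundle()
  b5 <- load_bundle(seq(380, 780, 5))
  s <- planckian_spd(2856)
  s1 <- scale_to_illuminance(s, 500, b1)
  s5 <- scale_to_illuminance(s, 500, b5)
  rel <- function(a, b) abs(a - b) / abs(a)
  expect_lt(rel(photopic_illuminance(s1, b1), photopic_illuminance(s5, b5)), 5e-3)
  expect_lt(rel(medi(s1, b1), medi(s5, b5)), 5e-3)
  expect_lt(rel(cla_2021(s1, b1)$value, cla_2021(s5, b5)$value), 5e-3)
  expect_lt(rel(cla_2018(s1, b1)$value, cla_2018(s5, b5)$value), 5e-3)
})

test_that("sensitivity_function enforces its invariants", {
  expect_error(sensitivity_function("f", c(400, 390), c(1, 1)), "increasing")
  expect_error(sensitivity_function("f", 380:780, rep(-1, 401)), "negative")
  expect_error(sensitivity_function("f", 400:780, rep(1, 381)), "380-780")
  expect_error(sensitivity_function("f", 380:780, rep(0.5, 401), "peak-1"), "peak-1")
})
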
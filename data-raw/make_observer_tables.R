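# Builds the plain-text observer tables shipped under inst/extdata/observers/.
# Run from the package root:  Rscript data-raw/make_observer_tables.R
#
# Sources (transcribed published tables / published template parameters):
#   - CIE 1924 photopic V(lambda)  == CIE 1931 y-bar, 5 nm steps
#   - CIE 1951 scotopic V'(lambda), 10 nm steps plus the 505/507 nm peak rows
#   - CIE 1931 2-deg colour-matching functions x-bar, y-bar, z-bar, 5 nm
#   - CIE daylight components S0, S1, S2, 10 nm
#   - Govardovskii et al. (2000) A1 visual-pigment template (alpha + beta band)
#   - Crystalline-lens optical density, young standard observer (anchor table)
#   - Macular pigment relative density, 2-deg central field (anchor table),
#     peak optical density 0.32 at ~458-460 nm, zero above 534 nm
#
# Derived tables written at 1 nm:
#   - melanopsin_lens_corrected.txt : pigment template (lambda_max 480 nm,
#     quantal basis) x lens transmittance, peak-normalized.  The circadian
#     light model's defining normalization (CL_A = 1000 for CIE illuminant A
#     at 1000 photopic lux, warm branch, 1548 * integral) is checked and
#     printed; it holds within 1.5 % and is almost insensitive to the
#     lens-density scale because of the peak renormalization.
#   - melanopic_s026_type.txt : same pigment template converted to energy
#     basis (x lambda/480) x unscaled lens transmittance, peak-normalized
#     (CIE S 026-type melanopic action spectrum; peak near 490 nm).

wl5 <- seq(380, 780, by = 5)

ybar <- c(
  0.000039, 0.000064, 0.000120, 0.000217, 0.000396, 0.000640, 0.001210,
  0.002180, 0.004000, 0.007300, 0.011600, 0.016840, 0.023000, 0.029800,
  0.038000, 0.048000, 0.060000, 0.073900, 0.090980, 0.112600, 0.139020,
  0.169300, 0.208020, 0.258600, 0.323000, 0.407300, 0.503000, 0.608200,
  0.710000, 0.793200, 0.862000, 0.914850, 0.954000, 0.980300, 0.994950,
  1.000000, 0.995000, 0.978600, 0.952000, 0.915400, 0.870000, 0.816300,
  0.757000, 0.694900, 0.631000, 0.566800, 0.503000, 0.441200, 0.381000,
  0.321000, 0.265000, 0.217000, 0.175000, 0.138200, 0.107000, 0.081600,
  0.061000, 0.044580, 0.032000, 0.023200, 0.017000, 0.011920, 0.008210,
  0.005723, 0.004102, 0.002929, 0.002091, 0.001484, 0.001047, 0.000740,
  0.000520, 0.000361, 0.000249, 0.000172, 0.000120, 0.000085, 0.000060,
  0.000042, 0.000030, 0.000021, 0.000015)

xbar <- c(
  0.001368, 0.002236, 0.004243, 0.007650, 0.014310, 0.023190, 0.043510,
  0.077630, 0.134380, 0.214770, 0.283900, 0.328500, 0.348280, 0.348060,
  0.336200, 0.318700, 0.290800, 0.251100, 0.195360, 0.142100, 0.095640,
  0.057950, 0.032010, 0.014700, 0.004900, 0.002400, 0.009300, 0.029100,
  0.063270, 0.109600, 0.165500, 0.225750, 0.290400, 0.359700, 0.433450,
  0.512050, 0.594500, 0.678400, 0.762100, 0.842500, 0.916300, 0.978600,
  1.026300, 1.056700, 1.062200, 1.045600, 1.002600, 0.938400, 0.854450,
  0.751400, 0.642400, 0.541900, 0.447900, 0.360800, 0.283500, 0.218700,
  0.164900, 0.121200, 0.087400, 0.063600, 0.046770, 0.032900, 0.022700,
  0.015840, 0.011359, 0.008111, 0.005790, 0.004109, 0.002899, 0.002049,
  0.001440, 0.001000, 0.000690, 0.000476, 0.000332, 0.000235, 0.000166,
  0.000117, 0.000083, 0.000059, 0.000042)

zbar <- c(
  0.006450, 0.010550, 0.020050, 0.036210, 0.067850, 0.110200, 0.207400,
  0.371300, 0.645600, 1.039050, 1.385600, 1.622960, 1.747060, 1.782600,
  1.772110, 1.744100, 1.669200, 1.528100, 1.287640, 1.041900, 0.812950,
  0.616200, 0.465180, 0.353300, 0.272000, 0.212300, 0.158200, 0.111700,
  0.078250, 0.057250, 0.042160, 0.029840, 0.020300, 0.013400, 0.008750,
  0.005750, 0.003900, 0.002750, 0.002100, 0.001800, 0.001650, 0.001400,
  0.001100, 0.001000, 0.000800, 0.000600, 0.000340, 0.000240, 0.000190,
  0.000100, 0.000050, 0.000030, 0.000020, 0.000010, rep(0, 27))

stopifnot(length(ybar) == length(wl5), length(xbar) == length(wl5),
          length(zbar) == length(wl5))

vprime_tab <- matrix(c(
  380, 0.000589,  390, 0.002209,  400, 0.009290,  410, 0.034840,
  420, 0.096600,  430, 0.199800,  440, 0.328100,  450, 0.455000,
  460, 0.567000,  470, 0.676000,  480, 0.793000,  490, 0.904000,
  500, 0.982000,  505, 0.998000,  507, 1.000000,  510, 0.997000,
  520, 0.935000,  530, 0.811000,  540, 0.650000,  550, 0.481000,
  560, 0.328800,  570, 0.207600,  580, 0.121200,  590, 0.065500,
  600, 0.033150,  610, 0.015930,  620, 0.007370,  630, 0.003335,
  640, 0.001497,  650, 0.000677,  660, 0.000313,  670, 0.000148,
  680, 0.000072,  690, 0.000035,  700, 0.000018,  710, 0.000009,
  720, 0.000005,  730, 0.000003,  740, 0.000001,  750, 0.000001,
  760, 0.000000,  770, 0.000000,  780, 0.000000), ncol = 2, byrow = TRUE)

wl10 <- seq(380, 780, by = 10)
S0 <- c(63.40, 65.80, 94.80, 104.80, 105.90, 96.80, 113.90, 125.60, 125.50,
        121.30, 121.30, 113.50, 113.10, 110.80, 106.50, 108.80, 105.30,
        104.40, 100.00, 96.00, 95.10, 89.10, 90.50, 90.30, 88.40, 84.00,
        85.10, 81.90, 82.60, 84.90, 81.30, 71.90, 74.30, 76.40, 63.30,
        71.70, 77.00, 65.20, 47.70, 68.60, 65.00)
S1 <- c(38.50, 35.00, 43.40, 46.30, 43.90, 37.10, 36.70, 35.90, 32.60,
        27.90, 24.30, 20.10, 16.20, 13.20, 8.60, 6.10, 4.20, 1.90, 0.00,
        -1.60, -3.50, -3.50, -5.80, -7.20, -8.60, -9.50, -10.90, -10.70,
        -12.00, -14.00, -13.60, -12.00, -13.30, -12.90, -10.60, -11.60,
        -12.20, -10.20, -7.80, -11.20, -10.40)
S2 <- c(3.00, 1.20, -1.10, -0.50, -0.70, -1.20, -2.60, -2.90, -2.80, -2.60,
        -2.60, -1.80, -1.50, -1.30, -1.20, -1.00, -0.50, -0.30, 0.00, 0.20,
        0.50, 2.10, 3.20, 4.10, 4.70, 5.10, 6.70, 7.30, 8.60, 9.80, 10.20,
        8.30, 9.60, 8.50, 7.00, 7.60, 8.00, 6.70, 5.20, 7.40, 6.80)
stopifnot(length(S0) == length(wl10), length(S1) == length(wl10),
          length(S2) == length(wl10))

# crystalline-lens optical density anchors (young standard observer)
lens_anchor <- matrix(c(
  380, 2.10,  390, 1.50,  400, 1.06,  410, 0.80,  420, 0.62,  430, 0.47,
  440, 0.36,  450, 0.29,  460, 0.24,  470, 0.20,  480, 0.17,  490, 0.15,
  500, 0.13,  520, 0.10,  540, 0.08,  560, 0.065, 580, 0.05,  600, 0.04,
  650, 0.02,  700, 0.01,  780, 0.00), ncol = 2, byrow = TRUE)

# macular pigment relative optical density anchors (2-deg central field)
mac_anchor <- matrix(c(
  380, 0.25,  390, 0.30,  400, 0.35,  410, 0.41,  420, 0.52,  430, 0.64,
  440, 0.80,  450, 0.95,  455, 0.99,  458, 1.00,  460, 0.99,  465, 0.93,
  470, 0.85,  475, 0.80,  480, 0.74,  485, 0.61,  490, 0.44,  495, 0.32,
  500, 0.22,  510, 0.11,  520, 0.05,  530, 0.01,  534, 0.00, 780, 0.00),
  ncol = 2, byrow = TRUE)
# Effective peak optical density of the macular transmittance used in the
# opponent terms.  Full central-field Snodderly-type densities (~0.3+) put
# the 2018 opponent switch below 2856 K, which contradicts the model's own
# printed calibration (CL_A = 1000 for illuminant A requires the warm branch
# at 2856 K) and the stated empirical warm/cold boundary; 0.10 places the
# 2018 switch at ~3010 K and the 2021 switch at ~3370 K, consistent with
# both printed properties.  See the methods vignette.
mac_peak_density <- 0.10

wl1 <- 380:780

# monotone-safe interpolation helpers
lin <- function(x, y, xout) approx(x, y, xout = xout, rule = 2)$y
trapz1 <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Govardovskii A1 pigment template, quantal sensitivity, lambda_max in nm
pigment_template <- function(wl, lmax) {
  x <- lmax / wl
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  d <- -40.5 + 0.195 * lmax
  beta <- 0.26 * exp(-((wl - lmb) / d)^2)
  alpha + beta
}

lens_density <- lin(lens_anchor[, 1], lens_anchor[, 2], wl1)
lens_density[lens_density < 0] <- 0
mac_shape <- lin(mac_anchor[, 1], mac_anchor[, 2], wl1)
mac_shape[wl1 > 534] <- 0
mac_shape[mac_shape < 0] <- 0
mp <- 10^(-mac_peak_density * mac_shape)

pig480 <- pigment_template(wl1, 480)

# -- melanopic action spectrum (S 026-type): energy basis, unscaled lens
smel <- pig480 * (wl1 / 480) * 10^(-lens_density)
smel <- smel / max(smel)
cat(sprintf("s_mel peak at %d nm\n", wl1[which.max(smel)]))

# -- melanopsin channel M_c: quantal basis x tabulated lens transmittance
V1 <- lin(wl5, ybar, wl1)
planck <- function(wl, TK) wl^-5 / (exp(1.4388e7 / (wl * TK)) - 1)
EA <- planck(wl1, 2856)
EA <- EA * 1000 / (683 * trapz1(wl1, EA * V1))      # illuminant A at 1000 lx

mc <- pig480 * 10^(-lens_density)
mc <- mc / max(mc)
cat(sprintf("M_c peak at %d nm; CL_A(A @ 1000 lx) = %.3f\n",
            wl1[which.max(mc)], 1548 * trapz1(wl1, mc * EA)))

# ---------------------------------------------------------------- output ----
out_dir <- file.path("inst", "extdata", "observers")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

write_tab <- function(file, header, wl, ...) {
  cols <- list(...)
  txt <- c(paste("#", header),
           apply(cbind(wl, do.call(cbind, cols)), 1, function(r)
             paste(formatC(r, format = "g", digits = 8), collapse = "\t")))
  writeLines(txt, file.path(out_dir, file))
}

write_tab("vlambda_photopic_1924.txt",
          "CIE 1924 photopic luminous efficiency V(lambda), 5 nm, peak 1 at 555 nm",
          wl5, ybar)
write_tab("vprime_scotopic_1951.txt",
          "CIE 1951 scotopic luminous efficiency V'(lambda), 10 nm (+505/507 nm), peak 1 at 507 nm",
          vprime_tab[, 1], vprime_tab[, 2])
write_tab("scone_zbar_based.txt",
          "S-cone fundamental, Smith-Pokorny-type: peak-normalized CIE 1931 z-bar (S prop. to Judd z-bar)",
          wl5, zbar / max(zbar))
write_tab("cmf_xbar_1931.txt", "CIE 1931 2-deg colour-matching function x-bar, 5 nm",
          wl5, xbar)
write_tab("cmf_ybar_1931.txt", "CIE 1931 2-deg colour-matching function y-bar, 5 nm",
          wl5, ybar)
write_tab("cmf_zbar_1931.txt", "CIE 1931 2-deg colour-matching function z-bar, 5 nm",
          wl5, zbar)
write_tab("daylight_components_cie.txt",
          "CIE daylight components S0 S1 S2, 10 nm (columns: nm, S0, S1, S2)",
          wl10, S0, S1, S2)
write_tab("lens_density_young.txt",
          "Crystalline-lens optical density, young standard observer (anchor-interpolated, 1 nm)",
          wl1, lens_density)
write_tab("macular_transmittance_snodderly_type.txt",
          sprintf("Macular pigment transmittance, 2-deg field, peak optical density %.2f near 458 nm, unity above 534 nm", mac_peak_density),
          wl1, mp)
write_tab("melanopsin_lens_corrected.txt",
          "Melanopsin sensitivity M_c: A1 pigment template lambda_max 480 nm (quantal) x crystalline-lens transmittance, peak-normalized, 1 nm",
          wl1, mc)
write_tab("melanopic_s026_type.txt",
          "Melanopic action spectrum (S 026-type): A1 pigment template lambda_max 480 nm, energy basis, x lens transmittance, peak-normalized, 1 nm",
          wl1, smel)

# ------------------------------------------------------------ sanity log ----
x1 <- lin(wl5, xbar, wl1); z1 <- lin(wl5, zbar, wl1)
d65cct <- 6500 * 1.4388 / 1.4380
xd <- 0.244063 + 0.09911e3 / d65cct + 2.9678e6 / d65cct^2 - 4.6070e9 / d65cct^3
yd <- -3.000 * xd^2 + 2.870 * xd - 0.275
M1 <- (-1.3515 - 1.7703 * xd + 5.9114 * yd) / (0.0241 + 0.2562 * xd - 0.7341 * yd)
M2 <- (0.0300 - 31.4424 * xd + 30.0717 * yd) / (0.0241 + 0.2562 * xd - 0.7341 * yd)
d65 <- lin(wl10, S0, wl1) + M1 * lin(wl10, S1, wl1) + M2 * lin(wl10, S2, wl1)
X <- trapz1(wl1, d65 * x1); Y <- trapz1(wl1, d65 * V1); Z <- trapz1(wl1, d65 * z1)
cat(sprintf("D65 reconstruction chromaticity: x = %.4f, y = %.4f (target 0.3127, 0.3290)\n",
            X / (X + Y + Z), Y / (X + Y + Z)))
d65n <- d65 / (683 * trapz1(wl1, d65 * V1))          # D65 at 1 lx
cat(sprintf("melanopic irradiance of D65 at 1 lx: %.4f mW m-2 (published 1.3262)\n",
            1000 * trapz1(wl1, d65n * smel)))
EA1 <- EA / 1000
cat(sprintf("melanopic DER of illuminant A: %.4f (published ~0.54)\n",
            trapz1(wl1, EA1 * smel) / trapz1(wl1, d65n * smel)))
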
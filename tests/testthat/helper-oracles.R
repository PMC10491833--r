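# independent oracles: separate code paths written directly from the printed
# model definitions, reading the bundled tables themselves

oracle_tables_dir <- function()
  system.file("extdata", "observers", package = "circlight")

oracle_read <- function(file, grid, fill = 0) {
  tab <- utils::read.table(file.path(oracle_tables_dir(), file))
  y <- approx(tab[[1]], tab[[2]], xout = grid, rule = if (fill == 1) 2 else 1)$y
  y[is.na(y)] <- fill
  y
}

# plain trapezoid written out longhand (independent of trapz_weights/pracma)
oracle_int <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * (x[-1] - x[-n])) / 2
}

# brute-force transcription of the 2021 circadian-light formula
oracle_cla_2021 <- function(s, grid = 380:780) {
  e <- approx(s$grid, s$irradiance, xout = grid, rule = 1)$y
  e[is.na(e)] <- 0
  V   <- oracle_read("vlambda_photopic_1924.txt", grid);  V  <- V / max(V)
  Vp  <- oracle_read("vprime_scotopic_1951.txt", grid);   Vp <- Vp / max(Vp)
  S   <- oracle_read("scone_zbar_based.txt", grid);       S  <- S / max(S)
  Mc  <- oracle_read("melanopsin_lens_corrected.txt", grid); Mc <- Mc / max(Mc)
  mp  <- oracle_read("macular_transmittance_snodderly_type.txt", grid, fill = 1)
  Vc  <- (V / mp) / max(V / mp)
  Sc  <- (S / mp) / max(S / mp)
  k <- 0.2616; RodSat <- 6.5
  imc <- oracle_int(grid, Mc * e)
  ivp <- oracle_int(grid, Vp * e)
  ivc <- oracle_int(grid, Vc * e)
  isc <- oracle_int(grid, Sc * e)
  ivmp <- oracle_int(grid, V * e / mp)
  sat <- 1 - exp(-ivp / RodSat)
  rod <- function(g) (ivp / (ivc + g * isc)) * sat
  by <- isc - k * ivc
  if (by > 0)
    1548 * (imc - 2.3 * rod(1.00) + 0.21 * (isc - k * ivmp) - 1.60 * rod(0.16))
  else
    1548 * (imc - 2.3 * rod(1.00))
}

# closed-form normal-equation OLS for y ~ 1 + x
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       rmse = sqrt(mean(res^2)))
}

# fine-grid Planckian locus search, independent of the package's bracketed
# minimization; 1 K steps
oracle_cct <- function(s, t_range, grid = 380:780) {
  e <- approx(s$grid, s$irradiance, xout = grid, rule = 1)$y
  e[is.na(e)] <- 0
  xbar <- oracle_read("cmf_xbar_1931.txt", grid)
  ybar <- oracle_read("cmf_ybar_1931.txt", grid)
  zbar <- oracle_read("cmf_zbar_1931.txt", grid)
  uv <- function(sp) {
    X <- oracle_int(grid, sp * xbar); Y <- oracle_int(grid, sp * ybar)
    Z <- oracle_int(grid, sp * zbar)
    c(4 * X, 6 * Y) / (X + 15 * Y + 3 * Z)
  }
  target <- uv(e)
  TT <- seq(t_range[1], t_range[2], by = 1)
  d2 <- vapply(TT, function(TK) {
    p <- grid^-5 / (exp(1.4388e7 / (grid * TK)) - 1)
    sum((uv(p) - target)^2)
  }, 0)
  TT[which.min(d2)]
}
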
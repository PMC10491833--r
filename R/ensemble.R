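# seeded synthetic stand-in for the measured 884-source corpus

#' Configuration of the synthetic light-source ensemble
#'
#' Defaults mirror the composition of the analysed corpus: 28 incandescent
#' (plain and filtered thermal radiators), 252 fluorescent, 419 LED and 185
#' daylight spectra — 884 in total — with correlated colour temperatures
#' confined to 2201--17815 K overall and |Duv| <= 0.0153. CCT targets are
#' sampled log-uniformly within each class range (the measured corpus' CCT
#' histogram is unknown; this is a documented stand-in assumption).
#'
#' @param seed integer RNG seed; mandatory so every ensemble is reproducible.
#' @param n_incandescent,n_fluorescent,n_led,n_daylight class counts (>= 0).
#' @param cct_ranges named list of per-class CCT sampling ranges (K), each
#'   within the global range.
#' @param cct_global global admissible CCT range (K).
#' @param duv_max admissible |Duv| for a generated spectrum.
#' @param grid wavelength grid in nm.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(seed,
                            n_incandescent = 28, n_fluorescent = 252,
                            n_led = 419, n_daylight = 185,
                            cct_ranges = list(incandescent = c(2201, 3250),
                                              fluorescent  = c(2500, 7500),
                                              led          = c(2201, 10000),
                                              daylight     = c(4000, 17815)),
                            cct_global = c(2201, 17815),
                            duv_max = 0.0153,
                            grid = 380:780) {
  stop_if_not_scalar_number(seed, "seed")
  counts <- c(incandescent = n_incandescent, fluorescent = n_fluorescent,
              led = n_led, daylight = n_daylight)
  if (any(counts < 0)) stop("class counts must be non-negative")
  for (cl in names(cct_ranges)) {
    r <- cct_ranges[[cl]]
    if (r[1] < cct_global[1] || r[2] > cct_global[2])
      stop(sprintf("class '%s' CCT range exceeds the global range", cl))
  }
  structure(list(seed = as.integer(seed), counts = counts,
                 cct_ranges = cct_ranges, cct_global = cct_global,
                 duv_max = duv_max, grid = grid),
            class = "ensemble_config")
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat(sprintf("<ensemble_config> seed %d, %d spectra (%s), CCT %g-%g K, |Duv| <= %g\n",
              x$seed, sum(x$counts),
              paste(sprintf("%s %d", names(x$counts), x$counts), collapse = ", "),
              x$cct_global[1], x$cct_global[2], x$duv_max))
  invisible(x)
}

runif1 <- function(lo, hi) stats::runif(1, lo, hi)
rlog_cct <- function(range) exp(runif1(log(range[1]), log(range[2])))

# solve the scalar cool/warm mix `r` so that cct(cool*r + warm) hits target;
# returns NULL when the target is not bracketed by the component pair
solve_mix_ratio <- function(cool, warm, target, grid, bundle) {
  cct_of <- function(logr) {
    e <- 10^logr * cool + warm
    cct_duv(spd(grid, e / max(e)), bundle)$cct - target
  }
  flo <- cct_of(-3); fhi <- cct_of(3)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NULL)
  r <- stats::uniroot(cct_of, c(-3, 3), tol = 1e-4)$root
  10^r
}

draw_led_params <- function(target) {
  phos_lo <- if (target < 3500) 590 else if (target < 6000) 560 else 540
  list(blue_peak = runif1(440, 460), blue_fwhm = runif1(16, 24),
       phos_center = runif1(phos_lo, phos_lo + 45),
       phos_fwhm = runif1(80, 120))
}

# canonical fluorescent phosphor chemistries: triphosphor lamps (europium /
# cerium narrow emitters near 450 / 543 / 611 nm) and halophosphate-like
# lamps (broad bands with a blue shoulder; built from ~2700 K warm white up
# to ~5000 K only, their canonical chemistry range); the blue and red band
# weights are later solved linearly for an exact target chromaticity
draw_fluor_params <- function(target_cct) {
  if (target_cct > 5000 || stats::runif(1) < 0.7) {
    list(type = "triphosphor",
         line_weights = c(runif1(0.05, 0.25), runif1(0.2, 0.6),
                          runif1(0.2, 0.6), runif1(0.1, 0.4)),
         blue  = list(center = runif1(445, 455), fwhm = runif1(45, 55)),
         green = list(center = runif1(540, 546), fwhm = runif1(25, 35)),
         red   = list(center = runif1(609, 613), fwhm = runif1(8, 15)))
  } else {
    list(type = "halophosphate",
         line_weights = c(runif1(0.05, 0.25), runif1(0.15, 0.45),
                          runif1(0.15, 0.45), runif1(0.1, 0.3)),
         blue  = list(center = runif1(475, 488), fwhm = runif1(50, 70)),
         green = list(center = runif1(565, 585), fwhm = runif1(100, 130)),
         red   = list(center = runif1(615, 635), fwhm = runif1(60, 90)))
  }
}

# target chromaticity on (or offset from) the Planckian locus: locus point at
# `TK` displaced by `duv` along the locus normal (positive above the locus)
locus_target_xy <- function(bundle, TK, duv) {
  p0 <- bundle$locus$uv_of_T(TK)
  p1 <- bundle$locus$uv_of_T(TK * 1.001)
  tg <- p1 - p0; tg <- tg / sqrt(sum(tg^2))
  nrm <- c(-tg[2], tg[1])
  if (nrm[2] < 0) nrm <- -nrm                      # point toward +v
  uv <- unname(p0 + duv * nrm)
  d <- 2 * uv[1] - 8 * uv[2] + 4
  c(x = 3 * uv[1] / d, y = 2 * uv[2] / d)
}

# solve non-negative weights (wb, wr) so that fixed + wb*blue + wr*red has
# chromaticity exactly (x_t, y_t); returns NULL when infeasible
solve_band_weights <- function(fixed, blue, red, xt, yt, bundle) {
  xt <- unname(xt); yt <- unname(yt)
  w <- trapz_weights(bundle$grid)
  XYZ <- function(e) c(sum(w * e * bundle$cmf$xbar), sum(w * e * bundle$cmf$ybar),
                       sum(w * e * bundle$cmf$zbar))
  pq <- function(e) { v <- XYZ(e); c(P = (1 - xt) * v[1] - xt * v[2] - xt * v[3],
                                     Q = -yt * v[1] + (1 - yt) * v[2] - yt * v[3]) }
  f <- pq(fixed); bl <- pq(blue); rd <- pq(red)
  A <- matrix(c(bl["P"], bl["Q"], rd["P"], rd["Q"]), 2, 2)
  if (abs(det(A)) < 1e-12) return(NULL)
  sol <- solve(A, -c(f["P"], f["Q"]))
  if (any(!is.finite(sol)) || any(sol <= 0)) return(NULL)
  sol
}

draw_filter_params <- function() {
  list(cutoff = runif1(460, 600), width = runif1(20, 60),
       floor = runif1(0.25, 0.8),
       direction = sample(c("longpass", "shortpass"), 1))
}

#' Generate the synthetic light-source ensemble
#'
#' Draws the configured number of spectra per technology class with a
#' resample-and-reject loop: a CCT target is sampled log-uniformly in the
#' class range, the family parameters are drawn, a scalar blue/warm mix is
#' solved by 1-D root search so the achieved CCT matches the target (LED,
#' fluorescent), and the spectrum is accepted only if its achieved CCT lies
#' inside both the class and global range and |Duv| is within bounds.
#' Identical `config` (including seed) yields a bit-identical ensemble.
#'
#' @param config an [ensemble_config()].
#' @param bundle an [load_bundle()] observer bundle on `config$grid`.
#' @param max_attempts rejection-loop bound per spectrum.
#' @return List with `spectra` (list of relative [spd()]s) and `manifest`
#'   (data.frame: id, source_class, family, cct_target, cct, duv).
#' @export
generate_ensemble <- function(config, bundle = load_bundle(config$grid),
                              max_attempts = 60) {
  stopifnot(inherits(config, "ensemble_config"))
  grid <- config$grid
  with_seed(config$seed, {
    spectra <- list()
    rows <- list()
    for (cl in names(config$counts)) {
      n <- config$counts[[cl]]
      if (n == 0) next
      rng <- config$cct_ranges[[cl]]
      for (i in seq_len(n)) {
        ok <- FALSE
        for (attempt in seq_len(max_attempts)) {
          target <- rlog_cct(rng)
          s <- switch(cl,
            incandescent = {
              if (stats::runif(1) < 0.5)
                synth_spd("planckian", list(T = target), grid)
              else
                synth_spd("planckian", c(list(T = target * runif1(0.9, 1.1)),
                                         list(filter = draw_filter_params())), grid)
            },
            led = {
              p <- draw_led_params(target)
              cool <- gaussian_band(grid, p$blue_peak, p$blue_fwhm)
              warm <- gaussian_band(grid, p$phos_center, p$phos_fwhm)
              r <- solve_mix_ratio(cool, warm, target, grid, bundle)
              if (is.null(r)) NULL
              else synth_spd("led", c(p, list(ratio = 1 / r)), grid)
            },
            fluorescent = {
              p <- draw_fluor_params(target)
              lines <- c(405, 436, 546, 578)
              fixed <- gaussian_band(grid, p$green$center, p$green$fwhm)
              for (j in 1:4)
                fixed <- fixed + p$line_weights[j] * exp(-((grid - lines[j]) / 2)^2 / 2)
              blue <- gaussian_band(grid, p$blue$center, p$blue$fwhm)
              red  <- gaussian_band(grid, p$red$center, p$red$fwhm)
              duv_t <- runif1(-0.012, 0.012)
              xy_t <- locus_target_xy(bundle, target, duv_t)
              sol <- solve_band_weights(fixed, blue, red, xy_t["x"], xy_t["y"], bundle)
              if (is.null(sol)) NULL
              else spd(grid, {e <- fixed + sol[1] * blue + sol[2] * red; e / max(e)},
                       source_class = "fluorescent",
                       metadata = list(family = "fluorescent", type = p$type,
                                       duv_target = duv_t))
            },
            daylight = synth_spd("daylight", list(cct = target), grid))
          if (is.null(s)) next
          cd <- cct_duv(s, bundle)
          in_range <- cd$cct >= max(rng[1], config$cct_global[1]) &&
            cd$cct <= min(rng[2], config$cct_global[2]) &&
            abs(cd$duv) <= config$duv_max
          if (in_range) {
            id <- sprintf("%s_%03d", cl, i)
            s$id <- id
            s$source_class <- cl
            spectra[[id]] <- s
            rows[[id]] <- data.frame(id = id, source_class = cl,
                                     family = s$metadata$family %||% cl,
                                     cct_target = target,
                                     cct = cd$cct, duv = cd$duv)
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop(sprintf("could not generate a '%s' spectrum near %0.f K after %d attempts",
                       cl, target, max_attempts))
      }
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    manifest$seed <- config$seed
    list(spectra = spectra, manifest = manifest)
  })
}
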
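# the correlation pipeline: metric table, r2 matrices, conversion fits,
# branch-discontinuity sweep, report

METRIC_COLUMNS <- c("E_v", "mEDI", "CL_A_2018", "CL_A_2021",
                    "CS_2018", "CS_2021", "gimenez_as_printed",
                    "L_eq", "M_TUD")

#' Compute the full metric table for a set of spectra
#'
#' Rescales every spectrum to each photopic illuminance level and evaluates
#' all metrics: mEDI, CL_A 1.0/2.0 with branch flag, CS_2018 and
#' CS_2021(t, f), the as-printed melatonin-suppression value (magnitude),
#' equivalent luminance and the TUD brightness model, together with the
#' spectrum's CCT/Duv and the sign of the 2021 opponent signal. Row order is
#' deterministic: spectra in input order, levels within spectrum. Spectra
#' with zero luminance are skipped with a warning.
#'
#' @param spectra list of [spd()] objects (relative or absolute).
#' @param levels photopic illuminance levels in lx, default `c(125, 500, 750)`.
#' @param t,f exposure time (h) and field factor for CS_2021.
#' @param duration,dilation exposure minutes and pupil flag for the
#'   suppression column.
#' @param bundle an [load_bundle()] observer bundle.
#' @param constants a [cla_constants()] list.
#' @return A data.frame of class `metric_table`, one row per
#'   spectrum x level.
#' @export
compute_metric_table <- function(spectra, levels = c(125, 500, 750),
                                 t = 1, f = 1.0, duration = 60, dilation = 0,
                                 bundle = load_bundle(),
                                 constants = cla_constants()) {
  if (!length(spectra)) stop("no spectra supplied")
  if (any(levels <= 0)) stop("illuminance levels must be positive")
  w <- trapz_weights(bundle$grid)
  rows <- vector("list", length(spectra) * length(levels))
  k <- 0L
  for (s in spectra) {
    e1 <- on_bundle_grid(s, bundle)
    ev1 <- 683 * sum(w * e1 * bundle$V$values)
    if (ev1 <= 0) {
      warning(sprintf("spectrum '%s' has zero luminance; skipped", s$id))
      next
    }
    cd <- cct_duv(spd(bundle$grid, e1, id = s$id), bundle)
    ii1 <- circadian_integrals(e1, bundle)
    sv  <- (ii1$is / ii1$iv) / bundle$sv_ee
    mel <- (ii1$ismel / ii1$iv) / bundle$mel_ee
    for (lev in levels) {
      sc <- lev / ev1
      ii <- lapply(ii1, `*`, sc)
      c18 <- cla_2018_from_integrals(ii, constants)
      c21 <- cla_2021_from_integrals(ii, constants)
      mEDI <- ii$ismel / bundle$d65_mel_per_lx
      k <- k + 1L
      rows[[k]] <- data.frame(
        id = s$id, source_class = s$source_class, level = lev,
        CCT = cd$cct, Duv = cd$duv,
        by_sign = sign(c21$by_signal),
        branch_2018 = c18$branch, branch_2021 = c21$branch,
        E_v = lev, mEDI = mEDI,
        CL_A_2018 = c18$value, CL_A_2021 = c21$value,
        CS_2018 = circadian_stimulus(max(c18$value, 0), 1, 1, constants),
        CS_2021 = circadian_stimulus(max(c21$value, 0), t, f, constants),
        gimenez_as_printed =
          gimenez_suppression(mEDI, duration, dilation)$magnitude,
        L_eq = lev * sv^0.24,
        M_TUD = m_tud(lev, sv, mel))
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  attr(out, "config") <- list(levels = levels, t = t, f = f,
                              duration = duration, dilation = dilation)
  class(out) <- c("metric_table", "data.frame")
  out
}

subset_rows <- function(table, subset, cct_threshold, partition_by = "cct") {
  sel <- switch(subset,
    all  = rep(TRUE, nrow(table)),
    warm = if (partition_by == "cct") table$CCT <= cct_threshold else table$by_sign <= 0,
    cold = if (partition_by == "cct") table$CCT >  cct_threshold else table$by_sign > 0,
    stop("unknown subset: ", subset))
  table[sel, , drop = FALSE]
}

#' Pairwise r2 matrices over metric-table subsets
#'
#' Pearson r2 for every metric pair, pooled across the illuminance levels
#' (or per level with `per_level = TRUE`), on the three subsets: all rows,
#' warm (CCT at or below the threshold) and cold (above). Partitioning can
#' alternatively use the actual sign of the 2021 opponent signal
#' (`partition_by = "by_sign"`); the two partitions can disagree near the
#' boundary for off-locus sources. A metric that is constant within a subset
#' yields `NA` (undefined correlation), never a silent 0.
#'
#' @param table a [compute_metric_table()] result.
#' @param metrics metric column names.
#' @param cct_threshold warm/cold partition boundary in K, default 3710.
#' @param partition_by `"cct"` or `"by_sign"`.
#' @param per_level if TRUE, return matrices per illuminance level.
#' @return Named list of symmetric r2 matrices (`all`, `warm`, `cold`), or a
#'   list of such lists when `per_level = TRUE`.
#' @export
pairwise_r2 <- function(table, metrics = METRIC_COLUMNS, cct_threshold = 3710,
                        partition_by = c("cct", "by_sign"), per_level = FALSE) {
  partition_by <- match.arg(partition_by)
  metrics <- intersect(metrics, names(table))
  if (per_level) {
    out <- lapply(split(as.data.frame(table), table$level), pairwise_r2,
                  metrics = metrics, cct_threshold = cct_threshold,
                  partition_by = partition_by, per_level = FALSE)
    return(out)
  }
  one <- function(subset) {
    d <- subset_rows(table, subset, cct_threshold, partition_by)
    if (nrow(d) < 3) stop(sprintf("subset '%s' has fewer than 3 rows", subset))
    m <- as.matrix(d[metrics])
    r2 <- suppressWarnings(stats::cor(m))^2
    r2[is.na(r2)] <- NA_real_     # constant column: undefined, not zero
    diag(r2) <- 1
    r2
  }
  list(all = one("all"), warm = one("warm"), cold = one("cold"))
}

#' Ordinary least-squares conversion fit between two metrics
#'
#' Fits `y_metric ~ x_metric` by OLS on the chosen subset, pooled across
#' illuminance levels; reports slope, intercept, Pearson r2 and the RMSE of
#' the response (root mean squared residual, y units).
#'
#' @inheritParams pairwise_r2
#' @param x_metric,y_metric metric column names.
#' @param subset `"all"`, `"warm"` or `"cold"`.
#' @return Object of class `metric_fit`.
#' @export
linear_fit <- function(table, x_metric, y_metric,
                       subset = c("all", "warm", "cold"),
                       cct_threshold = 3710,
                       partition_by = c("cct", "by_sign")) {
  subset <- match.arg(subset); partition_by <- match.arg(partition_by)
  d <- subset_rows(table, subset, cct_threshold, partition_by)
  if (nrow(d) < 3) stop("fewer than 3 rows in subset")
  x <- d[[x_metric]]; y <- d[[y_metric]]
  if (stats::sd(x) == 0) stop("degenerate fit: `x_metric` has zero variance")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  structure(list(x_metric = x_metric, y_metric = y_metric, subset = subset,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = unname(stats::cor(x, y)^2),
                 rmse = sqrt(mean(res^2)), n = length(x)),
            class = "metric_fit")
}

#' @export
print.metric_fit <- function(x, ...) {
  cat(sprintf("<metric_fit> %s = %.4f * %s %+.4f  [%s, n = %d, r2 = %.3f, RMSE = %.3f]\n",
              x$y_metric, x$slope, x$x_metric, x$intercept, x$subset, x$n,
              x$r2, x$rmse))
  invisible(x)
}

#' Branch-discontinuity sweep along the Planckian locus
#'
#' Evaluates the opponent signals, CL_A 1.0/2.0, CS_2018/CS_2021 and mEDI on
#' a Planckian CCT grid at a fixed illuminance level, locates the b-y
#' sign-change CCT for each model version, and reports the magnitude of each
#' metric's jump across the boundary pair of grid points. mEDI has no case
#' split and serves as the continuous control.
#'
#' @param cct_grid CCT grid in K, step at most 25 K.
#' @param level photopic illuminance in lx.
#' @param bundle an [load_bundle()] observer bundle.
#' @param t,f CS_2021 exposure parameters.
#' @param constants a [cla_constants()] list.
#' @return Object of class `discontinuity_sweep`: list with the per-CCT
#'   `table`, `boundary_cct` (per version; NA when no sign change in range)
#'   and `jumps`.
#' @export
discontinuity_sweep <- function(cct_grid = seq(2200, 8000, by = 25),
                                level = 500, bundle = load_bundle(),
                                t = 1, f = 1.0, constants = cla_constants()) {
  if (max(diff(cct_grid)) > 25) stop("CCT grid step must be at most 25 K")
  w <- trapz_weights(bundle$grid)
  rows <- lapply(cct_grid, function(TK) {
    e <- planck_rel(bundle$grid, TK)
    e <- e * level / (683 * sum(w * e * bundle$V$values))
    ii <- circadian_integrals(e, bundle)
    c18 <- cla_2018_from_integrals(ii, constants)
    c21 <- cla_2021_from_integrals(ii, constants)
    data.frame(cct = TK,
               by_2018 = c18$by_signal, by_2021 = c21$by_signal,
               CL_A_2018 = c18$value, CL_A_2021 = c21$value,
               CS_2018 = circadian_stimulus(max(c18$value, 0), 1, 1, constants),
               CS_2021 = circadian_stimulus(max(c21$value, 0), t, f, constants),
               mEDI = ii$ismel / bundle$d65_mel_per_lx)
  })
  tab <- do.call(rbind, rows)
  crossing <- function(by) {
    i <- which(sign(by[-1]) != sign(by[-length(by)]) & by[-length(by)] != 0 |
                 by[-length(by)] == 0 & by[-1] != 0)
    if (!length(i)) NA_integer_ else i[1]
  }
  i18 <- crossing(tab$by_2018); i21 <- crossing(tab$by_2021)
  jump <- function(col, i) if (is.na(i)) NA_real_ else abs(tab[[col]][i + 1] - tab[[col]][i])
  structure(list(
    table = tab, level = level,
    boundary_cct = c(v2018 = if (is.na(i18)) NA_real_ else mean(tab$cct[i18 + 0:1]),
                     v2021 = if (is.na(i21)) NA_real_ else mean(tab$cct[i21 + 0:1])),
    jumps = c(CS_2018 = jump("CS_2018", i18), CS_2021 = jump("CS_2021", i21),
              CL_A_2018 = jump("CL_A_2018", i18), CL_A_2021 = jump("CL_A_2021", i21),
              mEDI = jump("mEDI", i21))),
    class = "discontinuity_sweep")
}

#' @export
print.discontinuity_sweep <- function(x, ...) {
  cat(sprintf("<discontinuity_sweep> %d CCT points at %g lx\n", nrow(x$table), x$level))
  cat(sprintf("  b-y sign change: 2018 at %.0f K, 2021 at %.0f K\n",
              x$boundary_cct["v2018"], x$boundary_cct["v2021"]))
  cat("  jumps:", paste(sprintf("%s = %.4g", names(x$jumps), x$jumps), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble (and optionally write) the correlation report
#'
#' Bundles the r2 matrices computed from the metric table, the conversion
#' fits, the discontinuity-sweep summary and the configuration echo into one
#' report. With `out_dir`, writes `report.json` plus one CSV per r2 matrix;
#' the JSON serialization is deterministic, so identical inputs produce
#' byte-identical files.
#'
#' @param table a [compute_metric_table()] result.
#' @param fits list of [linear_fit()] results.
#' @param sweep a [discontinuity_sweep()] result.
#' @param cct_threshold partition boundary in K.
#' @param config configuration echo (seed, levels, ...), stored verbatim.
#' @param out_dir optional output directory.
#' @return Object of class `correlation_report` (invisibly when writing).
#' @export
build_report <- function(table, fits, sweep, cct_threshold = 3710,
                         config = list(), out_dir = NULL) {
  r2 <- pairwise_r2(table, cct_threshold = cct_threshold)
  report <- structure(list(
    config = c(config, attr(table, "config"),
               list(cct_threshold = cct_threshold, n_rows = nrow(table))),
    r2 = r2,
    fits = lapply(fits, unclass),
    sweep = list(level = sweep$level, boundary_cct = as.list(sweep$boundary_cct),
                 jumps = as.list(sweep$jumps))),
    class = "correlation_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    json <- jsonlite::toJSON(unclass(report), digits = NA, auto_unbox = TRUE,
                             na = "null", pretty = TRUE)
    writeLines(json, file.path(out_dir, "report.json"))
    for (nm in names(r2))
      utils::write.csv(round(r2[[nm]], 6),
                       file.path(out_dir, sprintf("r2_%s.csv", nm)))
    return(invisible(report))
  }
  report
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d rows, partition at %g K\n",
              x$config$n_rows, x$config$cct_threshold))
  cat(sprintf("  r2(CL_A_2021, mEDI): all %.3f, warm %.3f, cold %.3f\n",
              x$r2$all["CL_A_2021", "mEDI"], x$r2$warm["CL_A_2021", "mEDI"],
              x$r2$cold["CL_A_2021", "mEDI"]))
  for (f in x$fits)
    cat(sprintf("  fit %s ~ %s [%s]: slope %.4f, intercept %.3f, r2 %.3f, RMSE %.3f\n",
                f$y_metric, f$x_metric, f$subset, f$slope, f$intercept, f$r2, f$rmse))
  invisible(x)
}

#' Run the full correlation analysis
#'
#' End-to-end pipeline: generate the seeded synthetic ensemble, compute the
#' metric table at the illuminance levels, fit the mEDI ~ CL_A 2.0
#' conversions on the all/warm/cold subsets, run the Planckian
#' discontinuity sweep, and assemble the report.
#'
#' @param config an [ensemble_config()].
#' @param levels illuminance levels in lx.
#' @param t,f CS_2021 exposure parameters.
#' @param cct_threshold warm/cold boundary in K.
#' @param out_dir optional report output directory.
#' @param bundle an [load_bundle()] observer bundle on `config$grid`.
#' @return List with `ensemble`, `table`, `fits`, `sweep`, `report`.
#' @export
run_correlation <- function(config, levels = c(125, 500, 750), t = 1, f = 1.0,
                            cct_threshold = 3710, out_dir = NULL,
                            bundle = load_bundle(config$grid)) {
  ens <- generate_ensemble(config, bundle)
  tab <- compute_metric_table(ens$spectra, levels = levels, t = t, f = f,
                              bundle = bundle)
  fits <- lapply(c("all", "warm", "cold"), function(ss)
    linear_fit(tab, "CL_A_2021", "mEDI", subset = ss,
               cct_threshold = cct_threshold))
  names(fits) <- c("all", "warm", "cold")
  sweep <- discontinuity_sweep(level = levels[min(2, length(levels))],
                               bundle = bundle, t = t, f = f)
  report <- build_report(tab, fits, sweep, cct_threshold = cct_threshold,
                         config = list(seed = config$seed, levels = levels,
                                       t = t, f = f),
                         out_dir = out_dir)
  list(ensemble = ens, table = tab, fits = fits, sweep = sweep, report = report)
}
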
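#' Absolute spectral irradiance distribution
#'
#' The universal input of the metric stack: spectral irradiance at the eye in
#' W m-2 nm-1 on a strictly increasing wavelength grid.
#'
#' @param grid wavelengths in nm, strictly increasing.
#' @param irradiance spectral irradiance in W m-2 nm-1, non-negative.
#' @param id free-form identifier.
#' @param source_class one of `"incandescent"`, `"fluorescent"`, `"led"`,
#'   `"daylight"`, `"other"`.
#' @param metadata free-form provenance list.
#' @return An object of class `spd`.
#' @export
spd <- function(grid, irradiance, id = "", source_class = "other",
                metadata = list()) {
  grid <- as.numeric(grid); irradiance <- as.numeric(irradiance)
  if (length(grid) != length(irradiance)) stop("grid/irradiance length mismatch")
  if (any(diff(grid) <= 0)) stop("wavelengths must be strictly increasing")
  bad <- which(irradiance < 0)
  if (length(bad))
    stop(sprintf("negative spectral irradiance at row %d (%g nm)", bad[1], grid[bad[1]]))
  source_class <- match.arg(source_class,
                            c("incandescent", "fluorescent", "led", "daylight", "other"))
  structure(list(id = id, grid = grid, irradiance = irradiance,
                 source_class = source_class, metadata = metadata),
            class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd> %s [%s]: %g-%g nm (%d points), peak %.4g W m-2 nm-1\n",
              if (nzchar(x$id)) x$id else "(unnamed)", x$source_class,
              min(x$grid), max(x$grid), length(x$grid), max(x$irradiance)))
  invisible(x)
}

#' Read / write SPD files
#'
#' SPD files are delimited text with two numeric columns, wavelength (nm) and
#' spectral irradiance (W m-2 nm-1). Lines starting with `#` are comments;
#' `# key: value` comment lines are parsed into metadata. A single
#' non-numeric header row is tolerated.
#'
#' @param path file path.
#' @param id identifier for the resulting spectrum; defaults to the file name.
#' @param source_class see [spd()]; taken from a `# source_class:` comment if
#'   present.
#' @return [read_spd()] returns an [spd()]; [write_spd()] returns `path`
#'   invisibly.
#' @export
read_spd <- function(path, id = NULL, source_class = NULL) {
  lines <- readLines(path, warn = FALSE)
  comments <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop(sprintf("'%s': no data rows", path))
  # tolerate one non-numeric header row
  first <- strsplit(trimws(body[1]), "[,;\t ]+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) body <- body[-1]
  fields <- strsplit(trimws(body), "[,;\t ]+")
  if (any(lengths(fields) < 2)) stop(sprintf("'%s': rows with fewer than two columns", path))
  wl <- as.numeric(vapply(fields, `[[`, "", 1L))
  ir <- as.numeric(vapply(fields, `[[`, "", 2L))
  if (any(is.na(wl)) || any(is.na(ir))) stop(sprintf("'%s': non-numeric data", path))
  if (any(diff(wl) <= 0))
    stop(sprintf("'%s': wavelengths not strictly increasing at row %d",
                 path, which(diff(wl) <= 0)[1] + 1L))
  bad <- which(ir < 0)
  if (length(bad))
    stop(sprintf("'%s': negative irradiance at row %d (%g nm)", path, bad[1], wl[bad[1]]))
  meta <- list()
  kv <- regmatches(comments, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+)$", comments))
  for (m in kv) if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  spd(wl, ir,
      id = id %||% meta$id %||% sub("\\.[^.]*$", "", basename(path)),
      source_class = source_class %||% meta$source_class %||% "other",
      metadata = meta)
}

#' @rdname read_spd
#' @param s an [spd()] to write.
#' @export
write_spd <- function(s, path) {
  stopifnot(inherits(s, "spd"))
  hdr <- c(sprintf("# id: %s", s$id),
           sprintf("# source_class: %s", s$source_class),
           "# columns: wavelength_nm, spectral_irradiance_W_m2_nm")
  extra <- setdiff(names(s$metadata), c("id", "source_class"))
  hdr <- c(hdr, vapply(extra, function(k)
    sprintf("# %s: %s", k, as.character(s$metadata[[k]])[1]), ""))
  rows <- sprintf("%.10g\t%.10g", s$grid, s$irradiance)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; zero outside the source support (a spectrum carries
#' no energy where it was not measured).
#'
#' @param s an [spd()].
#' @param grid target grid in nm, strictly increasing, within 360--830 nm.
#' @export
resample_spd <- function(s, grid) {
  stopifnot(inherits(s, "spd"))
  grid <- as.numeric(grid)
  if (!length(grid)) stop("empty target grid")
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  if (min(grid) < 360 || max(grid) > 830) stop("target grid must lie within 360-830 nm")
  y <- stats::approx(s$grid, s$irradiance, xout = grid, rule = 1)$y
  y[is.na(y)] <- 0
  spd(grid, y, id = s$id, source_class = s$source_class, metadata = s$metadata)
}

# spectrum irradiance on the bundle grid
on_bundle_grid <- function(s, bundle) {
  stopifnot(inherits(s, "spd"), inherits(bundle, "observer_bundle"))
  if (isTRUE(all.equal(s$grid, bundle$grid))) return(s$irradiance)
  resample_spd(s, bundle$grid)$irradiance
}

#' Photopic illuminance of a spectrum
#'
#' \eqn{E_v = 683 \int E_\lambda V_\lambda d\lambda} in lx, by trapezoidal
#' quadrature on the bundle grid.
#'
#' @param s an [spd()].
#' @param bundle an [load_bundle()] observer bundle.
#' @export
photopic_illuminance <- function(s, bundle) {
  e <- on_bundle_grid(s, bundle)
  683 * sum(trapz_weights(bundle$grid) * e * bundle$V$values)
}

#' Scale a spectrum to a target photopic illuminance
#'
#' Multiplies the spectrum by `target / photopic_illuminance(s)`; the
#' spectral shape is unchanged. This is how a relative SPD is converted to an
#' absolute one at a fixed vertical illuminance level.
#'
#' @inheritParams photopic_illuminance
#' @param target target illuminance in lx, > 0.
#' @export
scale_to_illuminance <- function(s, target, bundle) {
  stop_if_not_scalar_number(target, "target")
  if (target <= 0) stop("`target` must be positive")
  ev <- photopic_illuminance(s, bundle)
  if (ev <= 0) stop("spectrum has zero photopic illuminance; cannot rescale")
  s$irradiance <- s$irradiance * (target / ev)
  s
}
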
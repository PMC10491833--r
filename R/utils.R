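# internal numeric helpers

# trapezoidal quadrature weights for an arbitrary strictly increasing grid;
# sum(w * y) == pracma::trapz(x, y)
trapz_weights <- function(x) {
  n <- length(x)
  dx <- diff(x)
  c(dx[1], dx[-1] + dx[-(n - 1)], dx[n - 1]) / 2
}

spectral_trapz <- function(x, y) pracma::trapz(x, y)

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
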
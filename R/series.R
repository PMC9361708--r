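#' Uniformly sampled signal
#'
#' Lightweight container for a uniformly sampled channel: start time, sampling
#' rate, values and a unit label. All signal-processing and model functions in
#' the package accept either a `uniform_series` or a bare numeric vector and
#' return the same kind they were given.
#'
#' @param values numeric vector of samples (finite, length >= 1).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param units unit label, e.g. `"rad"`, `"N"`, `"mm"`, `"N.m"`.
#' @return An object of class `uniform_series`.
#' @examples
#' s <- uniform_series(sin(seq(0, 1, by = 0.01)), fs = 100, units = "rad")
#' head(series_time(s))
#' @export
uniform_series <- function(values, fs, t0 = 0, units = "") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("invalid-rate: 'fs' must be a single positive number", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("data error: 'values' must have length >= 1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("data error: 'values' must be finite", call. = FALSE)
  structure(list(t0 = as.numeric(t0), fs = fs, values = values,
                 units = as.character(units)),
            class = "uniform_series")
}

#' @rdname uniform_series
#' @param x object to test or convert.
#' @export
is_uniform_series <- function(x) inherits(x, "uniform_series")

#' @rdname uniform_series
#' @export
series_time <- function(x) {
  stopifnot(is_uniform_series(x))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz, t0 = %g s%s\n",
              length(x$values), x$fs, x$t0,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  cat("  range:", format(range(x$values), digits = 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.uniform_series <- function(x, ...) {
  data.frame(time = series_time(x), value = x$values)
}

# --- internal helpers to work transparently on series or numeric ------------

.series_values <- function(x) if (is_uniform_series(x)) x$values else as.numeric(x)

.series_fs <- function(x, fs = NULL) {
  if (is_uniform_series(x)) x$fs
  else if (is.null(fs)) stop("'fs' must be given for a bare numeric vector",
                             call. = FALSE)
  else fs
}

.series_rewrap <- function(values, template, units = NULL) {
  if (is_uniform_series(template)) {
    uniform_series(values, fs = template$fs, t0 = template$t0,
                   units = if (is.null(units)) template$units else units)
  } else values
}

.check_same_grid <- function(a, b) {
  na <- length(.series_values(a)); nb <- length(.series_values(b))
  if (na != nb)
    stop("alignment error: series lengths differ (", na, " vs ", nb, ")",
         call. = FALSE)
  if (is_uniform_series(a) && is_uniform_series(b) &&
      !isTRUE(all.equal(a$fs, b$fs)))
    stop("alignment error: sampling rates differ", call. = FALSE)
  invisible(TRUE)
}

.clip01 <- function(x) pmin(1, pmax(0, x))

# evaluate expr with a deterministic RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
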
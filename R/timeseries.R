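#' Culture time series container
#'
#' One culture's sampled trajectory: viable cell density, glucose, lactate,
#' antibody, and optionally vessel volume and temperature, on a strictly
#' increasing time grid. Missing measurements are `NA`, never zero-filled.
#' Canonical units: time h, `X` cells/mL, `S` and `Lac` g/L, `P` mg/L,
#' `V` mL; unit conversion is an I/O concern and never happens inside the
#' math.
#'
#' @param time Sampling times (h), strictly increasing.
#' @param X Viable cell density (cells/mL).
#' @param S Glucose (g/L).
#' @param Lac Lactate (g/L), optional.
#' @param P Antibody (mg/L), optional.
#' @param V Vessel volume (mL), optional.
#' @param temperature Culture temperature (degrees C), optional.
#' @param cell_line,condition,replicate Metadata labels.
#' @return A data.frame of class `culture_timeseries` with metadata
#'   attributes.
#' @export
culture_timeseries <- function(time, X, S, Lac = NA_real_, P = NA_real_,
                               V = NA_real_, temperature = NA_real_,
                               cell_line = NA_character_,
                               condition = NA_character_,
                               replicate = NA_integer_) {
  n <- length(time)
  if (n < 1L) stop("a culture time series needs at least one sample", call. = FALSE)
  if (any(!is.finite(time))) stop("sampling times must be finite", call. = FALSE)
  if (n > 1L && any(diff(time) <= 0)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  recycle <- function(v) if (length(v) == 1L) rep(v, n) else v
  X <- recycle(X); S <- recycle(S); Lac <- recycle(Lac); P <- recycle(P)
  V <- recycle(V); temperature <- recycle(temperature)
  lens <- vapply(list(X, S, Lac, P, V, temperature), length, integer(1L))
  if (any(lens != n)) stop("all measurement vectors must match length(time)", call. = FALSE)
  for (nm in c("X", "S", "Lac", "P")) {
    v <- get(nm)
    if (any(v < 0, na.rm = TRUE)) {
      stop(sprintf("negative values in '%s' are not a valid concentration", nm),
           call. = FALSE)
    }
  }
  structure(
    data.frame(time = as.numeric(time), X = as.numeric(X), S = as.numeric(S),
               Lac = as.numeric(Lac), P = as.numeric(P), V = as.numeric(V),
               temperature = as.numeric(temperature)),
    cell_line = cell_line, condition = condition, replicate = replicate,
    class = c("culture_timeseries", "data.frame")
  )
}

#' @export
print.culture_timeseries <- function(x, ...) {
  cat(sprintf("Culture time series: %s / %s / replicate %s, %d samples over %g h\n",
              attr(x, "cell_line"), attr(x, "condition"),
              as.character(attr(x, "replicate")), nrow(x), max(x$time) - min(x$time)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

ts_metadata <- function(series) {
  list(cell_line = attr(series, "cell_line"),
       condition = attr(series, "condition"),
       replicate = attr(series, "replicate"))
}

# rows of `series` with time inside [window[1], window[2]]
window_rows <- function(series, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  which(series$time >= window[1] - 1e-9 & series$time <= window[2] + 1e-9)
}
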
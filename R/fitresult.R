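#' Fit result container
#'
#' Parameter estimates with the goodness-of-fit bookkeeping used throughout
#' the estimation module. Linearized fits (log-linear growth rate,
#' Lineweaver-Burk) are gated by the published acceptance rule: the fit is
#' flagged valid only when r^2 exceeds 0.97. Fits without a published gate
#' (yield slope, Luedeking-Piret fits) are always flagged valid; their r^2 is
#' reported for diagnostics only.
#'
#' @param estimates Named numeric vector of parameter estimates.
#' @param r_squared Coefficient of determination in `[0, 1]`.
#' @param n_points Number of data points used.
#' @param residuals Per-point residuals (on the fitted scale).
#' @param gated Logical; does the published r^2 > 0.97 validity rule apply?
#' @param details Optional list of extra diagnostics.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(estimates, r_squared, n_points, residuals = numeric(0),
                       gated = FALSE, details = list()) {
  stopifnot(is.numeric(estimates), !is.null(names(estimates)))
  r_squared <- max(0, min(1, r_squared))
  structure(
    list(estimates = estimates, r_squared = r_squared,
         n_points = as.integer(n_points), residuals = residuals,
         valid = if (gated) r_squared > 0.97 else TRUE,
         gated = gated, details = details),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result:\n")
  for (nm in names(x$estimates)) cat(sprintf("  %s = %g\n", nm, x$estimates[[nm]]))
  cat(sprintf("  r^2 = %.6f on %d points; valid = %s%s\n",
              x$r_squared, x$n_points, x$valid,
              if (x$gated) " (r^2 > 0.97 rule applied)" else ""))
  invisible(x)
}

# r^2 that treats an exact fit to constant data as perfect rather than 0/0
r_squared_of <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= .Machine$double.eps * max(1, sum(observed^2))) {
    return(if (ss_res <= .Machine$double.eps * max(1, sum(observed^2))) 1 else 0)
  }
  1 - ss_res / ss_tot
}
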
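#' Kinetic parameter set for a CHO culture model
#'
#' Bundles the constants of the threshold-modified Monod growth law, the
#' substrate yield balance and the Luedeking-Piret production law, together
#' with optional extensions (first-order death after substrate depletion,
#' maintenance consumption, a two-regime lactate sub-model) that let simulated
#' trajectories show the death phase and full glucose depletion seen in real
#' batch cultures.
#'
#' Canonical internal units are hours, cells/mL, g/L (glucose, lactate;
#' identical to mg/mL) and mg/L (antibody; identical to ug/mL). With these
#' units `alpha * r_x` and `beta * X` both come out in mg/L/h with no
#' conversion factors.
#'
#' @param mu_max Maximum specific growth rate (1/h). Must be > 0.
#' @param K_s Half-velocity constant (g/L glucose above threshold). Must be > 0.
#' @param S_t Threshold glucose concentration below which growth stops (g/L).
#' @param Y_xs Cell/substrate yield coefficient (cells per mg glucose).
#' @param alpha Growth-associated production constant (ug antibody per cell).
#' @param beta Non-growth-associated production constant (ug/cell/h).
#' @param k_d First-order death rate applied while glucose is at or below the
#'   threshold (1/h). Default 0 (no death phase).
#' @param m_s Maintenance glucose consumption (mg/cell/h). Default 0
#'   (growth-linked consumption only).
#' @param y_lac_x Lactate produced per cell grown (mg lactate/cell), optional.
#' @param q_lac_cons Specific lactate consumption after glucose depletion
#'   (ng/cell/day), optional.
#' @return An object of class `kinetic_parameters` (a named list).
#' @examples
#' kinetic_parameters(mu_max = 0.040, K_s = 0.664, S_t = 0.58, Y_xs = 2.59e6)
#' @export
kinetic_parameters <- function(mu_max, K_s, S_t, Y_xs,
                               alpha = 0, beta = 0,
                               k_d = 0, m_s = 0,
                               y_lac_x = NA_real_, q_lac_cons = NA_real_) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.nan(x)) {
      stop(sprintf("'%s' must be a single numeric value", nm), call. = FALSE)
    }
    as.numeric(x)
  }
  mu_max <- num1(mu_max, "mu_max"); K_s <- num1(K_s, "K_s")
  S_t <- num1(S_t, "S_t"); Y_xs <- num1(Y_xs, "Y_xs")
  alpha <- num1(alpha, "alpha"); beta <- num1(beta, "beta")
  k_d <- num1(k_d, "k_d"); m_s <- num1(m_s, "m_s")
  y_lac_x <- num1(y_lac_x, "y_lac_x"); q_lac_cons <- num1(q_lac_cons, "q_lac_cons")
  if (!(mu_max > 0)) stop("mu_max must be > 0", call. = FALSE)
  if (!(K_s > 0)) stop("K_s must be > 0", call. = FALSE)
  if (!(S_t >= 0)) stop("S_t must be >= 0", call. = FALSE)
  if (!(Y_xs > 0)) stop("Y_xs must be > 0", call. = FALSE)
  if (!(alpha >= 0)) stop("alpha must be >= 0", call. = FALSE)
  if (!(beta >= 0)) stop("beta must be >= 0", call. = FALSE)
  if (!(k_d >= 0)) stop("k_d must be >= 0", call. = FALSE)
  if (!(m_s >= 0)) stop("m_s must be >= 0", call. = FALSE)
  if (!is.na(y_lac_x) && y_lac_x < 0) stop("y_lac_x must be >= 0", call. = FALSE)
  if (!is.na(q_lac_cons) && q_lac_cons < 0) stop("q_lac_cons must be >= 0", call. = FALSE)
  structure(
    list(mu_max = mu_max, K_s = K_s, S_t = S_t, Y_xs = Y_xs,
         alpha = alpha, beta = beta, k_d = k_d, m_s = m_s,
         y_lac_x = y_lac_x, q_lac_cons = q_lac_cons),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (threshold-Monod + Luedeking-Piret)\n")
  cat(sprintf("  mu_max = %g 1/h, K_s = %g g/L, S_t = %g g/L\n",
              x$mu_max, x$K_s, x$S_t))
  cat(sprintf("  Y_xs   = %g cells/mg\n", x$Y_xs))
  cat(sprintf("  alpha  = %g ug/cell, beta = %g ug/cell/h\n", x$alpha, x$beta))
  if (x$k_d > 0 || x$m_s > 0) {
    cat(sprintf("  k_d = %g 1/h, m_s = %g mg/cell/h\n", x$k_d, x$m_s))
  }
  if (!is.na(x$y_lac_x) || !is.na(x$q_lac_cons)) {
    cat(sprintf("  lactate: y_lac_x = %g mg/cell, q_lac_cons = %g ng/cell/day\n",
                x$y_lac_x, x$q_lac_cons))
  }
  invisible(x)
}

#' Modify a subset of fields of a kinetic parameter set
#'
#' @param params A `kinetic_parameters` object.
#' @param ... Named fields to replace (same names as [kinetic_parameters()]).
#' @return A new, re-validated `kinetic_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "kinetic_parameters"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) {
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  vals <- unclass(params)
  vals[names(repl)] <- repl
  do.call(kinetic_parameters, vals)
}

registry_key <- function(cell_line, temperature, source) {
  sprintf("%s@%g/%s", cell_line, temperature, source)
}

#' Build a parameter registry
#'
#' A registry maps (cell line, culture temperature, source tag) keys to
#' [kinetic_parameters()] sets. Lookup of a missing key is always an error,
#' never a silent default, so conflicting published values (distinguished by
#' their source tag) can never be mixed silently.
#'
#' @param entries A list of entries, each a list with fields `cell_line`,
#'   `temperature` (degrees C), `source` (a tag naming where the values come
#'   from) and `params` (a `kinetic_parameters` object).
#' @return An object of class `parameter_registry`.
#' @seealso [cho_parameter_registry()] for the shipped registry,
#'   [registry_lookup()], [read_registry()], [write_registry()].
#' @export
parameter_registry <- function(entries) {
  stopifnot(is.list(entries))
  keyed <- list()
  for (e in entries) {
    stopifnot(is.list(e), inherits(e$params, "kinetic_parameters"))
    key <- registry_key(e$cell_line, e$temperature, e$source)
    if (key %in% names(keyed)) stop("duplicate registry key: ", key, call. = FALSE)
    keyed[[key]] <- e
  }
  structure(keyed, class = "parameter_registry")
}

#' @export
print.parameter_registry <- function(x, ...) {
  cat(sprintf("Parameter registry with %d entries:\n", length(x)))
  for (key in names(x)) cat("  ", key, "\n", sep = "")
  invisible(x)
}

#' Look up a parameter set in a registry
#'
#' @param registry A `parameter_registry`.
#' @param cell_line Cell line label, e.g. `"r-CHO"` or `"n-CHO"`.
#' @param temperature Culture temperature in degrees C.
#' @param source Source tag, e.g. `"table2"`.
#' @return The stored `kinetic_parameters` object.
#' @export
registry_lookup <- function(registry, cell_line, temperature, source = "table2") {
  stopifnot(inherits(registry, "parameter_registry"))
  key <- registry_key(cell_line, temperature, source)
  if (!key %in% names(registry)) {
    stop(sprintf("no registry entry for key '%s'; available keys: %s",
                 key, paste(names(registry), collapse = ", ")), call. = FALSE)
  }
  registry[[key]]$params
}

#' Registry of fitted CHO kinetic parameter sets
#'
#' The parameter sets determined from batch shake-flask experiments for the
#' naive (n-CHO) and recombinant, antibody-producing (r-CHO) cell lines at 33
#' and 37 degrees C, as published. Two source tags are shipped: `"table2"`
#' carries the tabulated batch-culture parameters, and `"fig3caption"` carries
#' the alternate values printed alongside the growth-rate figure, which differ
#' for some entries; keeping both under distinct tags makes the provenance of
#' every downstream fit explicit.
#'
#' For the producing line at 37 degrees C no single non-growth-associated
#' constant fits all data sets; the registry carries the midpoint of the
#' published range 1.38-3.38e-8 ug/cell/h (see [beta_range_37C()]).
#'
#' @return A `parameter_registry` with entries for
#'   `n-CHO`/`r-CHO` at 33 and 37 degrees C (`table2`) and the alternate
#'   `fig3caption` entries.
#' @examples
#' reg <- cho_parameter_registry()
#' registry_lookup(reg, "r-CHO", 33)
#' @export
cho_parameter_registry <- function() {
  parameter_registry(list(
    list(cell_line = "n-CHO", temperature = 33, source = "table2",
         params = kinetic_parameters(mu_max = 0.038, K_s = 0.286, S_t = 0.96,
                                     Y_xs = 6.08e6, alpha = 0, beta = 0)),
    list(cell_line = "n-CHO", temperature = 37, source = "table2",
         params = kinetic_parameters(mu_max = 0.05, K_s = 1.023, S_t = 0.58,
                                     Y_xs = 6.08e6, alpha = 0, beta = 0)),
    list(cell_line = "r-CHO", temperature = 33, source = "table2",
         params = kinetic_parameters(mu_max = 0.040, K_s = 0.664, S_t = 0.58,
                                     Y_xs = 2.59e6, alpha = 7.65e-7, beta = 7.68e-8)),
    list(cell_line = "r-CHO", temperature = 37, source = "table2",
         params = kinetic_parameters(mu_max = 0.040, K_s = 0.664, S_t = 0.58,
                                     Y_xs = 1.70e6, alpha = 7.65e-7, beta = 2.38e-8)),
    list(cell_line = "n-CHO", temperature = 37, source = "fig3caption",
         params = kinetic_parameters(mu_max = 0.050, K_s = 2.058, S_t = 0.60,
                                     Y_xs = 6.08e6, alpha = 0, beta = 0)),
    list(cell_line = "r-CHO", temperature = 33, source = "fig3caption",
         params = kinetic_parameters(mu_max = 0.043, K_s = 0.929, S_t = 0.60,
                                     Y_xs = 2.59e6, alpha = 7.65e-7, beta = 7.68e-8))
  ))
}

#' Published range for the non-growth-associated constant at 37 degrees C
#'
#' No unique `beta` fits the producing line's batch data at 37 degrees C; the
#' published range is returned (ug/cell/h).
#' @return Numeric vector `c(lower, upper)`.
#' @export
beta_range_37C <- function() c(1.38e-8, 3.38e-8)

#' Shipped parameter lookup
#'
#' Convenience wrapper over [registry_lookup()] against the shipped registry
#' [cho_parameter_registry()].
#'
#' @inheritParams registry_lookup
#' @return A `kinetic_parameters` object (a copy; the registry is rebuilt on
#'   every call and never mutated).
#' @examples
#' get_default_parameters("r-CHO", 33)
#' get_default_parameters("n-CHO", 37, source = "fig3caption")
#' @export
get_default_parameters <- function(cell_line, temperature, source = "table2") {
  registry_lookup(cho_parameter_registry(), cell_line, temperature, source)
}

#' Substrate-dependent yield coefficients from batch cultures
#'
#' The cell/substrate yield coefficient was observed to depend on the initial
#' glucose concentration; this table carries the per-condition values for both
#' cell lines at 33 degrees C (cells per mg glucose).
#'
#' @return A data.frame with columns `cell_line`, `S0` (g/L) and `Y_xs`
#'   (cells/mg).
#' @export
cho_yield_table <- function() {
  data.frame(
    cell_line = rep(c("n-CHO", "r-CHO"), each = 4L),
    S0 = rep(c(4.8, 3.6, 2.4, 1.2), 2L),
    Y_xs = c(1.08e7, 7.25e6, 3.58e6, 2.69e6,
             2.79e6, 3.19e6, 1.81e6, 7.18e5)
  )
}

## --- registry (de)serialization: flat TOML dialect -------------------------
## One [section] per entry; keys cell_line/temperature/source plus the numeric
## parameter fields. Floats are written with %.17g so a write/read round trip
## is bit-identical.

fmt_toml_value <- function(x) {
  if (is.character(x)) sprintf('"%s"', x) else formatC(x, format = "g", digits = 17)
}

#' Write a parameter registry to a plain-text config file
#'
#' @param registry A `parameter_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_registry()]
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "parameter_registry"))
  lines <- c("# chokinetics parameter registry",
             "# units: h, g/L, cells/mL, mg/L; see ?kinetic_parameters")
  for (i in seq_along(registry)) {
    e <- registry[[i]]
    lines <- c(lines, "", sprintf("[entry%02d]", i),
               sprintf("cell_line = %s", fmt_toml_value(e$cell_line)),
               sprintf("temperature = %s", fmt_toml_value(e$temperature)),
               sprintf("source = %s", fmt_toml_value(e$source)))
    p <- e$params
    for (nm in names(unclass(p))) {
      if (is.na(p[[nm]])) next
      lines <- c(lines, sprintf("%s = %s", nm, fmt_toml_value(p[[nm]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter registry from a plain-text config file
#'
#' Parses the flat dialect written by [write_registry()]: `[section]` headers,
#' `key = value` pairs, `#` comments.
#'
#' @param path Input file path.
#' @return A `parameter_registry`.
#' @export
read_registry <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sections <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      if (!is.null(current)) sections[[length(sections) + 1L]] <- current
      current <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(current)) stop("key/value pair outside any [section] in ", path, call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (grepl('^".*"$', val)) {
        val <- sub('^"(.*)"$', "\\1", val)
      } else {
        val <- as.numeric(val)
      }
      current[[key]] <- val
    } else {
      stop("unparseable line in registry file: ", ln, call. = FALSE)
    }
  }
  if (!is.null(current)) sections[[length(sections) + 1L]] <- current
  entries <- lapply(sections, function(s) {
    meta <- s[c("cell_line", "temperature", "source")]
    if (any(vapply(meta, is.null, logical(1L)))) {
      stop("registry entry missing cell_line/temperature/source", call. = FALSE)
    }
    pfields <- s[setdiff(names(s), c("cell_line", "temperature", "source"))]
    list(cell_line = s$cell_line, temperature = s$temperature, source = s$source,
         params = do.call(kinetic_parameters, pfields))
  })
  parameter_registry(entries)
}
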
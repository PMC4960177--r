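## Delimited-text interchange format for culture time series.
## One CSV holds any number of cultures, one row per sample, keyed by
## (condition, replicate). Canonical file units match the internal ones:
## glucose/lactate in g/L, antibody in mg/L, cells per mL. Missing values are
## empty cells.

ts_required_cols <- c("time_h", "viable_cells_per_ml", "glucose_g_per_l",
                      "lactate_g_per_l", "mab_mg_per_l", "condition",
                      "replicate")
ts_optional_cols <- c("volume_ml", "temperature_c", "cell_line")

#' Write culture time series to a delimited text table
#'
#' @param dataset A [culture_timeseries()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_timeseries()]
#' @export
write_timeseries <- function(dataset, path) {
  if (inherits(dataset, "culture_timeseries")) dataset <- list(dataset)
  rows <- lapply(dataset, function(ts) {
    stopifnot(inherits(ts, "culture_timeseries"))
    data.frame(time_h = ts$time,
               viable_cells_per_ml = ts$X,
               glucose_g_per_l = ts$S,
               lactate_g_per_l = ts$Lac,
               mab_mg_per_l = ts$P,
               volume_ml = ts$V,
               temperature_c = ts$temperature,
               cell_line = attr(ts, "cell_line"),
               condition = attr(ts, "condition"),
               replicate = attr(ts, "replicate"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read culture time series from a delimited text table
#'
#' Validates the schema (missing mandatory columns are an error naming the
#' column), requires rows already sorted by time within each
#' (condition, replicate) culture - out-of-order rows are an error, never a
#' silent re-sort - and rejects duplicate sampling times within a culture.
#'
#' @param path Input CSV path.
#' @return A named list of [culture_timeseries()] objects, one per
#'   (condition, replicate).
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ts_required_cols, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(raw$condition, raw$replicate, sep = "/")
  dup <- duplicated(data.frame(key, raw$time_h))
  if (any(dup)) {
    stop(sprintf("duplicate (condition, replicate, time) row(s), first at line %d",
                 which(dup)[1] + 1L), call. = FALSE)
  }
  out <- list()
  for (k in unique(key)) {
    d <- raw[key == k, , drop = FALSE]
    if (is.unsorted(d$time_h, strictly = TRUE)) {
      stop(sprintf("rows of culture '%s' are not sorted by time; refusing to re-order silently", k),
           call. = FALSE)
    }
    out[[k]] <- culture_timeseries(
      time = d$time_h,
      X = d$viable_cells_per_ml,
      S = d$glucose_g_per_l,
      Lac = d$lactate_g_per_l,
      P = d$mab_mg_per_l,
      V = if ("volume_ml" %in% names(d)) d$volume_ml else NA_real_,
      temperature = if ("temperature_c" %in% names(d)) d$temperature_c else NA_real_,
      cell_line = if ("cell_line" %in% names(d)) d$cell_line[1] else NA_character_,
      condition = as.character(d$condition[1]),
      replicate = d$replicate[1])
  }
  out
}
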
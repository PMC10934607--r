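#' Read a signal from CSV
#'
#' Accepts either a two-column file with header `time_s,value` or a
#' single-column `value` file (then `fs` must be given). The time column is
#' validated for uniform sampling: successive deltas may deviate from their
#' median by at most 1 percent.
#'
#' @param path Path to the CSV file (comma separator, `.` decimal, one
#'   header line).
#' @param fs Sampling rate in Hz, required for single-column files.
#' @return A [uniform_signal()].
#' @export
read_signal_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  parse_col <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("parse error in column '%s', data row %d: %s",
                   name, bad[1], col[bad[1]]), call. = FALSE)
    v
  }
  if (all(c("time_s", "value") %in% names(df))) {
    tt <- parse_col(df$time_s, "time_s")
    vv <- parse_col(df$value, "value")
    dt <- diff(tt)
    med <- stats::median(dt)
    if (med <= 0) stop("time column not increasing", call. = FALSE)
    off <- which(abs(dt - med) > 0.01 * med)
    if (length(off))
      stop(sprintf("non-uniform sampling at data row %d (delta %.6g s vs median %.6g s)",
                   off[1] + 1L, dt[off[1]], med), call. = FALSE)
    uniform_signal(vv, fs = 1 / med, t0 = tt[1])
  } else if ("value" %in% names(df)) {
    if (is.null(fs))
      stop("single-column file needs an explicit `fs`", call. = FALSE)
    uniform_signal(parse_col(df$value, "value"), fs = fs)
  } else {
    stop("expected columns 'time_s,value' or 'value' in ", path,
         call. = FALSE)
  }
}

#' Write a signal to CSV
#'
#' Two columns `time_s,value`; timestamps with 6 decimals, values at full
#' precision.
#'
#' @param sig A [uniform_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "uniform_signal"))
  df <- data.frame(time_s = sprintf("%.6f", signal_times(sig)),
                   value = format(sig$samples, digits = 15, trim = TRUE,
                                  scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tachogram from CSV (columns `time_s,rr_ms`)
#' @param path Path to the CSV file.
#' @return A [tachogram()].
#' @export
read_tachogram_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "rr_ms") %in% names(df)))
    stop("expected columns 'time_s,rr_ms'", call. = FALSE)
  tachogram(df$rr_ms, df$time_s)
}

#' Write a tachogram to CSV (columns `time_s,rr_ms`)
#' @param tacho A [tachogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tachogram_csv <- function(tacho, path) {
  stopifnot(inherits(tacho, "tachogram"))
  df <- data.frame(time_s = sprintf("%.6f", tacho$times),
                   rr_ms = sprintf("%.3f", tacho$intervals))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Write a JSON output, checking it first against the named schema under
# inst/schemas.
write_json_output <- function(obj, path, schema = NULL) {
  if (!is.null(schema)) check_schema(obj, schema)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Validate an output object against a bundled schema
#'
#' A light structural check: every key listed as `required` in the schema
#' file (`inst/schemas/<name>.schema.json`) must be present, and keys with
#' a declared `type` must match (`number`/`array`/`object`/`string`).
#'
#' @param obj A named list about to be serialized.
#' @param name Schema name (e.g. `"events"`, `"stats"`, `"agreement"`,
#'   `"hrv"`, `"truth"`, `"rpeaks"`).
#' @return `TRUE`, invisibly; errors describe the first violation.
#' @export
check_schema <- function(obj, name) {
  path <- system.file("schemas", paste0(name, ".schema.json"),
                      package = "fcghs")
  if (path == "") stop("unknown schema: ", name, call. = FALSE)
  sch <- jsonlite::read_json(path)
  req <- unlist(sch$required)
  missing <- setdiff(req, names(obj))
  if (length(missing))
    stop(sprintf("output does not match schema '%s': missing key '%s'",
                 name, missing[1]), call. = FALSE)
  for (key in names(sch$properties)) {
    if (!key %in% names(obj)) next
    want <- sch$properties[[key]]$type
    if (is.null(want)) next
    v <- obj[[key]]
    ok <- switch(want,
                 number = is.numeric(v) && length(v) == 1L,
                 integer = is.numeric(v) && length(v) == 1L,
                 array = is.numeric(v) || is.list(v) || is.logical(v),
                 object = is.list(v),
                 string = is.character(v) && length(v) == 1L,
                 TRUE)
    if (!ok)
      stop(sprintf("output does not match schema '%s': key '%s' is not %s",
                   name, key, want), call. = FALSE)
  }
  invisible(TRUE)
}
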
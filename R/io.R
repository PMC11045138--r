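#' Read a timeseries from delimited text
#'
#' Files carry a `time_days,value` header and one row per sample. Dense
#' series additionally carry `# t0=<days>` and `# dt=<days>` metadata lines
#' before the header and may encode missing values as empty fields; files
#' without metadata are read as sparse `sampled_series`.
#'
#' @param path File path.
#' @return A `dense_series` or `sampled_series`.
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty series file: ", path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || body[1] != "time_days,value")
    stop("expected header 'time_days,value' in ", path)
  if (length(body) < 2) stop("series file has no data rows: ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = c("numeric", "numeric"))
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=")[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  if (!is.null(meta$dt)) {
    dense_series(df$value, t0 = if (!is.null(meta$t0)) meta$t0 else df$time_days[1],
                 dt = meta$dt)
  } else {
    if (anyNA(df$value)) stop("sparse series cannot contain missing values")
    if (is.unsorted(df$time_days, strictly = TRUE))
      stop("times must be strictly increasing in ", path)
    sampled_series(df$time_days, df$value)
  }
}

#' Write a timeseries as delimited text
#'
#' @param x A `dense_series` or `sampled_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "dense_series")) {
    writeLines(c(sprintf("# t0=%.17g", x$t0), sprintf("# dt=%.17g", x$dt)),
               con)
    df <- data.frame(time_days = series_times(x), value = x$values)
  } else if (inherits(x, "sampled_series")) {
    df <- data.frame(time_days = x$times, value = x$values)
  } else stop("cannot write object of class ", paste(class(x), collapse = "/"))
  writeLines("time_days,value", con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read / write event times
#'
#' Delimited text with header `event_time_days`.
#'
#' @param path File path.
#' @return An `event_series`.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  if (!"event_time_days" %in% names(df))
    stop("expected header 'event_time_days' in ", path)
  event_series(df$event_time_days)
}

#' @rdname read_events
#' @param x An `event_series`.
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "event_series"))
  utils::write.csv(data.frame(event_time_days = x$event_times), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export / import a frequency grid as JSON
#'
#' @param grid A `frequency_grid`.
#' @param path Output path.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "frequency_grid"))
  jsonlite::write_json(
    list(N = grid$N, dt_days = grid$dt, f_values = grid$f_values,
         seed = grid$seed, target_periods = grid$target_periods,
         removal_ceiling_days = grid$removal_ceiling),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(N = as.integer(j$N), dt = j$dt_days,
                 f_values = as.numeric(j$f_values),
                 target_periods = as.numeric(j$target_periods),
                 removal_ceiling = j$removal_ceiling_days,
                 seed = as.integer(j$seed)),
            class = "frequency_grid")
}

#' Export a fit as JSON
#'
#' Writes `delta`, the objective, the polynomial coefficients, and the
#' nonzero oscillation coefficients with their grid indices and periods.
#'
#' @param fit A `bpwp_fit`.
#' @param grid The `frequency_grid` of the fit.
#' @param path Output path.
#' @export
write_fit <- function(fit, grid, path) {
  stopifnot(inherits(fit, "bpwp_fit"), inherits(grid, "frequency_grid"))
  nz <- which(fit$x != 0)
  per <- grid_periods(grid)
  jsonlite::write_json(
    list(delta = fit$delta, objective = fit$objective, p = length(fit$z),
         z = fit$z,
         grid_ref = list(N = grid$N, dt_days = grid$dt, seed = grid$seed),
         x_nonzero = data.frame(index = nz, f = grid$f_values[nz],
                                period_days = per[nz],
                                amplitude = abs(fit$x[nz]),
                                sign = sign(fit$x[nz]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a spectrum table
#'
#' Delimited text `period_days,amplitude,significant,threshold`.
#'
#' @param spectrum A `bpwp_spectrum`.
#' @param path Output path.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- as.data.frame(spectrum)[, c("period_days", "amplitude",
                                    "significant", "threshold")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("bpwp_spectrum", "data.frame")
  out
}

#' Export shuffle-null thresholds
#'
#' Delimited text `period_days,threshold`, one row per coefficient; set
#' `amplitudes = TRUE` to also write the full per-iteration amplitude matrix
#' alongside (same path with suffix `_amplitudes.csv`).
#'
#' @param null A `null_distribution`.
#' @param grid The `frequency_grid` the null was built on.
#' @param path Output path.
#' @param amplitudes Also write the full amplitude matrix (default `FALSE`).
#' @export
write_null <- function(null, grid, path, amplitudes = FALSE) {
  stopifnot(inherits(null, "null_distribution"),
            inherits(grid, "frequency_grid"))
  utils::write.csv(data.frame(period_days = grid_periods(grid),
                              threshold = null$threshold),
                   path, row.names = FALSE, quote = FALSE)
  if (amplitudes) {
    utils::write.csv(as.data.frame(null$amplitudes),
                     sub("(\\.[^.]*)?$", "_amplitudes.csv", path),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
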
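# Typed CSV readers/writers shared by the analysis stages.  Units are part
# of the column names (delay_ps, frequency_cm1, wavelength_nm): the paper's
# convention mixes eV, cm^-1, nm and ps, and silent conversion is the main
# foreseeable bug class, so every file states its units.

.check_columns <- function(df, needed, path) {
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(sprintf("file '%s' is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.check_numeric_rows <- function(df, cols, path, skip = 0L) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "" &
                   df[[cl]] != "NA")
    if (length(bad)) {
      stop(sprintf("file '%s': malformed value in column '%s' at data row %d",
                   path, cl, bad[1L] + skip), call. = FALSE)
    }
    df[[cl]] <- v
  }
  df
}

.write_csv_atomic <- function(df, path, header_lines = character()) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(close(con), add = TRUE)
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con); on.exit(NULL)
  file.rename(tmp, path)
  invisible(path)
}

#' Write / read a pump-probe transient CSV
#'
#' Columns `delay_ps`, `signal`, `sigma`, `channel`; delays are stored in
#' ps and converted to seconds on reading.  Generator ground truth (when
#' present) travels in a reserved `#` comment header.
#'
#' @param x A [transient()].
#' @param path File path.
#' @return `read_transient_csv` returns a [transient()];
#'   `write_transient_csv` returns `path` invisibly.
#' @export
write_transient_csv <- function(x, path) {
  stopifnot(inherits(x, "transient"))
  hdr <- sprintf("channel: %s", attr(x, "channel"))
  tp <- attr(x, "true_params")
  if (!is.null(tp)) {
    hdr <- c(hdr, paste0("true_params: ",
                         jsonlite::toJSON(unclass(tp), auto_unbox = TRUE,
                                          digits = NA)))
  }
  df <- data.frame(delay_ps = x$delay_s * 1e12, signal = x$signal,
                   sigma = x$sigma,
                   channel = attr(x, "channel"))
  .write_csv_atomic(df, path, hdr)
}

#' @rdname write_transient_csv
#' @export
read_transient_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  .check_columns(df, c("delay_ps", "signal", "channel"), path)
  df <- .check_numeric_rows(df, intersect(c("delay_ps", "signal", "sigma"),
                                          names(df)), path)
  sigma <- if ("sigma" %in% names(df)) df$sigma else NULL
  out <- transient(df$delay_ps * 1e-12, df$signal, sigma = sigma,
                   channel = df$channel[1L])
  tp_line <- grep("^# true_params:", hdr, value = TRUE)
  if (length(tp_line)) {
    tp <- jsonlite::fromJSON(sub("^# true_params: ", "", tp_line[1L]))
    attr(out, "true_params") <- do.call(kinetic_params, tp)
  }
  out
}

#' Write / read a laser power-dependence series CSV
#'
#' Columns `pulse_energy`, `yield`, `sigma`, `wavelength_nm`.
#'
#' @param x A [power_series()].
#' @param path File path.
#' @return `read_power_series_csv` returns a [power_series()].
#' @export
write_power_series_csv <- function(x, path) {
  stopifnot(inherits(x, "power_series"))
  df <- data.frame(pulse_energy = x$pulse_energy, yield = x$yield,
                   sigma = x$sigma,
                   wavelength_nm = attr(x, "wavelength_nm"))
  .write_csv_atomic(df, path)
}

#' @rdname write_power_series_csv
#' @export
read_power_series_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  .check_columns(df, c("pulse_energy", "yield"), path)
  df <- .check_numeric_rows(df, intersect(c("pulse_energy", "yield", "sigma",
                                            "wavelength_nm"), names(df)), path)
  power_series(df$pulse_energy, df$yield,
               sigma = if ("sigma" %in% names(df)) df$sigma else NULL,
               wavelength_nm = if ("wavelength_nm" %in% names(df))
                 df$wavelength_nm[1L] else NA_real_)
}

#' Write / read a vibrational frequency set CSV
#'
#' One frequency (cm^-1) per line under the header `frequency_cm1`; the
#' set's role travels in a `#` comment line.
#'
#' @param x A [frequency_set()].
#' @param path File path.
#' @return `read_frequency_csv` returns a [frequency_set()].
#' @export
write_frequency_csv <- function(x, path) {
  stopifnot(inherits(x, "frequency_set"))
  .write_csv_atomic(data.frame(frequency_cm1 = x$frequencies), path,
                    sprintf("role: %s", x$role))
}

#' @rdname write_frequency_csv
#' @export
read_frequency_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  hdr <- grep("^# role:", readLines(path, n = 5L), value = TRUE)
  role <- if (length(hdr)) sub("^# role: *", "", hdr[1L]) else "minimum"
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  .check_columns(df, "frequency_cm1", path)
  df <- .check_numeric_rows(df, "frequency_cm1", path)
  frequency_set(df$frequency_cm1, role = role)
}

#' Write / read a 2D photoelectron spectrum CSV
#'
#' Matrix layout: first row is the eKE axis (eV), first column the
#' photon-energy axis (eV), body the intensity.
#'
#' @param x A `pe_spectrum_2d`.
#' @param path File path.
#' @return `read_pe2d_csv` returns a `pe_spectrum_2d` (without component
#'   masks).
#' @export
write_pe2d_csv <- function(x, path) {
  stopifnot(inherits(x, "pe_spectrum_2d"))
  m <- rbind(c(NA, x$eke), cbind(x$hv, x$intensity))
  tmp <- paste0(path, ".tmp")
  utils::write.table(m, tmp, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "hv_eV.eke_eV")
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_pe2d_csv
#' @export
read_pe2d_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  m <- as.matrix(utils::read.csv(path, header = FALSE, skip = 1L,
                                 colClasses = "numeric"))
  first <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  eke <- as.numeric(first[-1L])
  structure(list(hv = unname(m[, 1L]), eke = eke,
                 intensity = unname(m[, -1L, drop = FALSE]),
                 components = NULL),
            class = "pe_spectrum_2d")
}
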
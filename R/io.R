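#' Read an in-line spectra series from wide CSV
#'
#' The dialect is one row per acquisition: the first header cell must be
#' `time_h` and the remaining header cells are wavelengths in nm. A
#' sidecar file `<path>.events.json` (a JSON array of sampling times in
#' hours), when present, populates `sampling_events`.
#'
#' @param path CSV file path.
#' @return A [spectra_series()].
#' @export
read_spectra <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("spectra file is empty or has no data rows: ", path, call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "time_h")
    stop("first header cell must be 'time_h', got '", header[1], "'",
         call. = FALSE)
  wl <- suppressWarnings(as.numeric(header[-1]))
  if (any(is.na(wl)))
    stop("non-numeric wavelength in header", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelength header is not strictly increasing", call. = FALSE)

  ncol_exp <- length(header)
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(f) != ncol_exp)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i, ncol_exp, length(f)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("line %d: non-numeric value", i), call. = FALSE)
    v
  })
  m <- do.call(rbind, rows)
  events <- NULL
  side <- paste0(path, ".events.json")
  if (file.exists(side))
    events <- as.numeric(jsonlite::read_json(side, simplifyVector = TRUE))
  spectra_series(m[, 1], wl, m[, -1, drop = FALSE], sampling_events = events)
}

#' Write an in-line spectra series to wide CSV
#'
#' Values are serialized at full double precision so that
#' `read_spectra(write_spectra(x))` is an identity on values. Sampling
#' events, when present, are written to `<path>.events.json`.
#'
#' @param series A [spectra_series()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(series, path) {
  stopifnot(inherits(series, "spectra_series"))
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  header <- paste(c("time_h", fmt(series$wavelengths)), collapse = ",")
  body <- apply(cbind(series$times, series$absorbance), 1L,
                function(r) paste(fmt(r), collapse = ","))
  writeLines(c(header, body), path)
  if (!is.null(series$sampling_events))
    jsonlite::write_json(series$sampling_events,
                         paste0(path, ".events.json"), digits = NA)
  invisible(path)
}

#' Read/write off-line assay series
#'
#' CSV with header `time_h,F_molL,POH_molL`; empty fields are missing
#' values.
#'
#' @param path CSV file path.
#' @return `read_offline_series()`: a data frame (classes
#'   `"offline_series"`, `"data.frame"`).
#' @export
read_offline_series <- function(path) {
  d <- utils::read.csv(path, colClasses = "numeric")
  req <- c("time_h", "F_molL", "POH_molL")
  if (!all(req %in% names(d)))
    stop("offline series must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  class(d) <- c("offline_series", "data.frame")
  d
}

#' @rdname read_offline_series
#' @param series Data frame with `time_h`, `F_molL`, `POH_molL`.
#' @export
write_offline_series <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("time_h", "F_molL", "POH_molL")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write UV spectra
#'
#' Single-condition files are CSV `wavelength_nm,absorbance`; the long
#' format adds a `condition` column in `pH6`, `pH12`, `NaOH02M` and is
#' split into a named list.
#'
#' @param path CSV file path.
#' @return A data frame, or a named list of data frames for the long
#'   format.
#' @export
read_uv_spectrum <- function(path) {
  d <- utils::read.csv(path)
  if ("condition" %in% names(d)) {
    if (!all(d$condition %in% c("pH6", "pH12", "NaOH02M")))
      stop("unknown 'condition' values; expected pH6, pH12, NaOH02M",
           call. = FALSE)
    return(lapply(split(d, d$condition),
                  function(s) s[, c("wavelength_nm", "absorbance")]))
  }
  if (!all(c("wavelength_nm", "absorbance") %in% names(d)))
    stop("UV spectrum needs columns 'wavelength_nm' and 'absorbance'",
         call. = FALSE)
  d
}
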
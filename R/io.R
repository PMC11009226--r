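#' Write a 1D spectrum as two-column delimited text
#'
#' Values are written with 17 significant digits so a read/write round trip
#' is exact at double precision. Header lines are `#`-prefixed
#' `key: value` pairs; the temperature is always recorded.
#'
#' @param spectrum a [spectrum1d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum1d <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_c: %.17g", spectrum$temperature), con)
  meta <- spectrum$metadata
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.atomic(v) && length(v) == 1L)
      writeLines(sprintf("# %s: %s", k, format(v, digits = 17)), con)
  }
  writeLines("# columns: wavenumber_cm1 absorbance", con)
  writeLines(sprintf("%.17g %.17g", spectrum$wavenumber,
                     spectrum$absorbance), con)
  invisible(path)
}

#' Read a 1D spectrum from delimited text
#'
#' Accepts the format of [write_spectrum1d()] (whitespace-separated, `#`
#' headers) or a CSV with named columns `wavenumber` and `absorbance`.
#'
#' @param path input path.
#' @param temperature override for the temperature, degC; otherwise taken
#'   from a `temperature_c` header if present.
#' @return A [spectrum1d()].
#' @export
read_spectrum1d <- function(path, temperature = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[[trimws(m[2L])]] <- trimws(m[3L])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no data rows in ", path)
  csv <- grepl(",", body[1L])
  if (csv && grepl("[A-Za-z]", body[1L])) {
    df <- read.table(text = body, header = TRUE, sep = ",",
                     strip.white = TRUE)
    need <- c("wavenumber", "absorbance")
    if (!all(need %in% names(df)))
      stop("CSV input must have columns 'wavenumber' and 'absorbance'")
    wn <- df$wavenumber
    ab <- df$absorbance
  } else {
    sep <- if (csv) "," else ""
    df <- tryCatch(
      read.table(text = body, header = FALSE, sep = sep,
                 colClasses = "numeric"),
      warning = function(w) stop("malformed numeric rows in ", path),
      error = function(e) {
        # find first offending row for the error message
        for (i in seq_along(body)) {
          v <- suppressWarnings(as.numeric(strsplit(
            trimws(body[i]), if (csv) "," else "[[:space:]]+")[[1L]]))
          if (length(v) < 2L || anyNA(v))
            stop("malformed row at data line ", i, ": '", body[i], "'")
        }
        stop("malformed data in ", path)
      })
    if (ncol(df) < 2L) stop("expected two numeric columns in ", path)
    wn <- df[[1L]]
    ab <- df[[2L]]
  }
  if (any(diff(wn) <= 0))
    stop("wavenumber column is not strictly increasing in ", path)
  if (is.null(temperature))
    temperature <- suppressWarnings(as.numeric(meta[["temperature_c"]]))
  if (length(temperature) == 0L) temperature <- NA_real_
  spectrum1d(wn, ab, temperature = temperature, metadata = meta)
}

#' Write a 2D IR waiting-time series to a directory
#'
#' Layout: `manifest.yml` (axes, waiting times, temperature, metadata) plus
#' one whitespace-delimited matrix file `tw_<index>.txt` per waiting time
#' (rows = probe axis `omega_t`, columns = pump axis `omega_tau`), written
#' with 17 significant digits for exact round trips.
#'
#' @param series a [spectrum2d_series()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_2dir_series <- function(series, dir) {
  stopifnot(inherits(series, "spectrum2d_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("tw_%03d.txt", seq_along(series$waiting_times))
  manifest <- list(
    format = "chex2dir-2dir-series-v1",
    temperature_c = series$temperature,
    omega_tau = series$omega_tau,
    omega_t = series$omega_t,
    waiting_times_ps = series$waiting_times,
    files = files,
    mode = series$metadata$params$mode %||% NA
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"),
                   precision = 17L)
  for (i in seq_along(files)) {
    con <- file(file.path(dir, files[i]), "w")
    m <- series$matrices[[i]]
    writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                              collapse = " ")), con)
    close(con)
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a 2D IR waiting-time series directory
#'
#' @param dir directory written by [write_2dir_series()].
#' @return A [spectrum2d_series()].
#' @export
read_2dir_series <- function(dir) {
  mf_path <- file.path(dir, "manifest.yml")
  if (!file.exists(mf_path)) stop("no manifest.yml in ", dir)
  mf <- yaml::read_yaml(mf_path)
  nt <- length(mf$omega_t)
  ntau <- length(mf$omega_tau)
  mats <- lapply(seq_along(mf$files), function(i) {
    fp <- file.path(dir, mf$files[[i]])
    if (!file.exists(fp))
      stop("manifest lists missing matrix file: ", mf$files[[i]])
    m <- as.matrix(read.table(fp, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != nt || ncol(m) != ntau)
      stop(sprintf("matrix file %s is %d x %d but the manifest axes are %d x %d",
                   mf$files[[i]], nrow(m), ncol(m), nt, ntau))
    m
  })
  spectrum2d_series(as.numeric(mf$omega_tau), as.numeric(mf$omega_t),
                    as.numeric(mf$waiting_times_ps), mats,
                    temperature = as.numeric(mf$temperature_c %||% NA),
                    metadata = list(mode = mf$mode))
}
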
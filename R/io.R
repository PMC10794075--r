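#' Read and write spectral datasets as CSV
#'
#' The on-disk dialect is a comma-separated table with a header row
#' `wavenumber,<id1>,<id2>,...`, `.` as the decimal separator and one row
#' per grid point. Rows may appear in any wavenumber order in a file;
#' reading sorts the axis ascending and keeps each trace paired with its
#' wavenumber. Round-tripping write then read reproduces grid and traces to
#' better than 1e-9.
#'
#' @param path file path.
#' @param mode trace mode to tag the spectra with, see [ftir_spectrum()].
#' @return `read_spectrum_csv()` returns a [spectral_dataset()];
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, mode = c("absorbance", "second_derivative")) {
  mode <- match.arg(mode)
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e))))
  if (ncol(raw) < 2)
    stop("spectrum CSV needs a wavenumber column plus at least one trace column")
  if (nrow(raw) < 1) stop("spectrum CSV has no data rows")
  num <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(raw[[j]]) & raw[[j]] != "")
    bad <- c(bad, which(is.na(raw[[j]]) | raw[[j]] == ""))
    if (length(bad) > 0)
      stop(sprintf("non-numeric or missing cell in column '%s', data row %d",
                   names(raw)[j], min(bad)))
  }
  wn <- num[[1]]
  grid <- grid_from_values(wn)  # rejects duplicates / non-uniform axes
  ord <- order(wn)
  traces <- do.call(rbind, lapply(num[-1], function(v) v[ord]))
  spectral_dataset(traces, grid = grid, ids = names(raw)[-1], mode = mode)
}

#' @rdname read_spectrum_csv
#' @param ds a `spectral_dataset` to write.
#' @export
write_spectrum_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- data.frame(wavenumber = ds$grid$values, t(ds$traces),
                   check.names = FALSE)
  names(df) <- c("wavenumber", ds$ids)
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write concentration tables as CSV
#'
#' Header `sample,Glc,Fru,Suc,GF2,GF3,GF4` (any subset of the component
#' vocabulary), concentrations in g/L.
#'
#' @param path file path.
#' @return `read_concentration_csv()` returns a [concentration_table()];
#'   the writer returns `path` invisibly.
#' @export
read_concentration_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  concentration_table(df)
}

#' @rdname read_concentration_csv
#' @param ct a `conc_table` to write.
#' @export
write_concentration_csv <- function(ct, path) {
  stopifnot(inherits(ct, "conc_table"))
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a minimal JCAMP-DX spectrum
#'
#' Supports the small fixed-format subset commonly produced for infrared
#' exchange: `##XUNITS=1/CM`, tabular `##XYDATA=(X++(Y..Y))` records in
#' plain (AFFN) form, with optional `##XFACTOR`, `##YFACTOR` and
#' `##TITLE`. Descending axes are reversed to the ascending in-memory
#' convention. Read-only; writing JCAMP is out of scope.
#'
#' @param path file path.
#' @param mode trace mode tag, see [ftir_spectrum()].
#' @return An [ftir_spectrum()].
#' @export
read_jcamp <- function(path, mode = c("absorbance", "second_derivative")) {
  mode <- match.arg(mode)
  lines <- readLines(path, warn = FALSE)
  field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^##", key, "="), "", hit[1]))
  }
  xunits <- field("XUNITS")
  if (is.null(xunits) || toupper(xunits) != "1/CM")
    stop("only ##XUNITS=1/CM JCAMP files are supported")
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (length(start) != 1)
    stop("expected exactly one ##XYDATA=(X++(Y..Y)) block")
  xf <- as.numeric(field("XFACTOR") %||% "1")
  yf <- as.numeric(field("YFACTOR") %||% "1")
  body <- lines[seq.int(start + 1, length(lines))]
  body <- body[!grepl("^##", body)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop("empty XYDATA block")
  xs <- list(); ys <- list()
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
    if (anyNA(vals) || length(vals) < 2)
      stop(sprintf("cannot parse XYDATA line: '%s'", ln))
    xs[[length(xs) + 1]] <- vals[1]
    ys[[length(ys) + 1]] <- vals[-1]
  }
  ny <- lengths(ys)
  x0 <- unlist(xs) * xf
  # per-line abscissa spacing from the next line start (last line reuses it)
  if (length(x0) > 1) {
    dx <- diff(x0) / ny[-length(ny)]
    dx <- c(dx, dx[length(dx)])
  } else {
    dx <- as.numeric(field("DELTAX") %||% NA) * xf
    if (is.na(dx)) stop("single-line XYDATA needs ##DELTAX")
    dx <- rep(dx, 1)
  }
  wn <- unlist(lapply(seq_along(ys), function(i)
    x0[i] + dx[i] * (seq_len(ny[i]) - 1)))
  y <- unlist(ys) * yf
  ord <- order(wn)
  ftir_spectrum(grid_from_values(wn[ord]), y[ord], mode = mode,
                label = field("TITLE") %||% basename(path))
}
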
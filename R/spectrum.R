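#' Single spectrum on a wavenumber grid
#'
#' A spectrum pairs a [make_grid()] axis with an intensity trace, either raw
#' absorbance (AU) or Savitzky-Golay second-derivative values
#' (AU per (cm\eqn{^{-1}})\eqn{^2}).
#'
#' @param grid a `wn_grid`.
#' @param trace numeric intensities, one per grid point; must be finite.
#' @param mode `"absorbance"` or `"second_derivative"`.
#' @param label free-text identifier.
#' @return An object of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(grid, trace, mode = c("absorbance", "second_derivative"),
                          label = "") {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "wn_grid"))
  if (length(trace) != length(grid$values))
    stop(sprintf("trace length %d does not match grid length %d",
                 length(trace), length(grid$values)))
  if (!all(is.finite(trace))) stop("trace values must be finite")
  structure(list(grid = grid, trace = as.numeric(trace), mode = mode,
                 label = as.character(label)),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> '%s' (%s), %g-%g cm^-1, %d points\n",
              x$label, x$mode, x$grid$stop, x$grid$start,
              length(x$grid$values)))
  invisible(x)
}

#' Crop to a wavenumber window
#'
#' Keeps exactly the grid points inside `[lo, hi]` (both endpoints
#' inclusive); trace values are untouched at the retained points.
#'
#' @param x an `ftir_spectrum` or `spectral_dataset`.
#' @param lo,hi window bounds in cm\eqn{^{-1}} (either order).
#' @return Object of the same class on the cropped grid.
#' @examples
#' s <- ftir_spectrum(make_grid(4000, 400, 2), rnorm(1801))
#' length(crop(s, 900, 1250)$trace) # 176
#' @export
crop <- function(x, lo, hi) UseMethod("crop")

crop_index <- function(grid, lo, hi) {
  w <- sort(c(lo, hi))
  keep <- which(grid$values >= w[1] - 1e-9 & grid$values <= w[2] + 1e-9)
  if (length(keep) == 0)
    stop(sprintf("window [%g, %g] does not intersect the grid span [%g, %g]",
                 w[1], w[2], grid$start, grid$stop))
  keep
}

#' @export
crop.ftir_spectrum <- function(x, lo, hi) {
  keep <- crop_index(x$grid, lo, hi)
  ftir_spectrum(grid_from_values(x$grid$values[keep]), x$trace[keep],
                mode = x$mode, label = x$label)
}

#' Collection of spectra sharing one grid
#'
#' Stored as a samples-by-wavenumbers trace matrix with unique sample ids.
#'
#' @param traces numeric matrix (samples in rows) or a list of
#'   `ftir_spectrum` objects on identical grids.
#' @param grid the shared `wn_grid` (ignored when `traces` is a list).
#' @param ids unique sample identifiers; defaults to spectrum labels or
#'   `s1, s2, ...`.
#' @param mode trace mode, as in [ftir_spectrum()].
#' @return An object of class `spectral_dataset` with fields `grid`,
#'   `traces`, `ids`, `mode`.
#' @export
spectral_dataset <- function(traces, grid = NULL, ids = NULL,
                             mode = c("absorbance", "second_derivative")) {
  mode <- match.arg(mode)
  if (is.list(traces) && !is.matrix(traces)) {
    spectra <- traces
    stopifnot(length(spectra) >= 1,
              all(vapply(spectra, inherits, TRUE, "ftir_spectrum")))
    grid <- spectra[[1]]$grid
    for (s in spectra) {
      if (!grids_identical(grid, s$grid))
        stop("all spectra in a dataset must share an identical grid")
    }
    modes <- unique(vapply(spectra, `[[`, "", "mode"))
    if (length(modes) != 1) stop("all spectra must share one mode")
    mode <- modes
    if (is.null(ids)) {
      ids <- vapply(spectra, `[[`, "", "label")
      if (any(ids == "")) ids <- paste0("s", seq_along(spectra))
    }
    traces <- do.call(rbind, lapply(spectra, `[[`, "trace"))
  }
  stopifnot(is.matrix(traces), inherits(grid, "wn_grid"),
            ncol(traces) == length(grid$values))
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(traces)))
  ids <- as.character(ids)
  if (length(ids) != nrow(traces)) stop("one id per spectrum required")
  if (anyDuplicated(ids))
    stop(sprintf("duplicated sample id: %s", ids[duplicated(ids)][1]))
  if (!all(is.finite(traces))) stop("trace values must be finite")
  dimnames(traces) <- list(ids, NULL)
  structure(list(grid = grid, traces = traces, ids = ids, mode = mode),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra (%s), %g-%g cm^-1, %d points\n",
              nrow(x$traces), x$mode, x$grid$stop, x$grid$start,
              length(x$grid$values)))
  invisible(x)
}

#' @export
crop.spectral_dataset <- function(x, lo, hi) {
  keep <- crop_index(x$grid, lo, hi)
  spectral_dataset(x$traces[, keep, drop = FALSE],
                   grid = grid_from_values(x$grid$values[keep]),
                   ids = x$ids, mode = x$mode)
}

#' Extract one spectrum from a dataset
#'
#' @param ds a `spectral_dataset`.
#' @param id sample id or row index.
#' @return An `ftir_spectrum`.
#' @export
get_spectrum <- function(ds, id) {
  stopifnot(inherits(ds, "spectral_dataset"))
  i <- if (is.character(id)) match(id, ds$ids) else as.integer(id)
  if (is.na(i) || i < 1 || i > nrow(ds$traces))
    stop(sprintf("no spectrum '%s' in dataset", id))
  ftir_spectrum(ds$grid, ds$traces[i, ], mode = ds$mode, label = ds$ids[i])
}
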
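#' Savitzky-Golay derivative parameters
#'
#' The acquisition-matched default is a 17-point window. The polynomial
#' order is not fixed by the acquisition convention; the default is 3,
#' which for symmetric windows yields the same second derivative as
#' order 2.
#'
#' @param window odd window length in points (>= polyorder + 1).
#' @param polyorder polynomial degree (>= 2, since a second derivative is
#'   taken).
#' @return An object of class `sg_params`.
#' @export
sg_params <- function(window = 17, polyorder = 3) {
  stopifnot(length(window) == 1, length(polyorder) == 1)
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder < 2) stop("polyorder must be >= 2 for a second derivative")
  if (window < polyorder + 1) stop("window must be >= polyorder + 1")
  structure(list(window = as.integer(window),
                 polyorder = as.integer(polyorder), deriv = 2L),
            class = "sg_params")
}

# central SG second-derivative coefficients, scaled to the grid step, so
# convolution yields d2A/dnu2 in AU per (cm^-1)^2
sg_coefficients <- function(p, step) {
  F <- signal::sgolay(p = p$polyorder, n = p$window, m = 2, ts = step)
  co <- F[(p$window + 1) / 2, ]
  as.numeric(co)
}

# valid-region convolution: one output value wherever the full window fits
sg_filter_valid <- function(trace, co) {
  drop(stats::embed(trace, length(co)) %*% rev(co))
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' At each point where the full window fits, the returned value is the
#' second derivative at the window center of the least-squares polynomial
#' fit to the windowed trace, expressed per (cm\eqn{^{-1}})\eqn{^2}. No
#' padding is invented: the returned spectrum lives on the grid trimmed by
#' half a window on each side, so a derivative taken on the full
#' acquisition grid is unaffected by edge handling anywhere inside the
#' fingerprint region. Values are carried with their natural sign --
#' absorbance maxima appear as second-derivative minima.
#'
#' @param s an absorbance [ftir_spectrum()].
#' @param p an [sg_params()].
#' @return An [ftir_spectrum()] with `mode = "second_derivative"`.
#' @examples
#' g <- make_grid(4000, 400, 2)
#' s <- ftir_spectrum(g, 3 * g$values^2)
#' range(second_derivative(s)$trace) # constant 6
#' @export
second_derivative <- function(s, p = sg_params()) {
  stopifnot(inherits(s, "ftir_spectrum"), inherits(p, "sg_params"))
  if (s$mode != "absorbance")
    stop("second_derivative expects an absorbance spectrum")
  n <- length(s$grid$values)
  if (n < p$window)
    stop(sprintf("grid length %d is shorter than the %d-point window",
                 n, p$window))
  co <- sg_coefficients(p, s$grid$step)
  h <- (p$window - 1) / 2
  keep <- seq.int(h + 1, n - h)
  ftir_spectrum(grid_from_values(s$grid$values[keep]),
                sg_filter_valid(s$trace, co),
                mode = "second_derivative", label = s$label)
}

#' Explanatory-variable matrix for modelling
#'
#' Assembles the samples-by-wavenumbers table consumed by the
#' simultaneous-equation and PLS stages. When the derivative is requested
#' it is computed on the full supplied grid *before* cropping, so window
#' edge effects fall outside any interior region; the region must lie
#' within the derivative's valid grid.
#'
#' @param ds a [spectral_dataset()] in absorbance mode (full acquisition
#'   grid when `use_derivative = TRUE`).
#' @param region length-2 window in cm\eqn{^{-1}} (either order).
#' @param use_derivative apply the Savitzky-Golay second derivative first?
#' @param p an [sg_params()].
#' @return Numeric matrix, rows in dataset order (names = sample ids),
#'   columns in ascending wavenumber order (names = wavenumbers).
#' @examples
#' lib <- default_band_library()
#' ds <- synthesize_dataset(table1_design(), lib, make_grid(4000, 400, 2))
#' dim(prepare_matrix(ds, c(900, 1250), use_derivative = TRUE)) # 18 x 176
#' @export
prepare_matrix <- function(ds, region = c(900, 1250), use_derivative = FALSE,
                           p = sg_params()) {
  stopifnot(inherits(ds, "spectral_dataset"), length(region) == 2)
  region <- sort(region)
  if (region[1] < ds$grid$start - 1e-9 || region[2] > ds$grid$stop + 1e-9)
    stop(sprintf("region [%g, %g] is wider than the grid span [%g, %g]",
                 region[1], region[2], ds$grid$start, ds$grid$stop))
  if (use_derivative) {
    if (ds$mode != "absorbance")
      stop("derivative preprocessing expects absorbance spectra")
    co <- sg_coefficients(p, ds$grid$step)
    h <- (p$window - 1) / 2
    n <- length(ds$grid$values)
    if (n < p$window) stop("grid shorter than the derivative window")
    values <- ds$grid$values[seq.int(h + 1, n - h)]
    if (region[1] < values[1] - 1e-9 || region[2] > values[length(values)] + 1e-9)
      stop("region overlaps the derivative edge margin; supply full-grid spectra")
    traces <- t(apply(ds$traces, 1, sg_filter_valid, co = co))
  } else {
    values <- ds$grid$values
    traces <- ds$traces
  }
  keep <- which(values >= region[1] - 1e-9 & values <= region[2] + 1e-9)
  out <- traces[, keep, drop = FALSE]
  dimnames(out) <- list(ds$ids, values[keep])
  out
}
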
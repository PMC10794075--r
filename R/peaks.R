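#' Peak-extraction parameters
#'
#' @param prominence minimum peak deviation as a fraction of the region's
#'   maximum baseline-subtracted deviation; in (0, 1). Default 0.02.
#' @param separation minimum spacing between retained peaks in
#'   cm\eqn{^{-1}}; must be at least the grid step. Default 6 (three grid
#'   steps at 2 cm\eqn{^{-1}}).
#' @param max_peaks cap on the number of peaks, kept by descending
#'   prominence. Default unlimited.
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(prominence = 0.02, separation = 6, max_peaks = Inf) {
  if (prominence <= 0 || prominence >= 1)
    stop("prominence must lie in (0, 1)")
  if (separation < 0) stop("separation must be non-negative")
  if (max_peaks < 1) stop("max_peaks must be at least 1")
  structure(list(prominence = prominence, separation = separation,
                 max_peaks = max_peaks), class = "peak_params")
}

#' Set of selected wavenumbers with provenance
#'
#' @param wavenumber cm\eqn{^{-1}} positions (unique).
#' @param source per-position provenance tag (the component the position
#'   came from).
#' @param prominence optional per-position relative prominence.
#' @return A `wn_set`: a data.frame sorted by wavenumber.
#' @export
wn_set <- function(wavenumber, source = NA_character_, prominence = NA_real_) {
  if (anyDuplicated(wavenumber))
    stop(sprintf("duplicated wavenumber in set: %g",
                 wavenumber[duplicated(wavenumber)][1]))
  df <- data.frame(wavenumber = as.numeric(wavenumber),
                   source = rep_len(as.character(source), length(wavenumber)),
                   prominence = rep_len(as.numeric(prominence),
                                        length(wavenumber)))
  df <- df[order(df$wavenumber), ]
  rownames(df) <- NULL
  class(df) <- c("wn_set", "data.frame")
  df
}

#' Extract characteristic peak wavenumbers from a pure-component spectrum
#'
#' For absorbance spectra, band centers are local maxima; for
#' second-derivative spectra they are local minima. Candidate extrema are
#' filtered by relative prominence (deviation from the region's baseline,
#' expressed as a fraction of the largest deviation -- invariant to adding
#' a constant offset), then thinned greedily in order of descending
#' prominence so retained peaks are at least `separation` apart, and
#' finally capped at `max_peaks`. A flat spectrum yields an empty set.
#'
#' @param pure an [ftir_spectrum()] covering `region`.
#' @param region length-2 window in cm\eqn{^{-1}}.
#' @param p a [peak_params()].
#' @param source provenance tag stored with each peak (defaults to the
#'   spectrum label).
#' @return A [wn_set()].
#' @examples
#' g <- make_grid(1250, 900, 2)
#' s <- ftir_spectrum(g, exp(-(g$values - 1080)^2 / 128))
#' extract_peaks(s, c(900, 1250))$wavenumber # 1080
#' @export
extract_peaks <- function(pure, region = c(900, 1250), p = peak_params(),
                          source = NULL) {
  stopifnot(inherits(pure, "ftir_spectrum"), inherits(p, "peak_params"))
  if (p$separation < pure$grid$step)
    stop("separation must be at least the grid step")
  s <- crop(pure, region[1], region[2])
  z <- if (pure$mode == "second_derivative") -s$trace else s$trace
  dev <- z - min(z)
  src <- source %||% pure$label
  if (max(dev) == 0) return(wn_set(numeric(0), character(0)))
  n <- length(z)
  if (n < 3) return(wn_set(numeric(0), character(0)))
  i <- 2:(n - 1)
  loc <- i[z[i] > z[i - 1] & z[i] > z[i + 1]]
  loc <- loc[dev[loc] >= p$prominence * max(dev)]
  loc <- loc[order(-dev[loc])]
  keep <- integer(0)
  for (l in loc) {
    if (length(keep) == 0 ||
        all(abs(s$grid$values[keep] - s$grid$values[l]) >= p$separation))
      keep <- c(keep, l)
  }
  if (length(keep) > p$max_peaks) keep <- keep[seq_len(p$max_peaks)]
  wn_set(s$grid$values[keep], source = src,
         prominence = dev[keep] / max(dev))
}

#' Build the A/B/C wavenumber-selection patterns
#'
#' The three nested explanatory-variable patterns for one target
#' component: A is every grid point in the region (the full fingerprint
#' model), B is the target component's own peak set, and C augments B with
#' every other component's peaks (the multi-component selection). By
#' construction B is a subset of C and C of A.
#'
#' @param component target component name.
#' @param peaksets named list of per-component peak sets ([wn_set()] or
#'   numeric vectors), e.g. from [extract_peaks()] on each pure spectrum.
#' @param region length-2 window in cm\eqn{^{-1}}.
#' @param grid the working [make_grid()] axis.
#' @return Named list of three [wn_set()] objects `A`, `B`, `C`; C carries
#'   the contributing component(s) of each wavenumber as provenance.
#' @export
build_selection <- function(component, peaksets, region, grid) {
  stopifnot(inherits(grid, "wn_grid"), length(region) == 2)
  if (!component %in% names(peaksets))
    stop(sprintf("no peak set supplied for target component '%s'", component))
  as_wn <- function(x) if (inherits(x, "wn_set")) x$wavenumber else as.numeric(x)
  region <- sort(region)
  in_region <- function(w) w[w >= region[1] - 1e-9 & w <= region[2] + 1e-9]
  b_wn <- in_region(as_wn(peaksets[[component]]))
  if (length(b_wn) == 0)
    stop(sprintf("peak set for '%s' is empty within the region", component))
  all_wn <- lapply(peaksets, function(x) in_region(as_wn(x)))
  union_wn <- sort(unique(unlist(all_wn)))
  src <- vapply(union_wn, function(w) {
    paste(names(all_wn)[vapply(all_wn, function(v) any(abs(v - w) <= 1e-9),
                               TRUE)], collapse = "+")
  }, "")
  for (w in union_wn) match_wavenumbers(w, grid$values)  # must sit on grid
  A <- wn_set(in_region(grid$values), source = "region")
  B <- wn_set(b_wn, source = component)
  C <- wn_set(union_wn, source = src)
  list(A = A, B = B, C = C)
}

#' Assignment-derived fallback peak positions
#'
#' Literature band-assignment centers for users without pure-component
#' spectra: the glucose, fructose and sucrose fingerprint assignments and
#' the shared fructo-oligosaccharide bands, with the second-derivative
#' variant reflecting the small apparent shifts seen in derivative
#' spectra.
#'
#' @param mode `"absorbance"` or `"second_derivative"`.
#' @return Named list of numeric wavenumber vectors per component.
#' @export
assignment_peaks <- function(mode = c("absorbance", "second_derivative")) {
  mode <- match.arg(mode)
  fos_abs <- c(930, 994, 1034, 1060, 1134)
  fos_der <- c(930, 994, 1030, 1060, 1138)
  fos <- if (mode == "absorbance") fos_abs else fos_der
  list(Glc = c(1034, 1080),
       Fru = 1064,
       Suc = if (mode == "absorbance") c(1000, 1056) else c(996, 1056),
       GF2 = fos, GF3 = fos, GF4 = fos)
}
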
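#' Gaussian band library for spectral synthesis
#'
#' A band library assigns every component a list of Gaussian bands
#' (`center` cm\eqn{^{-1}}, `width` = Gaussian sigma in cm\eqn{^{-1}},
#' `height` = AU per g/L at the center) plus a set of broad water-background
#' bands. It is the ground-truth absorptivity profile \eqn{k_i(\nu)} used
#' by the Beer-Lambert mixer.
#'
#' Each component must carry its field-assigned fingerprint centers:
#' 1080 and 1034 (Glc), 1064 (Fru), 1056 and 1000 (Suc) and the shared
#' fructo-oligosaccharide bands 1134, 1034 and 930 cm\eqn{^{-1}}
#' (GF2/GF3/GF4); libraries missing them are rejected.
#'
#' @param components named list (names from [sugar_components()]) of
#'   data.frames with columns `center`, `width`, `height`.
#' @param water data.frame of the same shape describing the broad water
#'   background bands (centers may lie anywhere on the acquisition grid).
#' @return An object of class `band_library`.
#' @seealso [default_band_library()]
#' @export
band_library <- function(components, water) {
  stopifnot(is.list(components), length(components) >= 1, is.data.frame(water))
  unknown <- setdiff(names(components), sugar_components())
  if (length(unknown) > 0)
    stop(sprintf("unknown component name(s): %s",
                 paste(unknown, collapse = ", ")))
  required <- list(Glc = c(1080, 1034), Fru = 1064, Suc = c(1056, 1000),
                   GF2 = c(1134, 1034, 930), GF3 = c(1134, 1034, 930),
                   GF4 = c(1134, 1034, 930))
  check_bands <- function(df, who, fingerprint = TRUE) {
    stopifnot(is.data.frame(df))
    if (!all(c("center", "width", "height") %in% names(df)))
      stop(sprintf("%s bands need columns center, width, height", who))
    if (nrow(df) < 1) stop(sprintf("%s needs at least one band", who))
    if (any(df$width <= 0) || any(df$height <= 0))
      stop(sprintf("%s band widths and heights must be positive", who))
    invisible(df)
  }
  for (cm in names(components)) {
    df <- check_bands(components[[cm]], cm)
    need <- required[[cm]]
    for (ctr in need) {
      if (!any(abs(df$center - ctr) <= 2))
        stop(sprintf("component %s is missing its assigned band near %g cm^-1",
                     cm, ctr))
    }
    if (any(df$center < 900 | df$center > 1250))
      stop(sprintf("component %s has a band center outside 1250-900 cm^-1",
                   cm))
  }
  check_bands(water, "water")
  structure(list(components = lapply(components, function(d)
    d[order(-d$height), c("center", "width", "height")]),
    water = water[, c("center", "width", "height")]),
    class = "band_library")
}

#' Default band library
#'
#' Assignment-driven library for the six juice sugars. Centers follow the
#' carbohydrate C-O/C-C stretching assignments in the fingerprint region:
#' glucose 1080 (C1-H bending) and 1034 cm\eqn{^{-1}} (ether C-O / alcohol
#' C-OH), fructose 1064, sucrose 1056 and 1000 (glycosidic linkage), and
#' the common fructo-oligosaccharide bands 1134, 1060, 1034, 994 and
#' 930 cm\eqn{^{-1}}. GF2/GF3/GF4 share those centers with relative heights
#' differing by roughly 10-25\% and slightly varying widths, plus two
#' small oligomer-specific minor bands each, emulating how the degree of
#' polymerization perturbs otherwise similar profiles. Each component also
#' carries a few minor unnamed bands for realistic spectral complexity.
#'
#' The absolute scale puts the strongest band at 0.002 AU per g/L, i.e.
#' about 0.2 AU at 100 g/L -- a typical ATR magnitude. The water
#' background is a sum of very broad Gaussians (O-H stretch, association
#' band, H-O-H bending and the low-wavenumber libration shoulder).
#'
#' @return A [band_library()].
#' @export
default_band_library <- function() {
  comp <- list(
    Glc = data.frame(center = c(1080, 1034, 1148, 1108, 996, 918),
                     width  = c(9, 10, 8, 8, 9, 12),
                     height = c(16, 20, 5, 7, 9, 4) * 1e-4),
    Fru = data.frame(center = c(1064, 1082, 1152, 1010, 978),
                     width  = c(9, 7, 8, 10, 9),
                     height = c(20, 12, 6, 8, 10) * 1e-4),
    Suc = data.frame(center = c(1056, 1000, 1134, 1110, 928),
                     width  = c(9, 9, 8, 8, 10),
                     height = c(18, 20, 6, 8, 5) * 1e-4),
    GF2 = data.frame(center = c(1134, 1060, 1034, 994, 930, 1118, 966),
                     width  = c(12, 12, 12, 12, 12, 10, 10),
                     height = c(10, 13, 14, 11, 12, 4, 3) * 1e-4),
    GF3 = data.frame(center = c(1134, 1060, 1034, 994, 930, 1090, 952),
                     width  = c(13, 13, 13, 13, 13, 10, 10),
                     height = c(13, 10, 11, 14, 9, 4, 3) * 1e-4),
    GF4 = data.frame(center = c(1134, 1060, 1034, 994, 930, 1160, 1014),
                     width  = c(12, 12, 12, 12, 12, 10, 10),
                     height = c(9, 13, 12, 10, 14, 4, 3) * 1e-4))
  water <- data.frame(center = c(3350, 2120, 1640, 580),
                      width  = c(180, 150, 40, 220),
                      height = c(0.9, 0.05, 0.35, 0.25))
  band_library(comp, water)
}

#' @export
print.band_library <- function(x, ...) {
  n <- vapply(x$components, nrow, 0L)
  cat(sprintf("<band_library> %d components (%s), %d water bands\n",
              length(n), paste(sprintf("%s:%d", names(n), n), collapse = ", "),
              nrow(x$water)))
  invisible(x)
}

#' Read or write a band library as YAML
#'
#' The text form is a mapping `components: {<name>: [{center, width,
#' height}, ...]}` plus a `water` band list, so libraries can be versioned
#' and edited outside R.
#'
#' @param path file path.
#' @return `read_band_library()` returns a [band_library()]; the writer
#'   returns `path` invisibly.
#' @export
read_band_library <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!all(c("components", "water") %in% names(obj)))
    stop("band library YAML needs 'components' and 'water' entries")
  to_df <- function(lst) do.call(rbind, lapply(lst, as.data.frame))
  band_library(lapply(obj$components, to_df), to_df(obj$water))
}

#' @rdname read_band_library
#' @param lib a `band_library` to write.
#' @export
write_band_library <- function(lib, path) {
  stopifnot(inherits(lib, "band_library"))
  to_list <- function(df) lapply(seq_len(nrow(df)), function(i)
    list(center = df$center[i], width = df$width[i], height = df$height[i]))
  yaml::write_yaml(list(components = lapply(lib$components, to_list),
                        water = to_list(lib$water)), path)
  invisible(path)
}
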
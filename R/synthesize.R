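# Gaussian band evaluation and Beer-Lambert mixing for synthetic fixtures.

band_profile <- function(values, bands) {
  out <- numeric(length(values))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$height[i] *
      exp(-(values - bands$center[i])^2 / (2 * bands$width[i]^2))
  }
  out
}

# evaluate a seeded expression without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Water background spectrum
#'
#' @param lib a [band_library()].
#' @param grid a [make_grid()] axis.
#' @return Absorbance [ftir_spectrum()] of pure water.
#' @export
water_spectrum <- function(lib, grid) {
  stopifnot(inherits(lib, "band_library"), inherits(grid, "wn_grid"))
  ftir_spectrum(grid, band_profile(grid$values, lib$water),
                mode = "absorbance", label = "water")
}

#' Pure-component absorbance profile
#'
#' Evaluates `conc` times the component's Gaussian bands on `grid` and adds
#' the water background, i.e. the spectrum of a single-sugar aqueous
#' solution. Local absorbance maxima sit at the band centers whenever
#' neighbouring bands are separated by a few sigma.
#'
#' @param component component name from [sugar_components()].
#' @param lib a [band_library()].
#' @param grid a [make_grid()] axis.
#' @param conc concentration in g/L (>= 0).
#' @return Absorbance [ftir_spectrum()].
#' @examples
#' s <- pure_profile("Glc", default_band_library(), make_grid(4000, 400, 2), 100)
#' @export
pure_profile <- function(component, lib, grid, conc) {
  stopifnot(inherits(lib, "band_library"), inherits(grid, "wn_grid"),
            length(conc) == 1, is.finite(conc))
  if (!component %in% names(lib$components))
    stop(sprintf("unknown component '%s' (library has: %s)", component,
                 paste(names(lib$components), collapse = ", ")))
  if (conc < 0) stop("concentration must be non-negative")
  tr <- conc * band_profile(grid$values, lib$components[[component]]) +
    band_profile(grid$values, lib$water)
  ftir_spectrum(grid, tr, mode = "absorbance",
                label = sprintf("%s_%g", component, conc))
}

#' Measurement noise model
#'
#' Additive iid Gaussian noise plus a per-spectrum linear baseline tilt.
#' The tilt slope is drawn uniformly in `[-1, 1]` and scaled so its total
#' excursion across the acquisition grid equals `drift` AU. `sd = 0,
#' drift = 0` is the noiseless model.
#'
#' @param sd iid Gaussian standard deviation in AU (default 5e-4).
#' @param drift baseline tilt amplitude in AU across the grid (default 1e-3).
#' @param seed optional integer; when set, generation is bit-for-bit
#'   reproducible and leaves the caller's RNG untouched.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = 5e-4, drift = 1e-3, seed = NULL) {
  stopifnot(sd >= 0, drift >= 0)
  structure(list(sd = sd, drift = drift, seed = seed), class = "noise_model")
}

apply_noise <- function(traces, values, noise) {
  if (is.null(noise)) return(traces)
  x <- (values - mean(range(values))) / diff(range(values))  # [-0.5, 0.5]
  for (i in seq_len(nrow(traces))) {
    slope <- stats::runif(1, -1, 1)
    traces[i, ] <- traces[i, ] +
      stats::rnorm(ncol(traces), 0, noise$sd) + noise$drift * slope * x
  }
  traces
}

#' Beer-Lambert mixture spectrum
#'
#' Additive mixing: the noiseless trace is the water background plus
#' `sum_i c_i k_i(nu)` over the supplied components (spectral additivity
#' and the Bouguer-Beer law). Optional measurement noise adds iid Gaussian
#' deviates and a linear baseline tilt.
#'
#' @param concs named numeric vector of concentrations in g/L, or a
#'   one-row [concentration_table()].
#' @param lib a [band_library()].
#' @param grid a [make_grid()] axis.
#' @param noise optional [noise_model()].
#' @param label spectrum label.
#' @return Absorbance [ftir_spectrum()].
#' @export
mix_spectrum <- function(concs, lib, grid, noise = NULL, label = "mixture") {
  stopifnot(inherits(lib, "band_library"), inherits(grid, "wn_grid"))
  if (inherits(concs, "conc_table")) {
    if (nrow(concs) != 1) stop("mix_spectrum takes a single sample row")
    concs <- conc_matrix(concs)[1, ]
  }
  if (is.null(names(concs)) || any(names(concs) == ""))
    stop("concentrations must be a named vector")
  unknown <- setdiff(names(concs), names(lib$components))
  if (length(unknown) > 0)
    stop(sprintf("component(s) not in band library: %s",
                 paste(unknown, collapse = ", ")))
  if (any(concs < 0)) stop("negative concentration")
  tr <- band_profile(grid$values, lib$water)
  for (cm in names(concs)) {
    if (concs[[cm]] > 0)
      tr <- tr + concs[[cm]] * band_profile(grid$values, lib$components[[cm]])
  }
  tr <- matrix(tr, nrow = 1)
  tr <- with_local_seed(if (!is.null(noise)) noise$seed else NULL,
                        apply_noise(tr, grid$values, noise))
  ftir_spectrum(grid, drop(tr), mode = "absorbance", label = label)
}

#' Synthesize a spectral dataset from a concentration table
#'
#' One Beer-Lambert mixture spectrum per table row, with the noise model
#' applied per spectrum. With a seeded noise model the whole dataset is
#' reproducible bit-for-bit; changing the seed changes only the noise, not
#' the underlying noiseless traces.
#'
#' @param ct a [concentration_table()].
#' @param lib a [band_library()].
#' @param grid a [make_grid()] axis.
#' @param noise optional [noise_model()].
#' @return A [spectral_dataset()] in acquisition (absorbance) mode.
#' @export
synthesize_dataset <- function(ct, lib, grid, noise = NULL) {
  stopifnot(inherits(ct, "conc_table"), inherits(lib, "band_library"),
            inherits(grid, "wn_grid"))
  cm <- conc_matrix(ct)
  unknown <- setdiff(colnames(cm), names(lib$components))
  if (length(unknown) > 0)
    stop(sprintf("component(s) not in band library: %s",
                 paste(unknown, collapse = ", ")))
  water <- band_profile(grid$values, lib$water)
  K <- vapply(colnames(cm), function(comp)
    band_profile(grid$values, lib$components[[comp]]),
    numeric(length(grid$values)))
  traces <- cm %*% t(K) + matrix(water, nrow(cm), length(grid$values),
                                 byrow = TRUE)
  traces <- with_local_seed(if (!is.null(noise)) noise$seed else NULL,
                            apply_noise(traces, grid$values, noise))
  spectral_dataset(traces, grid = grid, ids = ct$sample, mode = "absorbance")
}

#' Pure-component standard set
#'
#' Convenience wrapper generating the single-sugar standard solutions used
#' for simultaneous-equation calibration: one spectrum per component at the
#' given concentration (by default ~120 g/L for mono-/disaccharides and
#' ~80 g/L for the fructo-oligosaccharides, matching typical standard
#' preparations).
#'
#' @param lib a [band_library()].
#' @param grid a [make_grid()] axis.
#' @param components component names (defaults to all in `lib`).
#' @param conc named or unnamed vector of standard concentrations in g/L,
#'   recycled across components.
#' @param noise optional [noise_model()].
#' @return List with `dataset` (a [spectral_dataset()], ids =
#'   component names) and `concentrations` (a [concentration_table()]
#'   with one nonzero component per row).
#' @export
standard_solutions <- function(lib, grid, components = names(lib$components),
                               conc = NULL, noise = NULL) {
  if (is.null(conc)) {
    conc <- ifelse(components %in% c("GF2", "GF3", "GF4"), 80, 120)
    names(conc) <- components
  }
  conc <- rep_len(unname(conc), length(components))
  m <- matrix(0, length(components), length(components),
              dimnames = list(components, components))
  diag(m) <- conc
  ct <- concentration_table(m)
  list(dataset = synthesize_dataset(ct, lib, grid, noise),
       concentrations = ct)
}
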
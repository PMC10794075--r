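#' Root mean square error
#'
#' @param pred,ref equal-length numeric vectors (length >= 1).
#' @return `sqrt(mean((pred - ref)^2))`, in the units of the inputs.
#' @export
rmse <- function(pred, ref) {
  if (length(pred) == 0) stop("rmse of empty input")
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  sqrt(mean((pred - ref)^2))
}

#' Fixed-intercept Beer-Lambert calibration at one wavenumber
#'
#' Regresses standard values on concentration as a straight line whose
#' intercept is pinned to the pure-water value at that wavenumber; the
#' least-squares slope through the fixed intercept is
#' `sum(c * (value - water)) / sum(c^2)`. A single standard determines the
#' slope exactly.
#'
#' @param conc standard concentrations in g/L (at least one > 0).
#' @param value measured values (absorbance or second-derivative units) at
#'   one wavenumber, same length as `conc`.
#' @param water_value pure-water value at that wavenumber (the fixed
#'   intercept).
#' @param component,wavenumber optional bookkeeping tags.
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `water`, `component`, `wavenumber`.
#' @export
fit_calibration <- function(conc, value, water_value,
                            component = NA_character_,
                            wavenumber = NA_real_) {
  if (length(conc) < 1 || length(conc) != length(value))
    stop("need matching conc/value standards")
  if (all(conc == 0)) stop("all standard concentrations are zero")
  slope <- sum(conc * (value - water_value)) / sum(conc^2)
  if (!is.finite(slope)) stop("non-finite calibration slope")
  structure(list(component = component, wavenumber = wavenumber,
                 slope = slope, water = water_value),
            class = "calibration_curve")
}

#' Calibrate slopes for all components at a set of wavenumbers
#'
#' Builds the full slope table `k_i(nu_j)` from single-sugar standard
#' spectra: each dataset row must contain exactly one nonzero component,
#' and all rows for a component enter its fixed-intercept regression at
#' every requested wavenumber.
#'
#' @param ds a [spectral_dataset()] of standard spectra.
#' @param ct [concentration_table()] of the standards (one nonzero
#'   component per row).
#' @param wavenumbers calibration wavenumbers; must lie on the grid of `ds`.
#' @param water an [ftir_spectrum()] of pure water in the same mode and on
#'   a grid containing `wavenumbers` (for second-derivative work, pass the
#'   derivative of the water spectrum).
#' @return An object of class `se_calibration`: slope matrix `K`
#'   (wavenumbers x components), water vector `water`, plus `wavenumbers`,
#'   `components` and `mode`.
#' @export
se_calibrate <- function(ds, ct, wavenumbers, water) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(ct, "conc_table"),
            inherits(water, "ftir_spectrum"))
  if (ds$mode != water$mode)
    stop("standards and water spectrum must share one mode")
  cm <- conc_matrix(ct)
  if (!all(ds$ids %in% rownames(cm)))
    stop("every standard spectrum needs a concentration row")
  cm <- cm[ds$ids, , drop = FALSE]
  nz <- rowSums(cm > 0)
  if (any(nz != 1))
    stop("each standard row must contain exactly one nonzero component")
  wavenumbers <- sort(wavenumbers)
  idx <- match_wavenumbers(wavenumbers, ds$grid$values)
  widx <- match_wavenumbers(wavenumbers, water$grid$values)
  comps <- colnames(cm)[colSums(cm > 0) > 0]
  K <- matrix(NA_real_, length(wavenumbers), length(comps),
              dimnames = list(wavenumbers, comps))
  for (cn in comps) {
    rows <- which(cm[, cn] > 0)
    for (j in seq_along(wavenumbers)) {
      K[j, cn] <- fit_calibration(cm[rows, cn], ds$traces[rows, idx[j]],
                                  water$trace[widx[j]])$slope
    }
  }
  structure(list(wavenumbers = wavenumbers, components = comps, K = K,
                 water = water$trace[widx], mode = ds$mode),
            class = "se_calibration")
}

match_wavenumbers <- function(wn, values, tol = 1e-6) {
  idx <- vapply(wn, function(w) {
    i <- which(abs(values - w) <= tol)
    if (length(i) != 1)
      stop(sprintf("wavenumber %g is not on the working grid", w))
    i
  }, 0L)
  idx
}

#' Square simultaneous-equation model
#'
#' Selects `m = K` calibration wavenumbers to form the square Beer-Lambert
#' system `K c = a - a_w` relating measured values to component
#' concentrations with the pure-water vector as intercept.
#'
#' @param calib an [se_calibrate()] result.
#' @param wavenumbers the selected wavenumbers (length = number of
#'   components).
#' @return An object of class `se_model` with the square slope matrix `K`,
#'   water vector, wavenumbers and component names.
#' @export
se_model <- function(calib, wavenumbers) {
  stopifnot(inherits(calib, "se_calibration"))
  if (length(wavenumbers) != length(calib$components))
    stop(sprintf("need exactly %d wavenumbers for a square system (got %d)",
                 length(calib$components), length(wavenumbers)))
  if (anyDuplicated(wavenumbers)) stop("selected wavenumbers must be unique")
  j <- match_wavenumbers(sort(wavenumbers), calib$wavenumbers)
  structure(list(wavenumbers = calib$wavenumbers[j],
                 components = calib$components,
                 K = calib$K[j, , drop = FALSE],
                 water = calib$water[j], mode = calib$mode),
            class = "se_model")
}

#' Solve a simultaneous-equation model for concentrations
#'
#' Solves `K c = measured - water` per sample. Solutions are returned raw
#' -- negative concentrations are reported, not clamped, unless
#' `clamp = TRUE` -- so error metrics see the solver output. Systems whose
#' slope matrix condition number exceeds `cond_cap` are rejected as
#' singular rather than returning garbage.
#'
#' @param model an [se_model()].
#' @param measured numeric vector of length m, or a samples-by-m matrix of
#'   values at `model$wavenumbers`.
#' @param cond_cap condition-number cap (default 1e10).
#' @param clamp truncate negative solutions to zero?
#' @return Named concentration vector (g/L), or a samples-by-components
#'   matrix for matrix input.
#' @export
solve_concentrations <- function(model, measured, cond_cap = 1e10,
                                 clamp = FALSE) {
  stopifnot(inherits(model, "se_model"))
  kappa_val <- kappa(model$K, exact = TRUE)
  if (!is.finite(kappa_val) || kappa_val > cond_cap)
    stop(sprintf("singular simultaneous-equation system (condition %.3g > cap %.3g) at wavenumbers %s",
                 kappa_val, cond_cap,
                 paste(model$wavenumbers, collapse = ", ")))
  vec <- !is.matrix(measured)
  if (vec) measured <- matrix(measured, nrow = 1)
  if (ncol(measured) != length(model$wavenumbers))
    stop("measured values must match the model wavenumbers")
  rhs <- t(measured) - model$water
  sol <- solve(model$K, rhs)
  resid <- max(abs(model$K %*% sol - rhs)) /
    max(max(abs(rhs)), .Machine$double.eps)
  if (resid > 1e-8)
    stop(sprintf("linear solve did not converge (relative residual %.3g)",
                 resid))
  out <- t(sol)
  colnames(out) <- model$components
  rownames(out) <- rownames(measured)
  if (clamp) out[out < 0] <- 0
  if (vec) out[1, ] else out
}

#' Exhaustive wavenumber-combination search for the SE method
#'
#' Enumerates every size-`k` subset of the candidate wavenumbers, builds
#' the square system for each, predicts all samples and scores the subset
#' by the mean per-component RMSE against the reference table. Singular
#' subsets are skipped and counted. Ties on mean RMSE are broken towards
#' the lower slope-matrix condition number, then lexicographic wavenumber
#' order, so the result is invariant to candidate ordering.
#'
#' @param calib an [se_calibrate()] result covering the candidates.
#' @param values samples-by-candidates matrix of measured values, columns
#'   in the order of `calib$wavenumbers` (e.g. the relevant columns of
#'   [prepare_matrix()]), or a [spectral_dataset()] from which they are
#'   extracted.
#' @param reference [concentration_table()] of the samples.
#' @param k subset size (defaults to the number of components: a square
#'   system).
#' @param cond_cap condition cap passed to the solver.
#' @return An object of class `se_search`: `wavenumbers` (winning subset),
#'   `per_component_rmse`, `mean_rmse`, `condition`, `n_evaluated`,
#'   `n_singular`.
#' @export
search_combinations <- function(calib, values, reference,
                                k = length(calib$components),
                                cond_cap = 1e10) {
  stopifnot(inherits(calib, "se_calibration"),
            inherits(reference, "conc_table"))
  if (inherits(values, "spectral_dataset")) {
    if (values$mode != calib$mode)
      stop("dataset mode does not match the calibration mode")
    idx <- match_wavenumbers(calib$wavenumbers, values$grid$values)
    values <- values$traces[, idx, drop = FALSE]
  }
  n <- length(calib$wavenumbers)
  if (k != length(calib$components))
    stop("square systems only: k must equal the number of components")
  if (n < k) stop("need at least k candidate wavenumbers")
  if (ncol(values) != n) stop("values must have one column per candidate")
  ref <- conc_matrix(reference, calib$components)
  if (nrow(values) != nrow(ref))
    stop("values and reference must cover the same samples")
  subsets <- utils::combn(n, k)
  best <- NULL
  n_singular <- 0L
  for (s in seq_len(ncol(subsets))) {
    j <- subsets[, s]
    Ks <- calib$K[j, , drop = FALSE]
    kap <- kappa(Ks, exact = TRUE)
    if (!is.finite(kap) || kap > cond_cap) {
      n_singular <- n_singular + 1L
      next
    }
    sol <- t(solve(Ks, t(values[, j, drop = FALSE]) - calib$water[j]))
    per <- sqrt(colMeans((sol - ref)^2))
    mean_r <- mean(per)
    cand <- list(wavenumbers = calib$wavenumbers[j],
                 per_component_rmse = stats::setNames(per, calib$components),
                 mean_rmse = mean_r, condition = kap)
    if (is.null(best) || mean_r < best$mean_rmse - 1e-12 ||
        (abs(mean_r - best$mean_rmse) <= 1e-12 &&
         (kap < best$condition - 1e-9 ||
          (abs(kap - best$condition) <= 1e-9 &&
           lexicographically_before(cand$wavenumbers, best$wavenumbers))))) {
      best <- cand
    }
  }
  if (is.null(best))
    stop(sprintf("every size-%d subset of candidates {%s} is singular",
                 k, paste(calib$wavenumbers, collapse = ", ")))
  best$n_evaluated <- ncol(subsets)
  best$n_singular <- n_singular
  structure(best, class = "se_search")
}

lexicographically_before <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.se_search <- function(x, ...) {
  cat(sprintf("<se_search> best subset: %s cm^-1\n  mean RMSE %.4g g/L (%d subsets, %d singular)\n",
              paste(x$wavenumbers, collapse = ", "), x$mean_rmse,
              x$n_evaluated, x$n_singular))
  invisible(x)
}
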
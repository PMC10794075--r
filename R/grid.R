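#' Construct a uniform wavenumber grid
#'
#' Builds the evenly spaced wavenumber axis (cm\eqn{^{-1}}) on which all
#' spectra in a dataset live. Endpoints are inclusive on both sides, so the
#' fingerprint region 1250--900 cm\eqn{^{-1}} sampled every 2 cm\eqn{^{-1}}
#' contains exactly 176 points. Grids are always stored ascending; display
#' in the descending spectroscopic convention is a rendering concern only.
#'
#' @param start,stop grid endpoints in cm\eqn{^{-1}} (either order).
#' @param step positive spacing in cm\eqn{^{-1}}; must divide
#'   `abs(stop - start)` exactly (to within 1e-9).
#' @return An object of class `wn_grid` with fields `start` (minimum),
#'   `stop` (maximum), `step` and `values` (ascending positions).
#' @examples
#' g <- make_grid(1250, 900, 2)
#' length(g$values) # 176
#' @export
make_grid <- function(start, stop, step) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            length(start) == 1, length(stop) == 1, length(step) == 1)
  if (start == stop) stop("grid endpoints must differ")
  if (step <= 0) stop("grid step must be positive")
  span <- abs(stop - start)
  k <- round(span / step)
  rem <- span - k * step
  if (abs(rem) > 1e-9) {
    stop(sprintf("span %g is not divisible by step %g (remainder %g)",
                 span, step, span %% step))
  }
  lo <- min(start, stop)
  values <- lo + step * seq.int(0, k)
  structure(list(start = lo, stop = max(start, stop), step = step,
                 values = values),
            class = "wn_grid")
}

# Build a wn_grid from raw positions (used by file readers); rejects
# non-uniform or duplicated axes.
grid_from_values <- function(values, tol = 1e-6) {
  if (length(values) < 1 || anyNA(values) || !is.numeric(values))
    stop("grid values must be numeric and non-missing")
  if (anyDuplicated(values))
    stop(sprintf("duplicated wavenumber: %g",
                 values[duplicated(values)][1]))
  values <- sort(values)
  if (length(values) == 1)
    return(structure(list(start = values, stop = values, step = 0,
                          values = values), class = "wn_grid"))
  d <- diff(values)
  step <- stats::median(d)
  if (any(abs(d - step) > tol * max(step, 1)))
    stop("wavenumber axis is not uniformly spaced")
  structure(list(start = values[1], stop = values[length(values)],
                 step = step, values = values),
            class = "wn_grid")
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("<wn_grid> %g-%g cm^-1, step %g (%d points)\n",
              x$stop, x$start, x$step, length(x$values)))
  invisible(x)
}

#' @export
length.wn_grid <- function(x) length(x$values)

grids_identical <- function(a, b, tol = 1e-9) {
  length(a$values) == length(b$values) &&
    all(abs(a$values - b$values) <= tol)
}
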
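# Shared fixtures built in code. The small grid keeps per-test synthesis
# cheap; the full acquisition grid is used where derivative edge margins
# matter.

full_grid <- function() make_grid(4000, 400, 2)
region_grid <- function() make_grid(1250, 900, 2)

fingerprint <- c(900, 1250)

five_sugars <- c("Glc", "Fru", "Suc", "GF2", "GF3")

# tiny two-component library with well-separated bands, for closed-form
# checks that should not depend on the realistic default library
toy_library <- function() {
  band_library(
    components = list(
      Glc = data.frame(center = c(1080, 1034), width = c(8, 8),
                       height = c(2e-3, 1e-3)),
      Fru = data.frame(center = 1064, width = 8, height = 2e-3)),
    water = data.frame(center = 1640, width = 40, height = 0.35))
}

# deterministic smooth test trace (sum of sinusoids) on a grid
smooth_trace <- function(values) {
  0.1 * sin(values / 40) + 0.05 * cos(values / 90) + 1e-4 * values
}

# independent windowed least-squares polynomial fit: second derivative at
# the window center (oracle for the Savitzky-Golay path)
polyfit_deriv2 <- function(trace, i, window, polyorder, step) {
  h <- (window - 1) / 2
  idx <- (i - h):(i + h)
  x <- (idx - i) * step
  fit <- stats::lm.fit(outer(x, 0:polyorder, `^`), trace[idx])
  2 * fit$coefficients[3]
}
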
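#' Sugar component vocabulary
#'
#' The fixed set of quantified components: glucose, fructose, sucrose and
#' the fructo-oligosaccharides 1-kestose (GF2), nystose (GF3) and
#' fructofuranosyl nystose (GF4).
#'
#' @return Character vector of component names in canonical order.
#' @export
sugar_components <- function() c("Glc", "Fru", "Suc", "GF2", "GF3", "GF4")

# Molar masses (g/mol), anhydro-linkage water ignored so that the
# transfructosylation stoichiometry conserves mass exactly. Used for
# glucosyl-mole bookkeeping, never for spectral synthesis.
sugar_molar_mass <- c(Glc = 180.16, Fru = 180.16, Suc = 342.30,
                      GF2 = 504.44, GF3 = 666.58, GF4 = 828.72)

#' Concentration reference table
#'
#' Samples-by-components table of concentrations in g/L, the response side
#' of every calibration. Component names are restricted to
#' [sugar_components()]; unknown names are rejected rather than carried.
#'
#' @param x data.frame with a `sample` id column (or row names) and one
#'   numeric column per component, or a numeric matrix with row names.
#' @return An object of class `conc_table` (a data.frame whose first column
#'   is `sample`).
#' @examples
#' concentration_table(data.frame(sample = "a", Glc = 10, Fru = 20))
#' @export
concentration_table <- function(x) {
  if (is.matrix(x)) {
    x <- data.frame(sample = rownames(x) %||% paste0("s", seq_len(nrow(x))),
                    x, check.names = FALSE)
  }
  stopifnot(is.data.frame(x), nrow(x) >= 1)
  if (!"sample" %in% names(x)) {
    x <- data.frame(sample = rownames(x) %||% paste0("s", seq_len(nrow(x))),
                    x, check.names = FALSE)
  }
  x <- as.data.frame(x, check.names = FALSE)
  comps <- setdiff(names(x), "sample")
  unknown <- setdiff(comps, sugar_components())
  if (length(unknown) > 0)
    stop(sprintf("unknown component name(s): %s (allowed: %s)",
                 paste(unknown, collapse = ", "),
                 paste(sugar_components(), collapse = ", ")))
  if (length(comps) == 0) stop("at least one component column required")
  comps <- intersect(sugar_components(), comps)  # canonical order
  x <- x[, c("sample", comps)]
  x$sample <- as.character(x$sample)
  if (anyDuplicated(x$sample))
    stop(sprintf("duplicated sample id: %s",
                 x$sample[duplicated(x$sample)][1]))
  for (cm in comps) {
    v <- x[[cm]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop(sprintf("component '%s' has non-numeric or missing values", cm))
    if (any(v < 0))
      stop(sprintf("negative concentration in component '%s'", cm))
  }
  rownames(x) <- NULL
  class(x) <- c("conc_table", "data.frame")
  x
}

#' Numeric matrix view of a concentration table
#'
#' @param ct a `conc_table`.
#' @param components optional subset of component names.
#' @return Numeric matrix (samples x components) with sample ids as row names.
#' @export
conc_matrix <- function(ct, components = NULL) {
  stopifnot(inherits(ct, "conc_table"))
  comps <- setdiff(names(ct), "sample")
  if (!is.null(components)) {
    missing <- setdiff(components, comps)
    if (length(missing) > 0)
      stop(sprintf("component(s) not in table: %s",
                   paste(missing, collapse = ", ")))
    comps <- components
  }
  m <- as.matrix(ct[, comps, drop = FALSE])
  rownames(m) <- ct$sample
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
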
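# End-to-end study harnesses: enzyme-treated juice (SE vs PLS, A/B/C in
# both absorbance and second-derivative mode) and the FOS-addition study
# (Table-style 18-sample design, leave-one-out).

#' Candidate wavenumbers for the simultaneous-equation search
#'
#' Unions the per-component peak sets into a candidate list of about
#' `n` wavenumbers by taking peaks round-robin across components in order
#' of descending prominence, so every sugar contributes its strongest
#' bands.
#'
#' @param peaksets named list of [wn_set()] objects.
#' @param n target candidate count (default 18).
#' @return A [wn_set()] with at most `n` positions.
#' @export
se_candidate_set <- function(peaksets, n = 18) {
  stopifnot(length(peaksets) >= 1)
  ordered <- lapply(peaksets, function(ps) {
    ps[order(-ps$prominence), , drop = FALSE]
  })
  chosen <- list()
  rank <- 1
  while (length(chosen) < n && rank <= max(vapply(ordered, nrow, 0L))) {
    for (cm in names(ordered)) {
      if (length(chosen) >= n) break
      ps <- ordered[[cm]]
      if (rank <= nrow(ps)) {
        w <- ps$wavenumber[rank]
        key <- sprintf("%.6g", w)
        if (is.null(chosen[[key]]))
          chosen[[key]] <- data.frame(wavenumber = w, source = cm,
                                      prominence = ps$prominence[rank])
      }
    }
    rank <- rank + 1
  }
  df <- do.call(rbind, chosen)
  wn_set(df$wavenumber, df$source, df$prominence)
}

study_provenance <- function(seed) {
  list(package = "ftirsugars",
       version = as.character(utils::packageVersion("ftirsugars")),
       r_version = R.version.string,
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Enzyme-treated juice study
#'
#' Generates the enzymatic fixture (concentration design plus synthetic
#' spectra), then quantifies the five reaction sugars (GF4 is excluded: it
#' is absent from the enzymatic design) by both the simultaneous-equation
#' method (exhaustive subset search over ~18 peak candidates) and PLS-1
#' under selection patterns A/B/C, in absorbance and second-derivative
#' mode. All stages share one seed, so a report regenerated from the same
#' configuration is identical apart from its timestamp.
#'
#' @param n_samples fixture size (default 75).
#' @param seed master seed for design jitter, noise and fold assignment.
#' @param noise a [noise_model()] (its seed field is ignored; the master
#'   seed governs).
#' @param lib a [band_library()].
#' @param grid acquisition [make_grid()] axis.
#' @param region modelling window in cm\eqn{^{-1}}.
#' @param sg an [sg_params()].
#' @param peaks a [peak_params()].
#' @param kp a [kinetic_params()].
#' @param doses,times design lattice, see [enzyme_design()].
#' @param n_groups,max_factors cross-validation settings.
#' @param n_candidates SE candidate count (default 18).
#' @param modes which explanatory-variable modes to run.
#' @return A `run_report` list: `config`, `concentrations`, per-mode
#'   `pls` tables and `se` search results, `selections`, `provenance`.
#' @export
run_enzyme_study <- function(n_samples = 75, seed = 1,
                             noise = noise_model(), lib = default_band_library(),
                             grid = make_grid(4000, 400, 2),
                             region = c(900, 1250), sg = sg_params(),
                             peaks = peak_params(), kp = kinetic_params(),
                             doses = seq(9000, 45000, length.out = 5),
                             times = c(0, 1, 2, 3, 4, 6),
                             n_groups = 3, max_factors = 10,
                             n_candidates = 18,
                             modes = c("absorbance", "second_derivative")) {
  modes <- match.arg(modes, several.ok = TRUE)
  config <- list(n_samples = n_samples, seed = seed,
                 noise = unclass(noise)[c("sd", "drift")],
                 region = sort(region), sg = unclass(sg),
                 peaks = unclass(peaks), kp = unclass(kp),
                 doses = doses, times = times, n_groups = n_groups,
                 max_factors = max_factors, n_candidates = n_candidates,
                 modes = modes, study = "enzyme")
  comps <- c("Glc", "Fru", "Suc", "GF2", "GF3")
  ct <- enzyme_design(n_samples, doses = doses, times = times, kp = kp,
                      seed = seed)
  ds <- synthesize_dataset(ct, lib, grid,
                           noise = noise_model(noise$sd, noise$drift,
                                               seed = seed + 1))
  water <- water_spectrum(lib, grid)
  pure <- lapply(comps, function(cm) pure_profile(cm, lib, grid, 100))
  names(pure) <- comps
  standards <- standard_solutions(
    lib, grid, components = comps,
    noise = noise_model(noise$sd, noise$drift, seed = seed + 2))
  ref5 <- concentration_table(as.data.frame(ct)[, c("sample", comps)])
  pls_out <- list()
  se_out <- list()
  selections_out <- list()
  for (mode in modes) {
    deriv <- mode == "second_derivative"
    pure_mode <- if (deriv) lapply(pure, second_derivative, p = sg) else pure
    water_mode <- if (deriv) second_derivative(water, p = sg) else water
    peaksets <- lapply(names(pure_mode), function(cm)
      extract_peaks(pure_mode[[cm]], region = region, p = peaks, source = cm))
    names(peaksets) <- names(pure_mode)
    selections <- lapply(comps, function(cm)
      build_selection(cm, peaksets, region, grid))
    names(selections) <- comps
    selections_out[[mode]] <- peaksets
    pls_out[[mode]] <- run_selection_experiment(
      ds, ref5, selections, mode = mode, region = region, sg = sg,
      n_groups = n_groups, seed = seed, max_factors = max_factors)
    candidates <- se_candidate_set(peaksets, n = n_candidates)
    std_ds <- standards$dataset
    if (deriv) {
      std_mat <- prepare_matrix(std_ds, region, use_derivative = TRUE, p = sg)
      std_ds <- spectral_dataset(std_mat,
                                 grid = grid_from_values(as.numeric(colnames(std_mat))),
                                 ids = std_ds$ids, mode = "second_derivative")
    }
    calib <- se_calibrate(std_ds, standards$concentrations,
                          candidates$wavenumber, water_mode)
    Xse <- prepare_matrix(ds, region, use_derivative = deriv, p = sg)
    vals <- Xse[, match_wavenumbers(calib$wavenumbers,
                                    as.numeric(colnames(Xse))), drop = FALSE]
    se_out[[mode]] <- search_combinations(calib, vals, ref5)
  }
  structure(list(config = config, concentrations = ct,
                 pls = pls_out, se = se_out, selections = selections_out,
                 provenance = study_provenance(seed)),
            class = "run_report")
}

#' Fructo-oligosaccharide addition study
#'
#' Runs the 18-sample FOS-addition design: synthetic absorbance spectra of
#' the packaged reference compositions, wavenumber selection from all six
#' pure-component profiles, and PLS-1 under patterns A/B/C for each of the
#' six sugars, evaluated by full (leave-one-out) cross-validation because
#' of the small sample count.
#'
#' @inheritParams run_enzyme_study
#' @param ct concentration design (defaults to [table1_design()]).
#' @return A `run_report`, as in [run_enzyme_study()].
#' @export
run_fos_study <- function(ct = table1_design(), seed = 1,
                          noise = noise_model(), lib = default_band_library(),
                          grid = make_grid(4000, 400, 2),
                          region = c(900, 1250), sg = sg_params(),
                          peaks = peak_params(), max_factors = 10) {
  stopifnot(inherits(ct, "conc_table"))
  comps <- setdiff(names(ct), "sample")
  config <- list(seed = seed, noise = unclass(noise)[c("sd", "drift")],
                 region = sort(region), sg = unclass(sg),
                 peaks = unclass(peaks), max_factors = max_factors,
                 n_samples = nrow(ct), study = "fos")
  ds <- synthesize_dataset(ct, lib, grid,
                           noise = noise_model(noise$sd, noise$drift,
                                               seed = seed + 1))
  pure <- lapply(comps, function(cm) pure_profile(cm, lib, grid, 100))
  names(pure) <- comps
  peaksets <- lapply(comps, function(cm)
    extract_peaks(pure[[cm]], region = region, p = peaks, source = cm))
  names(peaksets) <- comps
  selections <- lapply(comps, function(cm)
    build_selection(cm, peaksets, region, grid))
  names(selections) <- comps
  pls <- run_selection_experiment(ds, ct, selections, mode = "absorbance",
                                  region = region, sg = sg,
                                  n_groups = nrow(ct), seed = seed,
                                  max_factors = max_factors)
  structure(list(config = config, concentrations = ct,
                 pls = list(absorbance = pls),
                 selections = list(absorbance = peaksets),
                 provenance = study_provenance(seed)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s study, %d samples, seed %s\n",
              x$config$study, x$config$n_samples, x$config$seed))
  for (mode in names(x$pls)) {
    cat(sprintf("  PLS (%s):\n", mode))
    print(x$pls[[mode]][, c("component", "selection", "n_wavenumbers",
                            "n_factors", "rmse", "r2")])
    if (!is.null(x[["se"]][[mode]])) {
      cat(sprintf("  SE (%s): %s\n", mode,
                  paste(x[["se"]][[mode]]$wavenumbers, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `metrics.csv` (the per-component, per-selection PLS table plus
#' SE results) and `report.json` (configuration echo, metrics and
#' provenance) into `dir`.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- do.call(rbind, lapply(names(report$pls), function(mode) {
    df <- report$pls[[mode]]
    data.frame(method = "pls", mode = mode, df)
  }))
  if (!is.null(report[["se"]])) {
    se_rows <- do.call(rbind, lapply(names(report[["se"]]), function(mode) {
      s <- report[["se"]][[mode]]
      data.frame(method = "se", mode = mode,
                 component = names(s$per_component_rmse),
                 selection = paste(s$wavenumbers, collapse = "|"),
                 n_wavenumbers = length(s$wavenumbers),
                 n_factors = NA_integer_,
                 rmse = as.numeric(s$per_component_rmse), r2 = NA_real_)
    }))
    metrics <- rbind(metrics, se_rows)
  }
  utils::write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  json <- list(config = report$config, metrics = metrics,
               provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
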
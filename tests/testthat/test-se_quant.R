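test_that("rmse matches its definition", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(3, -4), c(0, 0)), sqrt((9 + 16) / 2))
  set.seed(21)
  p <- rnorm(40); r <- rnorm(40)
  naive <- sqrt(sum((p - r)^2) / 40)  # two-pass oracle
  expect_equal(rmse(p, r), naive, tolerance = 1e-12)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:4), "differ")
})

test_that("fixed-intercept calibration slopes are exact", {
  # single standard determines the slope exactly
  cc <- fit_calibration(100, 0.2 + 0.05, water_value = 0.05)
  expect_equal(cc$slope, 0.002)
  # symmetric +/- noise at mirrored concentration pairs cancels
  base <- fit_calibration(c(50, 50), c(0.1, 0.1), 0)$slope
  pert <- fit_calibration(c(50, 50), c(0.1 + 1e-3, 0.1 - 1e-3), 0)$slope
  expect_equal(pert, base, tolerance = 1e-12)
  expect_error(fit_calibration(c(0, 0), c(1, 2), 0), "zero")
})

test_that("calibration on noiseless standards recovers generator slopes", {
  lib <- default_band_library()
  g <- full_grid()
  comps <- five_sugars
  # five-level standards per component
  rows <- do.call(rbind, lapply(comps, function(cm) {
    m <- matrix(0, 5, length(comps), dimnames = list(NULL, comps))
    m[, cm] <- c(20, 40, 60, 90, 120)
    m
  }))
  rownames(rows) <- paste0("std", seq_len(nrow(rows)))
  ct <- concentration_table(rows)
  ds <- synthesize_dataset(ct, lib, g)
  wn <- c(1000, 1034, 1056, 1064, 1080, 1134)
  calib <- se_calibrate(ds, ct, wn, water_spectrum(lib, g))
  for (cm in comps) {
    b <- lib$components[[cm]]
    truth <- vapply(sort(wn), function(nu)
      sum(b$height * exp(-(nu - b$center)^2 / (2 * b$width^2))), 0)
    expect_equal(unname(calib$K[, cm]), truth, tolerance = 1e-9)
  }
})

test_that("the square solve inverts identity systems and exact mixtures", {
  # identity slope matrix with zero water: c equals the measured values
  calib <- structure(list(wavenumbers = c(1000, 1034), components = c("Glc", "Fru"),
                          K = diag(2), water = c(0, 0), mode = "absorbance"),
                     class = "se_calibration")
  m <- se_model(calib, c(1000, 1034))
  expect_equal(unname(solve_concentrations(m, c(3.2, 1.5))), c(3.2, 1.5))

  # noiseless five-sugar mixture: any nonsingular subset is exact
  lib <- default_band_library()
  g <- full_grid()
  std <- standard_solutions(lib, g, components = five_sugars)
  truth <- c(Glc = 27.4, Fru = 21.2, Suc = 8.9, GF2 = 9.4, GF3 = 3.1)
  ds <- synthesize_dataset(concentration_table(t(as.matrix(truth))), lib, g)
  for (wn in list(c(1000, 1034, 1064, 1080, 1134),
                  c(930, 994, 1056, 1064, 1080))) {
    calib <- se_calibrate(std$dataset, std$concentrations, wn,
                          water_spectrum(lib, g))
    model <- se_model(calib, wn)
    vals <- ds$traces[1, match(sort(wn), g$values)]
    got <- solve_concentrations(model, vals)
    expect_equal(got[names(truth)], truth, tolerance = 1e-6)
  }
})

test_that("singular systems are flagged, not silently solved", {
  calib <- structure(list(wavenumbers = c(1000, 1002), components = c("Glc", "Fru"),
                          K = matrix(c(1, 1, 2, 2), 2),  # duplicated row info
                          water = c(0, 0), mode = "absorbance"),
                     class = "se_calibration")
  m <- se_model(calib, c(1000, 1002))
  expect_error(solve_concentrations(m, c(1, 1)), "singular")
  expect_error(se_model(calib, c(1000, 1000)), "unique")
})

test_that("solutions are linear in the measured vector and never clamped by default", {
  calib <- structure(list(wavenumbers = c(1000, 1034), components = c("Glc", "Fru"),
                          K = matrix(c(2e-3, 1e-3, 0.5e-3, 1.8e-3), 2),
                          water = c(0.01, 0.02), mode = "absorbance"),
                     class = "se_calibration")
  m <- se_model(calib, c(1000, 1034))
  a1 <- c(0.05, 0.04); a2 <- c(0.02, 0.09)
  c1 <- solve_concentrations(m, a1)
  c2 <- solve_concentrations(m, a2)
  mix <- solve_concentrations(m, 0.3 * a1 + 0.7 * a2 + 0.0 * m$water)
  # affine in measured: subtract the water-only solution
  c0 <- solve_concentrations(m, m$water * 0)
  expect_equal(mix - c0, 0.3 * (c1 - c0) + 0.7 * (c2 - c0),
               tolerance = 1e-10)
  low <- solve_concentrations(m, c(0.0, 0.0))
  expect_true(any(low < 0))
  expect_true(all(solve_concentrations(m, c(0, 0), clamp = TRUE) >= 0))
})

test_that("the exhaustive search enumerates C(n, K) subsets and is exact on noiseless data", {
  lib <- default_band_library()
  g <- full_grid()
  std <- standard_solutions(lib, g, components = five_sugars)
  ct <- enzyme_design(12, seed = 6)
  ct5 <- concentration_table(as.data.frame(ct)[, c("sample", five_sugars)])
  ds <- synthesize_dataset(ct5, lib, g)
  pure <- lapply(five_sugars, function(cm) pure_profile(cm, lib, g, 100))
  names(pure) <- five_sugars
  psets <- lapply(five_sugars, function(cm)
    extract_peaks(pure[[cm]], fingerprint, source = cm))
  names(psets) <- five_sugars
  cands <- se_candidate_set(psets, 18)
  expect_equal(nrow(cands), 18)
  calib <- se_calibrate(std$dataset, std$concentrations, cands$wavenumber,
                        water_spectrum(lib, g))
  vals <- ds$traces[, match(calib$wavenumbers, g$values)]
  res <- search_combinations(calib, vals, ct5)
  expect_equal(res$n_evaluated, 8568)  # C(18, 5)
  expect_lt(res$mean_rmse, 1e-6)
  expect_length(res$wavenumbers, 5)

  # invariance to candidate ordering (calibration already sorts; feed a
  # permuted candidate list and value matrix)
  set.seed(123)
  perm <- sample(seq_len(18))
  calib2 <- se_calibrate(std$dataset, std$concentrations,
                         cands$wavenumber[perm], water_spectrum(lib, g))
  res2 <- search_combinations(calib2, ds, ct5)
  expect_equal(res2$wavenumbers, res$wavenumbers)

  # n = K: the single subset is returned regardless of its error
  wn5 <- cands$wavenumber[1:5]
  calib5 <- se_calibrate(std$dataset, std$concentrations, wn5,
                         water_spectrum(lib, g))
  res5 <- search_combinations(calib5, ds, ct5)
  expect_equal(res5$n_evaluated, 1)
  expect_equal(res5$wavenumbers, sort(wn5))
})

test_that("SE error grows monotonically with injected noise", {
  lib <- default_band_library()
  g <- full_grid()
  std <- standard_solutions(lib, g, components = five_sugars)
  ct <- enzyme_design(25, seed = 14)
  ct5 <- concentration_table(as.data.frame(ct)[, c("sample", five_sugars)])
  wn <- c(1000, 1034, 1064, 1080, 1134)
  calib <- se_calibrate(std$dataset, std$concentrations, wn,
                        water_spectrum(lib, g))
  model <- se_model(calib, wn)
  errs <- vapply(c(0, 5e-4, 2e-3, 8e-3), function(sd) {
    ds <- synthesize_dataset(ct5, lib, g, noise_model(sd, 0, seed = 77))
    pred <- solve_concentrations(model, ds$traces[, match(sort(wn), g$values)])
    mean(sqrt(colMeans((pred - conc_matrix(ct5))^2)))
  }, 0)
  expect_true(all(diff(errs) > 0))
})
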
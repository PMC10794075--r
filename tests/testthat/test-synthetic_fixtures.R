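test_that("pure profiles peak at their assigned band centers", {
  lib <- default_band_library()
  g <- full_grid()
  s <- pure_profile("Glc", lib, g, 100)
  pk <- extract_peaks(s, fingerprint)$wavenumber
  expect_true(all(c(1080, 1034) %in% pk))
  # every assignment center in the library is a detectable maximum at 100 g/L
  named_centers <- list(Glc = c(1080, 1034), Fru = 1064,
                        Suc = c(1056, 1000),
                        GF2 = c(1134, 1034, 930), GF3 = c(1134, 1034, 930),
                        GF4 = c(1134, 1034, 930))
  for (cm in names(named_centers)) {
    pk <- extract_peaks(pure_profile(cm, lib, g, 100), fingerprint)$wavenumber
    for (ctr in named_centers[[cm]]) {
      expect_true(any(abs(pk - ctr) <= 4),
                  label = sprintf("%s center %g detected", cm, ctr))
    }
  }
})

test_that("a zero-concentration profile is the water background", {
  lib <- toy_library()
  g <- region_grid()
  expect_equal(pure_profile("Glc", lib, g, 0)$trace,
               water_spectrum(lib, g)$trace)
  expect_error(pure_profile("Suc", lib, g, 10), "unknown component")
  expect_error(pure_profile("Glc", lib, g, -1), "non-negative")
})

test_that("profile values match the closed-form Gaussian evaluation", {
  lib <- toy_library()
  g <- region_grid()
  conc <- 57.3
  s <- pure_profile("Fru", lib, g, conc)
  w <- water_spectrum(lib, g)$trace
  # single isolated band: value at the center is conc*height + background
  i <- which(g$values == 1064)
  expect_equal(s$trace[i], conc * 2e-3 + w[i], tolerance = 1e-12)
  # direct evaluation at arbitrary points
  at <- c(1000, 1042, 1068, 1120)
  expected <- conc * 2e-3 * exp(-(at - 1064)^2 / (2 * 8^2)) +
    0.35 * exp(-(at - 1640)^2 / (2 * 40^2))
  expect_equal(s$trace[match(at, g$values)], expected, tolerance = 1e-12)
})

test_that("noiseless mixing is additive and homogeneous", {
  lib <- default_band_library()
  g <- region_grid()
  w <- water_spectrum(lib, g)$trace
  m1 <- mix_spectrum(c(Glc = 10, Fru = 20), lib, g)$trace
  m2 <- mix_spectrum(c(Glc = 20, Fru = 40), lib, g)$trace
  expect_equal(m2 - w, 2 * (m1 - w), tolerance = 1e-12)
  p1 <- pure_profile("Glc", lib, g, 10)$trace
  p2 <- pure_profile("Fru", lib, g, 20)$trace
  expect_equal(m1, p1 + p2 - w, tolerance = 1e-12)
})

test_that("noiseless mixtures equal brute-force summation over all bands", {
  lib <- default_band_library()
  g <- full_grid()
  concs <- c(Glc = 23.1, Fru = 18.4, Suc = 12.9, GF2 = 7.2, GF3 = 2.2,
             GF4 = 0.9)
  s <- mix_spectrum(concs, lib, g)
  set.seed(99)
  at <- sample(g$values, 20)
  oracle <- vapply(at, function(nu) {
    tot <- sum(lib$water$height *
                 exp(-(nu - lib$water$center)^2 / (2 * lib$water$width^2)))
    for (cm in names(concs)) {
      b <- lib$components[[cm]]
      tot <- tot + concs[[cm] ] *
        sum(b$height * exp(-(nu - b$center)^2 / (2 * b$width^2)))
    }
    tot
  }, 0)
  expect_equal(s$trace[match(at, g$values)], oracle, tolerance = 1e-12)
})

test_that("seeded synthesis is reproducible and seeds change only noise", {
  lib <- toy_library()
  g <- region_grid()
  ct <- concentration_table(data.frame(sample = c("a", "b"),
                                       Glc = c(10, 30), Fru = c(5, 2)))
  d1 <- synthesize_dataset(ct, lib, g, noise_model(seed = 4))
  d2 <- synthesize_dataset(ct, lib, g, noise_model(seed = 4))
  d3 <- synthesize_dataset(ct, lib, g, noise_model(seed = 5))
  expect_identical(d1$traces, d2$traces)
  expect_false(identical(d1$traces, d3$traces))
  clean <- synthesize_dataset(ct, lib, g)$traces
  # noise is zero-mean and small: both seeds sit near the same clean trace
  expect_lt(max(abs(d1$traces - clean)), 5e-3)
  expect_error(mix_spectrum(c(Glc = -1), lib, g), "negative")
})

test_that("the time-course starts at the supplied composition", {
  ct <- simulate_enzyme_course(enzyme_initial_composition(), 9000,
                               times = c(0, 1, 6))
  m <- conc_matrix(ct)
  expect_equal(unname(m[1, ]), unname(enzyme_initial_composition()),
               tolerance = 1e-12)
  # sucrose decreases, products appear
  expect_true(all(diff(m[, "Suc"]) < 0))
  expect_true(all(m[-1, "GF2"] > 0))
  expect_equal(m[, "Fru"], c(t0h = 20.7, t1h = 20.7, t6h = 20.7))
})

test_that("zero rate constants freeze the composition", {
  kp <- kinetic_params(0, 0, 0)
  ct <- simulate_enzyme_course(enzyme_initial_composition(), 45000,
                               times = c(0, 2, 6), kp = kp)
  m <- conc_matrix(ct)
  expect_equal(m[3, ], m[1, ], tolerance = 1e-12)
  expect_error(kinetic_params(-1, 0, 0), "non-negative")
  expect_error(simulate_enzyme_course(c(Glc = 10), 9000, 1), "Suc")
})

test_that("glucosyl moles are conserved, matching an lsoda oracle", {
  skip_if_not_installed("deSolve")
  kp <- kinetic_params(k3 = 2e-10)  # exercise the full chain
  times <- c(0, 0.5, 1, 2, 4, 6)
  ct <- simulate_enzyme_course(enzyme_initial_composition(), 27000,
                               times = times, kp = kp)
  gm <- glucosyl_moles(ct)
  expect_lt(max(abs(gm - gm[1])), 1e-6)
  expect_true(all(conc_matrix(ct) >= 0))

  # independent stiff integrator on the same mass-action system
  rhs <- function(t, y, p) {
    v1 <- p$k1 * p$d * y[1]^2
    v2 <- p$k2 * p$d * y[1] * y[2]
    v3 <- p$k3 * p$d * y[1] * y[3]
    list(c(-2 * 342.30 * v1 - 342.30 * v2 - 342.30 * v3,
           504.44 * (v1 - v2), 666.58 * (v2 - v3), 828.72 * v3,
           180.16 * (v1 + v2 + v3)))
  }
  sol <- deSolve::ode(c(S = 41.9, G2 = 0, G3 = 0, G4 = 0, Glc = 18.7),
                      times, rhs,
                      list(k1 = kp$k1, k2 = kp$k2, k3 = kp$k3, d = 27000),
                      rtol = 1e-10, atol = 1e-12)
  m <- conc_matrix(ct)
  expect_equal(m[, "Suc"], unname(sol[, "S"]), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(m[, "GF3"], unname(sol[, "G3"]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("GF2 rises then falls as the chain extends", {
  kp <- kinetic_params()
  ct <- simulate_enzyme_course(enzyme_initial_composition(), 45000,
                               times = seq(0, 40, by = 2), kp = kp)
  g2 <- conc_matrix(ct)[, "GF2"]
  expect_gt(max(g2), g2[1])
  expect_lt(g2[length(g2)], max(g2))
})

test_that("the enzymatic design covers the lattice with sensible spans", {
  ct <- enzyme_design(75, seed = 42)
  m <- conc_matrix(ct)
  expect_equal(nrow(m), 75)
  expect_true(all(m[, "GF4"] == 0))
  # at a fixed dose, sucrose falls with reaction time
  design <- attr(ct, "design")
  for (d in unique(design$dose)) {
    rows <- which(design$dose == d)
    med <- tapply(m[rows, "Suc"], design$time[rows], mean)
    expect_true(all(diff(med) < 0))
  }
  # spans emulate the study ranges: sucrose from its untreated level down
  # to a few g/L
  expect_lt(min(m[, "Suc"]), 5)
  expect_gt(max(m[, "Suc"]), 38)
  expect_gt(max(m[, "Glc"]), 25)
  # degenerate lattice without jitter gives identical rows
  flat <- enzyme_design(4, doses = 9000, times = 2, seed = 1, jitter_sd = 0)
  fm <- conc_matrix(flat)
  expect_equal(fm[1, ], fm[2, ], tolerance = 1e-14)
  expect_error(enzyme_design(1), "at least 2")
  expect_error(enzyme_design(5, doses = numeric(0)), "empty")
})

test_that("the packaged FOS-addition design matches the printed table", {
  ct <- table1_design()
  expect_equal(nrow(ct), 18)
  m <- conc_matrix(ct)
  expect_equal(unname(m["A", ]), c(18.5, 21.6, 41.3, 5.0, 6.4, 1.0))
  expect_equal(unname(m["R", ]), c(29.3, 23.2, 26.8, 9.1, 9.2, 1.3))
  expect_true(all(m[, "GF4"] <= 2.2))
  expect_identical(unname(attr(ct, "variety")[["A"]]), "Valencia orange")
})

test_that("band libraries validate and round-trip through YAML", {
  lib <- default_band_library()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_band_library(lib, path)
  back <- read_band_library(path)
  expect_equal(back$components$Glc$center, lib$components$Glc$center)
  expect_equal(back$water$height, lib$water$height)
  # a library missing an assigned center is rejected
  bad <- lib$components
  bad$Glc <- bad$Glc[bad$Glc$center != 1080, ]
  expect_error(band_library(bad, lib$water), "1080")
})
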
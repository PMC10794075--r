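# ftirsugars

Chemometric quantification of sugars and fructo-oligosaccharides (FOS) in
citrus juices from mid-infrared ATR-FTIR spectra.

Juice processors who reduce endogenous sucrose by enzymatic
transfructosylation, or who fortify juices with FOS preparations, need to
track six structurally similar carbohydrates at once: glucose (Glc),
fructose (Fru), sucrose (Suc), 1-kestose (GF2), nystose (GF3) and
fructofuranosyl nystose (GF4). HPLC resolves them but is slow and
maintenance-heavy at a production site; ATR-FTIR needs no pretreatment, and
the carbohydrate C–O/C–C stretching modes give each sugar a characteristic
absorption pattern in the fingerprint region (1250–900 cm⁻¹). This package
implements the two quantification routes that compete in that setting, plus
everything needed to test them without access to a spectrometer.

## What is implemented

**Simultaneous-equation (SE) method.** By spectral additivity and the
Bouguer–Beer law, the absorbance of a K-sugar mixture at wavenumber ν is

    A(ν) = A_w(ν) + Σᵢ kᵢ(ν) cᵢ ,

with the pure-water absorbance A_w as a fixed intercept. Slopes kᵢ(νⱼ) are
calibrated from single-sugar standards (least squares through the fixed
intercept), K wavenumbers are chosen from ~18 peak candidates by exhaustive
search over all C(n, K) subsets, and concentrations follow from the square
linear solve K c = a − a_w. Singular subsets are flagged and skipped, never
silently solved.

**PLS-1 (NIPALS) with wavenumber selection.** Mean-centered partial least
squares with a single response, written from scratch: sequential
weight/score/loading extraction with deflation, a regression-vector form
that reproduces the sequential reconstruction, grouped cross-validation
with one global factor count chosen by minimum CV RMSE, and R² computed on
held-out predictions. Explanatory variables are either raw absorbance or
Savitzky–Golay second derivatives (17-point window by default, computed on
the full grid before cropping so edge effects never reach the model).
Three nested selection patterns are compared per sugar:

* **A** — all 176 fingerprint points (1250–900 cm⁻¹ at 2 cm⁻¹),
* **B** — only the target sugar's own peak wavenumbers,
* **C** — B plus the peaks of every other component in the sample.

**Synthetic fixture generator.** Gaussian band libraries built on the
published band assignments (Glc 1080/1034, Fru 1064, Suc 1056/1000, shared
FOS bands 1134/1060/1034/994/930 cm⁻¹) over a broad water background, iid
noise plus baseline drift, a mass-action transfructosylation time-course
(Suc+Suc→GF2+Glc, GF2+Suc→GF3+Glc, GF3+Suc→GF4+Glc, integrated by RK4 with
exact glucosyl-unit conservation), a 75-sample dose × time enzymatic design
and the packaged 18-sample FOS-addition reference design. Every stage is
seeded and reproducible bit for bit.

## Worked example

```r
library(ftirsugars)

grid <- make_grid(4000, 400, 2)         # acquisition grid, 1801 points
lib  <- default_band_library()

## 75-sample enzyme-treated juice fixture with measurement noise
ct <- enzyme_design(75, seed = 42)
ds <- synthesize_dataset(ct, lib, grid, noise_model(seed = 43))

## second-derivative PLS-1 for glucose on the full fingerprint region
X  <- prepare_matrix(ds, c(900, 1250), use_derivative = TRUE)
cross_validate(X, conc_matrix(ct)[, "Glc"], n_groups = 3, seed = 1)
#> <pls_cv> RMSE 0.1918 g/L, R2 0.9977, 3 factor(s), 3 groups
```

Glucose spanning roughly 18–31 g/L in the fixture is recovered with a
cross-validated error of about 0.2 g/L from three latent factors. The
FOS-addition study runs the A/B/C comparison by leave-one-out on the 18
reference compositions:

```r
fos <- run_fos_study(seed = 7)
subset(fos$pls$absorbance, component == "Suc")
#>   component selection n_wavenumbers n_factors      rmse        r2
#> 7       Suc         A           176         8 0.1967851 0.9996558
#> 8       Suc         B             5         5 1.4842659 0.9804157
#> 9       Suc         C            19        10 0.1783966 0.9997171
```

The single-component pattern B loses accuracy (1.48 g/L) because the other
sugars absorb at overlapping wavenumbers; adding their peak information
(pattern C, 19 wavenumbers) restores full-spectrum accuracy with a tenth
of the variables. The SE search on the same enzymatic fixture enumerates
all 8568 five-wavenumber subsets:

```r
rep <- run_enzyme_study(seed = 42)
rep$se$second_derivative
#> <se_search> best subset: 996, 1012, 1064, 1080, 1110 cm^-1
#>   mean RMSE 0.4741 g/L (8568 subsets, 0 singular)
```

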
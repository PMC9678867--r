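# tirfcell

Intensity-independent quantification of single-cell TIRF microscopy images.

## The problem

TIRF (total-internal-reflection fluorescence) microscopy images the
contact-area of an adherent cell — the ~100 nm slab where the membrane meets
the substrate — by exciting fluorophores with an evanescent wave. That wave
decays exponentially with height, so per-pixel intensity is **not**
proportional to fluorophore density and photometric statistics are biased.
`tirfcell` is for cell biologists and biophysicists who want to quantify
*where* fluorescent structures (here: F-actin patches) sit in the
contact-area without trusting *how bright* they are.

## The method

Given a bright-field / TIRF image pair of one cell:

1. **Segment** the cell in the bright-field frame (blur → Otsu → closing →
   largest component) and fit an ellipse; its geometric elongation is
   `E_BFM = log2(a/b)` for semi-axes `a >= b`.
2. **Binarize** the TIRF frame: normalized intensity `> 0.25` → 1, else 0.
3. **Score** the binary patch distribution by central second moments about
   the cell centroid, combined into Hu's rotation invariants
   `phi1 = mu20 + mu02`, `phi2 = (mu20 - mu02)^2 + 4 mu11^2`, and the
   elongation

   ```
   E_TIRFM = log2( sqrt(lambda1 / lambda2) ),   lambda_{1,2} = 2 pi (phi1 ± sqrt(phi2))
   ```

   — 0 for isotropic distributions, ~2 for highly polarized cells, and
   invariant to translation, rotation and scale.
4. **Classify** the adhesion stage (I attaching / II spreading /
   III expanding) from `E_TIRFM` with configurable band edges (1.0, 1.65).
5. **Profile** the ellipse in 72 equal-angle sectors: per-sector surface
   density `sigma_theta = A^L_theta / A^T_theta` (bright area over sector
   area) and its probability-normalized profile `f_sigma(theta)`.

A seeded synthetic generator (`generate_cell()`, `generate_cohort()`)
produces image pairs with known ground truth for all three stages, so the
entire pipeline is testable without microscope data. Cohort runs report
Pearson correlation between the two elongation scores and a one-way ANOVA of
`E_TIRFM` across called stages.

## Worked example

```r
library(tirfcell)

cell <- generate_cell(synth_config(stage = "III", seed = 42))
rec  <- run_cell(cell$bfm, cell$tirfm, cell_id = "demo")
rec[, c("cell_id", "e_bfm", "e_tirfm", "stage", "n_bright_px")]
#> # A tibble: 1 × 5
#>   cell_id e_bfm e_tirfm stage         n_bright_px
#>   <chr>   <dbl>   <dbl> <fct>               <int>
#> 1 demo    0.586    1.97 III_expanding        7289
```

The synthetic expanding-stage cell has a moderately elongated footprint
(`e_bfm = 0.586`, axis ratio ~1.5) but strongly polarized actin
(`e_tirfm = 1.97`, principal spread ~4x the transverse one), so it is called
stage III. Its sector profile shows where the 7289 bright pixels sit:

```r
head(rec$profile[[1]], 3)
#> # A tibble: 3 × 7
#>   sector theta_deg area_total_px area_bright_px sigma f_sigma zero_area
#>    <int>     <dbl>         <int>          <int> <dbl>   <dbl> <lgl>
#> 1      0       2.5           626            460 0.735  0.0501 FALSE
#> 2      1       7.5           617            433 0.702  0.0478 FALSE
#> 3      2      12.5           593            313 0.528  0.0360 FALSE

autoplot(rec$profile[[1]])   # polar plot of f_sigma(theta)
```

A full 48-cell cohort (17 attaching, 19 spreading, 12 expanding):

```r
rep <- run_cohort(generate_cohort(c(17, 19, 12), seed = 1))
rep
#> <cohort_report> 48 cells (48 analysed)
#>   stage counts (I/II/III): 17/19/12
#>   Pearson r(E_BFM, E_TIRFM) = 0.975
#>   one-way ANOVA across stages: F = 1.11e+03, p = 5.58e-39
glance(rep)     # one-row cohort summary
tidy(rep)       # per-cell records
autoplot(rep)   # E_TIRFM vs E_BFM scatter, coloured by stage
```

The two elongation scores correlate strongly across the cohort and the
stage groups separate decisively, which is exactly what the generator's
stage presets are built to produce.

## Command line

`inst/cli/tirfcell.R` wraps the same functions:

```sh
Rscript inst/cli/tirfcell.R synth  --out images/ --seed 1 --counts 17,19,12
Rscript inst/cli/tirfcell.R cohort --dir images/ --out report/
Rscript inst/cli/tirfcell.R run    --bfm cell_001_bfm.tif --tirfm cell_001_tirfm.tif --out report/
Rscript inst/cli/tirfcell.R profile --bfm cell_001_bfm.tif --tirfm cell_001_tirfm.tif --out prof.csv
```

Every pipeline constant (threshold, sector count, band edges, centroid mode,
…) lives in a flat YAML/JSON config; see `?pipeline_config`.

## Further reading

The methods vignette (`vignettes/quantifying-actin-elongation.Rmd`) explains
the model, the coordinate and normalization conventions, the synthetic
generator's calibration, and the package's limitations.
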
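# pitenhance

Contrast enhancement and quality assessment for backscattering 3×3
Mueller-matrix polarimetry images of tissue.

Polarization imaging records how a sample transforms linearly polarized
light: sixteen intensity frames, one per pair of generator/analyzer angles
in {0°, 45°, 90°, 135°}, determine a per-pixel 3×3 Mueller matrix whose
m11-normalized elements carry microstructural information — in brain tissue,
they can separate glioma from non-glioma regions. The diagonal element
images have usable contrast; the off-diagonal ones (m12, m13, m21, m23,
m31, m32) usually do not. This package implements an enhancement scheme for
exactly that situation, together with everything needed to evaluate it.

## The method

For a region's pixel population *X*, the central moment coefficients

> P3 = E(X−μ)³/σ³  (skewness: asymmetry of the frequency-distribution histogram)
> P4 = E(X−μ)⁴/σ⁴  (kurtosis: peakedness of the FDH)

differ systematically between tissue types. The image is partitioned into
*i·j/N²* non-overlapping *N*×*N* sub-regions ("segmentation mode N"), P3
and P4 are computed per sub-region, and the resulting blockwise-constant
**enhancement matrices** S-P3 / S-P4 are blended with the original element
image *I* through convex weights:

> I-S-P3(i,j)<sub>seg-N</sub> = α·I(i,j) + β·P3(i,j)<sub>seg-N</sub>,  α + β = 1

(and likewise for P4). Quality is quantified by the contrast
C = Σ<sub>δ</sub> δ²·p(δ) over adjacent-pixel gray differences, the mean
gradient MG, and their relative improvements Cp = (C(e)−C(o))/C(o),
MGp = (MG(e)−MG(o))/MG(o), with paired t-tests across samples.

Because no clinical images are deposited with the published study, the
package also ships a seeded phantom generator: two-region Mueller element
images whose regional (P3, P4) follow the published per-element values,
realized exactly through a Johnson-system/Gaussian-copula construction with
tissue-like spatial texture. See the methods vignette
(`vignettes/polarization-enhancement.Rmd`) for the model, parameter
defaults, and design rationale.

## Worked example

```r
library(pitenhance)

cfg <- phantom_config(shape = c(120L, 60L), texture = 4, seed = 7)
ph  <- generate_phantom(cfg)
ph
#> <pit_phantom> 120 x 60 px, geometry 'half', texture 4 px, seed 7, clip rate 0

img  <- element_image(ph$mueller, "m12")
maps <- blockwise_cmc(img[1:60, ], N = 10)   # glioma half, segmentation mode 10
head(tidy(maps$P3), 3)
#> # A tibble: 3 × 8
#>   block_row block_col     n     mu  sigma     P3    P4 valid
#>       <int>     <int> <int>  <dbl>  <dbl>  <dbl> <dbl> <lgl>
#> 1         1         1   100 0.0266 0.0133 -1.07   4.75 TRUE
#> 2         1         2   100 0.0228 0.0248 -0.430  2.21 TRUE
#> 3         1         3   100 0.0196 0.0116  0.297  1.91 TRUE

enh <- overlay_enhance(img[1:60, ], maps$P3, alpha = 0.9)
c(original = image_contrast(img[1:60, ]), enhanced = image_contrast(enh$values))
#>     original     enhanced
#> 0.0009636521 0.0010394909
```

Each block row is one sub-region's moment summary; the overlay at
α = 0.9/β = 0.1 raises the display-normalized contrast of this glioma
half-image by about 8%. The factorial protocol sweeps elements × regions ×
coefficients × α × N and summarizes improvement rates:

```r
sw <- sweep_assessment(ph, elements = c("m12", "m23"),
                       alphas = c(0.5, 0.7, 0.9), Ns = c(4L, 10L))
glance(sw)
#> # A tibble: 1 × 6
#>   n_samples n_cells frac_improved_C frac_improved_MG mean_Cp mean_MGp
#>       <int>   <int>           <dbl>            <dbl>   <dbl>    <dbl>
#> 1         1      48           0.979            0.979    2.39    0.368

autoplot(sw, "C")   # bar chart of C by overlay-scale group, per element/region
```

`sweep_phantom_replicates()` repeats this over seeded phantom replicates,
and `significance_table()` runs the per-element paired t-tests. File-based
runs (`cmd_simulate()`, `cmd_enhance()`, `cmd_assess()`) read YAML/JSON
configurations and write TIFF/PNG/CSV/JSON bundles; the same commands are
available from a shell:

```sh
inst/cli/pitenhance simulate --out runs/phantom --seed 1
inst/cli/pitenhance assess   --out runs/assessment --seed 1
```

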
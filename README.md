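# rbcdi

Quantifies red blood cell (RBC) deformability from brightfield images of
cells elongating in microfluidic shear flow, and provides the statistical
layer used to compare donor groups (e.g. healthy controls vs. chronic
lymphocytic leukemia patients) and to compare analysis pipelines with each
other.

## What it computes

Each imaged cell is summarized by the deformability index

```
DI = (L_X − L_Y) / (L_X + L_Y)
```

where `L_X` is the cell's extent along the flow axis and `L_Y` its
transverse extent: 0 for a circle, approaching 1 for extreme elongation,
and independent of magnification. Applied wall shear stress τ (dyn/cm²)
converts to wall shear rate via γ̇ = 100·τ/μ (s⁻¹) for a suspension of
viscosity μ (mPa·s; default 1.12, RBCs in Dextran 70 at 37 °C).

Two independent image pipelines produce per-cell `DI`:

- **`run_sinewin()`** — background suppression by subtracting a 1-D
  squared-sine-window convolution (100 samples) applied along the flow
  axis, contrast enhancement, Otsu-based object detection, least-squares
  ellipse fitting to a subpixel cell contour, and three acceptance
  criteria (elongated along flow; `L_X − L_Y ≥ 0.2·L_X`; size windows).
- **`run_dog()`** — Difference-of-Gaussians band-pass (σ = 0.7 and 16 px),
  horizontal white top-hat (45-px line), binarization at 1.06× the Otsu
  threshold, border and 50–130-px area filtering, farthest-point axis
  measurement, and a DI ≤ 0.35 artifact cap.

Per-image results pool into `DI_Total`/`DI_Mean` (`summarize_image()`),
per-donor profiles across shear conditions (`aggregate_donor()`), and the
statistics layer covers Shapiro–Wilk, exact/approximate Mann–Whitney,
linear mixed-effects models with Satterthwaite degrees of freedom and
partial eta squared (`fit_mixed_model()`, `partial_eta_squared()`),
Pearson correlation, and Bland–Altman agreement (`bland_altman()`), with
broom-style `tidy()`/`glance()` and `autoplot()` methods.

A synthetic generator (`generate_image()`, `generate_cohort()`) renders
streamline backgrounds and elliptical cells with known ground truth, and
donor cohorts from a saturating DI–shear response calibrated against
published group profiles (`reference_di_profiles()`), so every pipeline
stage is testable without raw microscopy data.

## Worked example

```r
library(rbcdi)

img <- generate_image(n_cells = 20, seed = 1)      # 400x400 px, known truth
res <- run_dog(img$grid, stress_dyn_cm2 = 3, donor_id = "d01",
               group = "healthy")
res$summary
#> # A tibble: 1 × 8
#>   donor_id group   stress_dyn_cm2 shear_rate_s1 n_cells di_total di_mean empty
#>   <chr>    <chr>            <dbl>         <dbl>   <int>    <dbl>   <dbl> <lgl>
#> 1 d01      healthy              3          268.      16     2.01   0.126 FALSE
```

Sixteen of the twenty rendered cells pass the DoG pipeline's filters at
3 dyn/cm² (shear rate 268 s⁻¹); their mean DI of 0.126 sits in the range
typical of moderately deformed RBCs. A synthetic cohort run through the
mixed model shows the kind of group comparison the package reports:

```r
cohort <- generate_cohort(cohort_model(), seed = 42)   # 13 healthy + 9 CLL donors
tidy(fit_mixed_model(cohort))
#> # A tibble: 3 × 6
#>   effect             df1   df2      f  p_value  eta2p
#>   <chr>            <int> <dbl>  <dbl>    <dbl>  <dbl>
#> 1 group                1  20.0 109.   1.49e- 9 0.845
#> 2 shear_rate           6 120.  266.   7.27e-67 0.930
#> 3 group:shear_rate     6 120.    1.18 3.20e- 1 0.0559
```

Here the generated group difference (healthy vs. CLL response curves) is
detected with a very large effect size (η²p = 0.845), shear dependence is
strong, and — with the default cohort parameters — the interaction is
small. The `eta2p` column is `F·df1/(F·df1 + df2)` evaluated on the
Satterthwaite-approximated degrees of freedom.

A command-line front end wraps the same functions
(`inst/cli/rbcdi.R`: `simulate`, `analyze`, `compare`, `stats`
subcommands).

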
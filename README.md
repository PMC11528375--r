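# hippomorph

Level-set morphometry of the hippocampus from manually traced MRI.

Hippocampal volume is a standard imaging biomarker, but volume alone
discards most of the structure's shape. `hippomorph` implements a complete
pipeline that turns per-slice manual tracings of the hippocampus (or any
compact brain structure) into a signed-distance **digital twin** — an
implicit 3D representation `phi(x)` that is negative inside the structure
and zero on its boundary — and then reads six morphological descriptors
off that representation:

| descriptor | definition | units |
|---|---|---|
| volume `V` | divergence-theorem volume of the zero-level surface | cm³ |
| surface area `A` | triangle-sum area of the zero-level surface | cm² |
| diameter `D` | `2 r_cir,min`, the smallest sphere containing the shape | cm |
| sphericity `S` | `r_in,max / r_cir,min` (max inscribed over min circumscribed radius) | — |
| roundness `R` | `(1/N) Σ r_i / r_cir,min`, mean corner curvature radius over the circumscribed radius | — |
| aspect ratio `AR` | shortest over longest principal-axis extent | — |
| volume-to-surface `V/A` | with its reciprocal `A/V` reported alongside | cm, cm⁻¹ |

The reconstruction follows the classical image-processing chain for manual
tracings: polygon rasterization → watershed component labeling on the
internal distance transform → non-local-means denoising of the MRI →
distance-regularized level-set evolution against the denoised image's edge
map → marching isosurface extraction. Around the geometry sit the study
statistics: inter-rater mismatch/matching and an auditable tuning
protocol, rater calibration regression, finite-population sample size,
Kolmogorov–Smirnov normality checks, Welch/Student t-tests (raw or from
published summary statistics), and quadratic volume-vs-age fits (OLS and
two weighted variants).

Because real patient MRIs are not required for validation, the package
ships first-class synthetic generators: voxelized phantoms (sphere,
ellipsoid, capsule, bent tube) with analytic ground-truth descriptors, and
a cohort simulator with configurable age law, sex/hemisphere offsets and
two-rater calibration structure. Every algorithm is tested against those
closed forms.

## Worked example

Segment a noisy synthetic hippocampus-scale phantom end to end and compare
the measured descriptors with the analytic truth:

```r
library(hippomorph)
set.seed(2)

ph   <- make_phantom(phantom_spec("sphere", r = 9.2, spacing = 0.5), noise_sd = 5)
den  <- nlm_denoise(ph$image)                  # patch-similarity denoising
init <- erode_mask(ph$mask, 1.0)               # deliberately imperfect init
twin <- evolve_level_set(init, den, evolution_params(iterations = 150))
dice_coefficient(twin$values < 0, ph$mask$values)
#> [1] 0.9906
describe_shape(twin)
#> Shape descriptors:
#>   volume           3.174 cm^3
#>   surface area    10.600 cm^2
#>   diameter         1.846 cm
#>   sphericity       0.962
#>   roundness        0.953
#>   aspect ratio     0.991
#>   V/S             0.2994 cm   (S/V 3.340 cm^-1)
```

The analytic values for this phantom are V = 3.262 cm³, A = 10.64 cm²,
D = 1.84 cm and S = R = AR = 1: from a noisy image and a deliberately
eroded initialization, the pipeline recovers the shape to a Dice of 0.99,
about 3% in volume and a few percent in the dimensionless descriptors.

The agreement and cohort tools work on plain tables:

```r
mismatch_percent(3.25, 3.35)        # rater disagreement on mean volume
#> [1] 3.030303
t_from_summary(3.81, 0.49, 302, 3.30, 0.74, 126)$t   # cohort vs published study
#> [1] 7.113
sample_size(N = 1724617, Z = 1.90, p = 0.035, q = 0.965, e = 0.05)$n
#> [1] 49
```

A thin command-line front end over the same functions lives at
`inst/cli/hippomorph.R` (subcommands `phantom`, `cohort`, `rasterize`,
`reconstruct`, `describe`, `agree`, `samplesize`).

## Documentation

The methods vignette (`vignettes/hippomorph-methods.Rmd`) describes the
model, the numerical choices (anti-aliasing scales, the touching-ball
corner radius estimator, stability bounds), the simulator's assumptions,
and known limitations. Every exported function carries roxygen
documentation.
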
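# gaitspec

Walking is quasi-periodic, so the spectrum of a raw accelerometry signal
recorded during a walking bout carries detailed information about gait —
where the energy sits relative to the fundamental stepping frequency, how
much leaks into half-integer harmonics, how controlled the stride is. Most
accelerometry studies collapse all of this into activity counts. `gaitspec`
keeps it: the package turns raw tri-axial hip-worn accelerometry from a
walking bout into a **scaled, cadence-aligned order-domain Fourier
spectrum** per subject, and relates those spectra to continuous health
outcomes (age, BMI, fitness measures, ...) with a **penalized
scalar-on-function linear model** whose penalty encodes the harmonic
structure of walking.

It is aimed at biostatisticians and physical-activity researchers who have
raw sub-second accelerometry from known walking bouts and want to model
outcomes on the full walking spectrum rather than on summary counts.

## The model

Each subject's bout is split into 10 s non-overlapping windows. Per window
the pipeline computes the vector magnitude
`vm(t) = sqrt(x1(t)^2 + x2(t)^2 + x3(t)^2)`, the vector magnitude count
(VMC, the mean absolute deviation of `vm`), a Hanning-tapered short-time
Fourier magnitude spectrum on a fixed 0–39.9 Hz grid (0.1 Hz steps), and
the cadence — the largest spectral peak in 1.2–4.0 Hz. Dividing the
frequency axis by the cadence moves each spectrum to the *order domain*,
where harmonics align at integer multiples across subjects; spectra are
averaged over windows, restricted to 546 points on [0.3, 5.75], and scaled
to equal 1 at order 1.

With `W_i(s)` the scaled spectrum of subject `i`, the outcome model is

    y_i = gamma_0 + Male_i gamma_1 + Cadence_i gamma_2 + VMC_i gamma_3
          + \int W_i(s) beta(s) ds + eps_i,      eps_i ~ N(0, sigma_eps^2)

Estimation minimizes `||y - X gamma - W beta||^2 + lambda ||L beta||^2`
with the decomposition penalty `L = a (I - P_Q) + P_Q`, where `P_Q`
projects onto the span of Gaussian bells centered at cadence multiples
0.5, 1.0, ..., 5.5 and `a = 2` penalizes directions outside that harmonic
subspace four-fold (in squared norm). `lambda` is the variance ratio
`sigma_eps^2 / sigma_beta^2` of the equivalent linear mixed model,
estimated by REML. Pointwise 95% confidence bands for `beta(s)` come from
the mixed-model covariance of the penalized estimator.

Because studies of this kind rarely deposit raw data, the package ships a
synthetic-cohort generator (`simulate_cohort()`) that produces realistic
quasi-periodic bouts and responses drawn from the model above with known
coefficients, so the whole chain is testable end to end.

## Worked example

```r
library(gaitspec)

co <- simulate_cohort(cohort_spec(n_subjects = 100, sigma_eps = 0.25, seed = 42))
print(co$features[[1]])
#> <gait_features> subject subj001 | cadence 2.00 Hz | VMC 0.248 g | 30 window(s) | 546 grid points

ds  <- assemble_design(co$features, co$covariates, co$y)
fit <- fit_functional_model(ds)
print(fit)
#> Penalized scalar-on-function fit (decomposition penalty, a = 2 )
#>   N = 100 subjects, p = 546 order-grid points
#>   lambda (REML) = 2.818e-05  [sigma_eps^2 = 0.05848, sigma_beta^2 = 2075]
#>   Scalar coefficients:
#>          intercept    male cadence    vmc
#> estimate   70.4216 -1.0662  1.9953 3.1446
#> se          1.4352  0.0537  0.2745 0.5262
#>   Cadence multiples with beta != 0 (pointwise 95% band): 2.5
```

The generating truth here is `gamma = (70, -1, 2, 3)` with a single
Gaussian bump in `beta(s)` at 2.5 multiples of the cadence: the scalar
coefficients are recovered to within their standard errors, and the band
flags exactly the bump location among the eleven candidate harmonics.
`plot(fit)` draws the estimated coefficient function with its pointwise
band. The same chain is available as shell commands through
`inst/scripts/gaitspec.R` (`simulate | preprocess | fit | all`), reading
and writing CSV/YAML/JSON artifacts.

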
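# svprecision

Precision modelling for small-volume (SV) kidney dosimetry in molecular
radiotherapy.

In [177Lu]Lu-DOTATATE therapy the kidneys are the dose-limiting organ, and
their absorbed dose is estimated from quantitative SPECT/CT. The reference
estimate averages over the segmented whole kidney parenchyma (WKP); a
lighter-weight alternative averages a handful of small spherical volumes
of interest (2 ml or 0.6 ml) placed in the parenchyma. This package is for
dosimetry and medical-physics researchers who want to quantify how precise
the SV approach is relative to the WKP reference, and how fast precision
improves as more SVs are averaged.

The core model: SV and WKP doses are noisy multiplicative observations of
the same true dose,

    X_SV,i = D_true · b · (1 + ε_i),     X_WKP = D_true · (1 + ε_WKP),

with jointly Gaussian, partially correlated noise. The precision statistic
is the relative difference RD(k) = 100·(SV_mean(k) − WKP)/WKP, whose
standard deviation across kidneys, U(k), is modelled by the power law

    U(k) = α·k^(−β) + γ,

where β = 1/2 is ideal central-limit scaling and the asymptote γ is the
residual relative imprecision of the WKP estimate itself — the best
achievable precision no matter how many SVs are averaged. The package
provides the generative noise simulator with closed-form oracles, the
normalization-factor (mean SV/WKP ratio) estimator with its SEM,
subset-pooled precision curves, the bounded nonlinear power-law fit,
rank-sum comparison between SV sizes, a calibrated synthetic-cohort
generator (no patient dose tables are publicly available), and a CLI.

## Worked example

```r
library(svprecision)

cohort <- generate_cohort(default_config(seed = 42))  # 36 kidneys x 10 conditions
recs   <- split_records(cohort)[["v2_f0"]]            # 2 ml SVs, unfiltered

nf <- normalization_factor(recs)       # mean SV/WKP ratio over 180 SVs
#> nf$nf = 1.1267, nf$sem = 0.0109     # recovers the generating bias 1.12

curve <- precision_curve(normalize_records(recs, nf$nf), 1:5)
#>  k u_percent n_samples
#>  1 12.956360       180
#>  2 10.801199       360
#>  3  9.987725       360
#>  4  9.568388       180
#>  5  9.404407        36

fit <- fit_power_law(curve)
#> alpha = 4.6796 %   beta = 0.9080   gamma = 8.2810 %
#> R^2 = 0.99950      path = lm
predict(fit, 100)                      # extrapolated precision at 100 SVs
#> 8.3524
```

Reading: a single 2 ml SV estimates the kidney dose with ~13 % relative
precision on this cohort; averaging five SVs improves it to ~9.4 %; the
fitted floor γ ≈ 8.3 % says further SVs cannot beat the WKP estimate's own
noise. The power law explains the curve with R² = 0.9995.

The same pipeline runs from a shell:

```sh
svprecision simulate --seed 42 --out cohort.csv
svprecision analyze  --in cohort.csv --volume 2 --filter 0 --kmax 5 \
                     --normalize --out curve.csv
svprecision fit      --in curve.csv --out fit.json
svprecision report   --in fit.json
```

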
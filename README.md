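# imvt

Integrative mean–variance testing for two-condition differential expression.

## The problem

Conventional differential-expression analysis asks whether a gene's *mean*
expression differs between two conditions. But a condition change can also
alter the *variance* of a gene's expression — genes embedded in co-expression
networks, or interacting with environmental factors, often respond with a
spread change rather than (or in addition to) a location change. A gene whose
mean and/or variance responds to the condition is *mean–variance
differentially expressed* (MVDE). Testing only the mean leaves the variance
signal on the table; testing the joint null

H₀₃ : μ₁ = μ₂ **and** σ₁² = σ₂²

recovers it.

The package is for analysts of bulk or single-cell expression matrices
(probes/genes × samples, two conditions, optional covariates) who want to
test H₀₃ per probe with honest type-I control, and for methodologists who
want the accompanying simulation machinery.

## The method

The mean component is the Welch t statistic with Welch–Satterthwaite degrees
of freedom; the variance component is the Levene statistic, the one-way
F-ratio on absolute deviations from the group mean (robust far beyond
normality, unlike the two-sample F ratio). Whenever the two groups jointly
follow a spherically symmetric distribution, the mean-heterogeneity and
variance-heterogeneity statistics are *independent under the dual null* — so
Fisher's method applies:

IMVT = −2 ( ln p_WT + ln p_Levene )  ~  χ²₄ under H₀₃.

The package ships the full comparator suite (Student t, Welch t, Student t
on standardized data, two-sample F, Levene, Brown–Forsythe, the Fisher
variants FWT/BFWT, the separate-tests rule SMVT with the level split
α₁ = α₂ = 1 − √(1−α), and the two-sample normal LRT against χ²₂), Monte-Carlo
engines for type-I-error and power studies under normal and Laplace
sampling, and a calibration pipeline for real matrices: robust-probe
selection, PCA screening of condition-associated background components,
residualization against covariates plus background components, genomic
inflation diagnostics, and BH-FDR / Bonferroni control.

## Worked example

Simulate a study with the anatomy of a normalized microarray experiment —
a dominant background component, latent condition-associated minor
components, covariates, and 50 planted MVDE probes among 5,000 (40 vs 40
samples) — then calibrate and test:

```r
library(imvt)
library(dplyr)

study <- simulate_study(seed = 1)
fit <- calibrate_study(study)
fit
#> mv_calibration: 5000 probes, 80 samples
#>   background: robust-probe, 2694 robust probes, 2 adjusted PC(s)
#>   genomic inflation: 4.748 before -> 0.964 after calibration

tidy(fit) |>
  arrange(p_imvt) |>
  select(probe_id, statistic_imvt, p_imvt, q_imvt, bonferroni_imvt) |>
  head(5)
#> # A tibble: 5 × 5
#>   probe_id   statistic_imvt   p_imvt     q_imvt bonferroni_imvt
#>   <chr>               <dbl>    <dbl>      <dbl> <lgl>
#> 1 probe_0028           49.2 5.26e-10 0.00000145 TRUE
#> 2 probe_0042           49.0 5.79e-10 0.00000145 TRUE
#> 3 probe_0013           46.2 2.24e- 9 0.00000373 TRUE
#> 4 probe_0046           45.1 3.87e- 9 0.00000438 TRUE
#> 5 probe_0027           44.8 4.38e- 9 0.00000438 TRUE
```

Reading the output: the raw per-probe IMVT p-values are massively inflated
(genomic inflation factor λ = 4.75 — latent structure, not biology), and
after adjusting for the two background components screened from the 2,694
robust probes, λ returns to 0.96. At FDR 0.05 the calibrated analysis makes
41 discoveries, and 49 of the 50 planted MVDE probes rank in the IMVT
top 100. The `q_imvt` column is the Benjamini–Hochberg adjusted p; the
`bonferroni_imvt` flag marks experiment-wide significance at 0.05/5000.

Single probes work the same way, as one-row tibbles:

```r
imvt(rnorm(40), rnorm(40, sd = 1.6))   # combined test
welch_t(c(1, 2, 3), c(2, 4, 6))        # mean component
levene_test(c(1, 2, 3), c(2, 4, 6))    # variance component
```

Monte-Carlo studies come back as tidy tables ready for ggplot2
(`plot_type1()`, `plot_power()`, `plot_qq()`, `plot_statistic_pair()`):

```r
power_study(tibble::tibble(r = 0, s = 0.5), "normal",
            replicates = 10000, seed = 1, tests = c("WT", "IMVT"))
#>   IMVT power 0.512 vs WT power 0.048 at (r, s) = (0, 0.5)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/imvt.R` (commands `test`, `simulate`, `calibrate`, `fixtures`);
see `?run_cli`.

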
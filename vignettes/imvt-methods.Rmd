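---
title: "Integrative mean-variance testing: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative mean-variance testing: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imvt)
```

## The model

For probe $i$, let $G_{ijc}$ be the expression of sample $j$ under condition
$c \in \{1, 2\}$, with per-condition means $\mu_{ic}$ and variances
$\sigma^2_{ic}$ estimated by the sample mean and the unbiased sample
variance. The dual null hypothesis is
$H_{03}: \mu_{i1} = \mu_{i2} \text{ and } \sigma^2_{i1} = \sigma^2_{i2}$.

The mean component is the Welch statistic
$WT = (\hat\mu_1 - \hat\mu_2) / \sqrt{\hat\sigma^2_1/n_1 +
\hat\sigma^2_2/n_2}$, referred to a t distribution with the (non-integer)
Welch–Satterthwaite degrees of freedom; two-sided p-values throughout. The
variance component is the Levene statistic: the one-way ANOVA F-ratio
computed on $Z_{ijc} = |G_{ijc} - \bar G_{ic}|$, referred to
$F_{1,\,n_1+n_2-2}$. The Brown–Forsythe variant centers on the group median
instead (midpoint interpolation for even samples), and the classical
two-sample F ratio $\hat\sigma^2_1 / \hat\sigma^2_2$ is also provided; its
two-sided p is $2\min(P(F \le f), P(F \ge f))$, capped at 1, because
variance heterogeneity is directionless here.

When the two groups jointly follow any spherically symmetric distribution,
the mean statistics (Student, Welch) are independent of the variance
statistics (F, Levene, Brown–Forsythe) under $H_{03}$ — a finite-sample
property, not an asymptotic one. The package verifies it empirically
(`independence_diagnostics()`) rather than re-deriving it. Independence
licenses Fisher's combination

$$\mathrm{IMVT} = -2(\ln p_{WT} + \ln p_{Levene}) \sim \chi^2_4
\text{ under } H_{03}.$$

The FWT and BFWT variants substitute the F and Brown–Forsythe p-values; the
separate-test rule (SMVT) rejects when either component rejects at
$\alpha_1 = \alpha_2 = 1 - \sqrt{1-\alpha}$, the equal split solving
$\alpha = \alpha_1 + \alpha_2 - \alpha_1\alpha_2$; and the two-sample normal
likelihood-ratio statistic $-2\ln\Lambda$ is referred to $\chi^2_2$.

Expectations worth keeping in mind, all reproduced by the test suite and
visible in `type1_error_study()` / `power_study()` output:

* At moderate samples ($n_1 = n_2 = 40$) WT, IMVT, and SMVT hold their
  nominal levels under both normal and Laplace sampling.
* The LRT's $\chi^2_2$ reference fails badly at small $n$ (inflation), and
  the FWT inflates under Laplace noise because the F component is a
  normality test in disguise. BFWT is conservative at small $n$.
* When variances differ ($s \neq 0$), IMVT beats every pure mean test by a
  wide margin; when only means differ it gives up a modest amount of power
  (the price of splitting the evidence across two components).

## Conventions and numerical choices

* **Reported SMVT p-value.** The split rule is a decision, not a p-value; we
  report $p = 1 - (1 - \min(p_{WT}, p_{LF}))^2$, which reproduces the split
  decision exactly at the equal split. This is a package convention.
* **Log safety.** Component p-values are clamped at `p_floor = 1e-300`
  before taking logs; the LRT is evaluated in log space.
* **Degenerate probes.** Zero pooled variance with equal means gives
  statistic 0, p = 1, with a warning naming the probe; with unequal means it
  is an error, as are zero variances where a test requires them. Levene-type
  tests return p = 1 when both numerator and denominator vanish, p = 0
  (logged) when only the denominator does.
* **STSD** divides each group by its own sample SD without centering:
  centering would erase the mean signal the test targets. The standardized
  groups have unit sample variance exactly, so the pooled variance of the
  standardized data is 1.
* **Seeding.** One seed generates one set of simulated matrices per call;
  every test is evaluated on the same replicates, so cross-test comparisons
  are paired, and reruns are bit-identical.

## The calibration pipeline

Real matrices carry latent structure: a dominant intensity component,
condition-associated minor components (impediment heterogeneity — it
confounds rather than informs), and covariate effects. `calibrate_study()`
separates this from condition-driven signal:

1. test all probes on the raw matrix (WT + Levene + IMVT) and record the
   genomic inflation factor $\lambda$ — the median $\chi^2_1$-transformed
   p-value divided by the null median 0.4549;
2. keep *robust* probes, those with $p_{WT} > \tau$ and $p_{LF} > \tau$
   ($\tau = 0.05$ by default);
3. compute principal components from the robust probes (probe-wise
   mean-centering, no scaling — normalized intensities share a scale;
   `scale.` is available) and flag components whose per-sample scores show
   mean or variance heterogeneity at $\tau_{pc} = 0.05$, unadjusted;
4. residualize the robust probes on intercept + covariates + flagged
   components, re-test, drop violators (drop-only; `passes` controls
   iteration);
5. recompute and re-screen components from the final robust set,
   residualize the *full* matrix on covariates + adjusted components
   (condition never enters the design), re-test everything, and report
   $\lambda$ after.

$\tau$ and $\tau_{pc}$ are deliberately unadjusted screening levels: the aim
is sensitive capture of background structure, not inference on components.
Both are exposed as arguments, and every inferred default is echoed to the
CLI log.

### Why flagged components must clear the noise floor

Two pathologies surfaced during development, and both are cured by one rule:
a flagged component enters the adjustment design only if its eigenvalue
exceeds `noise_floor_mult` (default 1.5) times the median eigenvalue.

First, screening all components at an unadjusted 0.05 flags several
pure-noise components per study *because* their scores happened to correlate
with the condition; regressing out directions selected for condition
correlation provably absorbs part of every probe's condition contrast, and
the absorptions accumulate ($\lambda$ can drop to 0.4–0.8 from this alone).
Second, the robust-probe selection itself manufactures such a component:
keeping only probes with large p-values suppresses variance along the
condition contrast, so a *trailing* component of the robust submatrix aligns
almost perfectly with the condition indicator (we have observed
$|\rho| = 0.64$ with a score-test p of $10^{-11}$); adjusting for it
annihilates signal and null alike. Components at the isotropic noise floor
are unidentifiable rotations of noise — they are not background structure,
and nothing of value is lost by excluding them.

The naive mode (`robust = FALSE`) computes components from *all* probes and
applies no floor. That is exactly the over-adjustment the robust pipeline
exists to avoid: its components absorb informative heterogeneity, $\lambda$
falls well below 1, and planted-probe recovery drops. It is kept as a
first-class mode because the contrast is instructive (and tested).

### Diagnostics

`genomic_inflation()` follows the standard median-$\chi^2_1$ construction;
`qq_band()` gives the pointwise central 95% interval of the
$\mathrm{Beta}(i, n-i+1)$ order statistic for each rank, which
`plot_qq()` draws on the $-\log_{10}$ scale. `bh_fdr()` wraps
`stats::p.adjust(method = "BH")`; `bonferroni_threshold()` is $\alpha/m$.

## What the synthetic generator emulates

`simulate_study()` produces the package's standard test bed: 5,000 probes,
40 + 40 samples, 50 planted MVDE probes. Its anatomy, and why each piece is
there:

* **A bright stratum carries the dominant component.** 3% of probes load at
  20 on a global factor; the leading PC then holds $> 95$% of total variance
  while a *typical* probe is not background-dominated. This mirrors
  normalized microarray data, where total variance concentrates in
  high-intensity probes. (A homogeneous dominant factor would swamp
  per-probe signal entirely; and a large bright stratum is a block of
  probes sharing one factor draw, whose near-identical p-values form a lump
  that destabilizes the $\lambda$ median.)
* **Two condition-associated minor factors** supply the impediment
  heterogeneity: one mean-shifted (shift 0.45 against score SD 0.5, a
  standardized difference of about 0.9 — strong enough for the screening
  test to flag it reliably, moderate enough that adjusting it does not
  absorb the condition contrast), one variance-inflated (spread multiplier
  2, flagged through the Levene screen, which costs the mean side nothing).
  With loadings of SD 0.35 on every probe these drive the uncalibrated
  $\lambda$ far above 1.3.
* **Covariates** (an age-like numeric and a derived binary) affect 20% of
  probes but are independent of the condition. Confounded covariates would
  force even an oracle adjustment to absorb condition contrast and push
  post-calibration $\lambda$ well below 0.9; independence keeps their
  adjustment free.
* **Planted MVDE probes** cycle through mean-only, variance-only, and dual
  effects ($r = s = 1.5$ by default: a mean shift of 1.5 noise-SDs and/or a
  noise-spread multiplier of 2.5), written to a `truth` table for recovery
  scoring.

On this fixture the full pipeline takes the uncalibrated IMVT $\lambda$ from
roughly 3–7 back into the vicinity of 1 and places nearly all planted probes
in the IMVT top 100 (the acceptance tests assert $\lambda_{before} > 1.3$,
$\lambda_{after} \in [0.9, 1.2]$, recovery $\ge 80$%).

What the generator does **not** emulate: probe–probe correlation beyond the
factor structure, skewed or heavy-tailed intensity noise (a Laplace option
exists but the default is normal), batch blocks, missing values, and
count-type mean–variance coupling. Passing tests on this fixture show the
pipeline recovers planted structure under the stated anatomy; they do not
certify behaviour on data violating it.

## Problem sizes

The test suite simulates at 10,000 replicates for calibration checks and
100,000 for the statistic-pair correlation studies; the full suite runs in
under a minute on one core, and `scripts/acceptance.R` (100,000 replicates)
in a few seconds. Paper-scale power surfaces over an $(r, s)$ grid at
100,000 replicates remain a `power_study()` call away.

## Known limitations

* The Levene and Brown–Forsythe references are asymptotic: at $n = 40$ their
  finite-sample null p-values deviate from uniform by up to about 0.02 in
  sup norm (Brown–Forsythe more than Levene), which leaks a point or two of
  anti-conservatism into IMVT at $\alpha = 0.05$ under heavy tails.
* The condition-specific variance estimates behind the Welch component are
  unstable at very small samples; the IMVT is a moderate-to-large-sample
  tool. A moderated mean test can be registered through the plug-in slot of
  `imvt()` (`mean_test =` any function returning a `p_value`), but none
  ships.
* $\lambda$ estimated across correlated probes is itself noisy; on a single
  study the post-calibration value scatters around 1 by roughly $\pm 0.15$
  even when calibration is exact.
* The robust-selection noise-floor rule assumes approximately isotropic
  probe-level noise; grossly heteroskedastic noise floors would call for a
  parallel-analysis style threshold instead.
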
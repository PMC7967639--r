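---
title: "Methods: from PAH congener tables to cancer risk and genotoxicity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from PAH congener tables to cancer risk and genotoxicity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahrisk)
```

This vignette documents the models behind `pahrisk`, the assumptions they
make, the parameters that matter, and the design decisions taken where a
choice was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Data model

The unit of air-quality observation is a **congener profile**: the
concentrations (ng m⁻³) of the 16 USEPA priority PAH congeners measured
on a PM2.5 filter, keyed by sample, school, zone (exposed vs comparative)
and site (indoor vs outdoor). `congener_registry()` fixes the 16
abbreviations, ring counts, the low/high molecular-weight split (LMW =
2–3 rings: NAP, ACY, ACP, FLU, PHE, ANT; HMW = 4–6 rings: the other ten)
and the conventional seven probable carcinogens (BaA, CYR, BbF, BkF, BaP,
IcP, DbA). The carcinogen set is a convention, not a law; it is exposed
through the registry so callers can regroup.

Raw GC–MS readings convert to air concentrations as
`C = C_determined × dilution / air_volume` with the study's 7.2 m³ sample
volume as default; the dilution factor is a user-supplied dimensionless
multiplier that absorbs the final extract volume. Non-detects and missing
values are treated identically and imputed at half the method detection
limit (`impute_below_mdl()`), the standard convention for left-censored
air-quality data; the operation is idempotent and refuses to guess when no
MDL is on record.

## TEQ and the inhalation risk model

Toxicity-equivalent concentration is the TEF-weighted sum over congeners
(`teq()`), linear and monotone by construction. Fluoranthene is absent
from some published renderings of the weighted sum; we default its TEF to
the Nisbet–LaGoy value 0.001 and expose it as an argument
(`tef_nisbet_lagoy(fla = )`).

The lifetime inhalation risk is

$$\mathrm{ILCR} = \mathrm{TEQ}\cdot 10^{-6}\cdot \mathrm{CSF}\cdot
\left(\frac{BW}{70}\right)^{1/3}\cdot
\frac{IR\cdot ED\cdot EF}{BW\cdot AT}.$$

The cube-root factor is the standard body-weight extrapolation of a slope
factor referenced to a 70 kg adult; the net dependence is $BW^{-2/3}$, so
risk strictly decreases with body weight. This reading of the compact
"BW/70 cube root" notation is the only one we found that reproduces the
reported per-school risks from the reported per-school TEQs to within a
few percent, which is why it is the implemented form. Units: TEQ in
ng m⁻³ (hence the 10⁻⁶ ng→mg conversion), IR in m³ day⁻¹, EF in
day year⁻¹, ED in years, AT in days, CSF in (mg kg⁻¹ day⁻¹)⁻¹.

The averaging time is 70 y × 365 d = 25,550 d. The study's distribution
table prints 25,500; the definition is arithmetic and the difference is
0.2%, so the arithmetic value is the default (`risk_params(AT = )`
overrides).

`calibrate_body_weight()` inverts the model in closed form
($BW = (K/\mathrm{ILCR})^{3/2}$). It is used to fix one representative
child body weight per exposure group from a reported group-mean risk at
the group-mean TEQ — the study reports group risks but not group body
weights, so the body weight is the natural free variable to close the
system with.

## Monte Carlo simulation and the unprinted spread parameters

`monte_carlo_ilcr()` pushes `n_iter` independent (TEQ, BW) draws through
the deterministic model; 10,000 iterations is the study convention and
takes well under a second. One seeded RNG stream drives the whole run and
the seed is recorded in the result. TEQ draws are floored at 0 (the
logistic left tail; mass ≈ 5 × 10⁻⁵ at the default exposed
configuration) and body weights at 1 kg.

The study's distribution table fixes the families and some parameters but
not all:

* **Exposed TEQ** ~ logistic with mean 17.35 ng m⁻³; the scale is not
  printed. Default: calibrated from the dispersion of the three exposed
  school TEQs (20.01, 16.89, 13.69), $s = \hat\sigma\sqrt{3}/\pi \approx
  1.74$; override with `generate_risk_inputs(logistic_scale = )`.
* **Comparative TEQ** ~ log-normal with *arithmetic* mean 2.21 and sd
  2.51; `lognormal_from_arithmetic()` inverts the moments
  ($\mu = 0.3787$, $\sigma = 0.9102$) so the arithmetic moments
  round-trip exactly.
* **Body weight** ~ negative binomial with success probability 0.206
  (exposed) / 0.307 (comparative); the size parameter is not printed.
  Default: the size that makes the distribution mean equal the calibrated
  group body weight (32.1 kg exposed, 27.4 kg comparative), overridable
  via `bw_mean`.

Because two spread parameters are calibrated rather than reported, the
probabilistic summaries are reproducible only up to a band; the package
treats a factor of two as the meaningful comparison scale for the Monte
Carlo mean and 95th percentile. One structural caveat: the study's
reported deterministic comparative group mean is itself about 1.9× its
reported simulated comparative mean, so no parameterisation calibrated to
the former can land on the latter; the simulated comparative mean here
sits right at the edge of the factor-of-two band, and we report it as
computed rather than adjust either calibration.

`sensitivity_analysis()` uses the Crystal-Ball-style convention:
Spearman rank correlation of each varying input with the output, squared
and normalised to sum to one across varying inputs. Body weight always
carries a negative correlation when it varies. Percentiles everywhere use
linear interpolation between order statistics (R's quantile type 7),
stated in the output headers.

## Source apportionment

`classify_source()` implements the six-ratio threshold taxonomy with a
half-open `[low, high)` interval convention — a value equal to a
breakpoint takes the label of the interval that starts there — because the
literature states thresholds without boundary handling and a total,
deterministic rule is required. BaA/CYR below 0.2 is labelled
`unclassified`: the literature defines only the coal (0.2–0.35) and
vehicular (> 0.35) bands for that ratio. Zero denominators yield an
undefined-ratio flag and the sample is excluded from that rule's tally
rather than forced into a category.

KMO and Bartlett's sphericity gate the PCA. KMO is computed from the
anti-image (partial) correlations via the inverse correlation matrix; a
dataset whose off-diagonal correlations are all zero raises an error
rather than returning a conventional 0, since "no correlation at all" is
a different failure from "poor sampling adequacy". Any two-variable
dataset has KMO exactly 0.5 (the partial correlation equals the
correlation), which the tests exploit as a closed-form oracle.

`run_pca_varimax()` standardises columns, takes eigenvectors of the
correlation matrix, retains eigenvalues > 1 (Kaiser criterion) and
rotates with `stats::varimax` under Kaiser normalisation. Rotation
preserves per-variable communalities to 1e-8 (tested); component signs
are normalised so each column sums nonnegative (loadings tables are
conventionally printed positive). With fewer than two retained components
rotation is skipped with a warning. Note that with 16 variables and only
a few dozen samples the Kaiser criterion tends to retain one or two more
components than were planted — a known small-sample property of the
eigenvalue-1 rule, visible in the generator tests.

Loading-strength labels (|loading| ≥ 0.75 heavy, 0.50–0.75 moderate,
0.30–0.50 weak, else none) use absolute values, and boundary values take
the stronger label, consistent with the half-open convention elsewhere.

## Genotoxicity statistics

`compare_groups()` reports the classical independent t-test (equal
variances, matching the study's SPSS workflow; Welch via
`var_equal = FALSE`) together with a per-group Shapiro–Wilk normality
gate at α = 0.05 and the Mann–Whitney counterpart. The non-parametric
result is reported *alongside* rather than silently substituted, so the
reader can see both. School-level spread uses one-way ANOVA and
Kruskal–Wallis. `stratified_comparison()` applies the same machinery per
covariate level within each exposure group, excluding (and flagging)
levels with fewer than two subjects.

`fit_tail_moment_model()` is OLS with backward elimination at p ≥ 0.05 —
the published description names exclusions "due to the violation of the
p-value" without naming an algorithm, and backward elimination is the
simplest procedure consistent with that description. Collinear designs
(condition number > 1e8) are rejected up front with the offending pair
named. `tail_moment_models()` ships the four published fixed-coefficient
equations; their open-burning slopes are negative as printed, even though
the accompanying narrative describes open burning as increasing damage —
the package reproduces the printed coefficients and leaves the
contradiction to the analyst.

## What the synthetic generators emulate — and what they do not

`generate_congener_profiles()` builds each sample as a nonnegative
mixture of hand-built source signatures plus a flat background, with
three stochastic layers: a log-normal day-to-day amplitude per signature
(cv 0.5, mimicking the large day-to-day spread of field totals), an
idiosyncratic log-normal clutter amplitude per congener (cv 1,
uncorrelated across congeners so non-marker congeners do not inherit the
planted factor structure), and multiplicative analytical noise (log-sd
0.25). The signature weight vectors are fixtures designed to satisfy the
diagnostic-ratio bands and loading patterns the apportionment stage
expects — they are *not* estimates of real emission inventories. The
generator self-checks at construction that each signature's noise-free
ratios fall inside its declared bands, and the defaults are chosen so a
planted dominant source is recovered by majority ratio call in at least
80% of samples.

`generate_population()` draws tail moments from a truncated normal at the
group moments (27.20 ± 8.21 exposed, n = 85; 21.03 ± 4.88 comparative,
n = 120 — truncation bias at these moments is < 0.5% and ignored),
Bernoulli lifestyle covariates, additive covariate shifts (default: the
mosquito-coil shift, with the base mean re-centred so the marginal group
mean is preserved), negative-binomial body weights, and school-level
exposure totals inherited by each child from a randomly assigned school.
Covariate prevalences and the carcinogenic share of school totals are
synthetic design choices (0.25–0.5, and 0.5 respectively), not reported
quantities.

What passing tests on these data do **not** show: the generators are
rank-1-per-source mixtures with log-normal noise — they carry no
meteorology, no seasonal trend, no spatial correlation between indoor and
outdoor samples, no measurement censoring structure beyond what the MDL
imputation tests construct explicitly, and subject covariates are
mutually independent, which real lifestyle variables are not. Results on
real field data depend on those features; the synthetic suite
demonstrates correctness of the machinery, not field validity.

## Numerical choices and problem sizes

Tolerances: exact TEQ arithmetic is tested to 1e-12; KMO/Bartlett against
brute-force oracles to 1e-8; communality preservation to 1e-8; noise-free
regression recovery to 1e-6. Degenerate inputs raise informative errors
(zero TEQ for contributions, empty draw vectors, all-constant sensitivity
inputs, singular correlation matrices, collinear designs). The test suite
uses 10,000-iteration Monte Carlo runs where the study convention is
asserted, 2,000 replicates for the power/type-I calibration of the group
comparison, 300–400 seeds for generator calibration checks, and n = 100
samples × 10 seeds for planted-source recovery — sizes chosen so the
whole suite completes in about a minute while keeping Monte Carlo error
well below every asserted tolerance.
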
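---
title: "Models and methods behind obesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind obesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesim)
```

## The scientific question

Obesity is highly heritable, yet its worldwide rise since the 1970s is
usually attributed to environment alone, on the argument that gene pools
cannot change that fast. `obesim` implements the quantitative machinery
needed to examine the opposite possibility: that the near-elimination of
childbirth mortality by modern obstetrics (roughly 1935–1945 in developed
nations) removed a strong negative selection pressure on a highly
polygenic BMI trait with large standing variation, allowing obesogenic
alleles to rise within a few generations.

The package has three layers:

1. a **polygenic trait model** linking a pooled obesogenic allele
   frequency to mean BMI, BMI variance, and obesity prevalence;
2. a **selection and simulation layer** converting childbirth-mortality
   parameters into fitness differentials and iterating the allele
   frequency forward in time, deterministically or as a Wright–Fisher
   process;
3. an **ecological statistics pipeline** (plus synthetic-data
   generators) for cross-country analyses of historical maternal
   mortality against modern obesity rates.

## The polygenic model

We assume $L$ exchangeable loci, each copy of the obesogenic allele
adding $a$ kg/m² of BMI, and a pooled frequency $p$ shared by all loci.
Mean BMI is anchored at a baseline $\mu_0$ at a reference frequency
$p_0$:

$$\mu(p) = \mu_0 + c\,L\,a\,(p - p_0),$$

where $c$ is 1 under *haploid accounting* (one counted allele per locus,
the default) and 2 under diploid accounting. The default is haploid
because the headline arithmetic of the hypothesis — 1,000 loci × 0.1
kg/m² × a 5-percentage-point frequency shift = +5 kg/m², i.e. mean BMI
25 → 30 — counts one allele per locus; the diploid flag doubles the
shift for users who prefer two-copy bookkeeping.

Genetic variance is binomial across loci, $c\,p(1-p)a^2L$, and
phenotypes add independent environmental noise with standard deviation
`env_sd`. With $L \ge 100$ the genetic value is close to normal, so
obesity prevalence uses the normal approximation

$$\Pr(\text{BMI} > T) = 1 - \Phi\!\left(\frac{T - \mu(p)}{\sqrt{c\,p(1-p)a^2L + \sigma_e^2}}\right),$$

verified in the test suite against brute-force genotype sampling to
within three Monte-Carlo standard errors. Neither the obesity cutoff
$T$ nor the phenotype variance is asserted by the hypothesis itself:
$T = 30$ kg/m² is the clinical convention and `env_sd = 3` kg/m² a
plausible adult-BMI residual scale; both are configuration, not claims.

## The selection model

A `mortality_schedule` holds the lifetime maternal death rate (LMDR,
the probability a woman dies of maternal causes in her lifetime), the
first-month newborn mortality, the relative risks obesity adds to each
(empirically about 3–4), and completed fertility. Obese-stratum rates
are `min(base × RR, 1)`; the cap only binds once the product exceeds
1 (e.g. LMDR 15% × RR 4 = 60%, uncapped; neonatal 14% × 4 = 56%).

Expected surviving offspring per woman are, with stratum-adjusted rates
$L^*$ and $N^*$:

* **terminal** (default): $F\,(1-L^*)(1-N^*)$ — a maternal death
  forfeits the whole reproductive output;
* **midpoint**: $F\,(1-L^*/2)(1-N^*)$ — death on average halfway
  through reproduction.

Both conventions are exposed because the frequently quoted
"obese women left about half the offspring" does not pin down one
formula: with historical-scale figures (LMDR 15%, neonatal 14%, RR 4)
the maternal-only terminal deficit is $1 - 0.40/0.85 \approx 53\%$,
while the combined maternal-plus-perinatal deficit is
$1 - (0.40\cdot 0.44)/(0.85\cdot 0.86) \approx 76\%$. The package never
silently derives the 50% constant; the deficit follows from whichever
schedule and convention the user configures.

The **balance model** abstracts the opposing pressures: each generation
$p' = \mathrm{clamp}\{p\,(1 + g - \ell),\,0,\,1\}$ with gain $g$
(stabilising replenishment of obesogenic alleles — e.g. the infertility
and survival floor against very low BMI) and loss $\ell$ (the
childbirth-mortality removal). Before obstetrics the pool is assumed
stationary, so $g$ is *calibrated* to the pre-transition loss
($g := \ell_{\text{pre}}$) rather than derived — the stabilising
pressure is asserted, not measured, and this is the one free parameter
of the relaxation arithmetic. Removing the loss then gives the worked
example: from a 10% pool with $g = \ell = 0.5$, one generation of
$\ell = 0$ yields $0.10 \times 1.5 = 15\%$, then 22.5%, growing
geometrically until the clamp.

## Forward simulation

`deterministic_trajectory()` iterates the balance update, switching
from the pre- to the post-transition schedule at
`transition_generation` (mapped by default to calendar year 1940, the
midpoint of the 1935–1945 obstetrics window, with 25-year generations).
`wright_fisher_trajectory()` is the finite-population counterpart:
each generation draws per-individual allele counts
$k_i \sim \mathrm{Bin}(cL, p)$, phenotypes with environmental noise,
obesity status by threshold, and resamples the next generation
binomially at the selection-weighted frequency plus the gain influx
$p_{\text{next}} = \sum w_i k_i / (cL\sum w_i) + g\,p$. The additive
form mirrors the deterministic $p(1-\ell) + g\,p$ exactly in
expectation.

One modelling point deserves emphasis. The deterministic recursion uses
the *pooled* accounting in which the whole obesogenic pool carries the
obese-stratum fitness deficit. The Wright–Fisher process, by contrast,
removes only the alleles actually carried by obese individuals — the
covariance between fitness and allele count — which is smaller whenever
obesity prevalence is below one. The two modes therefore agree exactly
when the selection differential is off (relative risks 1, or after the
relaxation), which is the regime the convergence tests exercise; under
active selection the deterministic loss is an upper bound on the
realised Wright–Fisher loss. We keep both because the pooled recursion
is the hypothesis's own arithmetic, while the Wright–Fisher mode makes
drift and finite-population behaviour testable.

Selection acts on the obese/non-obese dichotomy, not continuously on
BMI, matching the framing of childbirth risk as an obesity effect; all
loci share one frequency (exchangeable loci, linkage equilibrium); no
mutation, migration, age structure or assortative mating.

### Cohort mixing

Cohorts born after the transition carry elevated obesity, but adult
*population* prevalence moves only as those cohorts become a larger
share of adults: the first elevated cohorts were a small fraction of
adults around 1970 and about half by 1980, which is when the epidemic
became visible. `adult_prevalence_series()` reproduces this lag with a
uniform adult age window (20–60 by default): prevalence stays flat
until elevated cohorts reach adulthood, rises, and accelerates as they
phase in — asserted in the tests as a non-negative second difference
during the phase-in window. Note the generation-length granularity:
with 25-year generations the first elevated cohort is born a generation
after the transition year, so calendar anchoring is conventional, not
calibrated to any nation's series.

## The cross-country pipeline

The pipeline mirrors classical ecological practice (and the SPSS
conventions of the original analyses):

* **Log transforms** of all analysis variables for homoscedasticity;
  non-positive cells are floored at half the column's smallest positive
  value (below-detection convention; configurable to `NA`), with
  machine-readable warnings.
* **Correlation matrices**: Pearson on logs and Spearman on raw values,
  pairwise-complete (per-cell n reported — this is why real-data cell
  Ns range widely), two-sided p-values.
* **Partial correlation** by the residual method (listwise-complete),
  p from $t$ on $n-k-2$ df; the test suite proves it identical to the
  classical recursive formula to $10^{-10}$.
* **Multivariate OLS** and **stepwise selection** on partial-F
  p-values with entry $p \le 0.05$ and removal $p \ge 0.10$; ties break
  on the smaller p, then input order, making the path deterministic.
  The suite checks the selected model is a stable subset under an
  exhaustive search with the same criterion (≤ 6 candidates).
* **Median split** on LMDR with ties going below (the above group is
  strictly greater than the median); the pipeline always computes and
  reports its own median rather than hard-coding a published one — the
  source analyses print both 0.48% and 0.45% for the same median, so
  neither is trustworthy as a constant.
* **Exponential fits** $\ln y = \alpha + \beta x$ for the
  obesity-versus-LMDR scatter, reporting the log-level correlation.
* **Fisher z comparison** of two partial correlations with the df
  correction $n - 3 - k$. The published contrast of $r = -0.573$
  (above-median, $n \approx 64$, 4 controls) versus $r = -0.336$ (all
  nations, $n = 133$, 4 controls) is quoted as $p = 0.03$; that value
  is reproduced by the **one-sided** probability (the two-sided value
  is ≈ 0.06), so both are always reported and the sidedness is explicit
  in the output.
* **Contingency analysis**: nations classified by MMR > 500 per
  100,000 (WHO very-high cutoff) × obesity > 19.5% (OECD-average
  convention), restricted to developing-nation classes, Pearson
  chi-squared without continuity correction by default (expected counts
  are large; Yates available by flag). On the published 2×2 counts
  [[58, 22], [1, 47]] the standard Pearson statistic is **59.87**
  (Yates: 57.07), not the published 42.592; the package reports the
  standard statistic and documents the discrepancy rather than
  reproducing an unexplained value.

Missingness follows the source conventions: pairwise for correlation
matrices, listwise for regressions and partial correlations (which is
how an N of 133 coexists with per-cell Ns of 147–191).

## The synthetic world

`generate_countries()` draws ~190 nations whose five covariates (LMDR,
GDP per capita, calorie intake, insufficient physical activity,
antibiotic consumption) are jointly Gaussian on the log scale with the
correlation structure of the real data (LMDR vs GDP ≈ −0.84, vs
calories ≈ −0.69, vs inactivity ≈ −0.45, vs antibiotics ≈ −0.75), and
plants a negative log-LMDR effect on log obesity:

$$\log O = \beta_0 - 0.2 \log \text{LMDR} + 0.8 \log \text{cal} + 0.25 \log \text{inact} + \varepsilon.$$

Choices and their reasons:

* LMDR is log-normal with median ≈ 0.48% and sd 1.5 on the log scale,
  spanning below 0.01% to ~15% — the observed 1990 range and skew.
* The planted slope −0.2 matches the real log-log regression scale;
  the residual sd 0.38 is derived in closed form so the
  confounder-adjusted partial correlation is −0.35 in expectation:
  with $\sigma_e = 1.5\sqrt{1 - R^2_{\text{LMDR}|\text{controls}}}
  = 0.707$ from the target matrix,
  $r = \beta\sigma_e / \sqrt{\beta^2\sigma_e^2 + \sigma^2}$ gives
  $\sigma = 0.38$. That places the planted world in the interior of
  the observed regime (≈ −0.3 to −0.6).
* Marginal locations (GDP ≈ 12,000, calories ≈ 2,800 kcal/day,
  inactivity ≈ 25%, antibiotics on an arbitrary defined-daily-dose
  scale) are realism anchors only; correlations and slopes, not
  locations, drive every test.
* MMR is LMDR divided by completed fertility (fertility itself rising
  with LMDR, clamped to 1.2–9 births), neonatal mortality is a
  log-scale companion of LMDR at $r \approx 0.88$, 1990 obesity is a
  scaled-down companion of 2016 obesity, and development classes come
  from GDP quantiles.
* Default per-column missingness (GDP 2%, calories 5%, inactivity 10%,
  antibiotics 15%) reproduces the real table's pairwise/listwise N
  gap (~190 pairwise, ~133 listwise).
* Rates are truncated at physical caps (obesity 80%, LMDR/inactivity
  90%, neonatal 50%); capped rows are recorded in an attribute because
  the planted identity is inexact on them.

What a green synthetic test does **not** establish: that real nations
satisfy the generator's joint-lognormal shape, that the real
LMDR–obesity association is causal, or that the published table values
are reproduced — the real multi-source dataset is not redistributed,
so the published Tables are covered property-wise (planted-effect
recovery, oracle agreement), never numerically.

## Numerical and design choices

* Probabilities are hard-capped at 1 after relative-risk scaling and
  allele frequencies clamped to [0, 1] after every update.
* Degenerate zero-variance prevalence is a step function (0.5 at exact
  equality of mean and threshold).
* In stepwise selection a term with an undefined partial-F p (perfect
  fit, zero standard error and zero estimate) is treated as removable;
  this only arises on noise-free diagnostics.
* Below-detection CSV cells `"<x"` are read as `x/2` (midpoint
  convention), keeping the magnitude information the marker carries;
  true zeros fall to the log floor.
* One seeded RNG per run; every artifact ships with a metadata sidecar
  (version, seed, config echo, input checksums, warnings) sufficient
  to regenerate it.
* Wright–Fisher drift enters through binomial resampling of $N \times
  cL$ alleles, so the per-generation drift variance is
  $p(1-p)/(N L c)$ — small for polygenic pools, which is itself a
  point of the large-standing-variation argument.

## Known limitations

* The exchangeable-loci pool is an accounting device; real
  architectures have an effect-size distribution, linkage and
  dominance, none of which are modelled.
* The deterministic relaxation arithmetic intentionally reproduces the
  pooled accounting of the hypothesis; as noted above it overstates
  the individual-based selection response under active selection.
* The ecological pipeline inherits all limits of ecological inference:
  nation-level associations, confounding, no causal identification.
* Calendar anchoring of generations is coarse (25-year steps); the
  simulator is not calibrated to any observed national obesity series,
  and makes no attempt to fit one.
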
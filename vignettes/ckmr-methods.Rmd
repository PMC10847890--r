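---
title: "Close-kin mark-recapture with closekin: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Close-kin mark-recapture with closekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Close-kin mark-recapture (CKMR) estimates adult abundance and survival from
the frequency of kin pairs among sampled animals: every sampled offspring
"marks" its parents' genotypes, and finding its half-sibling or parent in a
later sample is a "recapture". `closekin` implements the half-sibling (HS)
and parent-offspring (PO) machinery for a long-lived, intermittently
breeding animal — the motivating system is a coastal shark with maturity at
12 years, longevity around 50, litters of 2–9 pups carried by 1–3 sires,
and females that pup every one to three years — together with an
individual-based simulator used to probe when simple CKMR models break.

## Kinship probability models

All models act on a *grouped pairwise comparison matrix*: every eligible
pair of samples contributes one Bernoulli trial to a cell keyed by
relationship (HS or PO), parental side, the younger member's birth year
$y_j$, and either the birth-year gap $\delta = y_j - y_i$ (HS) or the
candidate parent's capture year $c_i$ (PO). A cell with $R$ trials and $Y$
kin pairs contributes a binomial term to the log-likelihood.

The per-pair probabilities, with $\phi$ adult annual survival,
$N^F_{t_0}, N^M_{t_0}$ mature female/male abundance at the reference year
$t_0$, $\lambda$ the annual finite growth rate, $\psi$ the proportion of
females breeding every $a$ years (the rest breed annually):

* **Base case** (stable population): maternal HS pairs occur with
  probability $\phi^{\delta} / N^F_{y_j}$ — the older sibling's mother must
  survive the gap and be the one of the $N^F$ equally likely mothers that
  bore the younger. Maternal PO pairs have probability
  $\phi^{\,y_j - c_i} / N^F_{y_j}$ when the candidate mother was captured
  before the offspring's birth (she must survive to it), and $1/N^F_{y_j}$
  otherwise (she is known alive then).
* **Growth-adapted**: abundance follows
  $N(t) = N_{t_0}\lambda^{\,t - t_0}$, so every denominator becomes
  $N_{t_0}\lambda^{\,y_j - t_0}$.
* **Multiennial**: with a fraction $\psi$ of females on an $a$-year cycle,
  the effective number of yearly breeders is
  $\tilde N = \frac{a + \psi - a\psi}{a} N^F$. Gaps divisible by $a$ can
  arise from any female; non-divisible gaps only from annual breeders,
  giving the two-branch probability
  $\frac{a\,\phi^{\delta}}{(a + \psi - a\psi)\,N^F_{t_0}\lambda^{y_j-t_0}}$
  (on cycle) and the same value times $(1-\psi)$ (off cycle). The
  frequency-weighted mean over the $a$ gap residues recovers the
  growth-adapted probability — a conservation identity the test suite
  checks for arbitrary $(a, \psi, \phi, \lambda)$, and the package's
  internal consistency check standing in for the unavailable derivation of
  the effective-breeder form.

Males are assumed to breed annually regardless of the female schedule, so
paternal HS and PO probabilities always use the growth-adapted form with
$N^M$. Survival and growth are shared across sexes. `a` is a fixed model
input, never estimated; $\psi$ is estimated only under the multiennial
variant. Under a truly annual population $\psi$ is not identifiable (any
value fits when no off-cycle deficit exists); this is documented behaviour,
not an error, and other parameters remain estimable.

## The individual-based simulator

`run_simulation()` is a two-sex, age-structured, stochastic birth-pulse
model with full pedigree retention. Each year runs breeding → sampling
hook → mortality → age increment. Eligible females draw a number of
distinct sires (uniform on {1, 2, 3} by default, clamped to the males
available) and 2–3 pups per sire (so yearly litters are always 2–9);
males face no mate limit. Survival is knife-edged into three stages:
young-of-year (age 0), juvenile (1–11), adult (12–50); individuals beyond
the maximum age die deterministically.

Defaults are chosen once as a realistic stand-in for the motivating
population, as the exact stage survivals behind the published study are
not in its main text: juvenile and adult survival 0.90 per year, sex ratio
0.5, founder census 10,270 at the stable age distribution (calibrated so
that four annual draws of 1.5% of the census yield about 616 samples), and
young-of-year survival **solved** so that the female Leslie matrix built
from the configuration has dominant eigenvalue 1 (`solve_stable_yoy_survival()`,
bisection to 1e-8). The founder census is the post-breeding standing
population of year 0, so the transition into year 1 begins with year-0
mortality; this keeps the expected post-breeding census constant under the
stationary configuration.

Population-trend regimes adjust juvenile and adult *mortality* additively:
∓0.01 from the first year produces realized growth of ±1% per year
(verified against the Leslie eigenvalue: 0.9894 and 1.0106); the severe
decline runs stable for 80 years and then draws Uniform(0.04, 0.07) added
mortality for the ten transitions spanning the final ten-year census
window. Under the 0.90-survival stand-ins this regime's own Leslie
transient predicts a realized ten-year decline of about 6%/year, and the
test asserts the simulator against that prediction rather than any
externally printed rate — a different baseline age structure would shift
the realized value.

Breeding periodicity: each female is assigned at birth whether she is a
multiennial breeder (probability `fraction_multiennial`) and a cycle
offset uniform over the `a` residue classes, so half of biennial females
first breed the year they mature and half the next year (thirds for
triennial). An off-cycle female breeds anyway with probability
`p_offcycle`, an on-cycle female fails with probability `p_fail` (both
0.10 in the off-cycle scenario, matching a "10% breed off-cycle and 10%
fail" configuration); off-cycle breeding does not reset a female's phase.

What the generator deliberately does **not** emulate: age-varying
fecundity, density dependence, spatial structure, gear selectivity within
an age window, capture heterogeneity, and genotyping error — kin labels
are taken from the pedigree truth (or supplied externally), so passing
tests demonstrate correctness of the estimation machinery under known
kinship, not robustness to kinship-inference error in real data.

## Sampling and aging error

Sampling is annual, non-lethal, and age-selective: `target_yoy` (age 0),
`sample_juveniles` (ages 1–11), `sample_all_ages` (0–50). The yearly draw
is `round(intensity × total living census)` taken uniformly without
replacement from the window — the intensity refers to the *total* census
even for narrow windows, which is why all three schemes yield the same
sample volume. Draw counts round half-away-from-zero; age assignment
rounds half-to-even (both documented constants).

Length-based aging error follows a von Bertalanffy curve
($L_\infty = 317.65$ cm, $K = 0.057$/yr, $t_0 = -2.302$ yr): each sample
gets a length drawn from a normal around its true length-at-age — fixed
3.0 cm standard deviation through age 2 (a stand-in for an unpublished
empirical age-length key; configurable), a CV of 5/10/20% from age 3 — and
the age is then re-assigned by inverting the curve and rounding. Negative
length draws are redrawn rather than truncated to keep small-age means
unbiased. Because the curve flattens, misassignment grows with age, while
young-of-year are almost never placed in the wrong cohort.

## Comparison matrix construction

Independence filters precede pair enumeration: one capture instance per
individual and one representative per full-sibling group (earliest
capture, ties to the lowest id — a deterministic rule, since the source
procedure does not specify one). The full-sibling collapse spans cohorts
by default; `collapse_full_sibs = FALSE` supports the exhaustively sampled
small-nursery variant that retains littermates. Within-cohort comparisons
are always removed ($\delta \ge 1$): they estimate a different quantity
than cross-cohort comparisons.

The HS pool is restricted to samples *immature at capture*; adults enter
only as potential parents on the PO side, where maturity is evaluated in
the offspring's birth year (assigned age at $y_j$ of at least 12). This
restriction is what pins the reference year: $t_0$ defaults to the birth
year of the second-oldest cohort in the dataset — 88 for young-of-year
sampling in years 87–90, and 77 for both the juvenile and all-ages
schemes. Ages entering the grouping are always *assigned* ages; the truth
is used only to label positives, mimicking error-free genetic kinship with
error-prone ages. Avuncular and grandparent-grandchild pairs, genetically
indistinguishable from half siblings, can optionally be counted as
HS false positives (`include_avuncular_as_hsp`) to probe contamination.

A pair in which both members pass the PO maturity filter is evaluated in
both orientations. Every builder is validated against an independent
O(n²) per-pair enumerator in the test suite.

## Bayesian estimation

Priors follow the study's table: hierarchical Normal(μ, σ) on each
abundance with Uniform(1, 10000) hyperpriors (near-flat over the plausible
range, implemented as printed), Uniform(0.5, 0.95) survival (0.99 ceiling
for the small-population profile), Uniform(0.95, 1.05) growth
(0.80–1.20 for severe decline, 0.70–1.30 for small populations), and
Uniform(0, 1) on ψ. Any parameter can be fixed by a zero-width bound.

The sampler is an adaptive random-walk Metropolis: bounded parameters are
logit-transformed and abundances log-transformed (with Jacobians, so the
stated priors are targeted exactly); the proposal covariance adapts
(Haario-style, scale $2.38^2/d$) during burn-in only, so retained draws
come from a fixed Markov kernel. Because the (μ, σ) hyper-block is weakly
identified and would dominate the autocorrelation time, it also receives
an independence Metropolis refresh from its prior each iteration — the
acceptance ratio then involves only the abundance-prior density, so no
likelihood re-evaluation is needed. Default protocol: two chains, 50,000
burn-in, 40,000 post-burn-in iterations thinned by 20 (2,000 retained per
chain), per-parameter split-chain Gelman–Rubin statistic with a 1.01
convergence gate; non-converging replicates are flagged and excluded from
scenario aggregates. Chains are seeded `seed + chain`, making every fit
bit-reproducible. Starting values are a method-of-moments abundance at
mid-prior survival, jittered per chain.

Cells whose probability is numerically zero contribute nothing when
$Y = 0$ and $-\infty$ otherwise; proposals implying a cell probability
above 1 are rejected. Abundance draws are bounded to the prior support
(1, 10000). A dataset with no positives at all drives the posterior to the
prior's upper range and is flagged "abundance unbounded by data".

Derived quantities: $N_s(t) = N_s(t_0)\lambda^{t-t_0}$ per retained draw
for any target year, effective female breeders via the cycle conversion
under the multiennial variant, 95% highest-posterior-density intervals
(narrowest mass-covering interval), and within-fit Pearson correlations of
pooled draws. Relative bias is (posterior median − truth)/truth.

## Scenario grid, windows, downsampling

`run_scenario()` reproduces the study design rows: validation (1.1),
avuncular contamination (1.2), ±1%, severe-decline and stable trends with
naive-vs-growth-adapted fits (2.1–2.4), biennial / biennial-with-off-cycle
/ triennial / annual breeding with naive, off-cycle-filtered-naive and
multiennial-adapted fits (3.1–3.4), and aging error at 5/10/20% CV
(4.1–4.3). The off-cycle-filtered naive fit estimates *effective breeders*;
its total-female estimate is recovered by multiplying by `a`, and mixing
PO cells into that model is expected to bias it — the two kinship
probabilities refer to different quantities. Truths are taken from the
simulation at the sampling census point: mature counts by sex in the
estimation year, the realized ten-year census ratio for $\lambda$, and,
for ψ, the realized fraction of sampled maternal half-sibling pairs whose
mother is multiennial.

`sliding_window_fit()` restricts samples to a 3-year, 5-year or full
window before the estimation year, re-anchors $t_0$ inside the window,
fits the multiennial model (maternal side only by default, matching the
use case where paternal assignment is unreliable) and derives abundance in
the estimation year; under biennial breeding a 3-year window contains a
single informative gap and is flagged low-information.
`downsample_fit()` refits on random per-year retentions (30%, 50
iterations by default) and averages medians and interval bounds.
`small_nursery_profile()` gives the heavily sampled small-population
configuration (about fifty adult females, biennial with 10% off-cycle
breeding and failure, 90% of young-of-year sampled annually); its census
is derived from the stable age distribution rather than fixed, since the
source's exact small-population structure is unspecified.

## Problem sizes and numerical notes

Replicate counts in the shipped tests and acceptance script are the
package's own scaled-down choices: 100 replicates for sampling-volume and
kin-yield summaries, 25 for parameter-recovery checks, around ten
converged fits per trend scenario for correlation summaries, with MCMC
runs of 6,000-30,000 burn-in and post-burn-in iterations depending on the
dataset's cohort richness — enough that Monte-Carlo error is small
against the tolerances asserted. Full 500-replicate grids are reachable by raising
`replicates` and using the default chain protocol.

Known limitations: the finite maximum age means an "immortal adult"
configuration still has a stationary solution (the infeasibility the
solver reports is the shrinking-population direction); abundance estimates
for very small populations carry the usual small-sample positive bias of
inverse-probability estimators; $\lambda$ is a single exponential rate, so
trend shifts inside the modeled window produce averaged estimates — the
windowed fits exist precisely to localize that averaging; and the
reported survival conflates true survival with detection when recaptures
are non-negligible, a configuration outside the intended sparse-sampling
regime.
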
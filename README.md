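# closekin

Close-kin mark-recapture (CKMR) estimates the abundance and survival of
*adults* from the frequency of kin pairs found among sampled animals —
each sampled offspring "marks" its parents' genotypes, and every
half-sibling or parent-offspring pair detected later is a recapture of
that mark. The approach is built for populations where conventional
mark-recapture fails: low-density, highly mobile, hard-to-age species
(the motivating case is a long-lived coastal shark sampled mostly as
juveniles in a nursery), where adults may never be observed at all.

`closekin` is a toolkit for designing and stress-testing such estimators.
It provides:

* a stochastic **individual-based population simulator** with full
  pedigree tracking: overlapping generations to age 50, knife-edged
  maturity at 12, litters of 2–9 pups via 1–3 sires, stage-structured
  survival with young-of-year survival solved for stationarity from the
  Leslie matrix, growth/decline regimes, and annual, biennial or triennial
  female breeding with stochastic off-cycle breeding;
* **age-selective sampling** schemes (young-of-year only, juveniles, all
  ages) with length-based aging error under a von Bertalanffy growth
  curve (forward length simulation, reverse-curve age re-assignment);
* construction of the grouped **pairwise comparison matrix** (half-sibling
  and parent-offspring cells with full-sibling and self-recapture
  deduplication, within-cohort removal, off-cycle filtering);
* closed-form **kinship probability models** — base case, exponential
  population growth, and intermittent (multiennial) breeding — combined in
  a grouped-binomial pseudo-likelihood;
* **Bayesian estimation** by adaptive random-walk Metropolis with the
  study's priors and chain protocol, split-chain Gelman–Rubin gating,
  highest-posterior-density intervals, derived abundance trajectories,
  effective-breeder conversion, and posterior cross-correlations;
* **scenario runners** for the full simulation grid, plus sliding-window
  and downsampling analyses for heavily sampled small populations, and a
  kin-label input dialect so externally inferred (genetic) kinship can be
  analyzed without a pedigree.

The central quantities, for a pair grouped by the younger member's birth
year `y_j` and birth-year gap `δ` (survival `φ`, growth rate `λ`,
abundance `N` at reference year `t0`, fraction `ψ` of females breeding
every `a` years):

```
P(MHSP) = φ^δ / (N♀(t0) λ^(y_j − t0))                          growth model
P(MHSP) = a φ^δ [1−ψ if δ ∤ a] / ((a+ψ−aψ) N♀(t0) λ^(y_j−t0))  multiennial model
Ñ♀ = ((a+ψ−aψ)/a) N♀                                           effective breeders
```

## A worked example

Simulate a stable population, sample all age classes at 1.5% for four
years, build the comparison matrices, and fit the growth-adapted model
with both half-sibling and parent-offspring cells:

```r
library(closekin)

lh  <- life_history()                      # survival_yoy solved -> 0.1296
sim <- run_simulation(lh, NULL, n_years = 90, total_census = 10270,
                      seed = 43, snapshot_years = 87:90)

s  <- draw_samples(sim, sampling_scheme("sample_all_ages", 0.015, 87:90),
                   seed = 7)               # 617 samples
d  <- dedupe_samples(s)                    # 592 after collapsing litters
ds <- combine_comparisons(build_hs_matrix(d), build_po_matrix(d))
#> t0 = 77; 80 maternal and 91 paternal half-sibling pairs, 33 PO pairs

fit <- fit_ckmr(ds, model_spec("growth", uses_po = TRUE),
                mcmc = mcmc_config(burn_in = 10000, n_iter = 10000,
                                   thin = 10, seed = 3))
print(fit)
#> <ckmr_fit> variant = growth + PO; 2 chain(s); converged: TRUE
#>  parameter    median hpdi_low hpdi_high   rhat
#>        N_f 1086.7671 584.4105 1663.5399 0.9993
#>        N_m 1088.5260 609.7855 1681.3587 1.0004
#>         mu 1155.3627   4.1217 4170.8677 1.0011
#>      sigma  466.5960  15.0086 6309.4185 1.0044
#>        phi    0.9239   0.8853    0.9499 1.0011
#>        lam    0.9898   0.9509    1.0343 0.9994
```

This replicate held 888 mature females and 926 mature males at the final
census with adult survival 0.90 — both truths well inside the 95%
intervals; single-replicate medians scatter around the truth by roughly
±20% at this sampling intensity and are unbiased on average (the
recovery tests quantify this). `derive_abundance(fit, 80:90)` projects the
abundance trajectory through the sampled decade, and
`cross_correlation(fit)` exposes the strong negative coupling between
abundance and growth rate that makes trend estimation the fragile part of
CKMR.

A command-line front end over the same functions ships in
`inst/scripts/ckmr` (subcommands `simulate`, `sample`, `compare`, `fit`,
`scenario`, `windows`).

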
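---
title: "Methods: fluctuation analysis, strand assignment and MMR efficiency"
author: "mutspectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluctuation analysis, strand assignment and MMR efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutspectra)
```

This vignette documents the statistical and mechanistic choices behind the
package: the estimators, the conventions where the field's practice leaves
room, the synthetic-data model, and what the tests do and do not establish
about real data.

## The measurement being modelled

A forward-mutation reporter (an arginine-permease gene in our running
examples) sits near a replication origin. Parallel cultures grown from
small inocula are plated on selective medium; the distribution of
resistant-colony counts encodes the mutation rate (fluctuation analysis).
Resistant isolates are sequenced to give a mutation spectrum: one row per
observed change, in 1-based coding-strand coordinates. Comparing a strain
with a defined dNTP pool imbalance (dCTP ~26-fold, dTTP ~14-fold over wild
type, dATP ~2-fold, dGTP normal) in the two orientations of the reporter
separates leading- from lagging-strand errors; comparing repair-proficient
and *msh2*Δ derivatives measures mismatch-repair efficiency.

## Rate estimation

`estimate_m_median()` solves the Lea–Coulson median equation
\(\tilde r/m - \ln m = 1.24\). The residual is strictly decreasing in
\(m\), so the root is unique; we bracket it and solve with `uniroot()` to a
tolerance of 1e-12 (the defining residual at the returned root is below
1e-9). `estimate_m_p0()` is the closed form \(m = -\ln p_0\). The rate is
\(\mu = m/N_t\) with \(N_t\) the final population; a plating fraction below
1 scales \(N_t\), not the counts. The alternative divisor \(2N_t\) is
exposed as `per_division = TRUE`, default off. Rates are carried on the
\(\times 10^{-7}\) per locus per generation scale everywhere, matching how
such rates are printed.

Conventions worth making explicit:

* **Median of an even number of cultures** — the lower of the two central
  order statistics, so the median is always an observed count and the
  estimator is well defined on integers.
* **Confidence intervals.** The published style of assay reports 95% CIs
  without a stated method, and raw culture counts are typically not
  deposited, so the package uses a construction that is reproducible
  without distributional assumptions: exact binomial order-statistic
  bounds on the population median count, pushed through the strictly
  monotone median estimator (for the p₀ method, Clopper–Pearson limits on
  \(p_0\) through \(-\ln\)). A consequence of discrete counts is that with
  very many cultures the interval can collapse onto the point estimate.
  With fewer than 5 cultures the order statistics degenerate and the
  interval widens to the sample range, with a warning. On simulated
  experiments (500 replicates, \(m = 2\), 30 cultures) empirical coverage
  of the 95% interval is ~95%; the test suite asserts ≥ 90%.

## Spectrum conventions

* **Isolate denominator.** Class and site rates are
  (events / isolates sequenced) × overall rate. Isolates occasionally
  carry two mutations, so total events can exceed isolates; the bundled
  per-strain summary reproduces the printed class rates (0.5, 33, 37 on
  the \(\times 10^{-7}\) scale) only with the isolate denominator, which
  fixes the convention.
* **Run pooling.** A single-base indel inside a homopolymer run is
  physically a slippage event anywhere in the run, so all indels of the
  same sign and base in one run are a single site keyed by the run span
  (`757-760:-G` style). Substitutions are never pooled. Insertions and
  deletions in the same run are distinct sites.
* **One-event bound.** A site or class with zero observed events enters
  ratios as `overall_rate / n_isolates` — the rate one event would imply —
  and every table carries the bound as an explicit flag column. Using the
  bound in the wild-type denominator of the hotspot fold is conservative
  (the true fold can only be larger).
* **Hotspots.** Threshold ≥ 10-fold over wild type, inclusive at exactly
  10.
* **Orientation comparison** reports the fold as larger/smaller rate
  (≥ 1) with the direction, and downgrades it to a one-sided `ge`/`le`
  statement when the smaller/larger side is a bound.

## Strand assignment

`template_roles()` derives which physical strand templates leading-strand
synthesis from the origin side and the gene orientation: a fork entering at
the coding strand's 5′ end reads the non-coding strand 3′→5′ in its
direction of travel, making it the leading-strand template; reversing the
gene (or an origin on the 3′ side) swaps the roles. This is a derivation,
not a lookup table, so flipping orientation is an involution — a property
the tests assert for every substitution type.

For a substitution X→Y, the two candidate misinsertions are
complement(Y) opposite template X (coding strand as template) and Y
opposite complement(X) (non-coding). Candidates survive when the
misinserted dNTP is in the excess set \(E\); a unique survivor yields the
call. Because complementation maps pyrimidines to purines, a strictly
pyrimidine \(E\) assigns all 12 substitution types uniquely — verified by
enumeration against an independent mismatch-then-resolution oracle.

The excess set is derived from the pool table as fold-change ≥ 5 (default
threshold). Five cleanly separates the strongly elevated pyrimidines
(26×, 14×) from the mildly elevated dATP (~2×) and leaves room on both
sides, and it is configurable rather than hard-coded.

Run indels use the next-incorporated-nucleotide rule: after copying the
run, each polymerase's next template base is the run's 5′ flank on its own
template strand, and the dNTP complementary to it stabilises the slippage
intermediate. Strands whose stabilising dNTP is in \(E\) qualify; zero or
two qualifiers give `unassigned`. Mismatch-extension context (purine tracts
downstream) is deliberately *not* used as a tie-breaker: it is described
qualitatively in the mechanistic literature, never as a decision rule, so
the package records it in the rationale text only. Complex events are
always unassigned, and `unassigned` is a result, never an error.

## MMR correction factors

`CF = rate(msh2Δ)/rate(MMR⁺)` on matching scopes, with the isolate
denominator on both sides. Bounds propagate: a zero-event MMR⁺ side makes
the CF a lower bound, a zero-event *msh2*Δ side an upper bound, both sides
zero is indeterminate and reported without a number (tables must not
invent values). Ratios of CFs across backgrounds carry the weaker of the
two flags. The class-level indel CF computed from the bundled strain
summary is ≈ 33.7; rounded inputs make the last digit of such ratios
sensitive, which is why the package always reports the recomputed value
with its inputs rather than a remembered constant.

Double-mutant hotspots are classified by single-mutant presence:
hot only in the MMR-null single → `pool_driven` (a repair-sensitive site
further enhanced by the imbalance), hot only in the pool-imbalance single →
`mmr_driven`, hot in both → `synergistic`; sites not hot in the double
mutant are excluded.

## The synthetic-data generator

`simulate_fluctuation()` implements the canonical Luria–Delbrück
assumptions: deterministic doubling (no death, no differential fitness),
mutation events per generation Poisson with mean (cells dividing) ×
(rate per division), and a clone of \(2^{G-g}\) resistant cells for a
mutation at generation \(g\) of \(G\). The initial population is
back-computed so growth is exactly \(G\) doublings. This is sufficient for
estimator testing; it does not model phenotypic lag, partial plating
stochasticity beyond binomial thinning, or fitness costs.

`simulate_spectrum()` builds one propensity row per possible error:

* substitutions — per site and template-strand pathway,
  `sub_weight × excess_mult^[misinserted dNTP ∈ E] ×
  extension_mult^(downstream support)`, where downstream support counts how
  many of the next 3 template bases would be copied using an excess dNTP;
* run indels — `exp(indel_slope × L)` per strand, times
  `indel_next_excess_mult` when the stabilising next nucleotide is in
  \(E\), split 80/20 into deletions and insertions.

Defaults (`excess_mult = 50`, `extension_mult = 2`, `indel_slope = 0.9`,
`sub_weight = 0.01`) were chosen once to emulate the assayed conditions: an
indel-dominated spectrum under the pyrimidine excess on a ~2 kb locus, an
exponential run-length dependence with slope ~0.9, and repair retentions
(1/50 substitutions, 1/300 A:T-run indels, 1/10 G:C-run indels) matching
the observed contrast between efficiently and poorly repaired sites. The
repair-deficient dataset samples events from the raw propensities; the
proficient dataset thins each drawn error by its category retention and
keeps drawing until `n_isolates` are retained — including the extra events
given to multi-mutation isolates, which must also be drawn from the
thinned distribution. Both datasets carry overall rates whose ratio equals
the *realised* retention, so correction-factor recovery is a closed test,
not a circular one.

What passing tests show — and do not. The generator encodes exactly the
mechanisms the analysis inverts, so recovery tests validate the
estimators' correctness, identifiability and the bookkeeping, at the
stated problem sizes (10⁴ cultures for estimator accuracy, 10⁴ isolates
for CF recovery, 200–500 replicates for coverage). They cannot detect
model misspecification in real spectra: sequence-context fidelity effects
beyond the stated multipliers, replication timing, damage-derived
mutations, or MMR saturation are all outside the generator.

## Numerical and degenerate-input choices

* Root finding: `uniroot` on a bracketing interval grown geometrically;
  tolerance 1e-12.
* All-zero counts: median method refuses (directing to p₀); p₀ with all
  zeros returns \(m = 0\) with a one-sided interval from the binomial
  lower limit.
* Statistical test tolerances: recovery tests use a 3-sigma band on
  \(\log \mathrm{CF}\) with variance \(1/k_- + 1/k_+\) from the two event
  counts — the naive binomial variance slightly understates the truth
  because of multinomial covariance and the correlated multi-mutation
  extras, so a 2-sigma band would reject valid runs.
* Property checks over generated cases use fixed seeds; estimator/p₀
  agreement is asserted for \(m \in \{1.5, 2, 3\}\) — below \(m \approx
  0.7\) the median count is typically 0 and the median method's
  precondition fails, so the comparison is undefined there.
* Table round-trips are exact: TSV with header, `"."` for empty ref/alt in
  event files, bound flags as separate logical columns.

## Known limitations

* The nonparametric CI is conservative-to-degenerate at extreme culture
  numbers; a bootstrap-over-cultures alternative would interpolate but
  would no longer be assumption-free.
* Full maximum-likelihood fluctuation estimation (and partial-plating
  likelihood corrections) is out of scope; the median and p₀ estimators
  are the ones the assay convention uses.
* Hotspot calling is the ≥ 10-fold rule only — no significance testing or
  multiplicity correction.
* Strand inference names the strand, never the polymerase; polymerase
  identity is interpretation, not measurement.
```{r session, eval = FALSE}
sessionInfo()
```
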
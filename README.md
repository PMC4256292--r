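# mutspectra

Analysis of forward-mutation reporter assays in budding yeast: spontaneous
mutation rates from fluctuation tests, mutation spectra and hotspots,
leading/lagging-strand assignment of replication errors under a dNTP pool
imbalance, and mismatch-repair (MMR) correction efficiency. The package is
aimed at experimentalists working with reporter genes such as *CAN1*, where
loss-of-function mutants are selected (e.g. on canavanine), resistant-colony
counts from parallel cultures encode the mutation rate, and sequencing of
independent resistant isolates yields the mutation spectrum.

## What it computes

**Mutation rate (fluctuation analysis).** For resistant-colony counts
*r₁…r_n* from parallel cultures, the expected number of mutational events
per culture *m* is estimated either by the Lea–Coulson method of the median —
the unique root of

```
r̃/m − ln m = 1.24
```

with *r̃* the median count — or, when most cultures carry no mutants, by the
p₀ method *m = −ln p₀*. The rate per locus per generation is *μ = m / N_t*
with *N_t* the final cells per culture (per-division convention *m/2N_t*
available behind a flag). Confidence limits are nonparametric:
order-statistic bounds on the median count pushed through the (monotone)
median estimator, or Clopper–Pearson limits on p₀.

**Spectra and hotspots.** Events are classified as single-base
substitutions (transition/transversion), single-base indels
(insertion/deletion) or complex events. Class and site rates use the
isolate denominator:

```
rate(class or site) = (events / isolates sequenced) × overall rate
```

Indels inside a homopolymer run are pooled over the run and reported with
the run's coordinate span (e.g. `757-760:-G`). A site is a hotspot when its
rate is ≥ 10-fold the wild-type rate at that site; where the wild type has
no observed event, the one-event upper bound `overall_rate / n_isolates`
serves as a conservative denominator and is flagged, never silently folded
into the number.

**Strand assignment.** Gene orientation plus the origin side determine
which strand templates leading-strand synthesis. A substitution X→Y has two
candidate origins — misinsertion of complement(Y) opposite template X on
the coding strand, or of Y opposite complement(X) on the non-coding strand.
Candidates whose misinserted dNTP is in the excess set of the pool
imbalance survive; a unique survivor gives the strand call. With a strictly
pyrimidine excess (dCTP, dTTP elevated) all 12 substitution types are
uniquely assignable. Run indels are assigned by the next-incorporated
nucleotide that stabilises the slippage intermediate. `unassigned` is a
first-class result.

**MMR efficiency.** The correction factor of a site or class is
`CF = rate(msh2Δ) / rate(MMR⁺)`; zero-event sides turn the CF into an
explicit lower/upper bound, and 0/0 is reported as indeterminate rather
than invented.

**Synthetic data.** A seeded generator produces Luria–Delbrück colony
counts (per-generation Poisson mutation events, deterministic clone
doubling) and paired MMR⁺/msh2Δ spectra from mechanistic site propensities
(excess-dNTP misinsertion, extension support, exponential run-length
slippage, per-category repair retention), so the whole pipeline is testable
end to end without wet-lab inputs.

## Worked example

```r
library(mutspectra)

pools <- dntp_pools()            # the imbalanced-pool mutant, default threshold 5
pools
#> dNTP pools (fold over wt): dATP=2, dCTP=26, dGTP=1, dTTP=14
#> excess set (>= 5x): dCTP, dTTP

# a mutation rate from simulated colony counts (24 cultures, N_t = 1e7)
expt <- simulate_fluctuation(sim_config(seed = 42, true_rate = 4.2e-7,
                                        n_cultures = 24))
estimate_rate(expt)
#> Mutation rate 3.86 x1e-7 per locus per generation (95% CI 2.05-5.45),
#> m=3.86, median method

# a synthetic reporter locus and a simulated spectrum under the imbalance
loc <- fixture_locus(2000, seed = 42)
sim <- simulate_spectrum(loc, pools, sim_config(seed = 42, n_isolates = 500,
                                                true_rate = 57e-7))
sim$mmr_plus
#> SpectrumDataset 'sim': 520 events in 500 isolates; overall rate 2.19 x1e-7;
#> imbalanced pools

strand_summary(assign_strand(sim$mmr_plus, pools))
#>   leading lagging unassigned
#> 1     146     168        206

head(site_rates(sim$mmr_plus)[order(-site_rates(sim$mmr_plus)$count), ], 3)
#>          site start end change             klass count       rate is_bound
#> 20   68-73:-G    68  73     -G single_base_indel    30 0.13153846    FALSE
#> 11   38-43:-C    38  43     -C single_base_indel    24 0.10523077    FALSE
#> 29 115-119:-C   115 119     -C single_base_indel    17 0.07453846    FALSE
```

The simulated rate estimate (3.86 ×10⁻⁷, CI 2.05–5.45) brackets the planted
4.2 ×10⁻⁷; the dominant sites are single-base deletions pooled over G/C
homopolymer runs, reported with their run spans; roughly a third of the
events cannot be assigned to a strand (indels whose flanks feed excess
dNTPs on both strands).

The per-strain summary table of rates and event counts that the worked
analyses are anchored to ships with the package:

```r
strain_summary()
```

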
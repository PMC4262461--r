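# finsoc

Social-structure inference from photo-identification sighting records.

Behavioural ecologists studying individually identifiable animals —
bottlenose dolphins and other cetaceans above all — describe a
population's social organisation from *group sightings*: on each survey
day, groups are encountered and their members photo-identified from
natural markings. Under the gambit of the group (members of a group are
taken to be associating), such records support a now-standard analysis
chain. `finsoc` implements that chain end to end, with a synthetic
fission–fusion society generator so every stage can be validated
against planted ground truth.

## What it computes

* **Half-weight association index (HWI)** for every dyad:
  `HWI = 2N / (N_A + N_B)`, with `N` the joint sightings and `N_A`,
  `N_B` each individual's totals — 0 for pairs never seen together, 1
  for constant companions — after the standard inclusion rules (first
  sighting of the day only; ≥80% identification coverage for groups of
  more than 8; calves excluded; at least 6 sightings per individual).
* **Group-permutation tests** for non-random association: checkerboard
  flips restricted to daily sampling periods (preserving group sizes
  and individual daily totals), sequential chain with burn-in, SD and
  CV of the indices as test statistics, `(r+1)/(n+1)` p-values in both
  tails; plus Mantel tests and dyad-class chi-squares.
* **Weighted network metrics** — strength, clustering coefficient,
  affinity — with group-bootstrap standard errors and chain-permutation
  significance, and **social differentiation** `S` (the CV of the true
  association indices) by beta-binomial maximum likelihood with a
  jackknife SE.
* **Community division**: average-linkage dendrogram on HWI similarity,
  cophenetic correlation (≥0.80 = good match), and the dendrogram cut
  maximising Newman's weighted modularity
  `Q = Σ_c [W_c/W − (G_c/Σg)²]`, in standard and
  gregariousness-controlled forms.
* **Temporal dynamics**: the lagged association rate
  `g(τ) = P(still associated τ days later)` with its null rate, fitted
  by binomial quasi-likelihood to eight exponential-decay models built
  from constant companions (CC), casual acquaintances (CA) and rapid
  disassociation (RD) — e.g. `g(τ) = a2 + a3·exp(−a1·τ)` — ranked by
  QAIC, with delete-one-block jackknife errors.
* **A seeded fission–fusion simulator** (`society_config()`,
  `generate_society()`, `simulate_sightings()`) that plants cliques,
  communities, residency classes and CC/CA/RD dynamics, and calibrates
  itself so the realized lagged association rate matches the
  configured curve.

## A worked example

Simulate a small study-shaped society (33 marked individuals, two
social units, eight 14-day summer seasons) and run the whole pipeline:

```r
library(finsoc)

cfg    <- society_config(seed = 7)   # the defaults are the study shape
report <- run_pipeline(cfg, seed = 7, n_permutations = 1000, n_boot = 200)
report
#> social-structure analysis report
#>   23 individuals retained, 50 groups, 41 sampling days
#> group permutation test: 1000 permutations x 100 flips (burn-in 1000)
#>   SD   observed 0.26453  null mean 0.21891  p(null >= obs) 0.0010  p(null <= obs) 1.0000
#>   CV   observed 1.58939  null mean 1.31853  p(null >= obs) 0.0010  p(null <= obs) 1.0000
#>   MEAN observed 0.16644  null mean 0.16603  p(null >= obs) 0.1748  p(null <= obs) 0.8262
#>   long-term preferred companions (CV, level 0.05): yes
#>   social differentiation S = 1.515 (SE 0.109)
#>   cophenetic correlation 0.965; modularity Q = 0.441 (5 units)
#>   best LAR model: CC+CA
```

Reading the numbers: of the 35 simulated animals, 23 survive the
inclusion filters (the rest are calves or too rarely seen). The
observed SD and CV of the half-weight indices exceed every one of 1,000
within-day permutations (`p(null >= obs) = 0.001`), so the population
has non-random, long-term preferred companions. Social differentiation
well above 0.5 marks a strongly differentiated society. The dendrogram
represents the association matrix faithfully (cophenetic correlation
0.965) and its best modularity cut (Q = 0.441, above the 0.3
usefulness convention) splits the population into units that follow
the planted cliques and communities.

Individual stages are plain functions on the report's objects:

```r
report$dyads
#> dyad classification: threshold 0.3329 (2 x mean 0.1664)
#>   preferred 28, avoided 120, neutral 105 of 253 unordered dyads

report$lar
#> lagged association rate model selection (c_hat = 12.121)
#>      model K   deviance       QAIC      dQAIC
#> 1    CC+CA 2    43.6912    9.60467    0.00000
#> 2      2CA 3    36.3622   11.00000    1.39533
#> 3 RD+CC+CA 3    41.6856   11.43920    1.83454
#> ...
#> best model: CC+CA (a2 = 0.498, a3 = 0.502, a1 = 0.214)
#> approximate casual-acquaintance duration: 4.7 days
```

At this deliberately small survey scale the constant-plus-decay model
wins: about half of a dolphin's associates are constant companions and
the rest casual acquaintances lasting around five days. With denser
calendars (e.g. `society_config(n_seasons = 1, days_per_season = 200)`)
the selected model and parameters converge on the planted CC/CA/RD
composition — that experiment is part of the test suite.

Real data enter through `read_sightings()` (delimited text, ISO dates,
column mapping via `dialect=`), after which the same functions apply;
`run_pipeline(path, outdir = "out")` writes every stage artifact
(filtered table, exclusion report, HWI matrix, edge list, metric
tables, newick dendrogram, community table, LAR curve and model
ranking) plus a JSON summary and a manifest of all seeds and
parameters.

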
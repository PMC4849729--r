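# drugflow

Drugs are technologies: once created, they spread from disease to disease as
new therapeutic applications are tried, largely independently of their
creators' original intent. `drugflow` implements a drug-centric analysis of
this process for anyone studying drug repurposing, portfolio dynamics or the
history of drug development from timestamped study records. Starting from two
simple event tables — one row per (drug, study, date) and one row per
(drug, disease, first-pairing date) — the package provides:

* **Accumulation analysis.** Birth-aligned average cumulative curves of
  studies per drug, `F(t')`, and of adopting diseases per drug, `G(t')`,
  with power-law fits `F(t) = α t^β` by log–log least squares; within-cohort
  quintile assignment and quintile transition ("momentum") matrices; and
  per-drug study rates over age windows.
* **A drug-centric disease taxonomy.** For each pair of diseases, the 2×2
  joint Bernoulli distribution of co-adoption over the drug universe and its
  mutual information `I(D_i; D_j)` (in nats) as a similarity; Ward
  hierarchical clustering of the derived distances with Newick export; and
  per-disease drug-exclusivity reports.
* **A disease-to-disease propagation network.** Diseases are modelled as
  nodes of a communication network that "send" drugs to each other as
  Poisson processes: the time for disease *i* to send a drug to disease *j*
  is exponential with rate λ<sub>ij</sub>, and the mean propagation delay is
  T<sub>ij</sub> = 1/λ<sub>ij</sub>. Rates are estimated from adoption
  times by maximum likelihood with right-censoring at the last observation
  time t<sub>max</sub>:

  L(λ<sub>ij</sub>) ∝ ∏<sub>observed</sub> λ<sub>ij</sub> e^(−λ<sub>ij</sub> Δt) · ∏<sub>censored</sub> e^(−λ<sub>ij</sub> (t<sub>max</sub> − t<sub>i</sub>)),

  which has the closed-form maximizer λ̂ = n<sub>observed</sub> / (Σ Δt +
  Σ (t<sub>max</sub> − t<sub>i</sub>)). A full multi-source variant
  (competing-sources hazard-sum log-likelihood, maximized by gradient-based
  ascent) accounts for every adoption that precedes a disease's own.
  Networks are thresholded at T < 100 years, analyzed with Dijkstra path
  metrics, and pairs of diseases can be compared directionally with
  bootstrap uncertainties and two-tailed t-tests.
* **A seeded cascade simulator.** Drugs are born as a Poisson process,
  seeded in one disease, and propagate over a latent rate matrix with
  exponential delays; study histories follow a time-rescaled Poisson process
  with cumulative intensity α t^β. The simulator returns the ground truth
  (rates, per-drug growth parameters), making every estimator testable for
  parameter recovery.
* **A pipeline runner.** `run_pipeline()` chains simulate → accumulate →
  taxonomy → network over YAML configurations and writes an MD5 manifest;
  identical configuration and seed give byte-identical artifacts.

## Worked example

A reconstructed single-drug study history
(`inst/extdata/posaconazole_synthetic.tsv`, a synthetic table consistent
with the published counts for the antifungal posaconazole: born 1998,
3 studies by age 5, 11 by age 10, 19 through 2010) illustrates the windowed
study-rate computation:

```r
library(drugflow)
path <- system.file("extdata", "posaconazole_synthetic.tsv", package = "drugflow")
studies <- read_study_table(path, observation_window(1990, 2010.999))
rate_in_window(studies, "posaconazole", 0, 5)
#> [1] 0.6
rate_in_window(studies, "posaconazole", 5, 10)
#> [1] 1.6
```

The drug's study rate went from 0.6 to 1.6 studies per year across its first
two 5-year periods — the accelerating profile typical of drugs meeting
clinical success.

End to end on simulated cascades, with the inferred network compared to the
simulator's truth:

```r
cfg <- simulation_config(n_diseases = 5, drugs_per_year = 100,
                         year_span = c(1990, 2010), rng_seed = 42)
sim <- simulate_dataset(cfg)
sim$ground_truth
#> <ground_truth> 5 diseases, 1998 drugs, 5 true edges

est <- infer_network(sim$adoptions, model = "full")
head(est[order(est$T_hat), ], 3)
#>    source target lambda_hat T_hat n_observed n_censored
#> 11    D04    D03     0.4344  2.30        342         18
#> 2     D03    D01     0.3895  2.57        677         66
#> 18    D02    D05     0.3875  2.58        774        118
```

The strongest inferred channel, D04 → D03 with an estimated rate of
0.434/yr (mean delay 2.3 years), corresponds to a true simulated rate of
0.403/yr. Directional timing of that pair:

```r
timing_comparison(sim$adoptions, "D04", "D03", n_boot = 1000, rng_seed = 7)
#> <timing_comparison> D04 vs D03
#>   first adopted by D04: 342 drugs; by D03: 174 drugs (p = 3.13e-14)
#>   delay D04 -> D03: 2.16 +/- 0.11 yr; D03 -> D04: 5.62 +/- 0.33 yr (p = 5.74e-19)
```

Drugs shared by the two diseases are both more often adopted first by D04
and travel D04 → D03 roughly 3.5 years faster than the reverse — D04 is the
"early adopter" of the pair, as built into the simulated rate matrix.

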
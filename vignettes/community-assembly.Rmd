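---
title: "Inferring community assembly processes under heavy-metal stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes under heavy-metal stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfassembly)
```

## The scientific question

Soil microbial communities — here, arbuscular mycorrhizal fungi (AMF)
profiled as OTUs along an urban-to-rural gradient — assemble through a mix
of **deterministic** processes (environmental filtering, e.g. by heavy-metal
stress) and **stochastic** processes (drift, dispersal). This package
implements the standard inferential toolkit for partitioning the two, plus
the habitat generalist/specialist classification that stratifies it, and a
pollution index quantifying the stress axis. Because the field data behind
any particular survey are not required to *test* this machinery, the package
ships a synthetic-data module that generates communities whose assembly
process is known by construction; every statistic can therefore be checked
against ground truth.

## The statistics and their assumptions

### Levins' niche breadth and the generalist/specialist classification

For OTU $i$ with relative use $P_{ij}$ of sample $j$, Levins' breadth is
$B_i = 1 / \sum_j P_{ij}^2$, ranging from 1 (all abundance in one sample) to
the number of samples $n$ (perfectly even use). Breadth alone does not
separate niche structure from sampling artifacts, so observed breadths are
compared to a permutation null: an OTU above the null's 97.5% quantile is a
**generalist**, below the 2.5% quantile a **specialist**, otherwise neutral
(ties are conservative: neutral).

The default null randomizes the count matrix with fixed row *and* column
sums (vegan's `quasiswap_count`), the null used by the established
generalist/specialist permutation classification. A subtlety worth stating
plainly: permuting a *single OTU's* abundances across samples can never be a
null for $B$, because $B$ is a symmetric function of the vector — every
permutation returns the observed value. Any informative null must break the
matrix structure, not the vector order. An alternative null
(`null_model = "across_otu"`) instead reassigns observed abundance vectors
to OTUs, conditioning on the observed set of breadths; it is exposed for
sensitivity analysis.

A second subtlety governs how the classifier behaves on *neutral* data. The
fixed-margin null embodies "random placement given margins". A community
assembled under Sloan's neutral model with low migration is **not** randomly
placed: the stationary Beta distribution for a rare OTU (shape
$Nm\,p_i \ll 1$) is strongly aggregated, and the classifier will — correctly
— flag that aggregation as apparent specialism. Drift mimicking specialism
is a property of the model, not a defect of the test. Consequently, the
package's false-positive harness uses an $m = 1$, moderately even
(lognormal, $\sigma_{\log} = 0.5$) background, where local communities are
pure random draws from the metacommunity and "no differential habitat use"
is true by construction; there the false-label rate sits at the nominal
level (≈5% at $\alpha = 0.05$).

### βMNTD, βNTI and the assembly partition

For samples $j,k$ with relative abundances $f$, the abundance-weighted beta
mean nearest taxon distance is

$$\beta\mathrm{MNTD}(j,k) = \tfrac12\Big[\sum_{i\in j} f_{ij}\,
\min_{i'\in k} d(i,i') + \sum_{i'\in k} f_{i'k}\,\min_{i\in j} d(i',i)\Big]$$

with $d$ the patristic distance on the phylogeny. The null shuffles tip
labels of the distance matrix (taxa-label randomization; implemented as a
row/column permutation of the patristic matrix, which is distributionally
identical to re-traversing a relabeled tree and much faster — the
equivalence is asserted by a brute-force oracle test). βNTI is the z-score
of the observed βMNTD against 999 such randomizations. |βNTI| ≤ 2 is read as
stochastic assembly; βNTI > 2 (phylogenetic overdispersion between samples:
variable selection) or βNTI < −2 (homogeneous selection) as deterministic.
Pairs whose null standard deviation is zero (e.g. a star phylogeny, or two
communities with identical membership, whose βMNTD is invariant under any
relabeling) are flagged degenerate and excluded from the fractions rather
than producing infinite z-scores.

βNTI has power only against *phylogenetically conserved* niches: if
environmental optima were independent of the tree, filtering would reshuffle
tips without changing nearest-taxon structure. The synthetic selection
generator therefore evolves optima by Brownian motion on the simulated
phylogeny.

### Sloan's neutral community model

Under neutral assembly with migration, an OTU with metacommunity relative
abundance $p$ has local relative abundance following
$\mathrm{Beta}(Nm\,p,\ Nm(1-p))$ at stationarity, so its expected occurrence
frequency across samples is the upper tail
$F(p) = 1 - I_{\bar d}(Nm\,p,\ Nm(1-p))$, with $I$ the regularized
incomplete beta function and $\bar d$ the detection limit as a relative
abundance. The package fits the single free parameter $Nm$ by least squares
on the (p, frequency) cloud — a bounded scalar search on $\log Nm$ over
$[\log 0.1, \log 10^6]$ with 5 multistart subintervals and tolerance
$10^{-8}$; $N$ is the mean read depth and $m = Nm/N$. $R^2 = 1 -
\mathrm{SSE}/\mathrm{SST}$ is reported as computed (it can be negative and
is never clamped). 95% bands are Wilson score intervals around the fitted
curve at $n$ = number of samples (Wilson rather than Wald because observed
frequencies sit at 0/1 routinely); OTUs above/below the band are
over-/under-represented relative to neutrality, band edges count as neutral.
Because the bands do not propagate the uncertainty in $p$ or in the fitted
$Nm$, their empirical coverage under matched neutral simulations runs a few
points below nominal (≈85–90% at 95%); tests assert the 85% floor.

### Pollution indexing and the correlation layer

Single-factor indices $P_i = C_i/S_i$ (measured over background
concentration) combine into the Nemerow composite index
$P_n = \sqrt{(\overline{P}^2 + P_{\max}^2)/2}$, which always lies between
the mean and the maximum; $P_n > 1$ (strictly) flags contamination.
Background values are a required input — they are region-specific reference
concentrations and are never hard-coded. The layer linking assembly to
pollution regresses βNTI (pairwise) on the pairwise mean of $P_n$ by OLS
(the absolute difference is available via `pairing`), correlates βNTI with
each metal by Spearman rank correlation (t approximation, average ranks for
ties), and tests each metal's Euclidean distance matrix against Bray–Curtis
community dissimilarity with a one-tailed Mantel permutation test (+1
correction, so p is never exactly 0). No multiple-testing correction is
applied in the reports by default, matching the conventions of the survey
literature this toolkit serves; `p.adjust` can be applied downstream.

## What the synthetic generator emulates — and what it does not

`simulate_study()` produces a 60-sample, 250-OTU survey: distances uniform
on 0–40 km, habitat categories by distance quartile, five metals at
background × (1 + gradient + lognormal noise) declining away from the urban
center, a Yule phylogeny, Sloan-neutral sampling (N = 1000 reads, m = 0.05)
weighted by Gaussian niches (σ = 0.1 on the unit gradient) with
Brownian-conserved optima, and 15 planted (near-uniform) generalists plus 10
planted single-sample specialists — roughly the scarce-generalist /
abundant-specialist prevalence these surveys report. Defaults were chosen
once, on ecological grounds, and the same conditions drive the tests and the
acceptance script.

Study-condition choices made where the design was genuinely open:

* **Neutral draws come from the stationary Beta**, not from birth–death
  dynamics: this matches exactly the model the NCM fit assumes, making
  parameter recovery a clean test. Real time-series autocorrelation is out
  of scope.
* **Metacommunity abundances** default to a log-series sample (x = 0.995),
  the long-tailed shape typical of AMF OTU tables; a lognormal option
  exists.
* **Strong-selection conditions** (used to verify that βNTI detects
  determinism): 20 samples across 5 contrasting habitat patches, 250 OTUs,
  N = 2000, m = 0.5, effective niche width 0.07. Nearest-taxon metrics need
  a rich taxon pool and multi-patch environmental contrast to resolve
  selection; with few taxa or a short gradient the βNTI signal of even
  strong filtering is weak — a known property of the metric, reproduced by
  the generator.
* **Brownian trait evolution** is mapped affinely onto the gradient range,
  preserving the phylogenetic correlation structure that powers βNTI.

What passing tests on these simulations do *not* show: robustness to
sequencing-depth variation and compositional artifacts, chimeras/taxonomy
errors, spatial autocorrelation of sites, or real AMF trait ecology. The
generator's phylogeny is also not an ITS gene tree; with real data the user
supplies whatever tree their marker supports, and the βNTI interpretation
inherits that tree's quality.

## Numerical and interface choices

* OTU tables are plain base matrices (samples × rows ordered, dense —
  hundreds of OTUs never justify sparse storage); trees are `ape::phylo`;
  orientation of input TSVs is stated by the caller, never auto-detected
  (silent transposition is the classic OTU-table bug). All-zero rows/columns
  are dropped at ingest with a warning.
* One global seed drives every stage through `derive_seed(stage, seed)`
  sub-seeds, so stage reordering never changes results and reruns are
  byte-identical.
* Strict inequalities throughout the classifications (breadth bounds, band
  edges, $P_n > 1$, |βNTI| > 2): ties resolve to the conservative category.
* Degenerate cases are flagged, never poisoned: βNTI `NA` with a
  `degenerate` flag; constant variables in Spearman batches return `NA`
  rather than aborting; constant regression predictors error with a clear
  message.
* Problem sizes in the shipped tests and acceptance script (60 × 250–300
  study tables, 999-permutation nulls, 199–999 βNTI randomizations) were
  chosen as the smallest sizes at which the statistical properties under
  test are stable.

## Known limitations

* The stochastic fraction is not decomposed into dispersal limitation /
  homogenizing dispersal / drift (no Raup–Crick layer).
* NMDS ordination is delegated to vegan (`metaMDS`) by the user; the package
  only emits the Bray–Curtis matrix it would consume.
* The βNTI ~ Pn regression treats sample pairs as independent observations,
  as is conventional for this analysis; pairs sharing a sample are in fact
  dependent, so its p-value is optimistic (the Mantel test is the
  permutation-honest alternative).
* The niche classifier's behavior on low-migration neutral data (above) is
  reported as measured; users comparing generalist/specialist counts across
  studies should match sequencing depths and consider the across-OTU null as
  a sensitivity check.
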
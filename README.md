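# amfassembly

Community-assembly analysis for soil microbial OTU tables along pollution
gradients — built for surveys of arbuscular mycorrhizal fungi (AMF) in
urban green-space soils under heavy-metal stress, and for anyone asking the
same question of a samples × OTUs count matrix: **how much of this
community's structure is deterministic selection, and how much is
stochastic drift and dispersal?**

The package implements, with tests against simulated ground truth:

* **Levins' niche breadth** $B = 1/\sum_j P_j^2$ per OTU, with a
  fixed-margin permutation null (1,000 `quasiswap_count` matrices, two-sided
  95% bounds) classifying OTUs as habitat *generalists*, *specialists* or
  neutral — `classify_otus()`.
* **βMNTD / βNTI**: abundance-weighted beta mean nearest taxon distance
  between every sample pair, standardized against a tip-shuffling null;
  |βNTI| ≤ 2 ⇒ stochastic, βNTI > 2 or < −2 ⇒ deterministic assembly —
  `beta_nti()`, `assembly_fractions()`.
* **Sloan's neutral community model**: least-squares fit of
  $F(p) = 1 - I_{\bar d}(Nm\,p,\ Nm(1-p))$ to the occurrence-frequency /
  abundance cloud, reporting the migration rate $m$, $R^2$, Wilson 95%
  bands and the fraction of OTUs consistent with neutrality — `fit_ncm()`.
* **Nemerow composite pollution index**
  $P_n = \sqrt{(\overline{P}^2 + P_{\max}^2)/2}$ over single-factor indices
  $P_i = C_i/S_i$, with $P_n > 1$ flagging contamination —
  `pollution_indices()`.
* The **correlation layer**: Shannon/richness, Bray–Curtis, Mantel tests,
  Spearman βNTI–metal correlations, OLS of βNTI on $P_n$, and shared/unique
  OTU partitions across habitat categories.
* A **synthetic-data module** (`simulate_study()` and friends) generating
  OTU tables, Yule phylogenies and metadata with known assembly process
  (Sloan-neutral, optionally filtered by Gaussian niches with
  Brownian-conserved optima) and known pollution structure, so every stage
  is verifiable without sequencing data.

`run_pipeline()` orchestrates the whole analysis (niche classification →
group-wise βNTI + NCM for all/generalist/specialist communities → pollution,
diversity, Mantel, regression, Venn) under one seed, writing TSV/JSON
artifacts and a run manifest. The numbered scripts under `analysis/` walk
the same pipeline as a narrative, stage by stage.

## Worked example

```r
library(amfassembly)

study <- simulate_study(seed = 20260919)   # 60 samples x 250 OTUs
manifest <- run_pipeline(study$table, study$tree, study$metadata,
                         study$backgrounds, out_dir = "results/pipeline",
                         seed = 20260919, n_perm_niche = 999, n_null_bnti = 999)
```

Running the same analysis through the staged scripts prints, for this seed:

```
Nemerow Pn: mean 2.13, range 1.04-3.35; 60/60 samples polluted (Pn > 1)
Spearman rho(distance, Pn) = -0.88 -> pollution decreases with distance
15 generalists, 123 specialists, 81 neutral of 219 OTUs
planted generalists recovered: 15/15
planted specialists recovered: 5/10
all        NCM: m = 0.025, R2 = 31.6%, neutral OTUs = 67.1% (n = 219)
all        betaNTI: deterministic 36.8% / stochastic 63.2% of 1770 pairs
generalist NCM: m = 0.987, R2 = 0.1%, neutral OTUs = 20.0% (n = 15)
generalist betaNTI: deterministic 0.0% / stochastic 100.0% of 174 pairs
specialist NCM: m = 0.009, R2 = 58.1%, neutral OTUs = 66.1% (n = 124)
specialist betaNTI: deterministic 43.4% / stochastic 56.6% of 1770 pairs
all        betaNTI ~ Pn: slope -0.679, R2 = 0.021, p = 1.28e-09 *** (n = 1770)
```

(Planted specialists that overwrote very rare OTUs keep their tiny read
totals, and a handful of reads confined to one site is statistically
indistinguishable from a rare neutral taxon — half of them are therefore
recovered here; specialists planted with substantial abundance are recovered
reliably, as the test suite shows.)

Reading: the metal gradient peaks at the urban center (ρ < 0 with
distance); every site exceeds the contamination threshold. Generalist taxa
assemble stochastically (no pair beyond |βNTI| = 2) with a high fitted
migration rate, while the whole community and especially the specialists
show substantial deterministic selection and far lower migration — the
qualitative pattern expected when environmental filtering along a stress
gradient acts on conserved niches. The βNTI ~ Pn regression links the
deterministic signal to pollution.

To run on real data instead, supply `read_otu_table()` /` read_tree()` /
`read_metadata()` paths plus measured background concentrations to
`run_pipeline()`.

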
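# cycadrisk

Phylogeny-aware extinction-risk analysis for cycads — the gymnosperm group
with the highest proportion of threatened species in the plant kingdom.

Traditional conservation metrics (richness, endemism, threat counts) ignore
the *evolutionary* cost of extinction: on a tree of life whose genera sit on
ancient stem branches but radiated only in the last few million years, the
loss of a handful of distinctive species can erase disproportionate amounts
of accumulated evolutionary history. `cycadrisk` implements, as tested and
reusable R functions plus a scripted analysis workflow, the chain of methods
used to quantify that risk for the complete cycad tree of life, and a
synthetic-data generator that emulates the cycad system so the whole
pipeline runs and is verified without any external downloads.

For phylogeneticists and conservation biogeographers, the package covers:

* **Species scores.** Faith's phylogenetic diversity
  (PD, rooted convention), fair-proportion evolutionary distinctiveness
  (ED, with `sum(ED) = PD` exactly), and EDGE priority scores
  `EDGE = ln(1 + ED) + GE·ln 2` with GE coded LC=0, NT/CD=1, VU=2, EN=3,
  CR=4 and Data Deficient species excluded before scoring.
* **Extinction scenarios.** Remaining PD after losing the top-50% ED
  species, all threatened species, or each IUCN category alone, each tested
  against the null of pruning equally many species at random
  (`p = (1 + #[null ≤ obs]) / (reps + 1)`, one-tailed toward "more loss
  than random"), with an exhaustive-enumeration mode on small trees.
* **Phylogenetic signal of threat.** The Fritz–Purvis D statistic for
  binary traits (D ≈ 1 random, ≈ 0 Brownian, < 0 strongly clumped) with its
  permutation and Brownian-threshold nulls, plus one-way ANOVA of ED across
  threat classes.
* **Diversification.** Maximum-likelihood fits of six models to branching
  times — pure birth, birth–death, density-dependent (DDL, DDX), and two-
  and three-rate Yule with shift-point search — selected by
  `ΔAIC_RC = AIC(best rate-constant) − AIC(best rate-variable)`, and a
  parametric rate comparison flagging clades with unusually fast
  branch-length distributions.
* **Biogeography.** Per-grid-cell SR, PD, weighted/corrected weighted
  endemism, phylogenetic endemism and mean EDGE; hotspot extraction
  (richest 2.5% and 5% of occupied cells); hotspot overlap (Venn regions),
  cumulative area, and protected-area coverage under the
  ≥ 50%-of-cell-protected rule.
* **Synthetic data.** Seeded generators for cycad-shaped trees (11
  monophyletic genera, stems 40–300 Myr, crowns 2–13 Myr), IUCN categories
  matching the global assessment's marginals (78 VU / 70 EN / 67 CR of
  339), phylogenetically
  structured occurrences on an abstract equal-area grid, patchy protection
  masks, and genus-constrained grafting of DNA-less species onto a
  constraint tree.

## Worked example

Simulate a 120-species, 8-genus cycad-like system, rank species by EDGE,
and ask whether losing the most evolutionarily distinct half of the flora
would prune more PD than random extinction:

```r
library(cycadrisk)

cfg     <- sim_config(seed = 7, n_species = 120, n_genera = 8,
                      threat_mode = "clustered")
tree    <- simulate_cycad_like_tree(cfg)
threats <- simulate_threats(tree, cfg)

edge_tab <- edge_scores(fair_proportion_ed(tree), threats)
head(edge_tab, 5)
#>   species category GE     ED  EDGE rank
#> 1  G2_sp1       CR  4 151.62 7.801    1
#> 2  G4_sp2       CR  4  97.79 7.366    2
#> 3  G3_sp5       CR  4  41.22 6.515    3
#> 4  G3_sp3       CR  4  39.81 6.482    4
#> 5  G3_sp4       CR  4  39.81 6.482    5

scenario_test(tree, edge_tab$species[1:60], reps = 100, seed = 1,
              scenario = "top-ED half")
#> Scenario 'top-ED half': 60 species lost, 820 of 1688 PD remaining (51.4% lost)
#>   null mean 1384 (sd 122), p = 0.009901, z = -4.63 [100 reps]

d_statistic(tree, threat_trait(threats), seed = 1)
#> Fritz-Purvis D = 0.405 (d_obs = 32.687)
#>   P_rand = 0 (departure from D = 1), P_BM = 0.008 (departure from D = 0)
#>   1000 permutations, 1000 Brownian simulations, prevalence 0.642
```

Read: the top-priority species is a Critically Endangered member of a small
genus carrying ~152 Myr of unique evolutionary history. Losing the top-ED
half of the flora leaves 820 of 1688 Myr of PD — far below the
random-pruning null mean of 1384 Myr (z = −4.6, p ≈ 0.01): distinctiveness-
blind extinction this severe essentially never happens by chance. Threat
status shows intermediate phylogenetic signal (D = 0.405) under the
clustered generative mode, distinguishable from both the random (D = 1) and
Brownian (D = 0) references.

The numbered scripts under `analysis/` run the full workflow — simulate
(`01`), diversification model selection and clade rates (`02`), threat
signal (`03`), extinction scenarios (`04`), hotspots and protection gaps
(`05`) — writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_diversification.R
Rscript analysis/03_threat_signal.R && Rscript analysis/04_scenarios.R
Rscript analysis/05_hotspots.R
```

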
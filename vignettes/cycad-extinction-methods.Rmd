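---
title: "Methods: phylogeny-aware extinction risk and diversity hotspots for cycads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeny-aware extinction risk and diversity hotspots for cycads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycadrisk)
```

# The question and the study system

Cycads are the most threatened major plant lineage: roughly 70% of the ~339
recognized taxa are assessed as Vulnerable (VU), Endangered (EN) or
Critically Endangered (CR). Their tree of life has an unusual,
coalescent-like shape — each of the 11 genera is monophyletic and sits at
the end of a very long stem branch (tens to hundreds of Myr), while nearly
all species-level divergences happened in the last ~12–2 Myr. On such a
"phylogenetic fuse" topology, losing the wrong species can cut away
disproportionate amounts of accumulated evolutionary history.

`cycadrisk` implements the full analysis chain for asking how extinction
would prune such a tree: species scores (ED, EDGE), scenario-based pruning
against randomization nulls, phylogenetic signal of threat, diversification
model selection on branching times, and grid-based diversity mapping with
hotspot and protected-area gap analysis. The numbered scripts under
`analysis/` run the chain end to end on synthetic data; every computation
lives in package functions so the same code is exercised by the test suite.

# Species scores

**Faith's PD** of a species set is the summed branch length of the minimal
*rooted* spanning subtree: the path up to the tree's original root is always
included (`faith_pd()`, `prune_to()` keeps it as a root edge). This is a
deliberate convention with two consequences that the package relies on:
fair-proportion ED sums exactly to total PD, and "remaining PD" stays well
defined when an entire side of the root is lost.

**Evolutionary distinctiveness** (`fair_proportion_ed()`) uses the fair
proportion scheme: each branch's length is divided equally among its
descendant tips and summed per tip. A species that is the sole survivor of
an ancient lineage (a monotypic genus on a 250-Myr stem) receives that whole
stem; a species inside a 100-tip radiation shares every deep branch 100
ways. On cycad-shaped trees ED is therefore extremely right-skewed, which is
what gives the "lose the top-ED species" scenario its bite.

**EDGE** combines distinctiveness with IUCN endangerment:
`EDGE = ln(1 + ED) + GE * ln 2`, with GE coded LC = 0, NT/CD = 1, VU = 2,
EN = 3, CR = 4 (`ge_code()`). Each GE step doubles the implicit extinction
odds, hence the `ln 2`. Data Deficient species are excluded *before*
scoring — passing DD to `ge_code()` is an error by design, not a silent 0 —
and the ranking breaks EDGE ties by species label so it is reproducible.

# Extinction scenarios and the random-pruning null

`scenario_test()` prunes a chosen loss set, computes the PD that survives,
and compares it with the PD remaining after pruning equally many tips
uniformly at random (default 100 randomizations).
The test is one-tailed in the direction "more loss than random", because
that is the scientific hypothesis throughout: p is the probability that a
random loss set leaves no more PD than the scenario does.

Two numerical choices made here deliberately:

* **p-value estimator.** We use the add-one form
  `p = (1 + #[null <= observed]) / (reps + 1)`, which cannot return an exact
  zero at 100 replicates; the raw count is recoverable from the stored null
  draws.
* **Exhaustive mode.** For small trees `random_prune_null(exhaustive =
  TRUE)` enumerates all `choose(n, k)` loss sets, which makes the null mean
  exact; the tests use this as an oracle against the sampled null.

`run_standard_scenarios()` builds the five canonical loss sets: the top-ED
species (the count is an explicit argument rather than a hard-coded
fraction — the conventional cut at the 339-species scale is 165, slightly
under half, and whether outgroups or DD species leave the pool before the
cut is a choice the caller should own), all threatened species (VU∪EN∪CR),
and each threatened category alone. DD species never enter a threat
scenario.

# Phylogenetic signal of threat: the D statistic

`d_statistic()` measures phylogenetic signal in the binary
threatened/nonthreatened trait. The observed trait-change sum `d` estimates
node values tips-to-root as unweighted child means and sums the absolute
child-child differences. `d` is then scaled between two Monte-Carlo
expectations — tip-label permutations (no signal) and Brownian-threshold
simulations with matched prevalence (strong signal) — giving
`D = (d_obs - mean d_BM) / (mean d_rand - mean d_BM)`, so D ≈ 1 for random
traits, ≈ 0 for Brownian clumping, < 0 for stronger-than-Brownian clumping.

The node-value estimator ignores branch lengths. Because the *same*
estimator is applied to the observed trait and to both nulls, the scaling is
internally consistent; implementations that weight by branch lengths may
return slightly different D on the same data. `P_rand` is the fraction of
permutation d-values ≤ observed (departure from D = 1); `P_BM` the fraction
of Brownian d-values ≥ observed (departure from D = 0). Both raw fractions
and add-one smoothed versions are reported, since a raw 0 can mean "smaller
than anything in 1000 draws", not "impossible". Polytomies are resolved to
zero-length bifurcations first; the resolution is deterministic (same input,
same binary tree).

The companion `ed_group_test()` is a classical one-way ANOVA of ED across
groups (threatened vs. not, or the five IUCN levels).

# Diversification models on branching times

All six models condition on two lineages at the root age and work on the
branching times alone. Between lineage-addition events the process is
constant-rate, so each event contributes `ln(k · rate)` and each interval
`-k · rate · Δt` with `k` the standing lineage count; the combinatorial
constant is carried identically by every model so AIC values are
comparable. The family:

| model | parameters | per-lineage rate |
|---|---|---|
| pureBirth | r | r |
| bd | r, a | Nee birth–death likelihood, net rate r, extinction fraction a |
| DDL | r0, K | r0 (1 − k/K), K > n |
| DDX | r0, x | r0 · k^(−x) |
| yule2rate | r1, r2, st | piecewise constant in time |
| yule3rate | r1, r2, r3, st1, st2 | piecewise constant in time |

The pure-birth MLE has the closed form events/lineage-time and is
cross-checked against a numeric optimum; `bd` is maximized by L-BFGS-B with
random restarts; DDL/DDX by Nelder-Mead with 10 seeded restarts (their
surfaces are mildly multimodal). The multi-rate Yule fits profile out the
rates (per-era closed form) and search shift points over the observed
branching times plus midpoints.

**Era admissibility.** An unrestricted shift search is degenerate: on a
300-tip constant-rate tree it reliably finds ~1.5-Myr micro-eras of a few
coincidentally clustered events whose unbounded profile rates add several
log-likelihood units. Requiring a minimum era occupancy (2 events) does not
remove this. We therefore also require every era to have real support:
duration of at least 5% of the root age *or* at least 10% of the total
lineage-time. The OR form matters on cycad-shaped trees, where a genuine
late-radiation era is short in absolute time (< 5% of a ~300-Myr root) but
carries a quarter of all lineage-time, while a genuine deep era is long but
lineage-poor. The thresholds were fixed by a specificity / sensitivity /
shift-recovery trade-off study on simulated constant-rate and multi-rate
trees (300 tips, 25 replicates per condition) and are not exposed as
user-facing tuning knobs.

**Model selection.** `select_model()` applies the printed rule:
`delta = AIC(best rate-constant) - AIC(best rate-variable)`, rate-variable
iff `delta > 0`, ties to the simpler family. A caveat documented here
deliberately: because the rate-variable fits maximize over shift locations,
the null distribution of `delta` is not centered where a naive AIC argument
puts it, and on constant-rate trees of a few hundred tips `delta > 0`
occurs more often than not even with the era-support rule. The sign of
`delta` is the field's conventional decision rule and is implemented as
stated, but a
user wanting a calibrated test should compare the observed `delta` against
`select_model()` outputs on trees simulated under the fitted constant-rate
model — exactly what the package's simulators make easy.

`clade_rate_comparison()` is the branch-length-distribution rate test: ML
exponential rates inside vs. outside a clade, pooled vs. separate, LRT
against chi-squared(1), flagging "hot" clades (shorter branches, faster
rates). It deliberately assesses branch lengths, not cladogenesis counts.

# Grid metrics, hotspots and protection

The geography is an abstract `width x height` equal-area lattice of nominal
100 x 100 km cells (no projection, no coastline — the statistical structure
is what matters). Per occupied cell: species richness SR; PD of the cell's
assemblage; weighted endemism `WE = sum of 1/range`; corrected weighted
endemism `CWE = WE / SR`; phylogenetic endemism PE (each branch's length
divided over the cells in its range, where a branch's range is the union of
its descendant tips' cells); and mean EDGE over scored species. Conservation
identities hold exactly and are tested: `sum ED = PD(all)`,
`sum_cells WE = S`, `sum_cells PE = PD`. Note two deliberate readings of
endemism conventions: the endemism *hotspot* metric is CWE (the
richness-corrected form, following the metric's original definition) while
both WE and CWE maps are emitted; and per-cell EDGE is the *mean*, not the
sum, so rich cells are not automatically EDGE hotspots.

Hotspots are the richest `ceil(p% · n_occupied)` cells per metric (2.5% and
5% tiers), ranked among *occupied* cells only — including empty ocean cells
in the percentile base would make SR hotspots meaningless — with ties broken
by cell id. A cell is "protected" iff its protected fraction is ≥ 0.5
(strict, so a mask of 0.49 everywhere gives zero coverage), and the
percent-of-range figure is reported as percent of occupied cells, labelled
as such, so its denominator is unambiguous.

# The synthetic data generator

The generator is a first-class module: it defines the conditions under
which every downstream claim is tested.

* **Trees.** `simulate_tree()` is a forward Gillespie birth–death simulator
  (extinct lineages pruned, total-extinction retries capped at 1000) with
  optional piecewise-constant birth rates for shift-recovery experiments; it
  stops at the target tip count and appends one unapplied waiting time so
  terminal branches have positive length. `simulate_cycad_like_tree()`
  builds the cycad shape directly: a backbone joining 11 genus stems at ages
  drawn from 40–300 Myr, genus crowns at 2–13 Myr (the scale of the cycad
  secondary calibrations), and lognormal-weighted genus sizes (every genus
  ≥ 1 species), so long-fuse monotypic genera arise naturally.
* **Threats.** Default category probabilities reproduce the global cycad
  assessment's marginals: 78 VU, 70 EN, 67 CR of 339 (215 threatened); the
  124 nonthreatened species are split 100 LC / 24 NT (an ~80/20 split,
  typical of IUCN-assessed plant groups), and DD defaults to 0. `"iid"` mode draws categories independently (no
  phylogenetic signal; D calibrates to 1); `"clustered"` mode thresholds a
  single Brownian liability at the category quantiles — exactly the
  Brownian-threshold null of the D statistic, so D calibrates to 0 by
  construction, and the realized category counts match the quotas exactly.
* **Occurrences.** Niche centers evolve as 2-D Brownian motion on the tree
  (rank-mapped to the lattice) so relatives co-occur; each range is a
  contiguous patch grown by random accretion with lognormal size (median 5
  cells, sd 1 on the log scale — narrow-endemic-dominated, as in cycads).
* **Protection.** Random blobs of fully protected cells grown until the
  grid mean hits the target (default 0.3), one partial boundary cell making
  the mean exact.

What the generator does **not** emulate: spatial autocorrelation of threat
with geography, range-size–threat correlation, coastlines and real
projections, sampling artefacts of occurrence databases, and taxonomic
uncertainty. Passing tests therefore demonstrate the *statistical machinery*
under the stated generative conditions, not claims about any real dataset.

`graft_missing_taxa()` is the stand-in for taxonomic imputation of species
without DNA data: each missing species attaches uniformly over the branches
of its genus crown (stem for monotypic genera) at a uniform age on the
chosen branch. It is a single draw, not a posterior: downstream metrics need
one complete tree, and the pipeline accepts replicate grafted trees (by
seed) where sensitivity to the imputation matters, rather than presuming how
many replicates the original analysis used.

# Reproducibility and problem sizes

Every stochastic function takes a seed and is byte-reproducible; the
pipeline writes a manifest echoing its configuration. The test suite runs
its calibration studies at 100 replicates on 120–300-tip trees (D-statistic
calibration at 200 tips with 150 Monte-Carlo draws per null; scenario-null
uniformity over 500 replicates at 99 randomizations; model-selection
operating characteristics at 300 tips) — sizes chosen so the whole suite
completes in minutes on one core while keeping Monte-Carlo standard errors
a few percent. Whether outgroup taxa belong in a given analysis
(diversification fits conventionally exclude them; distinctiveness
rankings may not) is answered by exposing `drop_outgroups()` as an explicit
step instead of a hidden default.

# Known limitations

* The D statistic's node-value estimator ignores branch lengths (see above);
  D is calibrated within this package's own nulls.
* The raw `delta_AICrc > 0` verdict is anticonservative on constant-rate
  trees (see the model-selection caveat); calibrate against simulated nulls
  for inference.
* The birth–death likelihood conditions on the root age and survival of the
  two root lineages; it is not a fossilized-birth–death or sampled-ancestor
  model.
* `graft_missing_taxa()` preserves genus monophyly and ultrametricity but
  ignores within-genus taxonomy (subgenera, species groups).
* The lattice is torus-free and unprojected; cells are nominal 10,000 km²
  regardless of latitude.
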
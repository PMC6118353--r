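---
title: "Food-web topology, random-removal null models and facilitation structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Food-web topology, random-removal null models and facilitation structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question this package addresses

Foundation species — spatially dominant, habitat-structuring organisms
such as seagrasses, mussel beds, marram grass or Spanish moss — support
many other species through *non-trophic* facilitation: they provide
attachment substrate, three-dimensional structure and stress relief
rather than food. A natural field design compares the food web sampled in
a foundation-species-dominated area (FS) with the web of a nearby bare
area (BA), replicated within and across ecosystems. Two questions follow:

1. Does the foundation species enhance food-web size and complexity
   (species richness, link density), and how do the other topology
   metrics respond?
2. Is the facilitation *random* across the trophic network, or *targeted*
   at particular trophic levels or feeding guilds? The operational test is
   a null model: prune each FS web by uniformly random species removal
   down to bare-area richness (RR webs) and ask which metrics of the real
   bare webs the pruned webs fail to reproduce.

`foundweb` implements the full pipeline: web reconstruction with
diet-based link filtering, a 19-metric topology panel, the random-removal
null model, the comparison statistics (mixed models, PCA), and a
synthetic-study generator that stands in for field data, with ground
truth attached.

## Data model

A food web is dichotomous (binary) and directed: a link `(prey,
predator)` records only that the interaction occurs. Self-links
(cannibalism) are allowed. In the adjacency representation rows are prey
and columns predators: `A[i, j] = 1` means species *j* eats species *i*.
Species carry an abundance count, an `is_foundation` flag (at most one
per web) and optional replicate isotope samples (δ13C, δ15N, in permil).
Isolated species are rejected at load time — a sampled web contains only
trophically connected taxa — but are produced transiently by
`induced_subweb()`, whose job is subsetting, not pruning; dropping
stranded species is the explicit business of the isolation cascade.

## The 19-metric panel and its conventions

The metric definitions follow the standard food-web literature; the
self-link conventions are fixed package-wide and stated here once:

* `S` species number; `L` counts **all** links including self-links;
  link density `Z = L/S`; connectance `C = L/S²` (directed denominator,
  self-links possible, hence `S²` rather than `S(S−1)`).
* **Generality** (mean prey count) *includes* self-links, so mean
  generality equals link density exactly. **Vulnerability** (mean
  predator count) *excludes* them, so mean vulnerability is
  `(L − #self)/S` ≈ link density minus the cannibal fraction. These two
  identities are the reason for the convention: they make the panel
  internally consistent and testable.
* **Links** is the mean number of distinct links incident to a species; a
  self-link counts once.
* **Basal / top / intermediate** fractions ignore self-links: basal = no
  prey, top = prey but no predators, intermediate = both. They sum to 1.
* **Herbivore / omnivore / carnivore** partition the consumers (non-basal
  species) by whether their prey are all basal, mixed, or all non-basal;
  they sum to `1 − basal`. **Cannibal** is the fraction of all species
  with a self-link.
* **Trophic level** is prey-averaged: `TL = 1` for basal species,
  `TL_i = 1 + mean(TL of prey)` otherwise, solved exactly as a linear
  system. Loops are fine as long as every species reaches a basal species
  through its diet; a consumer cycle with no basal input makes the system
  singular and is reported as an error rather than patched over.
* **Chain length** is the minimum number of feeding links to any basal
  species (basal species score 0), by breadth-first search.
* **Maximum trophic similarity**: for a species pair, shared prey plus
  shared predators over distinct prey plus predators of the pair; each
  species reports its maximum over partners, the web the mean.
* **Clustering, path length, compartmentalization** are computed on the
  undirected simple projection. Species of degree < 2 contribute 0 to
  clustering. Path length averages over *connected* ordered pairs only,
  keeping the metric finite on fragmented webs (the null model produces
  them); substituting `S` for unreachable pairs would conflate
  fragmentation with distance. Compartmentalization is the mean pairwise
  Jaccard overlap of neighbourhoods with the focal pair removed from both
  sets — the classical compartment measure, chosen because it is exactly
  testable by enumeration.

All pairwise-structure metrics (similarity, path length,
compartmentalization, clustering) are verified in the test suite against
independent brute-force enumeration on hundreds of small random webs.

## Web reconstruction

Field webs start as maximized literature-based candidate networks that
are then constrained, in a fixed order:

1. **Rare-species filter**: species with fewer than 3 counted individuals
   are removed (strict inequality; the threshold is configurable). Counts
   are interpreted per web; pooling counts across replicates is the
   caller's choice before loading.
2. **Forbidden links**: expert-flagged implausible interactions (e.g.
   predator–prey size discrepancies) are removed where present.
3. **Diet filter**: for every consumer with two or more prey, a Bayesian
   stable-isotope mixing model estimates the diet composition, and links
   whose posterior-mean contribution is below 5% (strictly) are dropped.
   Filtering on the posterior mean (not mode or credible bound) is the
   package's choice; single-prey consumers are never filtered (their
   proportion is 1 by construction), and self-links are exempt — a
   species is not a source in its own diet model.

Species left without any link afterwards are dropped and logged as
isolated. Every removal is recorded with its stage and reason, and the
whole pipeline is deterministic given a seed.

## The mixing model

The model is the standard two-tracer mixture: for isotope *j*,
`X_j = Σ_k p_k (s_jk + c_jk) + ε_j`, with diet proportions
`p ~ Dirichlet(1,…,1)`, Normal source signatures `s_jk`, Normal trophic
enrichment `c_jk` (defaults Δ15N = 3.4 ± 1.0 permil, Δ13C = 1.0 ± 0.5
permil per step — conventional literature values, configurable) and an
inferred Normal residual. Marginalizing sources and enrichment gives a
Normal likelihood with mean `Σ p_k (μ_jk + λ_j)` and variance
`Σ p_k² (ω_jk² + τ_j²) + σ_j²`, which a random-walk Metropolis sampler
explores on the softmax parameterization of the simplex (plus log σ),
with the proposal scale adapted toward ~30% acceptance during burn-in
(the first half of the chain) and frozen afterwards. A single chain is
used; convergence is validated operationally, by parameter-recovery tests
on simulated consumers (mean absolute error < 0.1 at 10,000 iterations)
rather than by a diagnostic statistic. Identifiability has the usual
limits: sources that are isotopically close, or consumers with many prey,
spread the posterior toward the prior, so the 5% filter is conservative
exactly where the tracers carry little information.

## The random-removal null model

For each ecosystem, the target interval is the t-based 95% confidence
interval of the mean species count over the bare replicate webs
(`mean ± t·sd/√n`, requiring at least two bare webs). Each FS web is then
pruned: remove one uniformly random species, then repeatedly remove any
species left *trophically isolated* — no link to another species; a lone
self-link does not count — until the richness target is reached.
Fragmentation into several components does **not** trigger removal; only
linklessness does. The foundation species enjoys no exemption by default
(facilitation, not trophic identity, is under test), though an exemption
flag exists.

Two procedural details matter and are deliberate:

* **Stopping point.** Stopping at the first count inside the interval
  would pile every pruned web against the interval's upper bound and bias
  the ensemble rich by about two species. Each replicate therefore draws
  its stopping point uniformly within the interval, which spreads pruned
  richness across the interval the way the bare webs themselves spread.
* **Undershoot and degeneracy.** If the cascade overshoots below the
  interval, or the pruned web strands a consumer cycle with no basal
  path (leaving trophic levels undefined), the replicate restarts with
  fresh randomness from the same seeded stream, up to a restart budget.
  Restarting preserves the uniform-removal null; accepting undershoots
  would bias toward low-connectivity survivors.

Several pruned replicates per FS web stabilize the null expectation;
because they are draws from the same null distribution and not
independent webs, they are averaged into one RR row per parent web before
any statistics.

## The synthetic-study generator

The generator emulates the field design: 7 ecosystems, 3–6 replicate
pairs each (defaults sum to 29 pairs), FS webs of ~25 species at
connectance ~0.15, BA webs of ~12 species. Choices, in order of
consequence:

* **FS webs** come from the classical niche model (uniform niche values,
  beta-distributed diet ranges with shape `1/(2C) − 1`), redrawn until
  connected, basal-reachable, and within a 5% relative tolerance of the
  target connectance — the usual practice when niche webs stand in for
  webs of prescribed connectance; without the tolerance, realized-C noise
  swamps the FS–BA connectance contrast that is actually present.
* **The foundation species** is a basal species pruned to roughly half
  the web-average link count (foundation species are weakly linked food
  sources; their role is structural). Prunings that would orphan a
  consumer's diet or strand a cycle are skipped.
* **BA webs** are built by *sequential* removal from their paired FS web
  — foundation species first (bare areas lack it), then one species at a
  time with the same isolation cascade the null model uses — rather than
  by one-shot subsampling. In `random` mode removal is uniform, so the
  bare webs satisfy the random-facilitation null *by construction*; the
  pipeline must then fail to reject BA ≈ RR, and the type-I behaviour of
  the whole chain is testable. In `targeted` mode species are removed
  with probability proportional to the facilitation weight of their guild
  (defaults: basal 0.5, carnivore 2) — retention in bare areas goes as
  1/weight, so strongly facilitated guilds (carnivores) are depleted in
  bare webs and weakly facilitated ones (basal species, which foundation
  species displace by competing for space) are enriched. This reproduces
  the deviation signature of interest: bare webs with more basal species
  and fewer carnivores than random pruning predicts, and pruned webs
  with correspondingly longer chains and higher trophic levels.
* **Isotopes**: basal δ13C is spread uniformly over a wide range (−32 to
  −14 permil) and δ15N starts near a baseline; every consumer's true diet
  is drawn Dirichlet over its prey, its tissue means solve the mixing
  identity exactly (a linear system, so feeding loops are handled), and
  replicate samples add Gaussian noise (sd 0.5 permil). True proportions
  are kept as ground truth for recovery tests.
* **Counts**: ~10% of species draw abundances below the rare threshold,
  exercising the rare-species filter.

What the generator does *not* emulate: the strong empirical scaling of
connectance with web size. Induced subwebs preserve connectance in
expectation — only the isolation cascade pushes it up — so the synthetic
FS–BA connectance contrast (~0.145 vs ~0.165) is much weaker than in real
webs (where bare-web connectance runs ~0.2 against 0.15). Passing tests
therefore show the pipeline detects the contrast's direction and the
null-model's equivalences, not that the generator matches empirical
connectance scaling. Degree distributions, interaction strengths and
abundance dynamics are likewise out of scope.

## The comparison layer

Each metric is compared across web types with a linear mixed model,
`metric ~ web_type + (1 | ecosystem)`, tested by a one-way ANOVA F-test
with Satterthwaite denominator degrees of freedom, and grouped with
Tukey-adjusted pairwise comparisons on the model's marginal means
(`emmeans`); grouping letters are assigned by maximal cliques of the
"not significantly different" graph, lettered in order of increasing
mean, so patterns read like `(b, a, a)` for "FS above the
indistinguishable BA/RR pair". Residual normality is checked with
Shapiro–Wilk at α = 0.05; on failure (and an all-positive response) the
model is refit on the log scale. Designs with a single ecosystem, or
singular random-effect fits, fall back to a fixed-effects ANOVA and are
flagged.

The panel-wide view is a PCA with webs as samples and the 19 metrics as
variables, on the **covariance** matrix by default: on raw scales a
"total variation" is meaningful and the axis structure reflects the
dominant metric (species number), which is precisely the composite-size
story a single axis should carry; a correlation-matrix option exists.
PC1 scores are then contrasted across web types with the same mixed
model. Under random facilitation the expected readout is FS separated
from both BA and RR on PC1, and BA vs RR non-significant there and on
most individual metrics.

## Numerical and testing notes

Tolerances and degenerate inputs: fraction identities hold to 1e-12; the
trophic-level system is solved by LAPACK and singularities are reported
with the offending species; empty webs, single-species webs
(similarity/graph metrics need S ≥ 2) and missing counts or isotopes are
errors, not warnings. All randomness flows from explicit integer seeds
through a deterministic sub-seed derivation, so every stage — study
generation, MCMC, null model, full pipeline — is exactly reproducible;
adding replicates never perturbs existing ones.

The test suite's problem sizes are chosen to keep the full run in a few
minutes while leaving the simulations honestly powered: brute-force
metric oracles on 200 random webs of up to 8 species; metric identities
on 500 niche-model webs; one full random-facilitation study (29 FS + 29
BA webs, 3 pruned replicates per FS web) for the null-model readout; 15
targeted studies for the deviation signature; 100 seeded runs for the
planted-link filter; 1000 simulated tables for the mixed model's type-I
calibration and 200 for power. The shipped reference table of published
per-type metric means is used only for arithmetic consistency checks of
the survey's headline ratios (2.1× species richness, 1.6× link density,
0.75× connectance, >50% facilitated species); the raw field webs were
never deposited, so absolute reproduction of that table is out of reach
by design.
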
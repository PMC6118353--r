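# foundweb

Food-web topology, random-removal null models and facilitation structure
for foundation-species ecosystems.

Foundation species (seagrasses, mussel beds, cordgrass, marram grass,
Spanish moss, freshwater macrophytes, ...) support other species mainly
*non-trophically* — through habitat structure and stress relief, not as
food. `foundweb` implements the analysis that tests what this does to
food webs: compare the trophic network of foundation-dominated areas (FS)
with paired bare areas (BA), and ask whether the difference is explained
by *random* facilitation across the network, using a null model that
prunes each FS web by uniformly random species removal (with secondary
deletion of trophically isolated species) down to bare-area richness
(RR webs).

The package provides:

* a dichotomous (binary, directed) food-web data model with edge-list /
  adjacency / species-table CSV I/O — rows prey, columns predators,
  self-links allowed;
* web reconstruction: rare-species filter (count < 3), expert
  forbidden-link list, and a Bayesian stable-isotope mixing model
  (`X_j = Σ_k p_k (s_jk + c_jk) + ε_j`, `p ~ Dirichlet(1,…,1)`) that
  prunes links contributing < 5% of a consumer's diet;
* the 19-metric topology panel: S, link density `Z = L/S`, connectance
  `C = L/S²`, vulnerability, generality, links, top/intermediate/basal
  fractions, herbivore/omnivore/carnivore/cannibal fractions, mean
  shortest chain length, prey-averaged trophic level (`TL_i = 1 +
  mean(TL_prey)`, solved exactly), maximum trophic similarity,
  clustering, path length, compartmentalization;
* the random-removal null model with per-ecosystem t-based 95% CI
  richness targets, isolation cascade and seeded reproducibility;
* the comparison layer: per-metric linear mixed models
  (`metric ~ web_type + (1 | ecosystem)`) with Satterthwaite F-tests and
  Tukey grouping letters, covariance PCA over all webs, and the PC1
  contrast;
* a synthetic-study generator (niche-model webs, isotope simulation with
  known true diets, random or guild-targeted facilitation) so the whole
  pipeline is exercisable and testable without field data.

## Worked example

```r
library(foundweb)

study <- generate_study(synth_config(), seed = 1)   # 29 FS + 29 BA webs
out <- run_study(study, reps_per_fs_web = 3, seed = 2)
out$summary[1:3, c("metric", "FS_mean", "BA_mean", "RR_mean", "F", "stars", "letters")]
```

```
          metric    FS_mean    BA_mean    RR_mean          F stars letters
1 species_number 24.1724138 12.0689655 11.7356322 556.751215   *** b, a, a
2   link_density  3.5007015  1.9764750  1.8714318 254.462145   *** b, a, a
3    connectance  0.1447718  0.1639498  0.1604492   5.584877    ** a, b, b
```

Species richness is about twice as high and link density ~1.8× higher
with the foundation species present, while connectance drops — and the
random-removal webs (RR) land on the bare webs (BA), sharing the letter
`a` against the foundation webs' `b`. The panel-wide view says the same:

```r
pca <- out$pca; pca
#> <pca_result> total variation 42.75; axis 1: 97.4%, axis 2: 1.4%
out$pc1
#> <lme_result> PC1: F(2, 77.98) = 718, p = 5.98e-51
#>   letters: BA=b, FS=a, RR=b
```

One composite axis carries almost all variation; it cleanly separates FS
from BA webs while leaving BA and RR indistinguishable — the random-
facilitation null holds for this (random-mode) study, as it should. In
`synth_config(facilitation_mode = "targeted")` studies, four metrics
deviate in the characteristic directions (bare webs keep more basal
species and fewer carnivores than random pruning predicts, with shorter
chains and lower trophic levels).

The numbered scripts under `analysis/` run the same workflow as a
narrated sequence — simulate, reconstruct (with planted spurious links),
metric panel, null model, statistics — writing their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_reconstruct.R
Rscript analysis/03_metrics.R
Rscript analysis/04_nullmodel.R
Rscript analysis/05_stats.R
```

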
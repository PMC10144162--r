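# floralint

Phylogenetic comparative tools for asking how pollinator mouthparts
shape the *integration* of floral phenotypes — the degree to which a
flower's parts vary as a coordinated whole rather than independently.
The package was built around study systems like the honeysuckles
(*Lonicera*), where 11 species span pollinators from small carpenter
bees (mean proboscis 2.45 mm) to hawk moths (41.15 mm), but every
component is generic: it needs a trait table, pollinator observations
and a rooted, branch-length-bearing tree.

It is aimed at researchers in pollination biology and phylogenetic
comparative methods who want the full chain — integration index,
assemblage-level trait matching, PGLS screening, piecewise structural
equation models — as tested, seedable functions rather than a one-off
analysis script.

## What it computes

**Integration index.** For a species with $N$ flowers and $T$ traits,
the variance of the eigenvalues $\lambda_i$ of the trait correlation
matrix (sample variance, divisor $T-1$, so perfect correlation attains
the maximum $T$), corrected by $-(T-1)/N$ and expressed as percent of
$T$, with a seeded percentile bootstrap CI.

**Composite proboscis length.** For a plant species visited by $n$
guilds with mean proboscis lengths $PL_i$ and visitation rates $VF_i$
(visits · flower⁻¹ · period⁻¹):

$$PLa = \sum_{i=1}^{n} PL_i \, VF_i \,/\, VF_n, \qquad VF_n = \sum_i VF_i .$$

**PGLS.** Generalized least squares with tree-derived covariance under
Brownian motion, Pagel's λ (profiled over [0, 1]) or stationary
Ornstein–Uhlenbeck correlation $e^{-\alpha d_{ij}}$, ML estimation,
AIC model comparison.

**Piecewise SEM.** Directed acyclic path models with correlated
errors over PLa and the floral traits; Shipley's d-separation basis
set, per-claim PGLS tests, Fisher's $C = -2\sum \ln p_i$
($\chi^2_{2k}$), $AIC = C + 2K$, and best-model selection among an
enumerable candidate family.

**Synthetic data.** A generator (`make_dataset("lonicera-like")`)
producing tree, species means with a known causal structure
(PLa→tube, PLa→stigma, stigma→upper lip, correlated errors
tube↔stigma and upper↔lower), individual flowers and pollinator
observations, with full ground truth for recovery studies.

## Worked example

```r
library(floralint)

ds <- make_dataset("lonicera-like", seed = 42)

# integration of one species, bootstrap CI
x <- as.matrix(ds$traits[ds$traits$species == "sp04", floral_traits()])
bootstrap_integration(x, n_boot = 2000, seed = 1, species_id = "sp04")
#> integration index [sp04]: T = 8 traits, N = 30 individuals
#>   raw eigenvalue variance 4.5539, corrected 4.3206, percent 54.007%
#>   bootstrap 95% CI [43.335, 64.997] (2000 replicates)

# composite proboscis length of its pollinator assemblage
vf  <- visitation_rates(ds$observations, "sp04")
pli <- guild_proboscis_means(ds$proboscis, guilds = names(vf))
composite_proboscis_length(pli, vf, species_id = "sp04")
#> pollinator assemblage [sp04]: 5 guild(s), VFn = 0.3497, PLa = 41.208 mm

# PGLS of a floral trait on PLa under Pagel's lambda
pgls(stigma_height ~ PLa, ds$species_means, ds$tree, model = "PL")
#> GLS fit (model PL, parameter = 1), n = 11, logLik = -16.5677, AIC = 41.1353
#>             estimate      se      t         p
#> (Intercept)    5.179 1.45372  3.563 6.093e-03
#> PLa            1.753 0.04209 41.644 1.324e-11
```

Reading the output: species `sp04` is the hawk-moth-pollinated end of
the preset — its assemblage PLa (41.2 mm) sits at the long extreme and
its flowers are strongly integrated (54% of the attainable maximum,
CI well above the short-proboscis species). The PGLS slope of stigma
height on PLa recovers the planted coefficient (1.765) within
estimation error, with λ̂ = 1 reflecting the Brownian residuals the
generator uses.

The whole chain — integration, PLa, PGLS screen, PSEM family fit and
selection — runs as one call:

```r
res <- run_pipeline(make_run_config(dataset = ds, seed = 42,
                                    out_dir = "out"))
```

writing `report.json`, per-stage TSV tables and an INFO log of every
screening decision into `out/`. File-based inputs (`trait_path`,
`tree_path`, `obs_path`, `prob_path` in `make_run_config()` or a YAML
config) replace the in-memory dataset for real data. A thin CLI with
`simulate` / `integrate` / `pla` / `pgls` / `psem` / `pipeline`
subcommands lives at `inst/cli/floralint.R`.

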
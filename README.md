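# catomics

Computational stages for a multi-omic question in peatland microbial
ecology: **why does amending anoxic peat with the polyphenol catechin
suppress methane production?** The working model is that anaerobic
catechin degradation is a hydrogen sink — the degradation routes and
the downstream breakdown of their common product phloroglucinol
consume H₂ via electron-recycling hydrogenases, starving
hydrogenotrophic and hydrogen-dependent methylotrophic methanogens.

The package implements, as tested reusable functions, the pipeline a
genome-resolved metatranscriptome + metabolome study of this system
needs:

- **Expression normalization** (`getmm`, `mag_on_filter`,
  `normalize_expression`): low-count filtering (counts < 5 removed),
  gene-length-corrected TMM (geTMM) with a brute-force-verified
  trimmed-mean implementation, and a per-sample genome-activity
  filter (MAGs with < 22 genes "on" zeroed).
- **Response classification** (`classify_all`): each active MAG at
  each timepoint is placed in one of six categories from two metrics,
  %both = 100·n_both/n_total and Δunique = 100·(n_unamended-only −
  n_catechin-only)/n_total, with thresholds 26 / 25 and extreme
  categories winning threshold ties: *resistant*, *responsive*,
  *sensitive*, *stimulated*, *lost function*, *gained function*.
- **Methanogen rule calling** (`call_potential`, `call_active`, plus
  a generic boolean rule engine): Mcr+Hdr confirmation, then
  hydrogenotrophic / acetoclastic / methylotrophic potential and
  per-sample active pathways, with the obligate-acetoclast
  *Methanotrichales* override.
- **Hydrogenase atlas** (`assign_directionality`,
  `class_expression`, `compare_classes`): (family, group) →
  hydrogen-use class mapping with provenance, class-level expression
  totals, and per-day ANOVA with Benjamini–Hochberg adjustment.
- **Hydrogen ledger** (`ledger_routes`, `net_reaction`,
  `apply_recycling`, `h2_per_substrate`): exact rational
  stoichiometry of the catechin degradation routes and phloroglucinol
  breakdown, with cofactor couples closed by PntAB, Rnf, the
  bifurcating [FeFe]-A3 hydrogenase, and the H₂-evolving [NiFe]-4e
  hydrogenase.
- **LC-MS artifact filter** (`filter_features`): in-source-fragment
  removal by retention-time binning (0.005 tolerance), cross-sample
  intensity correlation (> 0.98), and MS2 confirmation (< 5 ppm),
  plus rejection of halogen-containing predicted compositions.
- **Community statistics** (`level_summaries`, `bray_curtis`,
  `permanova`, `kruskal_dunn_bh`): beta-diversity at gene / MAG /
  annotation level, cross-treatment distance contrasts, and the
  hypothesis-testing machinery (PERMANOVA re-implemented and
  cross-checked against vegan; Kruskal–Wallis + Dunn + BH).
- **Synthetic data** (`gen_expression_dataset`,
  `gen_methanogen_fixture`, `gen_lcms_dataset`): every pipeline input
  with planted ground truth, so everything above is testable offline.

## Worked example

Generate a synthetic microcosm experiment, normalize it, classify the
responses, and ask the ledger the headline question:

```r
library(catomics)

ds <- gen_expression_dataset(simulation_design(n_mags = 20, seed = 1))
res <- normalize_expression(ds$counts, ds$catalog)
cl <- classify_all(res$expr, ds$catalog, ds$samples)
head(cl$records[, c("mag_id", "day", "pct_both", "delta_unique", "category")], 5)
#>    mag_id day pct_both delta_unique        category
#> 1 MAG_001   0     39.0        -8.47       resistant
#> 2 MAG_002   0     12.8       -55.32      stimulated
#> 3 MAG_003   0     34.4       -31.25 gained_function
#> 4 MAG_004   0     18.9        -3.33      responsive
#> 5 MAG_005   0     46.9        36.73   lost_function
```

MAG_002 expressed most of its genes only under catechin (Δunique =
−55 with little shared expression): *stimulated*. MAG_005 kept a core
of shared genes but lost a third of its repertoire in the amended
microcosms: *lost function*. On this dataset the classifier recovers
100% of the planted categories.

Beta-diversity at the MAG level, with treatment and time as
sequential PERMANOVA terms:

```r
lv <- level_summaries(res$expr, ds$catalog)
d <- bray_curtis(lv$mag)
permanova(d, ds$samples, factors = c("treatment", "day"),
          n_perm = 999, seed = 1)
#>        term df    ss    r2    f     p
#> 1 treatment  1 0.069 0.117 4.01 0.002
#> 2       day  4 0.108 0.183 1.57 0.036
#> 3  Residual 24 0.413 0.700   NA    NA
#> 4     Total 29 0.589 1.000   NA    NA
```

Both treatment and time structure the simulated community (p = 0.002
and 0.036 at 999 permutations), as they do in the real system.

The hydrogen ledger, from the shipped route chemistry:

```r
h2_ledger_report()[1:3, 1:3]
#>            route_id substrate h2_consumed_net
#> 1        naringenin taxifolin               3
#> 2       eriodictyol taxifolin               2
#> 3 dihydrokaempferol taxifolin               1
```

Read: degradation of one catechin (via its 1:1 activation product
taxifolin) through the naringenin route, including breakdown of its
phloroglucinol moiety to acetate, consumes up to 3 mol H₂ once the
cofactor couples are closed by the PntAB / Rnf / [FeFe]-A3 /
[NiFe]-4e systems — versus 2 via eriodictyol and 1 via
dihydrokaempferol, and compared with the 4 H₂ demanded by
hydrogenotrophic methanogenesis (`h2_per_substrate("methanogenesis_reference")`).

## Layout

```
R/                     implementation (one file per analysis stage)
tests/testthat/        unit, property, and acceptance tests
scripts/acceptance.R   stoichiometric results as JSON
vignettes/             methods vignette (models, parameters, limits)
```
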
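# stcnet

Expression-dynamics analysis for short ordered-condition designs — e.g. a
control / allergen-challenged / four-weeks-after study with three arrays per
condition. The package chains four stages, each usable on its own:

1. **Differential expression** by the random-variance-model (RVM) moderated
   F-test. A gamma prior on inverse gene variances,
   `1/σ² ~ Gamma(a, scale = b)`, is fitted by marginal maximum likelihood
   (under the model, `s²ab ~ F(d, 2a)` for the pooled within-group variance
   `s²` on `d` residual df). Each gene is tested with
   `F = MS_between / [(d·s² + 2/b)/(d + 2a)] ~ F(m−1, d+2a)`, which adds
   `2a` denominator degrees of freedom — the difference between an unusable
   and a usable test at 2–3 replicates per group. Genes with raw `p < 0.05`
   **and** Benjamini–Hochberg `FDR < 0.05` are selected.
2. **Trend-profile clustering** (series test of cluster, STC): all
   `(2c+1)^(m−1) − 1` unit-change model profiles are enumerated (8 for three
   conditions, `c = 1`); DEG trajectories — first-group-anchored log2 ratios
   of within-group geometric means — are assigned to the best-correlated
   profile; profile significance compares observed counts with the mean
   count over all `m!` condition orderings by a one-sided Fisher's exact
   test.
3. **Gene-set over-representation** from GMT annotations: enrichment ratio
   `Re = (nf/n)/(Nf/N)`, one-sided Fisher (exact hypergeometric tail) and
   chi-squared p-values against the expression-matrix universe.
4. **Co-expression network** over the genes of selected profiles (default:
   the up-then-down profile and its mirror): edges where `|Pearson r|` of
   log2 signals exceeds a threshold; per-node degree, local clustering
   coefficient and k-core; hubs ranked by degree.

A synthetic-data generator plants trend profiles, inverse-gamma gene
variances, enriched gene sets and a correlated hub module, so every stage is
verifiable against ground truth without any external download.

## Worked example

```r
library(stcnet)
cfg <- pipeline_config(sim = sim_config(seed = 1), out_dir = "run", seed = 1)
res <- run_pipeline(cfg)
```

The default configuration simulates 2000 genes (3 conditions × 3
replicates), 10% planted on profile 5 (up then back down), 5% each on
profiles 2 and 6, a 41-gene hub module inside profile 5, 50 random gene sets
plus one planted set per profile. The run prints its stages and returns the
fitted objects; the same numbers land in `run/` as TSV/JSON.

```r
res$prior
#> RVM variance prior: a = 1.987 , b = 10.4
#> Residual df per gene: 6 ; moderated denominator df: 9.9743
#> Fitted on 2000 genes; logLik = 3011.09
```

The fitted prior recovers the generating hyperparameters (a = 2, b = 10) and
nearly doubles the effective residual df (6 → 9.97).

```r
summary(res$deg)
#> Genes tested:       2000
#> p < 0.05:           474
#> FDR < 0.05:         374
#> Selected (both):    374

as.data.frame(res$significance)
#>   profile observed expected        p significant
#> 1       0        1     7.17 9.96e-01       FALSE
#> 2       1        1    59.83 1.00e+00       FALSE
#> 3       2       92    61.67 4.30e-03        TRUE
#> 4       3        4    57.67 1.00e+00       FALSE
#> 5       4        0    59.83 1.00e+00       FALSE
#> 6       5      188    63.00 8.33e-23        TRUE
#> 7       6       79    57.67 2.92e-02        TRUE
#> 8       7        9     7.17 4.01e-01       FALSE
```

374 of the 400 planted genes survive the joint p/FDR rule, and exactly the
three planted profiles (2, 5, 6) show significantly more assigned genes than
their permutation expectation.

```r
head(as.data.frame(res$enrichment[["5"]]), 3)
#>                 set nf   n Nf   Re fisher_p significant
#> 1 planted_profile_5 33 188 40 8.78 9.12e-29        TRUE
#> 2    random_set_029 10 188 40 2.66 2.92e-03        TRUE
#> 3    random_set_015  7 188 40 1.86 7.50e-02       FALSE

head(res$hubs, 3)
#>         gene profile degree clustering kcore
#> 1 gene_00001       5     37  0.6276276    19
#> 2 gene_00038       5     36  0.6555556    19
#> 3 gene_00036       5     36  0.6460317    19
```

The planted set is the top enrichment hit for the profile-5 gene list
(enrichment ratio 8.8, Fisher p ≈ 1e-28), and the designated hub
(`gene_00001`) tops the degree ranking of the profile-5/2 network.

## Command line

```sh
Rscript inst/cli/stcnet.R run-all --out run --seed 1          # synthetic
Rscript inst/cli/stcnet.R run-all --out run \
    --matrix expr.tsv --design design.tsv --gmt sets.gmt      # your data
Rscript inst/cli/stcnet.R stc --matrix expr.tsv --design design.tsv --out out
```

Subcommands `simulate`, `deg`, `stc`, `enrich`, `network`, `run-all`; inputs
are tab-separated text (gene × sample matrix, two-column sample→group
design, standard GMT). Reruns with one seed and configuration are
byte-identical.

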
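---
title: "Expression dynamics over ordered conditions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression dynamics over ordered conditions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcnet)
```

# The problem

Allergen-challenge studies (and many other short-series designs) profile
expression over a small number of *ordered* conditions — for instance nasal
mucosa from control mice, mice two hours after an ovalbumin (OVA) challenge,
and mice four weeks after the last challenge — with only a handful of arrays
per condition. Two questions dominate: *which genes move* across the
conditions, and *how* they move — up with the challenge and back down as
symptoms resolve, up and sustained, steadily down, and so on — because the
shape of the trajectory, not just its existence, is what links a gene to the
phenotype. stcnet implements that analysis end to end: moderated-F
differential expression, trend-profile clustering with a permutation test,
gene-set over-representation, and a co-expression network with hub ranking,
plus a synthetic-data generator that makes every stage verifiable against a
known ground truth.

# Differential expression: the random variance model

With 2–3 replicates per condition, per-gene variance estimates on `d = S - m`
residual degrees of freedom (here `9 - 3 = 6`) are too unstable for a
classical one-way F-test. The random variance model (RVM) shares variance
information across genes: each gene's inverse variance of log2 signals is
taken to follow a gamma prior,

$$ 1/\sigma^2 \sim \mathrm{Gamma}(a,\ \mathrm{scale} = b), $$

under which the pooled within-group variance $s^2$ satisfies
$s^2 a b \sim F(d, 2a)$ marginally. We estimate $(a, b)$ by maximizing the
marginal likelihood of the observed residual variances under this F form
(L-BFGS-B on log-parameters, box constraints $a \in [10^{-3}, 10^6]$,
$b \in [10^{-9}, 10^9]$, method-of-moments start; non-convergence is an
error, never a silent default). Each gene is then tested with the moderated
statistic

$$ F = \frac{\mathrm{MS}_\text{between}}
           {(d\,s^2 + 2/b)\,/\,(d + 2a)}
   \ \sim\ F(m - 1,\ d + 2a) \text{ under the null,} $$

so the prior effectively adds $2a$ denominator degrees of freedom. Genes are
selected when both the raw p-value and the Benjamini–Hochberg FDR are below
0.05 — the joint rule keeps the all-null false-selection count near zero.

Choices worth knowing:

* **Analysis scale.** Variances and mean squares are computed on log2
  signals. The inputs are positive linear-scale values (e.g. RMA output
  back-transformed), and the group summaries used downstream are geometric
  means of linear signals — identical to arithmetic means of log2 signals,
  which keeps the two stages on one consistent scale.
* **FDR procedure.** Benjamini–Hochberg step-up (via `stats::p.adjust`), the
  standard choice where a method is described only as "FDR analysis".
* **Degenerate inputs.** A constant matrix is a fitting error. If the
  between-gene dispersion of variances is essentially zero the likelihood
  pushes $a$ to its upper bound; the fit warns that the prior is degenerate
  rather than failing. Zero-variance genes are excluded from hyperparameter
  fitting (their density is singular) but are tested normally — the
  moderated denominator is strictly positive.
* **Classical limit.** As the prior vanishes ($a \to 0$, $b \to \infty$) the
  moderated variance tends to $s^2$ and the denominator df to $d$, so both
  the statistic and the p-value converge to the classical one-way ANOVA;
  the suite asserts this against an independently coded ANOVA. In the other
  direction ($a \to \infty$ with $1/(ab)$ fixed at $s^2$) only the statistic
  converges — the df keep growing — and only statistic equality is asserted
  there.

# Trend profiles (series test of cluster)

A *model profile* is a vector of per-transition changes in
$\{-c, \dots, +c\}$ anchored at 0 in the first condition. With $m$ ordered
conditions there are $(2c+1)^{m-1} - 1$ non-constant profiles; for $m = 3$,
$c = 1$, exactly 8. Profiles are numbered lexicographically
($-c < \dots < 0 < \dots < +c$, first transition most significant), which
yields the conventional semantics for three conditions: ids 0–2 fall at the
first transition, 3–4 are flat first, 5–7 rise first; id 5 is
up-then-back-down (positions 0, 1, 0), id 6 up-then-sustained (0, 1, 1), id
7 steadily up (0, 1, 2). The numbering is asserted by tests against those
trend descriptions. The catalogue is data-independent; "one unit" is
calibrated per gene by the correlation matching below.

Selected DEG are transformed to first-group-anchored log2 ratios
(`0, log2(g2/g1), ..., log2(gm/g1)` with `gk` the within-group geometric
mean) and each gene is assigned to the profile whose position vector has the
highest Pearson correlation with its ratio vector. The correlation includes
the anchored zero entry — dropping it would leave only $m - 1 = 2$ points
for the three-condition design, making the correlation degenerate. Constant
ratio vectors have undefined correlation and are left unassigned; exact ties
go to the lowest profile id (deterministic and documented).

**Profile significance.** For every one of the $m!$ orderings of the
condition columns (identity included), ratio vectors are re-anchored to the
permuted first group and re-assigned; a profile's expected count is its mean
count over the orderings. The observed count is compared to the rounded
expectation by a one-sided Fisher's exact test on
`[observed, n - observed; round(expected), n - round(expected)]`,
alternative "greater", at raw $\alpha = 0.05$ with no correction across
profiles. Three open choices were settled as follows: the identity ordering
is included in the average (the permutation *runs* comprise all orderings);
the test is one-sided toward excess (the question is whether *more* genes
land on a profile under the true ordering); and expected counts are rounded
half-up because Fisher's test needs integer cells — a binomial alternative
(`method = "binomial"`) avoids the rounding entirely and is provided for
sensitivity checks.

# Gene-set over-representation

For a gene list of size $n$ from a universe of size $N$, and a set with
$N_f$ universe members of which $n_f$ are in the list, we report the
enrichment ratio $R_e = (n_f/n)/(N_f/N)$, the one-sided Fisher p-value
(hypergeometric upper tail of at least $n_f$ overlaps), and a chi-squared
p-value from the 2×2 table without continuity correction. Fisher drives the
significance flag at raw $p < 0.05$; the chi-squared column is reported for
parity with common practice, and a Benjamini–Hochberg column is included for
users who want multiplicity control (the flag deliberately does not use it).
The universe is the set of genes on the expression matrix, not the union of
the annotation file — the microarray background is what the list was drawn
from. List genes absent from the universe are dropped with a logged count;
sets are intersected with the universe and empty sets removed. Gene sets are
read and written as standard GMT (id, description, members), with
line-numbered errors for malformed records.

# Co-expression network

Over the genes of the profiles of interest — by default the up-then-down
profile and its mirror (ids 5 and 2 for three conditions) — Pearson
correlations of log2 signals are computed across *all* samples jointly,
since the condition dynamics are the biological signal. An edge joins two
genes when $|r| \ge$ a threshold; weights keep the sign. Per node we report
degree, the local clustering coefficient $2e_i/(k_i(k_i-1))$ (0 by
convention below degree 2), and the k-core index (the largest $k$ surviving
iterative removal of all nodes of degree $< k$); metrics are computed with
igraph and verified in the suite against brute-force oracles (exhaustive
subset search for k-cores on small graphs, triangle counting, an independent
peeling implementation). Hubs are ranked by degree, ties by clustering
coefficient, then gene id.

The edge threshold is the one genuinely free parameter. `build_network()`
defaults to 0.8, a common choice for microarray co-expression maps; the
synthetic pipeline default is 0.99 (see below). Because published analyses
of this kind rarely state their adjacency rule, hub *identities* on a given
dataset depend on this choice, and no external degree/clustering/k-core
values are asserted by the package.

# The synthetic-data generator

`simulate_dataset()` emulates the three-condition, three-replicate design:
per-gene log2 group means are `baseline + effect_size × profile position`
for planted genes and flat at `baseline` for null genes; replicate log2
values are i.i.d. normal around the group means; per-gene variances are
drawn from the inverse-gamma prior of the RVM (reciprocal of a
`Gamma(a, scale = b)` draw, floored at 1e-6); signals are exponentiated so
geometric means of the linear values recover the planted log2 means exactly.
Defaults — chosen once as realistic study conditions and then left alone —
are 2000 genes, groups control/OVA/4w_after with 3 replicates each (the
study design has 6 animals per group but 3 arrays per group; the generator
defaults to the arrays and leaves the count configurable), effect 1.0 log2
per unit step, prior `a = 2`, `b = 10` (median per-replicate log2 sd about
0.24, typical residual noise for RMA-normalized arrays), baseline log2 mean
8, and planted fractions of 10% on profile 5 and 5% each on profiles 2
and 6.

**The hub module.** One co-regulated module is planted inside profile 5: a
designated hub plus 40 spokes. All module genes share a latent sample-level
factor — the hub's own noise vector, centered within each condition so the
co-fluctuation never shifts group means (module genes stay cleanly on their
trend) — with the hub carrying the factor exactly and each spoke carrying
`0.95 ×` the factor plus independent remainder. Hub–spoke noise correlation
is therefore 0.95 and spoke–spoke 0.95² ≈ 0.90; a correlation-through-the-
hub design cannot do better, since two spokes at correlation ρ with a common
hub are themselves correlated at least 2ρ² − 1. Module genes use a fixed
noise sd of 0.2 log2 units: small enough that they remain clearly
differentially expressed, large enough that at the top of the correlation
range the hub separates from its spokes. Accounting for the trend variance
shared by all profile-5 genes, the expected total correlations are ≈ 0.993
(hub–spoke) and ≈ 0.985 (spoke–spoke), which is why the synthetic pipeline
thresholds edges at 0.99: it cuts between the two. This is also the honest
caveat about the module: with 9 samples, sample correlations are noisy
(Fisher-z sd ≈ 0.41), so hub recovery is a strong expectation, not a
certainty, at these sample sizes.

What the generator deliberately does **not** emulate: probe-level array
structure and RMA itself, batch effects, missing values, correlated
background genes beyond the one module, heavy-tailed noise, or pathway
topology. Passing recovery tests therefore demonstrates that the pipeline's
inference is correct *under its own model assumptions* — it does not certify
performance on real arrays, where normalization artefacts and correlated
nulls can inflate both false DEG and spurious edges.

`simulate_gene_sets()` adds `n_sets` random sets plus one planted set per
requested profile, drawing 90% of a planted set's members from that
profile's genes (at least 80% by construction, which is what the enrichment
recovery tests assume). `simulate_random_graph()` provides Erdős–Rényi
fixtures whose metrics small-scale brute force can verify.

# The pipeline and its reproducibility contract

`run_pipeline()` chains simulate/read → DEG → trend profiles → per-profile
enrichment → network, writing every table as TSV (plus GraphML for the
network), per-profile gene lists, a run log, and a JSON manifest recording
the package version, seed, thresholds, fitted prior and warning counts. No
timestamps are recorded anywhere, so one configuration and seed reproduce
the bundle byte for byte; the suite asserts this. Any stage failure aborts
the run with the stage name and cause. A thin command-line front end
(`inst/cli/stcnet.R`, subcommands `simulate`, `deg`, `stc`, `enrich`,
`network`, `run-all`) exposes the same functions for shell use.

# Problem sizes used by the verification suite

The suite favors many small, sharply targeted simulations: hyperparameter
recovery and the variance-distribution check use 10,000 genes; null
calibration uses 2000; trend recovery uses 50 replicate datasets of 400
genes (10% planted on profile 5 and 10% on its mirror, per-replicate sd
concentrated near 0.25); enrichment exactness uses 1000 random tables with
universes up to 200; network exactness uses exhaustive-subset k-core checks
on graphs of up to 12 nodes and independent-peeling checks on 200 random
graphs of up to 50 nodes; end-to-end checks run the full pipeline on
600–2000 genes. These sizes were chosen so each property is tested with
comfortable statistical margin while the whole suite stays quick.

# Known limitations

* The profile catalogue assumes equally spaced, ordered conditions; unequal
  spacing and STEM-style reduction of the catalogue to a non-redundant
  subset are out of scope (with 8 profiles there is nothing to reduce).
* Raw p-values drive profile and enrichment significance, mirroring common
  practice for this analysis; the BH column is available where users prefer
  control of the FDR across sets.
* Network conclusions are threshold-dependent by nature; treat hub lists as
  rankings under a stated threshold, not absolute facts.
* Gene identifiers are opaque strings; no symbol normalization or
  probe-to-gene mapping is attempted.

# A minimal session

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 1), out_dir = "run", seed = 1)
res <- run_pipeline(cfg)
res$significance            # observed vs permutation-expected profile counts
head(res$enrichment[["5"]]) # over-represented sets among profile-5 genes
head(res$hubs)              # degree / clustering / k-core ranking
```
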
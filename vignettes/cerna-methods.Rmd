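---
title: "Methods: ceRNA network analysis with cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network analysis with cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

# Scientific problem

Competing endogenous RNAs (ceRNAs) are transcripts — typically long
non-coding RNAs (lncRNAs) or circular RNAs (circRNAs) — that carry binding
sites for the same microRNAs as protein-coding mRNAs. When such a "sponge"
transcript is abundant it sequesters the shared miRNAs, de-repressing the
mRNA; when its dose drops, the freed miRNAs repress the mRNA. The classic
setting for this package is a two-genotype, two-state stem-cell study:
wild-type 46,XX lines versus 45,X (Turner syndrome) lines, each assayed as
induced pluripotent stem cells (iPSC) and as differentiated cardiomyocytes
(CM). Genes that escape X-chromosome inactivation (XCI) are expressed from
both X copies in 46,XX cells, so a 45,X cell carries roughly half their
dose. An XCI-escaping sponge therefore loses half its dose in 45,X
cardiomyocytes, and every mRNA it de-represses inherits part of that
dosage perturbation — a candidate molecular mechanism for the cardiac
phenotypes of X monosomy.

`cernet` implements the full analysis chain for this design:
normalization and QC, differential expression (DE), miRNA target
prediction, co-expression filtering, circuit assembly, enrichment
statistics, qPCR helpers, and a synthetic-data generator with known
ground truth that lets every stage be validated end to end.

# Analysis model

## Normalization

Arrays are quantile-normalized: each sample's sorted intensity vector is
replaced by the mean sorted vector, so all samples share one empirical
distribution. Ties receive the mean of the reference values their
occupied ranks would take, which keeps the transform deterministic and
idempotent. The implementation is `quantile_normalize()`; the test suite
cross-checks it against `limma::normalizeQuantiles(ties = TRUE)`.

One design decision matters here: **all RNA classes are normalized
together** (`analyze_cerna()` stacks mRNA, lncRNA and circRNA matrices
before normalizing, then splits them again). Quantile normalization
forces a common distribution, so whatever fraction of features carries
real signal is partially absorbed into the reference. On a full array
(thousands of features, a few percent regulated) the distortion is
negligible; on a small per-class slice (say 150 circRNAs of which 20%
are regulated) it visibly compresses fold changes. Normalizing the
combined matrix mirrors how a single-array platform is processed and
keeps the regulated fraction small.

## Differential expression

For each feature the fold change is the ratio of *linear-scale* group
means, and the p-value is a two-tailed Student's t-test on log2 values:
paired by cell line for the within-genotype differentiation contrasts
(CM vs iPSC in WT, CM vs iPSC in TS), unpaired Welch for the
cross-genotype contrast (TS-CM vs WT-CM), where no natural pairing
exists. A feature is called DE when `fc >= 2` or `fc <= 0.5`
(inclusive) **and** `p < 0.05` (strict). Degenerate features are guarded
explicitly: zero variance with zero difference gives p = 1; zero
variance with a nonzero difference gives the smallest representable
double rather than an infinite statistic. The three DE lists per RNA
class are summarized as the seven disjoint regions of a three-set Venn
partition (`venn_partition()`).

## miRNA targets

`predict_targets_seed()` scans transcripts for canonical seed sites: the
reverse complement of miRNA nucleotides 2–7 (6mer core), optionally
extended by a match to nucleotide 8 (m8) and/or an adenine opposite
nucleotide 1 (A1), giving the 6mer, 7mer-A1, 7mer-m8 and 8mer classes.
Each window is reported once under its most specific class. circRNAs are
scanned as their doubled sequence with sites restricted to starts within
the first copy, so back-splice-junction sites are found without
duplicating linear ones. Predicted tables can be merged with imported
tables by union or, conservatively, intersection
(`merge_target_tables()`).

## Co-expression and circuit assembly

Every DE sponge (lncRNA or circRNA, union over the three contrasts) is
correlated with every DE mRNA across the cardiomyocyte samples of both
genotypes. Edges are kept when the Pearson correlation exceeds `r > 0.2`
with `p < 0.05` from the exact t-distribution of
`t = r * sqrt(n-2) / sqrt(1-r^2)`. The threshold is *signed* by default:
ceRNA logic predicts positive co-movement of a sponge and the target it
de-represses. A retained edge becomes a circuit when the two endpoints
share at least one predicted miRNA (`assemble_circuits()`); the shared
miRNA set is recorded on the circuit, and an optional hypergeometric
tail probability (`shared_mirna_enrichment()`) quantifies how surprising
the sharing is given each endpoint's miRNA count. Biological focusing is
a separate, explicit step: `filter_circuits()` can require the sponge
host to escape XCI and the mRNA to belong to a user-supplied gene set.

## Enrichment and qPCR

`enrich_collection()` performs hypergeometric over-representation of a
query list against a GMT collection with Benjamini–Hochberg adjustment;
the universe is the measured feature set, not the genome. The qPCR
module implements comparative-Ct quantification (`delta_delta_ct()`,
fold = efficiency^-ddCt with a housekeeping reference such as GAPDH or
U6) and mitochondrial copy number per nucleus from the cycle gap between
a mitochondrial amplicon and a single-copy nuclear gene
(`mtdna_copies_per_nucleus()`).

# The synthetic-data generator

`generate_dataset(sim_config(...))` simulates the full study on the log2
scale:

```
x[f, s] = baseline[f]
        + effect[f]                * 1[s is CM]
        + log2(ts_dosage_factor)   * 1[s is TS and f escapes XCI]
        + u[f, line(s)] + eps[f, s]
```

with `effect` drawn as a random sign times N(state_effect_mean,
state_effect_sd) for a `cm_fraction` of each class, a per-line random
intercept `u ~ N(0, line_sd)` that gives the paired tests something to
pair on, and residual noise `eps ~ N(0, sigma)`. Planted circuits
replace their target mRNA's row entirely: the target has *no* direct
group effect; its value is `baseline + beta * (sponge - mean(sponge))`
plus its own line intercept and noise, so every bit of its group
structure is inherited through the coupling — exactly the signal a ceRNA
analysis is supposed to detect. Planted sponges are forced to be both
differentiation-regulated and XCI-escaping, matching the biological
scenario. The emitted target table registers each circuit's miRNAs
against both endpoints and adds `decoy_ratio` times as many uniformly
random interactions.

Default dimensions (2,000 mRNAs, 800 lncRNAs, 400 circRNAs, 10% of each
class differentiation-regulated, 1,000 miRNAs, 10 circuits with 2 miRNAs
each) are the package's standard simulated study. The regulated fraction
is deliberately kept at ~10% so that quantile normalization — part of
the pipeline under test — behaves as it would on a real array; early
designs with a 20% regulated fraction on small classes measurably
compressed planted fold changes, which is a property of quantile
normalization itself, not a bug.

## Realism and limits

The generator is additive-Gaussian on log2 intensities with a global
per-feature dosage step; it does not model probe saturation,
intensity-dependent variance, batch effects, or partial XCI escape
(escape is all-or-nothing at `ts_dosage_factor`). miRNA decoys are
uniform rather than seed-sequence-derived, so decoy structure is
unclustered. Sponge–target coupling is linear in log2 with a single
`beta`; competition among multiple targets of one miRNA pool is not
modeled. These simplifications are intentional: they keep every planted
effect analytically checkable (at `sigma = 0` the pipeline's DE calls
must equal the planted set *exactly*, and sponge–target correlations are
exactly 1).

## Recovery characteristics

Because all XCI-escaping sponges share the same genotype-dosage signal,
correlation alone cannot tell two escape sponges apart; false pairings
are controlled not by the correlation threshold but by the sparsity of
miRNA sharing — hence the large miRNA universe and small per-circuit
miRNA counts. With 10 lines per genotype, `beta = 0.9`, `sigma = 0.3`,
30 planted circuits and 5:1 decoys, recovery across five seeds averages
~0.98 sensitivity at ~0.04 false-discovery proportion. Per-seed values
fluctuate (a single missed circuit at 30 planted is 0.033 of
sensitivity), so the package's self-check evaluates the *mean over
seeds*, a deliberate robustness choice documented in the acceptance
tests.

# Numerical choices

* All statistics use exact distribution functions from `stats`
  (`pt`, `phyper`); BH adjustment delegates to `p.adjust`.
* Quantile normalization, correlation thresholding and DE calling are
  deterministic; the only randomness in the package is the generator's,
  and it is fully governed by `sim_config(seed = ...)`.
* Run directories are byte-reproducible: numeric output is formatted
  with `%.6g`, full-precision round-trip files use `%.17g`, files are
  written through binary connections with `\n` line endings, and the
  stage log carries no timestamps. The acceptance suite pins a golden
  run by md5.
* PCA uses `svd()` on the centered sample-by-feature matrix with the
  sign of each component fixed by making its largest-magnitude loading
  positive, so scores are reproducible across runs.
* Hierarchical QC clustering uses `1 - PCC` distance with average
  linkage; dendrograms export to Newick via `ape`.

# Running the pipeline

```{r, eval = FALSE}
ds <- generate_dataset(sim_config(seed = 1))
dir <- tempfile("bundle")
write_synthetic_bundle(ds, dir)
# write a YAML config pointing at the bundle, then:
res <- run_pipeline(file.path(dir, "config.yaml"), tempfile("run"))
score_recovery(res$circuits, ds$truth)
```

The same entry points are exposed as a command-line tool at
`system.file("cli", "cernet.R", package = "cernet")` with `simulate`,
`run`, `targets` and `qpcr` subcommands, and
`scripts/acceptance.R --seed <int> --out <path>` reproduces the
package's headline numbers as a JSON report.
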
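---
title: "Methods: allele-specific expression analysis of reciprocal F1 hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression analysis of reciprocal F1 hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hybridASE)
```

## The biological setting

*Caenorhabditis briggsae* (a selfing hermaphrodite species) and
*C. nigoni* (an outcrossing gonochoristic species) produce viable F1 female
hybrids in both crossing directions: **BN** (C. briggsae father x C. nigoni
mother) and **NB** (C. nigoni father x C. briggsae mother). Because the two
genomes are diverged enough for most RNA-seq reads to map uniquely to one
parental genome, expression in a hybrid can be resolved per haplotype:
each hybrid sample yields a *C. briggsae*-allele and a *C. nigoni*-allele
count column for every one-to-one ortholog pair. Together with the two
parental transcriptomes this supports three classifications per ortholog
pair:

* **Inheritance mode** — where the hybrid's *total* expression sits relative
  to the parents: `no_change`, `cbr_dominant` / `cni_dominant` (matching one
  parent), `additive` (intermediate), `overdominant` / `underdominant`
  (transgressive, outside the parental range).
* **Regulatory mode** — following the classical cis/trans framework:
  `conserved` (no significant divergence between parents or between alleles
  within the hybrid), `cis` (the allele ratio inside the hybrid mirrors the
  parental expression ratio, so the divergence travels with the allele), and
  `trans` (the allele ratio deviates from the parental ratio, implicating
  the hybrid's cellular environment).
* **Imprinting** — parent-of-origin expression: a gene whose maternal (or
  paternal) allele carries at least 75% of the pair's expression in *both*
  reciprocal hybrids.

The default experimental design mirrors the study layout the package
emulates: three *C. nigoni* replicates and two replicates each of
*C. briggsae*, BN and NB, with each hybrid replicate split into two
haplotype columns — 13 count columns in total.

## The statistical engine

Every classification consumes the same two-group differential-expression
core (`run_de()`):

1. **Normalization.** Per-column library sizes are totals over the full
   pre-filter table. Trimmed-mean-of-M-values factors (`tmm_factors()`;
   30% trim on log-ratios, 5% on average abundance, precision-weighted)
   correct residual composition bias; effective library sizes are
   `lib_size * factor`.
2. **Expression filter.** A pair is *expressed* iff its CPM exceeds 2
   (strictly) in at least 4 of the 13 haplotype-level columns
   (`filter_expressed()`). The filter sentence it implements is read as
   "keep iff CPM > 2 in >= 4 columns", the only reading consistent with the
   13-column layout.
3. **Dispersion.** Counts follow a negative binomial with variance
   `mu + phi * mu^2`. The common `phi` maximizes the conditional
   log-likelihood given each gene's within-group total on library-size
   equalized counts; per-gene values maximize the gene's own conditional
   likelihood plus the common curve weighted as 10 prior degrees of freedom
   (`estimate_dispersion(prior_df = 10)`, configurable). With no replicated
   group, `phi` falls back to 0.05 with a warning.
4. **Exact test.** Columns are scaled to the geometric-mean effective
   library and summed into group pseudo-sums (rounded to integers). The
   test conditions on `s = sum_a + sum_b`; group totals are NB with means
   proportional to replicate numbers and dispersion `phi / n`. The
   two-sided p-value sums the conditional probabilities of all splits no
   more probable than the observed one, with relative tolerance `1 + 1e-7`
   (the probability-mass rule; at `phi = 0` this is the exact binomial
   two-tail). `s = 0` gives p = 1 by convention.
5. **Multiplicity.** Benjamini-Hochberg step-up FDR across genes
   (`bh_fdr()`).

Log2 fold changes are `log2(mean CPM_a + 0.5) - log2(mean CPM_b + 0.5)` on
effective library sizes; the 0.5 prior keeps them finite and is
configurable (`prior_count`).

## Thresholds

| parameter | default | units / role |
|---|---|---|
| `alpha_fdr` | 0.05 | FDR cutoff, inheritance and regulatory rules (strict `<`) |
| `alpha_raw` | 0.05 | raw-p cutoff, allele-level and TE contrasts |
| `lfc_cut` | 1 | log2 fold-change cutoff (strict `>` for "changed") |
| `reg_delta` | 1.8 | log2 units; max `|ratio_P - ratio_H|` for a cis call |
| `imprint_cutoff` | 0.75 | minimum allele fraction, inclusive, both hybrids |
| `imprint_min_total` | 5 | combined CPM floor below which fractions are no-calls |
| `min_cpm`, `min_columns` | 2, 4 | expression filter |
| `enrich_alpha`, `lor_cut` | 0.01, 0.4 | chromosome enrichment flags |
| `te_min_cpm`, `te_min_columns` | 1, 2 | TE family filter (inclusive `>=`) |

Conventions adopted where the source material is ambiguous:

* The FDR (not the raw p-value) is used in every inheritance clause; the
  surrounding text interchanges "P-value" and "FDR" but states the cutoff
  as FDR = 0.05. Allele-level contrasts (shared up-regulated allele sets,
  TE families) use the raw p-value, matching their stated convention.
* The regulatory divergence threshold 1.8 is interpreted on the log2 scale,
  since both ratios are plotted and compared in log2 units.
* The within-hybrid allele contrast used by the regulatory classifier is BH
  FDR-adjusted ("no significant DEGs (FDR > 0.05)" is the conserved rule).
* Reciprocal-best-hit ranking uses the bit-score-like `score` column; equal
  top scores between different subjects disqualify a gene (conservative).
  "Same position on the chromosome" for representative-gene selection means
  any coordinate overlap, with overlap chains resolved transitively and
  span ties broken by the lexicographically smaller gene id.
* Maternal/paternal *leaning* (as opposed to imprinting) is not
  operationally defined in the source; the mean maternal-allele fraction
  `((1 - f_BN) + f_NB) / 2` compared with 0.5 is adopted.
* The imprinting expression floor (combined 5 CPM) is this package's own
  guard: allelic fractions of near-zero counts are noise.

## The synthetic-data generator

`scenario_config()` + `build_truth()` + `simulate_counts()` generate
allele-resolved experiments with known truth. Class-conditional rules
(log2-CPM scale, before noise): `no_change` genes have parental divergence
`d = 0` and no hybrid offset; dominant genes sit exactly at one parent's
level with `|d| >= effect_size`; additive genes at the parental log2
midpoint; transgressive genes `effect_size` beyond the parental extreme.
Regulatory rules: `conserved` forces `d = 0` and allele ratio `r = 0`;
`cis` sets `r = d`; `trans` sets `r = 0` with `|d| >= effect_size`.
Divergence magnitudes are `effect_size + Exp(mean 0.5)` so `|d| >=
effect_size` holds without piling every gene onto the boundary.

Three design choices deserve explanation:

* **Joint feasibility.** `conserved` regulation is only realizable on
  `no_change` genes (a transgressive gene with `d = r = 0` would be
  invisible to the regulatory contrasts yet regulated in trans — a
  contradiction), and `cis`/`trans` require parental divergence. Mixes that
  demand an impossible pairing are rejected with an error naming the pair;
  feasible mixes are realized by constrained assignment, so the conserved
  fraction equals the `no_change` fraction.
* **Balanced divergence signs.** Within each inheritance class, half the
  divergent genes favor each species. An uncontrolled sign imbalance is a
  composition bias that no global scaling method can distinguish from a
  true shift — with 5/6 of genes strongly divergent, a random imbalance
  shifts the trimmed-mean normalizer by several tenths of a log2 unit and
  would make every downstream call systematically wrong. Real data are far
  less divergent than the recovery scenarios, so this choice removes a
  simulation artifact rather than an observed biological feature.
* **Imprinted genes come from the `no_change`/`conserved` pool**, since the
  imprint overrides the hybrid allele ratio (maternal or paternal fraction
  0.9 by default, comfortably beyond the 0.75 call threshold) and would
  falsify a `cis`/`trans` truth label.

Counts are NB draws per column (`variance = mu + phi mu^2`; Poisson at
`phi = 0`) with expected CPM from the truth table and per-sample library
sizes `Normal(lib_size_mean, cv * mean)`, truncated and rounded. Hybrid
replicate reads split between haplotype columns by the gene's allele
ratio. A single root seed feeds derived sub-streams (truth, library sizes,
counts, gene sets), so every output is byte-reproducible.

**What the generator does not emulate:** read-level mapping ambiguity (it
plants perfectly haplotype-resolved counts), gene-length and GC effects,
correlated biological replicates, unbalanced allele-specific mappability,
partially imprinted or isoform-specific effects, and the long-tailed
expression distributions of real transcriptomes (baselines are uniform on
log2-CPM [3, 10]). Recovery results therefore demonstrate correctness of
the statistical pipeline under its own assumptions, not expected accuracy
on real libraries.

## Numerical choices and degenerate inputs

* Exact-test enumerations run over all splits `k = 0..s`; above
  `s = 2e5` the sum is restricted to a `1e-14`-quantile window (always
  including the observed split) and renormalized.
* Dispersion optimization evaluates the conditional likelihood on a fixed
  60-point log grid (1e-4 to 5, plus a near-zero point), refines the common
  value by golden-section search between the bracketing grid points, and
  takes per-gene maxima on the grid.
* TMM: reference column is the one whose upper-quartile count fraction is
  closest to the mean; genes with a zero in either column are excluded;
  all-zero columns get factor 1 with a warning; factors are normalized to
  geometric mean 1.
* `fisher_2x2()` reports the sample odds ratio `(ad)/(bc)` with the
  Haldane-Anscombe 0.5 correction iff any cell is zero (so the `|log2 OR| >
  0.4` flag is always evaluable); the all-zero table returns p = 1 with an
  `NA` odds ratio and a warning.
* Missing statistics exclude a pair from classification with a warning —
  never a silent default category.
* Constant vectors make the rank correlation undefined: `NA` plus warning.
* Single-chromosome enrichment input yields degenerate tables and a
  warning, no flags.

## Problem sizes used by the tests

Recovery experiments run at 3,000 ortholog pairs (the six inheritance
classes at 500 genes each, effect 2.0, `phi = 0.05`; regulatory recovery at
parental divergence 2.5), null calibration at 5,000 genes, and imprinting
at 500 pairs with 50 planted imprints. These sizes give per-class recall
estimates with standard errors under 0.02 while keeping a full run in the
low minutes on one CPU. The imprinting scenario draws baselines from
log2-CPM [5, 10]: the 75% fraction rule presupposes detectably expressed
genes, and at trace expression the fraction estimator's sampling noise
(not the rule) dominates the outcome.

## Known limitations

* The exact test on pseudo-sums reproduces the intent, not the bit-level
  behavior, of quantile-adjusted conditional ML pipelines; p-values agree
  with the classic small-p exact test to ~1e-6 in cross-checks.
* The regulatory classifier collapses the compound categories
  (cis + trans, compensatory) of the wider literature into three classes.
* Chromosome enrichment treats pairs as exchangeable across chromosomes;
  gene clustering or co-expression would make the Fisher tests optimistic.
* Imprinting calls are detection-only; validation against external
  imprinted-gene databases is out of scope.
* Ka/Ks values, when supplied, are consumed as precomputed annotations and
  only joined to categories; the package does not compute them.
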
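---
title: "Screening miRNA-target correlation rewiring between tumor and normal tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening miRNA-target correlation rewiring between tumor and normal tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrewire)
```

## The question and the model

MicroRNAs repress their target mRNAs, so in healthy tissue a functional
miRNA-target pair tends to show a *negative* Pearson correlation across
samples. This package implements a screen for pairs whose anticorrelation is
present in normal tissue and lost ("rewired") in tumors. The analysis is a
chain of simple, auditable steps rather than a single model fit:

1. **Normalization.** Raw read counts are scaled by median-of-ratios size
   factors: for sample $j$,
   $s_j = \mathrm{median}_i \, k_{ij} / (\prod_v k_{iv})^{1/n}$, the median
   taken over features with positive counts in every sample. Expression
   enters all downstream steps as $\log_2(k_{ij}/s_j + 1)$; group means for
   filtering and fold changes use the pre-log normalized scale.
2. **Differential expression.** Each feature is compared between healthy
   controls (HC, adjacent normal tissue) and each tumor stage group (Early =
   stage I-II, Advanced = stage III-IV). The fold change is the ratio of
   group means with the pseudocount,
   $\log_2\!\big((\bar k_T + 1)/(\bar k_{HC} + 1)\big)$, and the p-value a
   two-sided Welch test on the log2 values, adjusted by Benjamini-Hochberg
   within each comparison. A feature is called up when $\log_2\mathrm{FC} >
   1$ and $p_{adj} < 0.05$ (down symmetrically; inequalities strict), kept
   only when the direction agrees in *both* comparisons, and removed when it
   is low-abundant (group mean of normalized counts below 5: the HC mean
   gates down-calls, the compared tumor group's mean gates up-calls).
3. **Critical pairs.** Candidate pairs are the experimentally validated
   miRNA-target interactions whose members are both differentially
   expressed. A candidate is *critical* when its Pearson correlation over
   healthy-control samples satisfies $r < -0.2$ and $p < 0.05$ (strict,
   two-sided t-based p with $n-2$ degrees of freedom).
4. **Rewiring statistic.** For patients contributing both a tumor and an
   adjacent normal sample, each critical pair gets $r$ over the paired
   normal samples and $r$ over the same patients' tumor samples;
   $\Delta r = r_{tumor} - r_{normal} > 0$ flags weaker anticorrelation in
   tumor. Restricting both correlations to the same patients removes the
   sample-size and inter-patient confounding that plagues the unpaired
   contrast.
5. **Pan-cancer aggregation.** Per-cancer results aggregate into frequency
   tables (how many cancer types call a feature DE, or a pair critical) and
   a bipartite miRNA-gene network of the pairs seen in at least three
   cancer types, exportable as SIF, GraphML or a lossless edge list.
6. **Enrichment.** Target genes of critical pairs are tested against
   user-supplied gene sets by the upper-tail hypergeometric test; raw
   $p < 0.05$ selects terms, and a Bonferroni column is reported alongside.

## Tunable thresholds

All cut-offs live in one `threshold_config()` object (overridable from a
YAML file via `read_config()`):

| parameter            | default | meaning                                             |
|----------------------|---------|-----------------------------------------------------|
| `lfc_cut`            | 1       | cut on \|log2 fold change\|, log2 units             |
| `padj_cut`           | 0.05    | BH-adjusted p cut for DE                            |
| `abundance_min`      | 5       | minimum group mean, normalized (pre-log) counts     |
| `r_cut`              | -0.2    | healthy-control Pearson r must fall below this      |
| `p_cut`              | 0.05    | correlation p cut                                   |
| `min_pair_frequency` | 3       | cancer types required for a pan-cancer network edge |
| `enrich_p_cut`       | 0.05    | raw-p cut for enrichment terms                      |
| `pseudocount`        | 1       | added inside the log2 transform and fold changes    |

Every inequality is strict, mirroring the symbols the thresholds were
defined with; values sitting exactly on a cut are rejected, and the boundary
behaviour is tested.

## Design choices where the design was open

- **DE engine.** The differential test is a Welch t-test on log2-normalized
  values, not a negative-binomial GLM. The scientific contribution here is
  the downstream correlation screen; the DE step only has to rank obvious
  tumor/normal differences, and the Welch test on log2 counts does that
  reliably at these effect sizes. The operation is isolated behind
  `de_test()` so an NB-based test can be swapped in without touching the
  screen.
- **Abundance-filter scale.** "Group mean below 5" is evaluated on
  normalized pre-log counts (the convention of size-factor-based tools); the
  alternative reading (raw counts) would make the filter depend on
  sequencing depth. For up-calls the compared tumor group's mean gates by
  default; `abundance_scope = "either"` switches to dropping an up-call when
  either tumor group is low.
- **"Weaker in tumor" adjudication.** The paired-design $\Delta r$ is the
  default because it is immune to the unequal sample sizes of the HC and
  tumor groups; `weaker_mode = "unpaired"` exposes the fallback (mean of
  early/advanced r against HC r).
- **Multiple aliquots.** When a patient owns several tumor or normal
  samples, the lexicographically smallest sample id is selected -
  deterministic without relying on metadata the analysis does not use.
- **TNS samples** (tumors lacking stage annotation) are excluded from the
  stage-based DE comparisons and unpaired correlations but remain eligible
  as the tumor member of a patient's pair, where stage is irrelevant.
- **Pair p-values are not multiplicity-adjusted in the screen** (the screen
  is defined on raw p); a BH column over the candidate HC p-values is
  emitted for transparency and never gates.
- **Node regulation in the network** is "mixed" when a feature is up in
  some cancers and down in others - lossless, rather than majority-vote.
- **Enrichment universe** defaults to the genes present in the expression
  matrix intersected with the annotation (standard over-representation
  practice), not the whole annotation; Bonferroni multiplies by the number
  of terms actually tested (those overlapping the query).
- **Pair identifiers are matched as exact strings**; no miRNA-arm (-3p/-5p)
  or gene-alias harmonization is attempted, as identifier curation is a
  data-preparation task outside the method.

## The synthetic cohort generator

Real multi-cancer read-count cohorts are too large to ship, so the package
carries a seeded generator, `generate_cohort()`, whose output has exactly
the statistical structure the screen assumes:

- **Marginals.** Counts are negative binomial with feature-specific
  baseline means drawn log-uniformly on `mean_log_range` (default
  $e^3 \approx 20$ to $e^8 \approx 3000$, spanning moderately to highly
  expressed features), common dispersion 0.15 (a typical bulk RNA-seq
  value), and a log-normal per-sample library-size factor (sigma 0.25).
- **Coupling.** A Gaussian copula imposes dependence: each feature owns a
  latent standard-normal vector; a planted pair's gene latent is
  $\rho z_{miRNA} + \sqrt{1-\rho^2}\,\varepsilon$ with $\rho =$
  `rho_normal` in normal samples and `rho_tumor` in tumor samples, then
  latents map through the normal CDF to NB quantiles. This gives exact
  marginal control with tunable dependence; the NB quantile step attenuates
  the latent $|\rho|$ somewhat (at $\rho = -0.75$ the realized sample
  correlation is about $-0.7$), and ties at low means are possible and
  accepted.
- **Planted truth.** Pair miRNAs are up- and pair genes down-regulated in
  tumor by $2^{\pm 1.5}$, so planted pairs pass the DE arm; decoy pairs
  (equal in number, listed in the emitted interaction database, fully
  uncoupled) carry the opposite orientation, so the anticorrelation screen
  is the step that must reject them. Balancing up- against down-shifts
  keeps the count composition symmetric, which matters because
  median-of-ratios size factors lose their anchor when most features of a
  small matrix shift the same way. For the same reason planted miRNAs each
  regulate several target genes (`targets_per_mirna`, default 3) - as real
  miRNAs do - so only a third of the 60-feature miRNA matrix is shifted at
  all. Standalone DE features, disjoint from all pair members, let tests
  exercise the DE screen independently of the correlation screen.
- **Paired design.** The first `n_paired_patients` patients own one normal
  and one tumor sample each; remaining samples belong to unpaired patients.
  Tumor samples carry stage labels alternating I/II (Early) and III/IV
  (Advanced).
- **Determinism.** One global seed drives independent substreams keyed by
  (stream, element index), so the same configuration regenerates
  bit-identical cohorts and enlarging a cohort does not reshuffle existing
  draws.

The reference configuration used throughout the test suite
(`default_recovery_config()`) is 300 genes, 60 miRNAs, 50 normal / 60
early / 40 advanced samples, 40 paired patients, 30 planted pairs with
$\rho_{normal} = -0.75$ and $\rho_{tumor} = -0.05$, and planted
$|\log_2\mathrm{FC}| = 1.5$. These sizes are the package's own choice of a
realistic single-cancer cohort; they keep the whole recovery suite fast
while giving the Welch test and the correlation screen power near 1 at the
planted effect sizes.

```{r recovery}
cohort <- generate_cohort(default_recovery_config())
res <- run_single_cancer(cohort$mrna, cohort$mirna, cohort$samples, cohort$db)
res
key <- function(df) paste(df$mirna_id, df$gene_id)
mean(key(cohort$truth$planted_pairs) %in% key(res$critical_pairs))  # recovery
pp <- res$paired_pairs
c(mean(pp$r_normal), mean(pp$r_tumor), mean(pp$weaker_in_tumor))
```

### What passing on synthetic data does and does not show

The generator emulates the features the method's correctness depends on:
NB marginals with library-size confounding, group-specific coupling,
planted fold changes, paired samples, stage labels. It does **not** emulate
batch effects, miRNA-arm annotation ambiguity, isoform structure, copy
number or methylation drivers of expression, or the long right tail of real
library-size variation. Recovery on the reference cohort therefore
validates the *implementation* - that each step computes what it claims and
their composition finds exactly the planted structure - not the biological
sensitivity of the thresholds on any real cohort.

## Numerical conventions and degenerate inputs

- Correlations are undefined (explicit `NA` records, never errors or silent
  drops) when fewer than 3 complete sample pairs exist or a vector is
  constant; undefined correlations fail the critical screen.
- A feature constant in both DE groups gets $p = 1$ when the group means
  agree and $p = 0$ otherwise.
- $|r| = 1$ maps to $p = 0$ rather than a division-by-zero in the t
  transform.
- Size factors require at least one all-positive feature row; otherwise the
  error instructs the caller to prefilter or add pseudocounts. Rows
  containing a zero are excluded from the median, not from the matrix.
- All output tables are written with fixed column orders and deterministic
  formatting, so identical inputs produce byte-identical files.

## Known limitations

- The Welch-on-log2 DE test is less powerful than an NB GLM at very low
  counts; with the abundance filter at 5 normalized counts this regime is
  largely excluded, but results near the filter boundary inherit the
  approximation.
- The hypergeometric enrichment ignores gene-length and expression-level
  selection biases and does no ontology graph propagation.
- Pan-cancer aggregation treats identifier strings literally; pairs that
  differ only by arm suffix or gene alias count as distinct.
- The screen is correlational: a critical pair losing anticorrelation in
  tumor is a candidate for regulatory rewiring, not evidence of a causal
  mechanism.
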
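# mirrewire

Screening for miRNA–target pairs whose negative correlation in normal
tissue is lost in tumors.

## The problem

MicroRNAs repress their target mRNAs, so across healthy-tissue samples a
functional miRNA–target pair tends to be *anticorrelated*. In tumors this
coupling is frequently disrupted. `mirrewire` implements an integrated
miRNA/mRNA read-count pipeline that makes this rewiring measurable, per
cancer type and pan-cancer:

1. median-of-ratios size-factor normalization and log2 transform;
2. differential expression of miRNAs and genes between healthy controls
   (HC) and early (stage I–II) / advanced (stage III–IV) tumors — Welch
   test on log2 values, BH adjustment, |log2FC| > 1, padj < 0.05,
   low-abundance filter (group mean of normalized counts < 5), and a
   direction-consistency rule across the two comparisons;
3. **critical pairs**: experimentally validated miRNA–target interactions
   (miRTarBase/miRecords-style tables) whose members are both DE and whose
   Pearson correlation in healthy controls satisfies r < −0.2 with
   p < 0.05;
4. **rewiring statistic**: on patients contributing both a tumor and an
   adjacent normal sample, Δr = r(paired tumor) − r(paired normal); Δr > 0
   means the anticorrelation weakened in tumor;
5. pan-cancer frequency tables and a bipartite miRNA–gene network of pairs
   critical in ≥ 3 cancer types (SIF/GraphML/edge-list export);
6. hypergeometric over-representation analysis of critical-pair target
   genes against GMT gene sets.

It is aimed at transcriptomics researchers with per-cancer raw count
matrices (features × samples), a sample annotation table (sample, patient,
tissue, stage) and a validated-interaction table. A seeded synthetic-cohort
generator with planted ground truth (Gaussian-copula negative-binomial
counts, group-specific coupling, planted fold changes, paired patients) is
included for validation and examples.

## Worked example

```r
library(mirrewire)

cohort <- generate_cohort(default_recovery_config())
res <- run_single_cancer(cohort$mrna, cohort$mirna, cohort$samples, cohort$db)
res
#> cancer_result: 150 samples (50 HC), 80 DEGs, 20 DEMs, 30 critical pairs, 40 paired patients

key <- function(df) paste(df$mirna_id, df$gene_id)
mean(key(cohort$truth$planted_pairs) %in% key(res$critical_pairs))
#> [1] 1
round(c(r_normal = mean(res$paired_pairs$r_normal),
        r_tumor  = mean(res$paired_pairs$r_tumor),
        weaker   = mean(res$paired_pairs$weaker_in_tumor)), 2)
#> r_normal  r_tumor   weaker
#>    -0.73     0.01     1.00
```

The cohort plants 30 anticorrelated pairs (latent ρ −0.75 in normal, −0.05
in tumor) among 30 uncoupled decoy pairs; the run recovers all 30 planted
pairs as critical, rejects the decoys, and every recovered pair shows
weaker anticorrelation in the paired tumor samples (mean r −0.73 in normal
vs 0.01 in tumor).

The same analysis as a scripted workflow, writing all tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohorts.R   # three seeded cohorts + ground truth
Rscript analysis/02_single_cancer.R      # per-cohort DE + critical pairs + Δr
Rscript analysis/03_pan_cancer.R         # frequency tables + bipartite network
Rscript analysis/04_enrichment.R         # ORA of critical-pair targets
```

Stage 2 prints, per cohort, e.g.:

```
SIM1: 80 DEGs, 20 DEMs, 30 critical pairs | planted recovery 100%,
weaker-in-tumor 100%, mean r normal -0.73 vs tumor 0.01 -> results/SIM1
```

Output tables (fixed column order, TSV): per-comparison DE records,
consistent DE status, `critical_pairs.tsv` (r/p/n per group, optional
per-stage), `paired_pairs.tsv` (r_normal, r_tumor, delta_r,
weaker_in_tumor), `pan_features.tsv`, `pan_pairs.tsv`, `network.sif`,
`network.graphml`, `network_edges.tsv`.

Thresholds are bundled in `threshold_config()` and can be read from YAML
with `read_config()`; the defaults are the ones listed above.

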
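# methdelta

Intra-individual differential methylation analysis for paired RRBS
experiments.

## The problem

Reduced representation bisulfite sequencing (RRBS) yields, per sample,
methylated/unmethylated read counts at hundreds of thousands of CpG
sites. In longitudinal designs where each individual is sampled twice —
before and after an exposure — two questions compete: what does the
methylome say about *development* (time/age), and what does it say about
the *experience* in between? Absolute methylation levels carry a strong
age signature but also large inter-individual variance; the imprint of an
experience can be easier to see in the **intra-individual change**

```
delta(r, i) = log2( (P10% + eps) / (P2% + eps) )
```

for region `r` and individual `i`, which cancels everything stable within
an individual (including cohort/batch offsets shared by both samples).

methdelta implements the full pipeline around this statistic:

1. **DMS calling** — per individual, a two-sided Fisher exact test on the
   2×2 methylated/unmethylated count table at P2 vs P10 for every CpG
   covered ≥ 10× in both samples, with Benjamini–Hochberg FDR control
   within the individual (DMS: q < 0.05).
2. **DMR coalescing** — sites shared by ≥ 2 individuals of either group,
   merged by single-linkage chaining at ≤ 100 bp.
3. **Matrices** — DMR × sample percent matrix (count-weighted region
   levels) and the DMR × individual delta matrix; linear cohort batch
   correction of the absolute levels.
4. **Decomposition** — exact-SVD PCA (samples as observations, regions
   centred not scaled), per-component folded AUC separation scores for
   age and experience, k-means row clustering, and selection of the
   regions driving the experience-separating delta component by loading
   threshold (±2.5e-2).
5. **Gene analysis** — Homer-style midpoint annotation against a GTF
   (promoter-TSS/TTS/exon/intron/intergenic, 20-kb TSS rule) and
   hypergeometric enrichment against user-supplied GMT gene sets.
6. **Simulation** — a beta-binomial generator of the full paired
   two-cohort design (19 individuals: 6+5 and 4+4 control+LBN) with
   ground-truth age/experience effect labels, used for recovery
   evaluation (`evaluate_recovery`).

Input formats: Bismark-style six-column coverage files, a CSV sample
manifest, GTF gene models, GMT gene sets; outputs are TSV/BED/JSON.

## Worked example

Simulate the default design and run the analysis in memory:

```r
library(methdelta)

cfg <- simulation_config(n_cpgs = 20000, seed = 1)
experiment <- generate_experiment(cfg)
res <- analyse_experiment(experiment$tables, experiment$manifest,
                          verbose = TRUE)
#> DMS: 20000 sites tested per individual (median), 909 significant (median)
#> DMR: 2427 shared sites -> 2325 regions
#> matrix: 2325 regions x 38 samples (0 dropped)
#> PCA: absolute EVR 0.16/0.04/0.04; delta EVR 0.08/0.07/0.06
#> selection: PC1, 197 positive / 231 negative regions

round(res$aucs$age_absolute, 3)
#>   PC1   PC2   PC3   PC4   PC5   PC6   PC7   PC8   PC9  PC10
#> 1.000 0.535 0.510 0.512 0.510 0.518 0.507 0.510 0.504 0.512

round(res$aucs$experience_delta, 3)
#>   PC1   PC2   PC3   PC4   PC5   PC6   PC7   PC8   PC9  PC10
#> 1.000 0.622 0.622 0.544 0.544 0.511 0.511 0.533 0.533 0.511

rec <- evaluate_recovery(res$selected, res$regions, experiment$truth)
sprintf("selection on delta PC%d: precision %.2f, recall %.2f, base rate %.3f",
        res$separating_pc, rec$precision, rec$recall, rec$base_rate)
#> "selection on delta PC1: precision 0.25, recall 0.56, base rate 0.084"
```

Reading the numbers: 2,325 DMRs were called from 20,000 simulated CpGs.
The first absolute-level component separates P2 from P10 perfectly (age
AUC 1.0, the developmental signature); the first delta component
separates control from LBN individuals perfectly (experience AUC 1.0).
Thresholding that component's loadings at ±0.025 selects 428 regions in
which true experience-effect regions are enriched three-fold over their
base rate among all DMRs (precision 0.25 vs base rate 0.084), at 56%
recall.

`run_pipeline(out_dir, sim_config = cfg)` performs the same analysis and
writes every stage's artifact (BED, TSVs, JSON run manifest); with
`manifest_path =` it starts from coverage files on disk instead, and with
`gtf = `/`gmt = ` it adds gene association and enrichment tables.

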
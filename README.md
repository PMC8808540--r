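# chipscape

Comparative analysis of cell-type-resolved histone-modification ChIP-seq.

## The problem

Sorting a tissue into its constituent cell populations before profiling
histone marks (H3K27ac for active enhancers, H3K4me3 for active TSSs)
makes it possible to ask *which cell type* carries the epigenomic
consequences of a germline condition — for example, how breast basal,
luminal progenitor, mature luminal and stromal fractions differ between
*BRCA1*-mutation carriers (MUT) and non-carriers (NC). `chipscape`
implements the full post-alignment analysis chain for such designs, for
analysts who have aligned reads (BED) and want a tested, reproducible
path from reads to biology:

* input-subtracted, depth-normalized signal in 100-bp windows:
  `(chip/N_chip − input/N_input) × 10⁶`;
* QC by fraction of reads in peaks (FrIP) and the peak-count rule
  (technical replicates with too few called peaks are discarded);
* a Poisson local-background peak caller (or imported narrowPeak files),
  blacklist filtering, majority-rules consensus per group
  (strict majority, `floor(n/2)+1` replicates) and a merged master set;
* a negative-binomial Wald test for differential modification
  (median-of-ratios normalization, trend-shrunk method-of-moments
  dispersion, selection at fold-change ≥ 2 and FDR < 0.05);
* enhancer calling: summit ± 500 bp H3K27ac regions excluding promoters
  (TSS ± 500 bp), NC/MUT overlap (Venn), genomic-location annotation,
  ±150 kb GWAS-SNP proximity, nearest-gene change fractions;
* PWM motif enrichment (hypergeometric vs dinucleotide-shuffled
  background), condition-differential motifs, cell-type-specific TFs
  (p < 10⁻⁴ in exactly one cell type) and their cross-condition
  preservation matrix;
* a fully seeded synthetic-study generator with planted ground truth
  (peaks, folds, enhancers, motifs, SNP enrichment) that exercises and
  validates every stage.

See `vignettes/methods.Rmd` for the model, parameter meanings and design
decisions.

## Worked example

Simulate the reference synthetic study (2 × 5 Mb genome, 4 cell types ×
2 conditions × 3 replicates, 2 × 10⁵ reads/sample) and run the whole
pipeline:

```r
library(chipscape)

study <- simulate_study(sim_params(seed = 17), "study/")
cfg   <- synthetic_config("study/", "out/", seed = 1)
rep   <- run_pipeline(cfg)
print(rep)
#> <pipeline_report> 32 samples, 1802 master regions
#>   BC: 88 up / 85 down differential regions
#>   LP: 87 up / 86 down differential regions
#>   ML: 85 up / 83 down differential regions
#>   SC: 83 up / 79 down differential regions
```

Per cell type ~90 regions in each direction are expected: the generator
plants 30 fold-4 differential regions per direction plus 60
condition-exclusive regions per condition. Recovery against the planted
truth:

```r
str(score_recovery(rep, study$truth))
#> $ peak_recall               : num 0.982
#> $ peak_precision            : num 1
#> $ enhancer_jaccard_min      : num 0.973
#> $ promoter_violations       : num 0
#> $ differential_recall       : num 0.854
#> $ differential_sign_accuracy: num 1
#> $ snp_fraction_nc_bc        : num 0.0934
#> $ snp_fraction_mut_bc       : num 0.169
#> $ gained_bc_from_lp         : int 1
#> $ gained_lp_from_bc         : int 0
```

Reading this: the caller recovers 98% of planted active regions with no
false peaks surviving blacklist/consensus; called enhancers match the
planted enhancer truth (overlap Jaccard ≥ 0.97 per cell type and
condition) and none touches a promoter window; 85% of the planted
fold-4 regions survive the full region-level chain (consensus →
counting → FC ≥ 2 & FDR < 0.05), every one with the correct sign (at the
count-matrix level the test's recall on planted fold-4 effects is 0.99,
measured by `scripts/acceptance.R`); MUT basal enhancers are
SNP-proximal about twice as often as NC basal enhancers (the planted
risk-locus excess); and the planted basal→luminal-progenitor motif shift
shows up as an asymmetric preservation matrix.

The same functions work on real data: point `pipeline_config()` at a
directory with `chrom.sizes`, `tss.bed`, `sample_sheet.csv`, `reads/`,
and optionally `genome.fa`, `blacklist.bed`, `snps.bed`, `pwms.txt`
(JASPAR-style), and use externally called narrowPeak files via
`read_regions()` where a production caller is preferred. A thin CLI
lives at `inst/scripts/chipscape.R`.

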
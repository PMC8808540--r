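---
title: "Methods: comparative ChIP-seq analysis across cell types and conditions"
author: "chipscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative ChIP-seq analysis across cell types and conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`chipscape` compares histone-modification ChIP-seq landscapes — typically
H3K27ac (active enhancers and promoters) and H3K4me3 (active TSSs) —
across FACS-sorted cell populations of one tissue (basal, luminal
progenitor, mature luminal and stromal fractions of breast tissue, in the
motivating design) and across two donor conditions, e.g. carriers (MUT)
and non-carriers (NC) of a germline *BRCA1* mutation. The pipeline starts
from aligned reads (BED intervals); trimming and alignment are upstream
concerns, and wet-lab steps are out of scope.

The analysis chain is: normalized signal → peak calling and QC →
majority-rules consensus and master set → negative-binomial differential
test → enhancer calling → motif enrichment and TF-specificity logic →
GWAS-SNP proximity. Every stage is exposed as an ordinary R function on
GRanges-based containers; `run_pipeline()` wires them together.

# Coordinates

All file formats are 0-based half-open (BED native). Internally regions
live in `GRanges` (1-based closed); the conversion happens exactly once,
in the readers/writers of `R/io.R`. Every boundary rule below is stated
in file coordinates and asserted in the tests in both conventions, so no
±1 drift can creep in. "Overlap" always means at least 1 bp: half-open
abutment does not count, for consensus building, promoter exclusion,
blacklist filtering and enhancer identity alike. This matches the default
sense of bedtools/DiffBind-style tooling; the minimum-overlap choice is
deliberately not a fraction because the upstream description of
"intersecting" regions gives none.

# Normalized signal

Signal is computed in fixed windows (default 100 bp) over the whole
genome. Reads are first extended by 100 bp on each side, so a 50-bp read
occupies 250 bp, a proxy for fragment occupancy. A window's coverage is
the number of (extended) reads overlapping it. The per-window signal is

    normalized signal = (chip / N_chip − input / N_input) × 10^6,

i.e. both tracks are scaled to reads-per-million before input
subtraction. Values can be negative where input exceeds ChIP; no floor is
applied. Two consequences are tested as invariants: rescaling a track's
counts and its read total together changes nothing, and swapping
chip/input flips the sign.

Sample similarity (the replicate-correlation heatmap) is Pearson
correlation of per-promoter signal, where a promoter window is
TSS ± 2 kb and the per-window entries are summed per gene. Summing versus
averaging is immaterial for Pearson at fixed window size; no log
transform is applied because the upstream procedure mentions none.
Correlations are annotated with conventional verbal bands
(high > 0.95, good > 0.9, fair > 0.75, low ≤ 0.75, poor < 0.6).

# Peak calling, QC, consensus

`call_peaks_poisson()` is a deliberately simple stand-in caller, not a
reimplementation of MACS2: per window the ChIP count is tested against a
Poisson rate `max(genome-wide input rate, local 10-kb input rate) ×
N_chip/N_input`; window p-values are BH-adjusted genome-wide; adjacent
significant windows merge; peaks under 200 bp are dropped; the summit is
the centre of the highest-count window (leftmost on ties). Externally
called narrowPeak files can be substituted at any point via
`read_regions()` — runs based on a production caller need no code change.

QC follows the peak-count rule: a technical replicate with fewer than
`min_peaks` called peaks is discarded (default 10 000, the appropriate
scale for a mammalian genome; `synthetic_config()` scales it to 300 for
the 10-Mb synthetic genome — the rule's intent is "a replicate that found
an order of magnitude fewer peaks than its siblings is broken", which is
scale-relative). Retained technical replicates of one cell sample are
pooled by summing coverage/concatenating reads; peak calling for
downstream analysis then happens per biological replicate.

Consensus per experimental group is majority-rules: overlap-connected
components (single linkage) are formed across the union of the
replicates' peaks; a component is valid if peaks from at least
`floor(n/2) + 1` distinct replicates contribute — a strict majority, so
n = 2 requires both. The consensus region is the union span of the
component, its summit inherited from the highest-scoring contributing
peak. The master set for counting is the overlap-merge of all groups'
consensus regions.

# Differential test

Reads are counted per master region (≥ 1 bp overlap) per biological
replicate. Depth normalization is median-of-ratios. The test is a
negative-binomial Wald test with the following concrete choices:

* **Dispersion.** Per-region method of moments on normalized counts,
  pooled across the two groups and floored at 1e-8; a log-linear
  mean–dispersion trend is fit on moment estimates pooled within 20
  mean-quantile bins (binned moments are nearly noise-free, unlike
  per-region ones); the working dispersion is the 50/50 linear blend of
  the per-region and trend values. This is intentionally not an
  empirical-Bayes MAP: the contract is calibrated error rates, not
  numerical identity with any specific tool.
* **Fold change.** log2 of the ratio of group means of normalized
  counts, with pseudo-count 0.5 for boundedness at zero. MUT is always
  the numerator.
* **Standard error.** Delta method through the NB variance function
  μ + αμ²: `Var(q̄_g) = Σ_j (μ_g/s_j + α μ_g²) / n_g²`, mapped to the
  log2 scale.
* **Reference distribution.** Student t with 4 × (n₁ + n₂ − 2) degrees
  of freedom rather than the normal. The 50/50 blend quarters the
  variance of the dispersion estimate entering the SE, which is
  equivalent to a variance estimate carrying four times the within-group
  degrees of freedom; with three replicates per group the normal
  reference is measurably anti-conservative (empirical type-I error
  ≈ 0.11 at nominal 0.05) while the moment-matched t reference is
  calibrated (≈ 0.05, verified in the acceptance suite on a 2000-region
  null simulation).
* **Selection.** |log2FC| ≥ log2(2) and BH FDR < 0.05 by default,
  partitioned by sign. Setting `fdr = 1` disables the FDR gate entirely
  (p-adjusted values can equal exactly 1).

The all-peak comparison reports, per cell type, the per-group medians of
mean normalized signal across master regions, the percent change of the
numerator median, and a two-sided paired t-test across regions (constant
differences are reported as p = 1).

# Enhancers

Enhancers are H3K27ac-high non-promoter regions: each consensus peak is
re-anchored to summit ± 500 bp (1 kb), and any window overlapping a
promoter (TSS ± 500 bp) by ≥ 1 bp is removed — a hard postcondition
asserted on every run. A summit exactly 1 kb from a TSS yields an
enhancer that abuts the promoter and is kept (half-open arithmetic).
Condition identity (the NC/MUT Venn) is ≥ 1 bp overlap of the 1-kb
windows, computed on overlap-connected union components so the Venn
classes partition cleanly; summits shift between conditions, so
exact-coordinate identity would be wrong.

Genomic-location annotation is a deliberate three-way simplification of
the finer categories annotation tools report: promoter vicinity (< 2 kb
between the enhancer edge and the nearest promoter-window edge, measured
in file coordinates) takes priority over genic (overlaps a gene span),
else distal intergenic. The contrasts of interest (promoter-vicinity
fraction, distal-intergenic fraction) survive this simplification; finer
exon/intron/UTR splits would be cosmetic on a synthetic gene model.

SNP proximity flags an enhancer when a SNP lies in
`[start − W, end + W)` with W = 150 kb by default — measured from the
region edges, inclusive left/exclusive right to match the half-open
convention. On the 10-Mb synthetic genome `synthetic_config()` scales W
to 5 kb: 123 SNPs with a 150-kb window would make essentially every
synthetic enhancer SNP-proximal and destroy the planted contrast, for
the same scale reason as the peak-count threshold.

Nearest-gene assignment measures distance from the region edges (0 if
the TSS is inside), breaking ties by smaller |distance|, then upstream
side, then lexicographic gene id — fixed here because annotation tools
disagree and the choice must be deterministic. Cell-type gene lists are
scored as "changed" when a gene is the nearest gene of ≥ 1 selected
differential region; the down-fraction uses a majority rule over the
gene's regions with ties counting as down.

# Motifs

PWMs are probability matrices (columns normalized, probabilities floored
at 1e-3 before log2-odds against a uniform background). A sequence hits
a motif when its best window score over both strands reaches 80% of the
motif's maximum achievable score; there is no universal PWM cutoff, so
the operating point is fixed and the recovery tests pin its behaviour.
Scanning is a vectorized pass over an integer-coded concatenation of the
sequence set (non-ACGT positions score −Inf), verified against an
exhaustive enumeration of all 4096 hexamers.

Enrichment is a one-sided hypergeometric test on sequences-with-≥-1-hit
against a dinucleotide-shuffled background (Altschul–Erickson Eulerian
shuffle, seeded, 2 copies per foreground sequence). Hypergeometric
counts were chosen over binomial background weighting because they are
exact and brute-force verifiable; repeat masking is moot on synthetic
genomes. Selection logic uses raw p-values against fixed alphas
(1e-4 throughout, the printed threshold for cell-type-specific TFs;
the condition-differential alpha is not printed upstream and defaults to
the same value, configurable), with BH q-values reported alongside for
transparency:

* condition-differential motifs: significant in one condition only;
* cell-type-specific TFs: significant in exactly one of the NC
  epithelial cell types (BC/LP/ML);
* preservation: the 3 × 3 matrix counting, for each pair (X, Y), the
  Y-specific motifs significant in MUT cell type X; the diagonal is
  "preserved", off-diagonals are cross-gains (the BC←LP entry is the
  basal-to-luminal-progenitor shift readout).

# The synthetic study generator

`simulate_study()` emulates the post-alignment inputs of a
four-cell-type × two-condition H3K27ac study at desk scale, with every
random draw under a fixed seed (Mersenne-Twister, integer paths only, so
regeneration is byte-identical across platforms). Reference conditions:
a 2 × 5 Mb genome at GC 0.41; 300 genes with ≥ 10 kb TSS spacing; 400
shared peaks, 120 cell-type-specific, 60 condition-differential (fold 4)
and 60 condition-exclusive peaks per class, widths uniform in
600–2000 bp, placed outside TSS ± 3 kb by a stick-breaking walk over the
free space (deterministic success, bounded retries); 2 × 10^5 reads per
sample at target FrIP 0.3; three biological replicates per condition;
123 SNPs of which 40% are planted within 2 kb of MUT-BC-exclusive
enhancer centres; 5 blacklist decoy regions receiving artificial pile-ups
in every ChIP sample. Design choices worth flagging:

* **Promoter activity.** Real H3K27ac also marks active promoters, and
  the replicate-correlation readout lives entirely in promoter windows,
  so the generator plants promoter peaks (TSS ± 400 bp) for 100
  housekeeping genes and 30 genes per cell type with per-(gene, cell
  type) Gamma(4) weights. Housekeeping weights are re-drawn per cell
  type, so cross-cell-type correlation stays visibly below
  within-sample correlation.
* **Condition-exclusive peaks** are the generator's mechanism for
  MUT-only/NC-only enhancers, the planted SNP excess, and the
  motif-shift scenario; in the `bc_lp_shift` scenario the LP cell-type
  motif is additionally written into MUT-BC-exclusive regions.
* **Differential fold** is applied symmetrically (×√fold on the
  favoured side, ÷√fold on the other) so the expected between-condition
  ratio equals the planted fold while both sides remain comfortably
  callable as peaks at default depth.
* **Replicate structure.** Biological replicates of a sample share the
  planted weights but receive an independent lognormal jitter
  (sd 0.15), which creates realistic NB overdispersion (α ≈ 0.02);
  technical replicates share the jitter and differ only in read
  sampling. Reads in active regions are placed Normal(centre, 75 bp);
  the enriched fraction is calibrated as
  `(FrIP_target − f_bg)/(1 − f_bg)`, with f_bg the genome fraction
  covered by active regions, because uniform background reads landing
  inside peaks also count toward measured FrIP.
* **Motif panel.** 20 synthetic consensus-dominated 12-mers (0.9 per
  consensus base) written in JASPAR-style text; at the 0.8 score
  threshold a single mismatch is rejected, keeping random hits near
  zero, which makes the enrichment logic sharp and the oracle tests
  exact. Synthetic motifs are used because no curated PWM collection is
  bundled; files and ids are labelled synthetic (`SYNTF*`).

What the generator does **not** model: GC bias, mappability, duplicate
reads, fragment-size variation, batch effects, and any sequence
composition structure beyond i.i.d. bases plus planted motifs. Passing
recovery tests therefore demonstrate the pipeline's logic and
calibration, not robustness to those real-data artifacts.

# Numerical and degenerate-input choices

* An all-zero input track makes the caller fall back to the genome-wide
  ChIP mean as background rate, with a warning.
* Missing summits (plain BED consensus) fall back to interval midpoints
  (`start0 + floor(width/2)`, the same convention as a narrowPeak −1
  summit), with a warning.
* Zero-count regions get p = 1; constant paired differences in the
  all-peak comparison get p = 1; a zero-variance sample is an error
  naming the sample.
* A count matrix with no all-positive region falls back to total-count
  size factors, with a warning.
* All problem sizes used by the test and acceptance suites (2000-region
  calibration matrices, the 10-Mb reference study, a 1.2-Mb small study
  for stage-level tests) were chosen once as representative desk-scale
  conditions.

# Known limitations

The caller is a stand-in: it has no fragment-length model, no peak-pair
shifting, and its q-values are window-level BH, so it should not be used
for production peak calling on real data (import MACS2 narrowPeak files
instead). The differential test deliberately trades DESeq2's
empirical-Bayes machinery for a transparent, verifiable estimator; on
deeply replicated designs it will be mildly conservative. The
three-way location taxonomy and the fixed motif-score threshold are
simplifications whose effects are bounded by the recovery tests but not
eliminated. Super-enhancer analysis and ontology enrichment are out of
scope.
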
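# cooccupy

Composite-site and co-occupancy analysis of ChIP-seq peak sets in R.

## The problem

When two transcription factors regulate a shared pool of enhancers, their
ChIP-seq peak sets overlap far more than chance placement would allow — and
in the most interesting case the two factors recognise a *composite*
(overlapping) DNA site, so that their binding is mutually exclusive and the
factor occupying the enhancer can switch as a tissue develops. A concrete
example is cardiac differentiation, where progenitor cells experience high
levels of a MEIS-family homeodomain factor and then, as they differentiate
and migrate into the heart, increasing levels of an NKX-family factor;
enhancers carrying a hybrid site can be handed from one factor to the
other. Establishing this computationally requires several linked analyses,
which this package provides as tested, reusable components for regulatory
genomicists:

* **Motif scanning with exact p-values.** PWMs (built from counts with
  background-proportional pseudocounts) are scored as log2 odds on both
  strands; score thresholds are set by an exact null-score distribution
  computed by dynamic programming (`score_distribution()`,
  `threshold_for_pvalue()`), the semantics of FIMO-class scanners.
* **Summit-window classification.** Each peak's summit ± 25 bp window is
  classified by occurrence of the canonical ("selex") motif and the hybrid
  ("de novo") composite motif into `denovo_only` / `selex_only` / `both` /
  `neither` (`classify_regions()`), plus `detect_composite()` for explicit
  overlapping-match geometry.
* **Co-occupancy statistics.** `overlap_partition()` gives the shared /
  exclusive partition of peak set A against B (e.g. 765 of 2,610 regions =
  29.31%); `summit_overlap()` restricts sharing to summits within ± 6 bp
  (direct site overlap vs mere proximity); `permutation_enrichment()`
  computes fold enrichment and an empirical p-value against a
  length-preserving uniform random-placement null with the add-one
  estimator `(1 + #{perm ≥ obs})/(n_perm + 1)`.
* **Target assignment and expression integration.** Every peak is assigned
  its two nearest genes within 1 Mb (summit-to-TSS); bound genes
  intersected with a differential-expression table (fold change ≥ 1.5,
  boundary inclusive) yield direct targets with down/up fractions, Venn
  counts, and exact 2×2 Fisher tests by expression-domain category
  (`fisher_exact_2x2()` uses the standard two-sided hypergeometric rule).
* **ZOOPS-EM motif discovery.** A minimal zero-or-one-occurrence-per-
  sequence EM with screened data-window starts and phase refinement
  (`discover_motif_zoops_em()`).
* **A synthetic-data generator with planted truth.**
  `simulate_dataset()` emits a small multi-chromosome genome with motif
  instances planted at peak summits, paired peak sets with an exactly
  controlled shared fraction and summit jitter, a gene annotation, a DE
  table, and `truth.json`; `audit_simulation()` re-verifies every planted
  fact from the emitted files. `run_pipeline()` wires all stages into one
  reproducible report.

File formats: BED3/BED6/narrowPeak (0-based half-open; narrowPeak column
10 is the summit offset), FASTA genomes, UCSC-style chrom.sizes, MEME
minimal motif files, and plain TSV for annotations, DE tables, and
category maps.

## Worked example

Generate a synthetic dataset at the default study conditions (261 A-peaks
vs 600 B-peaks, shared fraction 0.2931, planted motif-class mix
50/40/5/5) and run the full pipeline:

```r
library(cooccupy)

sim <- simulate_dataset(sim_config(seed = 42), "sim_out")
p <- sim$paths
cfg <- pipeline_config(genome_fasta = p$genome_fasta,
                       chrom_sizes = p$chrom_sizes,
                       peaks_a = p$peaks_a, peaks_b = p$peaks_b,
                       annotation = p$annotation, motifs = p$motifs,
                       de_table = p$de_table, categories = p$categories,
                       out_dir = "pipeline_out", n_perm = 200, seed = 7)
rep <- run_pipeline(cfg)

rep$overlap
#> $n_a
#> [1] 261
#> ...
#> $n_shared_a
#> [1] 76
#> $pct_shared_a
#> [1] 29.12
rep$classification$pct
#> $denovo_only
#> [1] 49.8
#> $selex_only
#> [1] 39.5
#> $both
#> [1] 5.7
#> $neither
#> [1] 5
rep$enrichment$fold
#> [1] 6.260297
rep$integration$n_direct_targets
#> [1] 52
```

Reading the numbers: 76 of the 261 A-peaks (29.12%) overlap a B-peak —
exactly the planted `round_half_up(0.2931 × 261)`; the summit ± 6 bp
criterion (`rep$summit_overlap`) splits those into directly overlapping
and merely proximal pairs; the planted de novo / selex / both / neither
mix of 50/40/5/5 is recovered within chance-match noise; overlap is
6.3-fold enriched over random placement of the A-set on this compact
genome; and the 52 direct targets are precisely the genes the generator
planted as bound-and-dysregulated, with their planted down/up split
(`rep$integration$pct_down`, `pct_up`). `audit_simulation("sim_out")`
independently re-verifies the emitted files against `truth.json`.

## Documentation

The methods vignette (`vignettes/cooccupy-methods.Rmd`) describes the
models, thresholds, numerical choices, generator design, and limitations.
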
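---
title: "Methods: co-occupancy and composite-site analysis with cooccupy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy and composite-site analysis with cooccupy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccupy)
```

## The question the package addresses

Two transcription factors can regulate a common pool of enhancers in two
distinct ways: by binding nearby but independent sites within the same
regulatory region, or through a *composite* (overlapping) site in which the
two recognition sequences share bases, so that binding is mutually
exclusive. Distinguishing these situations from ChIP-seq data requires a
chain of analyses that this package implements as reusable, individually
tested components: motif-occurrence classification of peak-summit windows,
overlap partitioning of two peak sets at both full-region and
summit-restricted resolution, a permutation null for overlap enrichment,
peak-to-gene assignment, and intersection with differential expression to
nominate direct targets. The motivating biological setting is cardiac
differentiation, where a homeodomain factor expressed in progenitors (a
MEIS-family protein) and one expressed in differentiating myocardium (an
NKX-family protein) can hand off a shared set of enhancers as cells
migrate and differentiate; the methods are generic to any pair of factors.

## Coordinate model

All intervals are 0-based half-open (the BED convention); a narrowPeak
summit is a 0-based offset from the interval start. When a peak has no
recorded summit, its midpoint `floor((start+end)/2)` stands in: summit
positions drive every downstream analysis (window extraction, the
summit-restricted overlap criterion, and gene distances), and the midpoint
is the conventional fallback for callers that do not emit summits. The
window "summit ± k" is materialised as the half-open interval
`[summit - k, summit + k + 1)`, clipped at chromosome ends, so its width is
at most `2k + 1`.

## Motif scanning with exact p-value thresholds

A motif is a position weight matrix over A,C,G,T built from counts with a
pseudocount distributed proportionally to the background
(`pwm_from_counts()`; default total pseudocount 0.1), scored as
`log2(prob/background)` in bits. `scan_pwm()` scores every window on both
strands (reverse-strand scores come from the reverse-complement matrix;
positions are always reported in forward coordinates) and skips windows
containing N.

Score thresholds are expressed as exact null p-values. The null
distribution of the score of a single background-drawn window is computed
by positional convolution (`score_distribution()`) after rounding each
log-odds entry to a multiple of the granularity (default 1e-3 bits, a
standard precision/runtime compromise; configurable).
`threshold_for_pvalue()` returns the smallest score whose tail probability
does not exceed the requested p. Two numerical details matter:

* **Selection happens on the discretised grid.** When a scan is given the
  null distribution, windows are selected by their rounded score against
  the rounded threshold. Selecting unrounded scores against a grid
  threshold would silently drop the consensus whenever rounding lifts the
  grid value above the true maximum; scoring and thresholding on the same
  grid keeps the p-value semantics exact.
* **Unattainable p-values return an unattainable threshold.** For a sharp
  width-6 motif under a uniform background the single best outcome already
  has probability `4^-6 ≈ 2.4e-4`, so no threshold achieves p ≤ 1e-4; the
  returned threshold then exceeds the maximum attainable score and a scan
  reports nothing. This mirrors the behaviour of p-value-driven scanners
  and is asserted in the tests rather than worked around.

The default scan p-value is 1e-4, the long-standing default of
occurrence-scanning tools. Region classification (`classify_regions()`)
scans the summit ± 25 bp window of every peak with two motifs — the
canonical ("selex") site and the hybrid ("de novo") composite site — and
assigns each region to exactly one of `denovo_only`, `selex_only`, `both`,
`neither`; marginal percentages ("de novo present" = both + denovo_only)
are reported alongside the exclusive partition, because published figures
typically quote the marginals.

## Composite-site geometry

`detect_composite()` reports every pair of matches from two scans whose
footprints overlap by at least `min_overlap_bp` (default 1) with
`|start_b − start_a|` bounded by `max_abs_offset` (default: the width of
the first motif). The defaults are deliberately permissive because
composite sites are defined only qualitatively in the literature; the
geometry (overlap and signed offset) is returned so callers can apply
stricter definitions.

## Overlap partitioning and the permutation null

`overlap_partition()` counts how many distinct A-intervals touch at least
one B-interval (multiple hits count once — the convention when one reports
"n of N regions were also bound"). `summit_overlap()` repeats the
partition after replacing both sets by their summit ± k windows (default
k = 6 bp): two peaks then count as shared only if their summits lie within
2k bp, which separates directly overlapping binding sites from co-binding
within the same broader region. The difference between the full-region and
summit-restricted shared counts is reported as "proximal but not direct".

`permutation_enrichment()` builds the null by relocating set A uniformly
at random (`shuffle_peaks()`): each interval keeps its length, draws a
chromosome with probability proportional to the number of feasible start
positions, and a start uniformly among them. Placements may overlap each
other and the original locations — the default semantics of
interval-shuffling toolkits; exclusion masks are out of scope. The
statistic is the shared A-count (matching the partition semantics; overlap
in bases would answer a different question), fold enrichment is
observed/mean, and the empirical p-value uses the add-one estimator
`(1 + #{perm ≥ obs})/(n_perm + 1)` so that finite permutation counts never
produce p = 0. Per-iteration seeds derive from the master seed by a
counter scheme, making results independent of iteration order and
bit-reproducible. A permutation mean of zero yields an infinite fold with
a warning rather than an error, since the observed count may still be
informative.

## Gene assignment and expression integration

Each peak is assigned its two nearest annotated genes within 1 Mb
(`two_nearest_genes()`), distance measured summit-to-TSS by default. The
choice of summit rather than interval edge is deliberate — every other
analysis in the workflow is summit-centric — but it is exposed as a
configuration switch (`mode = "summit"|"edge"`) because annotation-driven
pipelines differ on this point. Ties are broken lexicographically by gene
id for determinism.

Differential-expression records are filtered by linear fold change
(|log2fc| ≥ log2(min_fc), boundary inclusive, default min_fc = 1.5) and
optionally adjusted p. `direct_targets()` intersects bound genes with the
filtered table: genes supported by several peaks count once (the support
count is retained for reporting), and the three Venn counts (bound-only,
shared, DE-only) are returned with the direction split.
`fisher_exact_2x2()` implements the standard exact two-sided rule — the
total probability, at fixed margins, of tables no more probable than the
observed one — with the sample odds ratio `ad/bc` (infinite when `bc = 0`);
the doubling convention for two-sided p exists but is not used.
Per-category direction tests (`category_direction_analysis()`) report raw
Fisher p-values, as is conventional for small category panels, with a
Benjamini–Hochberg column alongside.

## ZOOPS-EM motif discovery

`discover_motif_zoops_em()` is a minimal single-width de novo discovery
routine under the zero-or-one-occurrence-per-sequence model: a sequence is
either pure background or carries one site at a uniform unknown offset
with prior probability gamma. The E-step computes the exact posterior over
(no site, site at each offset); the M-step re-estimates the matrix from
expected letter counts with pseudocounts and gamma from the expected site
count. Two standard refinements substantially improve recovery:

* **Screened data-window starts.** Random windows rarely coincide with a
  motif instance, so the routine screens `n_candidates` (default 20 per
  restart) window-seeded matrices with two EM iterations and fully
  converges only the best `n_starts`.
* **Phase refinement.** EM readily converges to a register shifted by one
  or two columns from the planted motif; after the best fit converges, EM
  is re-run from column-shifted copies of it and the highest-likelihood
  phase wins.

Sites are modelled on the given strand only; full multi-width discovery,
alternative sequence models, and dinucleotide backgrounds are out of
scope. Everything is deterministic given the seed.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` produces the complete input bundle with a
machine-readable truth record. Its defaults are the package's study
conditions, a tenth-scale rendition of a typical embryonic-heart ChIP
experiment: 261 A-peaks against 600 B-peaks with shared fraction 0.2931 on
a 6.2 Mb five-chromosome genome (four 1.5 Mb peak chromosomes plus a
0.2 Mb peak-free "desert" chromosome whose genes can never fall within
range of a peak); a planted motif-class mix of 50/40/5/5 for
denovo_only/selex_only/both/neither; summit jitter of sd 20 bp among
shared peak pairs so that the summit ± 6 bp criterion splits shared peaks
into direct-overlap and merely proximal subsets; and a DE table in which
30% of bound genes are planted as direct targets (adjusted p drawn from
U(0, 0.01), |log2fc| ≥ log2(1.5)) while every other gene carries
sub-threshold noise (adjusted p from U(0.2, 1), |log2fc| < log2(1.5)) —
an unambiguous separation chosen so that truth recovery is deterministic.

The built-in motifs are a selex-like 7-mer `TCAAGTG` (carrying the AAGTG
core) and a MEIS-like 6-mer `TGACAG`; the hybrid composite site
`TGAAGTGACAG` merges a degraded selex half (`TGAAGTG`, one substitution
from the canonical site) with the full MEIS site over a 2 bp overlap. The
degraded half is essential: were the hybrid to contain the exact selex
consensus, every hybrid-planted region would also classify as
selex-positive and the four classes would not be separable. Sharp matrices
(100 pseudo-observations per position, pseudocount 0.1) make the 1e-4
scan threshold equivalent to near-exact string matching, so planted-class
recovery is limited only by rare chance background matches (about 1% of
regions).

Direction of each planted target is drawn from its expression-domain
category's down-bias (defaults: AVC 0.50, chamber 0.75, pan 0.45 over a
0.30/0.35/0.35 category mix), giving an expected overall down-fraction
near 0.57 — the regime in which a factor acts as both activator and
repressor with a chamber-restricted repressive bias. The global
`frac_down` (default 0.556) applies to DE-only genes. Truth records the
realised draws, so downstream recovery checks are exact regardless of the
randomness.

Counts are made exact by construction: the shared-peak count is
`round_half_up(f · n_peaks_a)` (recorded in the truth file), non-shared
B-peaks are placed by rejection sampling to avoid any A-peak, A-peaks are
spaced at least 400 bp apart so that jittered partners and ± 25 bp summit
windows never collide across peaks, and planting is by substring
substitution at the summit so scans recover sites exactly.
`audit_simulation()` re-reads every emitted file and re-verifies the whole
truth record, naming any failed assertion.

What the generator does **not** emulate: read-level noise and peak-calling
artefacts, GC or mappability structure, realistic inter-peak spacing and
peak-width distributions, correlated expression noise, or incomplete
annotations. Passing the planted-truth tests therefore demonstrates that
the analysis chain is correct and deterministic, not that it is robust to
the messiness of real ChIP-seq — on real data the same quantities carry
the sampling noise of the experiment.

## Reporting conventions and numerical choices

Percentages are rounded half-up (29.31 for 765/2,610), at 2 decimals for
overlap partitions, 1 decimal for motif-class and direction fractions, 0
decimals for enhancer-validation rates — matching how such figures are
printed in the literature. The pipeline report excludes timestamps so
reruns are byte-identical; a content hash over inputs and configuration
(excluding the output directory) lets unchanged reruns reuse the cached
report. All randomness flows from explicit seeds; library code never
perturbs the caller's RNG state.

## Problem sizes used in validation

The test-suite operating points were chosen as the package's own
validation design: scanner/oracle equivalence on one hundred 2 kb
sequences with motif widths 5–8 and full enumeration of all `4^w` windows
up to width 8; the permutation null checked against exhaustive placement
of a 10 bp interval on a 100 bp chromosome at 5,000 permutations; Fisher
exactness against direct enumeration for 500 random tables with margins up
to 40; end-to-end planted-truth recovery at the default 261-peak scale
with 100-permutation enrichment; and motif discovery on twenty independent
collections of two hundred 50-mers each carrying one planted 6-mer. These
sizes give tight oracle comparisons while keeping the whole suite fast
enough to run routinely.

## Known limitations

Strand is ignored in all interval logic; shuffling has no exclusion or
GC-matching masks; only two peak sets are compared at a time; the
discovery routine fits a single width on a single strand; exact
contingency tests are limited to 2×2; and annotation input is a flat
TSS table, not a transcript model (GTF/GFF parsing is out of scope).
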
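---
title: "Methods: gapped-repeat response element analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gapped-repeat response element analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raregrammar)
```

## The problem

Nuclear hormone receptors of the RAR/RXR family bind DNA as dimers on
response elements (RAREs) built from two copies of a hexameric half-site
(consensus `5'-RGKTCA-3'`) separated by a short spacer. The arrangement of
the two half-sites — direct (DR), everted (ER) or inverted (IR) repeat — and
the spacer length (0–12 bp) encode which receptor pairs bind and how the
bound complex behaves. `raregrammar` implements the computational machinery
needed to ask, for a set of binding peaks (e.g. from CUT&RUN), *which*
repeat grammar is enriched, what co-occurs next to it at fixed spacings, and
how binding relates to transcriptional response classes and chromatin
state — plus a synthetic-data generator with planted ground truth so that
every stage can be validated end to end without external data.

## Motif model

A motif is a position frequency matrix (PFM): a `4 x w` column-stochastic
matrix over A, C, G, T (this base order is fixed everywhere, including
files). Composite repeats are built from a half-site `H` as

* `DR(n) = H · N_n · H` (→N→),
* `IR(n) = H · N_n · rc(H)` (head-to-head, →N←),
* `ER(n) = rc(H) · N_n · H` (tail-to-tail, ←N→),

where `N_n` is `n` background-distributed spacer columns and `rc` is the
reverse complement. These orientation conventions follow standard
nuclear-receptor usage (e.g. the well-known everted-repeat "ER8" site);
they are normative for this package because swapping the ER and IR
conventions silently swaps all ER/IR results downstream. Spacer columns
equal the background distribution so they contribute exactly 0 log-odds:
spacer bases in RAREs are unconstrained.

Scoring uses base-2 log-odds against a background `b` with additive
pseudocount `c` (default `1e-4`, applied to both numerator and
denominator): `score(base, i) = log2((p_i(base) + c) / (b(base) + c))`.
The maximum attainable score is the sum of column maxima, and a window is a
*hit* when its score reaches `0.7 x` that maximum (the fraction is
configurable via `scan_config()`). Ambiguity codes (N and friends) score
zero — the neutral, background-equivalent treatment of masked sequence.
Scanning covers both strands; offsets are always reported on forward
coordinates. On IUPAC expansion: `K` denotes G/T; part of the
nuclear-receptor literature glosses the half-site `K` position as G/C, and
`RGKTCR` also circulates as the trimmed core. Both spellings are accepted
as input; the package defaults to `RGKTCA` and follows IUPAC strictly.

## Enrichment statistics

Counting is ZOOPS ("zero or one occurrence per sequence"): a peak with ten
hits contributes one. Against a background set, three tests are available:

* **binomial** — upper tail of `Binomial(n_t, p0)` at the target ZOOPS
  count, with `p0` the background ZOOPS proportion;
* **Fisher** — one-sided exact test on the `2 x 2` ZOOPS table;
* **rank-sum** — one-sided Mann–Whitney on per-sequence *average odds*
  scores, `log2` of the mean over all windows (both strands) of
  `2^(window log-odds)`; exact for small untied samples, midrank normal
  approximation with continuity correction otherwise.

The repeat-type × spacer matrix (`repeat_enrichment_matrix()`) evaluates
every `(kind, spacer)` composite plus the monomeric half-site — monomer
enrichment is biologically meaningful (loose, RXR-independent chromatin
association) — for every peak subset against one shared background, and
flags cells with `-log10 p < 1.3` as not enriched (N.E.). Two numerical
guards matter:

* With a finite background, rare composites often have a background ZOOPS
  count of exactly zero, making the plug-in `p0 = 0` degenerate; a single
  spurious target hit would then claim unbounded significance and dominate
  the matrix. The binomial path therefore floors the background proportion
  at `1/(n_b + 1)` (rule-of-three style) for zero-count cells.
  `binomial_enrichment()` itself, used directly, reports the degenerate
  case as the smallest positive double with an `underflow` attribute.
* Under the null (background vs background) the discrete upper-tail test is
  conservative, which is what the calibration suite checks.

Backgrounds come from either a first-order Markov model trained on the peak
set itself (dinucleotide counts with pseudocount 1; `train_markov1()` /
`sample_markov1()`) or a GC-matched subset of candidate intervals
(`gc_matched_background()`: decile length matching, stratified draw, then
greedy swaps until the mean GC gap is within tolerance, default 0.02). The
shared-background choice for the enrichment matrix is an assumption — a
per-subset background is possible by calling the matrix per subset.

## Spacing co-occurrence

`run_spacing()` centers each sequence on its best primary-motif site
(threshold 0.7 × max; sequences without a primary site are dropped and
counted), trims to the site ± `margin` (default 100 bp), and re-orients so
the primary reads 5'→3' on the forward strand. Centering on best primary
sites rather than peak summits is the default because the question is about
geometry relative to the bound element; summit-centered input can be
supplied directly. Each sequence then contributes its single best secondary
site with score ≥ 0.75 × the secondary's maximum (the fractional reading of
a "minscore −0.75" convention, consistent with the 0.7 fraction used for
hits), non-negative edge-to-edge gap, and overlap with the primary below
6 bp; partial overlaps below the exclusion count as gap 0 and are sided by
motif centers. Cells are (gap, quadrant): same/opposite strand ×
downstream/upstream.

Significance uses a uniform placement null: with `G = floor((margin −
w_secondary)/bin) + 1` admissible gap bins and 4 quadrants, a cell has null
probability `1/(4G)`; the per-cell p-value is the binomial upper tail at
the observed count among the `n_effective` sequences with a qualifying
secondary site, and the E-value multiplies by the `4G` cells and the number
of secondary motifs in the database. Results below `p = 1e-5` are reported,
sorted by E-value. One sequence contributes one placement — the model that
makes the uniform null correct — so secondary sites beyond the best per
sequence are deliberately ignored.

## Integrating peaks with expression response classes

Differential-expression tables (gene, log2FC, adjusted p, mean normalized
count) are consumed, never re-fit. All thresholds use strict inequalities
exactly as printed in the consumed tables' conventions: DEG means
`padj < 0.05` and `|log2FC| > 0.3` for agonist contrasts (`> 1` for the
genotype contrast); a stricter agonist preset `padj < 0.01` is exposed
because both cutoffs are in circulation, and neither is hard-coded as
"correct". Genes are classified per time point and direction as responsive
to **both** agonists (the selective and the pan agonist), to one only, with
`ko_responds` true iff the knockout showed a same-direction call at the
same time for a triggering agent — "similarly respond" is read as requiring
direction and time to match. The three agent classes partition the DEGs,
which keeps the "only" rows non-redundant.

Peak filtering retains sites with `-log10(q) > 5`, removes peaks whose
overlap with any knockout peak reaches 0.1 of their own length, and can
keep the top 2000 by integer score (ties broken by chromosome then start,
so the operation is deterministic and idempotent). Annotation links each
peak to the gene with the nearest TSS *by summit*, signed negative upstream
relative to gene strand, with inclusive tier boundaries: proximal promoter
`|d| ≤ 250`, cis-regulatory `|d| ≤ 3000`, else gene body when the summit
lies in a gene span, else distal. Nearest-gene linkage is the default
(windowed linkage can be emulated from the links table). The tier table
counts, per response-class row, total DEGs ≥ with ≥1 peak ≥ with a link at
CRE distance ≥ with a proximal-promoter link — a nesting that must hold for
any input and is property-tested. Conditional silencing calls use mean
normalized counts: silenced in the knockout iff KO mean < 10 and parental
mean > 50 (and the reverse for activated).

## Spike-in normalization and chromatin states

Spike-in scaling is single-scalar: `f = spike/(spike + genome)` per sample
and `scale = K/f`, with `K = 1` or `K = min f` (reference choice shifts all
scales by one constant; the pairwise ratio law `scale_i/scale_j = f_j/f_i`
holds exactly either way). Differential-region classification takes the
fold-enrichment statistic FE as a log2-scale change (the conventional
reading consistent with `FE > 1` / `FE < −1` extreme subsets): enriched iff
`FE > 0` and `FDR < 0.05`, depleted iff `FE < 0`, else ns; the extreme
subsets and their comparison sets are exported for motif work. Promoter
states come from peak-call overlap of TSS ± 1000 bp (the window is a
package choice, configurable; the ±250/±3000 constants are available where
promoter-tier semantics are wanted): active (H3K4me3 only), bivalent
(both), repressed (H3K27me3 only), quiescent; transitions between two
conditions are labeled maintained / bivalency_gained / bivalency_lost /
repressed_switch / activated / other.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of the motivating
experiment so that planted truth is recoverable by the pipeline:

* **genome** — i.i.d. bases at a configured GC (default 0.45);
* **annotation** — genes with ≥ 5 kb TSS spacing, random strands, 2–8 kb
  spans;
* **peaks** — summit-to-nearest-TSS tiers realized by rejection sampling at
  configured proportions (defaults 38% proximal, 12% CRE, 30% gene body,
  20% distal, motivated by published feature distributions of receptor
  peaks), widths `N(300, 75²)` bp, integer scores uniform 50–1000,
  `-log10 q` above the inclusion cutoff;
* **planted motifs** — a Bernoulli subset of peaks receives one instance
  sampled column-wise from the motif PFM (matching the probabilistic model
  used for scoring) within ±50 bp of the summit, random strand; overlapping
  peaks redraw positions so instances never overwrite each other;
* **expression** — negative-binomial counts over a genotype × agent × time
  design in triplicate (12 groups), multiplicative condition effects of
  `2^±effect_log2fc`, median-of-ratios normalization, Welch t-tests on
  `log2(normalized + 1)` with per-contrast BH adjustment (the pipeline
  consumes DE tables, so the simulator only needs calibrated p-values —
  a deliberate choice over re-fitting a published differential package);
  conditionally silenced/activated genes are constructed directly against
  the <10 / >50 normalized-count rule;
* **spike-ins** — per-sample fractions uniform in a configured range over a
  fixed read total.

Everything derives from one seed and reruns are byte-identical. What the
generator does **not** emulate: read-level artifacts (it produces no
FASTQ), fragment-length structure, alignment and duplication noise, batch
effects, genomic repeat content, and realistic linkage between peaks and
the genes they regulate. Passing recovery tests therefore demonstrates the
pipeline's statistical machinery and bookkeeping, not performance on real
chromatin data.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally and in BED-family files.
* Ties: `which.max` semantics everywhere — leftmost window for trimming and
  primary-site selection; equal-scoring strands resolve to `+`.
* `trim_to_core()` information content is `2 + Σ p log2 p` bits per column
  with `0 log 0 = 0`.
* Empty sequence sets are legal where a count can be zero (`zoops_count`
  returns `(0, 0)`), and error where a statistic needs data.
* Sequences shorter than a motif contribute no windows (scan) or `-Inf`
  (average odds, excluded with a warning from the rank-sum test).
* Probabilities written to motif files carry 6 decimals; readers
  renormalize columns, so write→read round-trips agree within `1e-6`.

## Problem sizes used by the test and acceptance suites

The suites run at desk scale, chosen to keep binomial confidence bounds
meaningful: genomes of 2 × 200–500 kb, 60–1000 peaks, 300-peak planted
subsets at rate 0.5, 100-seed recovery runs, 100-rep null calibrations at
60 + 60 sequences of 200 bp, expression designs of 400 genes × 72 samples,
and 1000 random tier-table fixtures. The headline genomic counts of any
real experiment (tens of thousands of consensus sites, thousands of DEGs)
depend on deposited data and are deliberately not reproduced here; the one
printed quantity that is recomputed from counts alone is the
knockout-enriched percentage of differential H3K4me3 sites
(7278 / 9291 ≈ 78%).

## Known limitations

* PFMs are independent-column models; dinucleotide dependence within
  half-sites is not representable.
* The uniform spacing null ignores sequence composition; a composition-aware
  null would need simulation per secondary motif.
* The greedy GC-matching swap can declare tolerance unattainable on
  adversarial candidate pools slightly before an exhaustive search would.
* `ko_responds` classification is threshold-based; borderline genes flip
  classes with the padj preset, which is why both presets are exposed.
* The E-value adjustment for secondary-motif multiplicity is Bonferroni-style
  and conservative when secondary motifs are redundant.
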
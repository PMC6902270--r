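---
title: "valleycall: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{valleycall: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the models, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open.

## The enhancer model

Active enhancers are bound by transcription factors in a
nucleosome-depleted core, while the flanking nucleosomes carry
H3K27ac. In ChIP-seq peak calls this appears as a *bimodal* pair of
acetylation peaks with a low-signal valley between them, and the
valley — not the peaks — is the candidate regulatory element.
H3K27me3 marks Polycomb-repressed chromatin; a valley overlapping an
H3K27me3 peak is treated as repressed, not active.

`call_enhancers()` operationalises this as:

1. merge H3K27ac peaks with gap <= 0 (overlapping or book-ended) —
   fragmented calls over one nucleosomal block should count once;
2. for every *adjacent* pair of merged peaks on a chromosome with
   inner gap `0 < g <= max_inner_gap` (default **3000 bp**), emit the
   inter-peak valley. Adjacency (rather than all pairs) prevents
   nested and overlapping valleys; a peak may flank two valleys;
3. drop valleys overlapped by >= 1 bp of merged H3K27me3
   (`max_me3_fraction = 0` — strict absence). Book-ended repressive
   peaks do not disqualify. The strict rule is deterministic; a
   coverage-ratio mode (`max_me3_fraction` in (0, 1]) is available
   when "low" rather than "absent" trimethylation is wanted;
4. assign each valley to the gene whose TSS is nearest the valley
   **midpoint** and classify its genomic context.

Open choices made here: the reported element is the valley rather than
the peak-to-peak span (the span is recoverable from the flank columns);
the distance anchor is the region midpoint, with a nearest-edge option
(`nearest_tss(anchor = "edge")`); ties go to the smaller TSS
coordinate, then the lexicographically smaller gene id, so output never
depends on input order.

The promoter window is **-2000/+500 bp** around the TSS, oriented by
strand — a conventional proximal-promoter definition; both margins are
arguments. Context precedence is promoter > exonic > intronic >
intergenic, decided by the valley midpoint, so the four classes
partition any region set.

Two conditions are compared by the **0 bp gap rule**: valleys that
overlap or book-end each other are the same element. Because one
valley can touch two valleys of the other condition, matches are
collapsed into connected components; the invariant
`unique + component members = total` then holds per condition, and the
number of common elements is the number of components.

## Signal profiles

`extract_matrix()` computes, for each length-1 anchor, the
length-weighted mean read density per bin across
`[anchor - window, anchor + window)`. Uncovered bases count as zero;
windows running past the chromosome start are zero-padded and flagged.
Minus-strand anchors are mirrored so downstream is always rightward.
Defaults: window **±5000 bp**, bin **50 bp** (200 bins, typical
heatmap resolution); TSS metaprofiles use ±2000 bp.

`cluster_profiles()` is Lloyd k-means with k-means++ seeding,
**10 restarts**, <= 300 iterations, best inertia kept; the seed is a
required argument so heatmaps are reproducible bit-for-bit. Rows are
not normalised by default (`normalize = TRUE` enables per-row max
scaling); k defaults to **5**, the cluster count used for
motif-centred acetylation heatmaps.

## Motif statistics

A PWM is stored as counts plus a background `b` and pseudocount `s`
(default 1, uniform background), giving per-column log2 odds
`log2((c + s*b) / (N + s) / b)`.

`score_threshold()` computes the *exact* distribution of the score of
a random background word by dynamic programming over scores rescaled
to an integer grid of **1e-3 bits** and returns the smallest
attainable score `s` with `P(score >= s) <= p` (default
**p = 1e-4**). Numerical details that matter:

* the returned threshold is lowered by half a grid unit per column so
  a word whose exact score rounds up to the grid value is still
  admitted; thresholds are therefore conservative within the grid
  resolution (width × 5e-4 bits);
* short or degenerate motifs may not attain the requested p at all
  (the 7-bp AP1 fixture's two consensus words jointly carry
  ~1.2e-4 of background mass), in which case the maximum attainable
  score is returned with a warning — the strictest scan the matrix
  admits;
* widths above 25 are refused rather than silently approximated.

`shuffle_enrichment()` uses the raw per-sequence statistic
`log(mean over windows and strands of 2^score)` — the log average
likelihood ratio, the classic raw score of shuffle-null enrichment
tools — averaged over sequences. The null shuffles each sequence
independently per replicate (mononucleotide by default, preserving
composition; `method = "di"` preserves dinucleotides via a
rejection-sampled Euler walk). Default **1000 shuffles**; empirical
p-values use the add-one rule and so are never 0.

`differential_motif_enrichment()` contrasts set A minus set B and
builds its null by pooling the per-sequence statistics and re-splitting
them into the original sizes — exact exchangeability under the null,
and cheap because per-sequence statistics are computed once. The
per-PWM e-value is Bonferroni (`p × #PWMs`), gated at **e <= 0.05**.

The shipped `ap1_fixture_pwm()` is a *synthetic* consensus-built
TGA(C/G)TCA matrix for tests and simulations, not a measured motif;
real analyses should load JASPAR matrices via `read_jaspar()`.

## Conservation scan

The scan is alignment-free footprinting: regulatory elements tend to
preserve clusters of short factor-binding words even when their order
rearranges. A **300 bp** window slides along the reference at
**50 bp** steps; a species supports a window when some 300 bp span of
its ortholog contains at least `min_shared` *distinct* **8-mers** of
the reference window, matched on either strand regardless of order or
position. Windows supported by >= **7** species (reference included,
of 9 supplied) are reported and merged into blocks.

`min_shared` defaults to **8**. This is the one deliberate departure
from a simple whole-sequence word lookup: a 300 bp window carries
~290 distinct 8-mers and the chance that a given 8-mer occurs
somewhere in a 1 kb sequence (both strands) is ~3%, so expected chance
sharing is ~9 words — a whole-sequence rule with a small `min_shared`
would support essentially every window. Requiring the shared words to
*cluster* within one species-side window brings the chance expectation
to ~2.6 words, and `min_shared = 8` puts random support at
P ≈ 0.006 per window while a planted 60 bp element at 5% divergence
still shares ~35 intact words. Chance support is not zero: a handful
of extra "supporting" species can join a genuinely conserved block,
which is why block species lists should be read as evidence, not
proof, of per-species conservation.

## Expression response

Counts are normalised in three independently toggleable steps modelled
on the standard nCounter scheme (the vendor procedure is not public in
detail): per-sample scaling by positive-control geometric means,
content scaling by housekeeping geometric means, then subtraction of
`mean + 2·sd` of the negative controls, floored at 1.

`respond()` computes the linear-scale ratio of means and an unpaired
t-test on log2 counts. Two printed threshold pairs exist for the same
analysis — **1.5/0.25** (figure preset, the default) and **1.25/0.75**
(methods preset) — and both ship; thresholds are inclusive and pair
with **alpha = 0.05**.

The t-test pools variances by default (`var_equal = TRUE`). This was
decided by calibration, not convention: with 3 replicates, Welch's
Satterthwaite correction can drop to 2 degrees of freedom and the null
call rate falls to ~0.036 instead of 0.05, violating the package's own
type-I calibration check, while the pooled test is almost exactly
calibrated under the count simulator (groups are homoskedastic on the
log scale by construction). Welch remains available.

`classify_direct()` encodes the cycloheximide argument: transcription
of a direct target needs no new protein synthesis, so a gene responding
in the same direction both with and without CHX is direct; a response
lost under CHX implies an intermediate regulator (indirect). Probes
responding only under CHX are reported separately, unclassified. The
CHX contrast baseline is FGF+CHX vs CHX-vehicle, so the drug's own
transcriptional footprint cancels; the recovery simulations classify
with the methods preset (1.25/0.75) because the planted repression of
|log2FC| = 2 lands exactly on the figure preset's 0.25 gate, where
sampling noise would censor half the true calls for a reason unrelated
to the statistics being tested. Classification accuracy is defined
over *all* endogenous probes (multi-class accuracy), the quantity a
practitioner cares about when reading the final table.

`enhancer_expression_test()` is the one-sided Mann-Whitney comparison
of expression for enhancer-associated vs other transcripts (normal
approximation with tie correction; exact enumeration, with a warning,
when a group has fewer than 3 members; fully tied input returns 0.5).

## What the synthetic data emulates — and what it does not

The generator produces every input the pipeline consumes, with truth
recorded for scoring:

* **Genome and genes.** I.i.d. bases at **GC 0.42** (an avian-like
  genome average), two 500 kb chromosomes, one gene per 12.5 kb slot
  with the TSS at a fixed slot offset. The slot layout guarantees a
  planted valley's nearest TSS is its designated target gene — that
  property is by construction, so recovery tests measure the caller,
  not placement luck.
* **Enhancer structures.** Per condition **40** structures: flanks of
  500-1200 bp around valleys of 200-2500 bp, 20% shared between
  conditions, peak edges jittered with a Gaussian of sd **30 bp**
  truncated so flanks never invade more than 25% of the valley
  (mimicking peak-caller boundary noise). Decoy bimodal pairs overlaid
  with H3K27me3 domains exercise the repressive filter, and extra
  H3K27me3 domains sit over a few gene loci in the treated condition.
* **Coverage.** Poisson counts in 25 bp bins around plateau rates
  (background 1, flanks 20, TSS shoulders 15 with a central dip of 3),
  giving the peak-dip-peak TSS metaprofile.
* **Motifs.** The fixture's maximum-score word written into 60% of
  treated-condition-only valleys at random offset and strand.
* **Orthologs.** Nine species; non-reference sequences are the
  reference with i.i.d. substitutions at rate **0.5** — saturation,
  emulating unalignable diverged background so that only planted
  elements (60 bp, 1% substitution, 8 of 9 species) remain detectable.
  At lower background divergence the entire locus is genuinely
  conserved at the 8-mer level and the scan correctly says so; 0.5 is
  the regime the conservation question is about.
* **Counts.** 216 probes (192 endogenous, 6 positive spike-ins, 8
  negatives, 10 housekeeping), four conditions × 3 replicates,
  negative-binomial endogenous counts with dispersion **0.1**,
  baselines log-uniform 200-2000, per-sample lane effects (log-normal
  sd 0.15), spike-ins near-Poisson. Planted: 10 direct and 10 indirect
  targets, split up/down, at |log2FC| = 2.

What it does **not** emulate: read-level artefacts (mappability, GC
bias, duplicates), false-positive/negative peak calls (edge jitter
only, though a spurious-peak stress mode would slot into the same
interface), fragment-size effects, correlated gene expression,
batch-by-condition confounding, and real phylogenetic covariance
between species. Passing the recovery tests therefore demonstrates the
*algorithms* are correct and calibrated under their stated noise
models — not that real peak callers or real NanoString lanes behave
this ideally.

## Problem sizes and determinism

The test suite and acceptance script run the study at desk scale: a
1 Mb genome with 40 enhancers per condition (20 generations in the
recovery check), 2 kb ortholog loci (50-100 sets), 150-300 bp
sequences for the null-calibration simulations (200 datasets, 99
shuffles each), and 25-50 count simulations — sizes chosen so the
whole suite exercises every stage in a few minutes while keeping
binomial confidence intervals meaningful. Every stochastic stage takes
an explicit seed; `run_all()` derives per-stage child seeds from the
master seed, writes all numbers with fixed formatting, and hashes every
output into `MANIFEST.tsv`, so a rerun with the same config is
bit-identical.

## Known limitations

* The bimodal definition only sees valleys *between* peaks: an
  enhancer whose flanks were merged into one peak by the caller, or
  whose valley exceeds 3 kb, is invisible by construction.
* Nearest-TSS assignment is a heuristic; without chromatin-contact
  data some distal valleys will be assigned to the wrong gene.
* The exact score distribution assumes an i.i.d. background; CpG
  depletion and repeats make real genomic backgrounds richer, which is
  why the shuffle null — which preserves composition per sequence — is
  the primary enrichment gate.
* The conservation scan reports word-sharing, not orthology: it cannot
  distinguish a conserved element from a lineage-specific repeat
  insertion shared by chance, and its equivalence to any particular
  footprinting tool is approximate by design.
* With 3 replicates the t-test has limited power; at |log2FC| = 2 and
  dispersion 0.1 a direct target must pass two independent contrasts,
  so a noticeable minority of true direct targets will be demoted to
  indirect in any single experiment. The classification table should
  be read with that asymmetry in mind.
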
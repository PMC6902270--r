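# valleycall

Regulatory-genomics toolkit for studying how a signalling pathway
rewires the enhancer landscape of an embryonic progenitor population —
built around the FGF-driven induction of otic-epibranchial progenitors
(inner-ear precursors), where FGF exposure rapidly deposits H3K27ac at
ear-specific enhancers while repressive H3K27me3 accumulates near
non-otic genes.

It is aimed at analysts who already have peak calls, coverage tracks
and multiplexed expression counts and want a reproducible, testable
implementation of the downstream analysis:

1. **Bimodal-valley enhancer calling.** Active enhancers sit in a
   nucleosome-depleted valley between two H3K27ac-marked flanks.
   `call_enhancers()` merges touching H3K27ac peaks, emits the valley
   between every adjacent peak pair with inner gap `0 < g <= 3000` bp,
   drops valleys overlapping any H3K27me3 peak (>= 1 bp; book-ended
   peaks do not disqualify), and annotates each valley with its nearest
   TSS (signed midpoint distance, deterministic tie-breaks) and genomic
   context (promoter > exonic > intronic > intergenic).
2. **Condition comparison.** `compare_conditions()` marks an enhancer
   common when a valley of the other condition overlaps or book-ends it
   (0 bp gap rule), collapsing chains into connected components, so
   `unique + members(common) = total` holds exactly per condition.
3. **Signal profiles.** `extract_matrix()` bins read density around
   anchors (TSSs, enhancer centres, motif sites; strand-aware),
   `metaprofile()` averages it (active TSSs show the classic
   peak-dip-peak acetylation shape), and `cluster_profiles()` runs
   seeded k-means (k-means++ initialisation, 10 restarts) on
   motif-centred matrices, k = 5 by default.
4. **Motif analysis.** `pwm()` builds log2-odds matrices
   (`log2((c + s*b) / (N + s) / b)`); `score_threshold()` computes the
   exact score distribution by dynamic programming on a 1e-3-bit grid
   and returns the smallest attainable score with
   `P(score >= s) <= p` (default p = 1e-4); `scan_pwm()` reports every
   qualifying window on both strands; `shuffle_enrichment()` tests the
   mean log average likelihood ratio against per-sequence
   mononucleotide shuffles with the add-one empirical p-value
   `(1 + #{null >= obs}) / (1 + n)`; `differential_motif_enrichment()`
   contrasts two enhancer sets with a pooled re-splitting null and a
   Bonferroni e-value gate (e <= 0.05).
5. **Conservation.** `find_conserved_blocks()` slides 300 bp windows
   along a reference locus and calls a window conserved when >= 7 of 9
   species share a cluster of >= 8 distinct 8-mers (either strand,
   order-free) within a 300 bp span of their ortholog — an
   alignment-free, rearrangement-tolerant footprinting scan.
6. **Expression response.** `normalize_counts()` applies
   positive-control, housekeeping and negative-control-background
   normalisation to nCounter-style tables; `respond()` calls per-probe
   up/down/unchanged from the fold change (presets 1.5/0.25 or
   1.25/0.75) and an unpaired t-test on log2 counts (p <= 0.05);
   `classify_direct()` applies the cycloheximide logic — a gene
   responding with and without translation blocked is a direct target,
   one responding only without CHX is indirect.
7. **Synthetic truth.** `generate_genome()`, `plant_enhancers()`,
   `plant_motifs()`, `make_orthologs()` and `simulate_counts()` build
   fully seeded inputs with recorded ground truth, so every stage is
   scored against a known answer without any external data.

`run_all()` chains everything from a single `run_config()` and writes a
run directory with a hash manifest; reruns with the same config are
bit-identical.

## Worked example

```r
library(valleycall)

sim <- generate_genome(seed = 42)              # 1 Mb, 80 genes
sim <- plant_enhancers(sim)                    # 40 enhancers/condition
sim <- plant_motifs(sim, fraction_fgf = 0.6)   # AP1 sites in FGF valleys

cnt <- call_enhancers(sim$peaks$CNT$ac, sim$peaks$CNT$me3,
                      sim$annotation, condition = "CNT")
fgf <- call_enhancers(sim$peaks$FGF$ac, sim$peaks$FGF$me3,
                      sim$annotation, condition = "FGF")
cmp <- compare_conditions(cnt, fgf)
print(cmp)
#> condition_comparison
#>   unique to A: 32
#>   unique to B: 32
#>   common components: 8
context_distribution(fgf)
#>   promoter     exonic   intronic intergenic
#>          1          5          3         31
```

The planted design (32 unique per condition, 8 shared) is recovered
exactly; most valleys are intergenic or intronic, as expected for
distal elements. Motif enrichment contrasts the FGF-unique against the
control-unique valleys:

```r
differential_motif_enrichment(
  interval_sequences(sim$genome, cmp$unique_b),
  interval_sequences(sim$genome, cmp$unique_a),
  list(ap1_fixture_pwm()), n_shuffles = 1000, seed = 7)
#>           pwm stat_a stat_b statistic p_value e_value significant
#> 1 AP1_fixture  0.385 -0.792      1.18   0.004   0.004        TRUE
```

The AP1-style motif planted in 60% of FGF valleys is flagged at
e = 0.004. The expression arm classifies direct vs indirect targets
from a four-condition count simulation:

```r
cs <- simulate_counts(seed = 42)
norm <- normalize_counts(cs$counts)
plain <- respond(norm, "FGF", "CNT", preset = "methods")
chx <- respond(norm, "FGF_CHX", "CHX", preset = "methods")
cls <- classify_direct(plain, chx)
print(cls)
#> target_classification:
#>     direct_up   direct_down   indirect_up indirect_down  unresponsive
#>             5             6            12             7           162
classification_accuracy(cls, cs$truth)
#> [1] 0.9427083
```

With 10 direct and 10 indirect targets planted at |log2FC| = 2 among
192 probes, 94-95% of probes get their true class in a typical run.

## Command line

A thin CLI over the same functions ships in `inst/cli/valleycall.R`
with subcommands `simulate`, `call`, `compare`, `profile`, `motifs`,
`conserve`, `respond`, `run-all`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/valleycall.R", package="valleycall"))')" \
  call --ac ac.bed --me3 me3.bed --genes genes.gff3 --max-gap 3000 --out enhancers.bed
```
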
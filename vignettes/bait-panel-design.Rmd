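---
title: "Designing and evaluating clade-specific target-capture bait panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating clade-specific target-capture bait panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcnbait)
```

## The problem

Molecular identification and phylogenomics in rapidly diversified plant
clades (the running example throughout this package is *Aloe* and its
Alooideae relatives) need many variable, low-copy nuclear (LCN) loci.
Universal probe sets recover such loci poorly in many monocots, and the
large genomes of these plants make shotgun sequencing wasteful. The
practical answer is a clade-specific RNA-bait panel: transcriptomes of a
few congeners are mined for single- to low-copy genes, the most variable
loci are selected, short biotinylated baits are tiled over their exons,
and capture experiments are scored by how many reads hit the targets and
how much of the targeted exon length is recovered.

`lcnbait` re-implements that workflow as a reusable, fully seeded toolkit:

1. **simulate** — generate congeneric transcript sets, capture reads and a
   ground-truth manifest;
2. **select** — cluster orthologs, transfer exon boundaries from an
   annotated reference, filter loci;
3. **design** — tile and screen baits into a panel with a manifest;
4. **evaluate** — per-sample capture statistics, coverage, recovery
   matrix, paralog flags;
5. **compare** — locus overlap and target-length surplus between two
   panels.

Each stage is exposed both as R functions and as a subcommand of the
`lcnbait` executable (`exec/lcnbait`).

## Locus selection

### Ortholog detection

Published pipelines use BLAST-based classifiers (MarkerMiner) for this
step. `lcnbait` instead uses reciprocal best match under a
shared-canonical-k-mer similarity: for two transcripts the score is the
number of shared canonical 21-mers divided by the k-mer count of the
smaller sequence, so an exact substring relation scores 1. Groups are
seeded from the alphabetically first species and grown species by species;
later anchor passes pick up loci absent from earlier species. Ties break
by lexicographic transcript id, which makes clustering invariant to input
file order.

Two deliberate tolerances matter:

* **Multi-copy detection.** A species' `copy_count` is the number of its
  transcripts scoring within 95% of its best match. Because k-mer survival
  decays like $e^{-kd}$ with divergence $d$, this detects only
  near-identical copies (roughly $d \lesssim 0.25\%$ at $k = 21$) — recent
  duplicates and alleles. More diverged paralogs are *not* merged into the
  group; they surface as unassigned singletons (and fail the presence
  filter), and their capture-side signature is later caught by the paralog
  flagging in the evaluation stage. This mirrors how BLAST-classifier
  pipelines behave on real data.
* **Reciprocity slack.** Strict "mutual best" is fragile at outer-clade
  divergence, where shared-21-mer counts are small and noisy: a 95-99%
  paralog can, by chance back-mutation, share a handful more k-mers with a
  distant congener than the true ortholog does. Since same-locus scores
  dwarf cross-locus scores (which are essentially 0), reciprocity is
  relaxed to "within 50% of the best back-score". The slack tolerates
  sampling noise among same-locus copies while still making cross-locus
  attachment impossible in practice.

### Rescue of missing species

A locus detected in all but one species is searched against that species'
unassigned transcripts by ungapped seed-and-extend local alignment of the
group consensus (majority base per column of a reference-anchored merge of
the members). The hit is accepted at identity ≥ 0.80 over ≥ 50% of the
consensus — both configurable in `selection_params()`.

### Exon annotation

Intron–exon boundaries come from an annotated reference gene set (in the
original workflow, a fully annotated model-grass genome). Each member is
aligned globally to the reference (Needleman–Wunsch, fixed scores match
+1 / mismatch −1 / gap −2, deterministic traceback) and the pairwise
alignments are merged on reference coordinates; insertion blocks between
consecutive reference positions widen to the longest insertion observed
there. Exon boundaries project through alignment columns; a boundary
falling in a gap moves to the nearest following non-gap column. Matching
groups to reference loci uses a smaller seed (`k_ref = 15` vs
`k_cluster = 21`) because the annotation donor is typically about twice as
divergent from the focal clade as the congeners are from each other —
short loci can share no 21-mer with it at all.

Kept loci are named after their matched reference locus (with a numeric
suffix on collision). This keys panel targets, assemblies and recovery
matrices consistently across pipeline stages.

### Filters

After trimming both alignment ends to the fully overlapping window, a
locus is kept iff

* at least `min_presence` (default 3) focal-clade species are present;
* no *internal* (mid-locus) exon is shorter than the bait length
  (default 80 bp) — short terminal exons are tolerated but receive no
  baits, since a bait crossing an exon boundary would span an intron in
  genomic DNA;
* SNP density is at least 20 per 1,000 bp. A column is polymorphic when
  it holds ≥ 2 distinct bases among `{A,C,G,T}`; gaps and `N` never count,
  and the denominator is the trimmed alignment's column count. This is the
  simplest auditable reading of a "SNPs per 1,000 bp" rule; per-pairwise
  difference counting would give systematically higher numbers.

Thresholds are strict as printed: a 79 bp internal exon fails, 80 passes;
density 19.99 fails, 20.0 passes.

## Bait design

Baits are emitted per locus, per source species and per exon (multi-
reference panel; cross-species duplicates collapse later in redundancy
screening). Within an exon of length $E \ge B$ (bait length $B = 80$),
starts form a ladder at step $s = \mathrm{round}(B/d)$ for tiling depth
$d = 3$ (so $s = 27$), plus a flush-right bait at $E - B$ when the ladder
does not land there. Every exon position is covered and baits never cross
exon boundaries. Average depth tends to $B/s = 80/27 \approx 2.96$ for
long exons, but the bait count is a sawtooth in $E$: in the trough just
before a new ladder start appears the depth is $80(m+2)/(27m+107)$, so
individual exons are guaranteed within 2% of the limit only from
$E \approx 2650$ (the mean over a range of lengths converges much
earlier). For the exon lengths the simulator draws (120–400 bp) edge
effects put the per-reference average nearer 2.4.

Screens run in a fixed order, and every drop is ledgered with its reason:

1. **ambiguous** — baits containing `N` (transcripts may carry `N`, baits
   may not);
2. **low complexity** — an exact tandem repeat of period ≤ 6 spanning
   ≥ 60% of the bait (a deterministic stand-in for simple-repeat
   masking);
3. **blacklist** — the bait shares a canonical 24-mer with any blacklist
   sequence (plastome, repeat families); canonical k-mers make the screen
   strand-insensitive;
4. **gc / tm** — GC above 75% is dropped. Melting temperature uses the
   documented basic long-oligo formula
   $T_m = 81.5 + 0.41\,\mathrm{GC\%} - 675/L$; because vendor
   hybridization models are on a different scale, the Tm cutoff ships
   *disabled* (`tm_max = NULL`) and GC does the work, with `tm_max`
   available for users who calibrate their own threshold;
5. **redundant** — two baits are redundant when, at the best ungapped
   relative offset, they overlap by at least `0.83 × B` bases (67 for
   defaults) with identity strictly above 0.95. A greedy first-kept-wins
   pass in canonical order (locus, exon, start, species) enforces this;
   a pigeonhole argument (≤ 3 mismatches in any qualifying overlap) lets
   a shared-16-mer prefilter skip almost all pairs without changing the
   result.

## Capture evaluation

Reads are assigned by a deterministic seed-and-extend pseudo-mapper: any
shared 31-mer proposes a (target, diagonal) placement, the placement with
the most matches over the in-bounds ungapped overlap wins, and a read
counts for exactly one reference provided the overlap spans ≥ 100 bases
(capped at the read length) at identity ≥ 0.90. The per-locus read count
is the *maximum* across that locus's references — the max-across-references
rule used when each capture reference is mapped separately. Per-locus
coverage is `reads × read length / reference length`, with the reference
length taken from the reference that yielded the maximum.

Recovery statistics use, as each locus's reference target length, the
longest reference among the panel's source species (the original report
does not state which of its four transcriptomes was the denominator; the
longest is the conservative choice). Assemblies longer than the reference
give recovery fractions above 1; they are retained and reported, not
truncated. A (sample, locus) pair is flagged as a potential paralog when
at least two contigs each cover ≥ 85% of the reference length — the
standard warning criterion of target-capture assemblers.

Group summaries are arithmetic means; count columns round to integers and
percentage columns to one decimal. The bundled
`capture_stats_table()` (27 enriched Asphodelaceae samples) provides the
worked example: the 23 *Aloe* rows average 2,712,317 reads after trimming
and 1,407,498 mapped.

## Panel comparison

Two panels' loci are compared by the same seed-and-extend local
alignment. An overlap is recorded when the aligned span exceeds 5% of the
shorter target; a 70% identity floor stands in for the alignment
significance testing a BLAST-based comparison would provide, so unrelated
loci never "overlap". Each locus reports at most its best partner, and
the surplus is the signed length difference summed over overlapping loci
(with the mean per locus rounded to an integer).

## The simulator and what it does (not) show

`sim_config()` defaults encode the study conditions the toolkit targets:

* a fixed 4-taxon tree — three focal congeners (pairwise divergence
  0.06–0.10 expected substitutions/site) plus one deeper congener at
  0.15–0.18 from the ingroup —
  mirroring a three-ingroup-plus-outgroup transcriptome design. Under
  Jukes–Cantor each site mutates along a branch of length $d$ with
  probability $\tfrac{3}{4}(1 - e^{-4d/3})$;
* 2–6 exons of 120–400 bp per locus (the lower bound sits above the bait
  length so only *injected* exons are short);
* adversarial injections at configurable rates (defaults 10–15%):
  branch-rescaled low-divergence loci (tree scaled by 0.03, giving
  ~5–9 SNPs/kb against a passing population at ~150–220 — the two
  populations are far from the 20/kb threshold by construction, so
  intended verdicts are unambiguous); one 40–70 bp internal exon; an
  extra paralogous copy at 95–99% identity in one species; complete
  absence from one uniformly drawn species; a 60 bp `AT` repeat embedded
  at identical coordinates in every species (identical so that the
  post-capture low-complexity screen, which needs exact repeats, sees it);
* reads of 150 bp drawn uniformly from targets (probability `f`) or from
  an i.i.d.-uniform background, both strands, error-free — the toolkit
  treats simulated reads as post-quality-trimming reads.

The truth manifest's intended verdicts are recomputed directly from the
emitted sequences (site-wise SNP density, true exon lengths, focal
presence), so an independent oracle can verify them, and the selection
pipeline recovers them exactly in the bundled configurations.

What passing these tests does **not** show: robustness to indels and
alignment error (the simulator emits gapless homologs; the merge machinery
handles insertions but is exercised only by constructed unit cases), to
sequencing error and chimeric reads, to base-composition bias, or to
paralogs old enough to assemble separately. Real transcriptome inputs
also bring fragmented and untranslated sequence the k-mer clustering has
not been tuned for.

## Numerical choices and degenerate inputs

* All coordinates are 0-based half-open everywhere in memory; conversion
  happens only at file boundaries (BED-like files are already 0-based).
* Alignment scores (1/−1/−2), seed sizes (21 clustering / 15 reference /
  24 blacklist / 31 mapping) and the X-drop (12, score +1/−2) are fixed
  constants of the method, documented rather than tuned.
* Ties everywhere break lexicographically (transcript ids, reference ids)
  or by fixed order (plus strand before minus), so identical inputs give
  byte-identical outputs regardless of file order.
* Empty locus lists, exon maps shorter than the bait, reads without seeds
  and missing assemblies are all valid inputs that produce empty outputs
  (with warnings where a user likely made a mistake); genuinely malformed
  inputs (duplicate FASTA ids, non-covering exon maps, reserved `-` in
  species names) are errors.
* Problem sizes used by the bundled tests and the reproduction script —
  10–30 loci, 4 species, 20,000 reads — were chosen as the smallest sets
  at which the binomial and filter-recovery properties are sharp.

## Known limitations

* The Tm model is intentionally simpler than vendor hybridization
  chemistry; absolute Tm cutoffs from capture-kit documentation cannot be
  transplanted onto it.
* The redundancy phrase "identity over the best ungapped offset" ignores
  gapped near-duplicates; at bait length 80 this is a negligible class.
* The pseudo-mapper is exact-seed based: reads diverged enough to share
  no 31-mer with any reference are invisible to it, so cross-clade
  capture experiments will read as lower on-target fractions than a
  sensitivity-tuned aligner would report.
* `cluster_orthologs` is quadratic in transcripts per species pair; it is
  meant for curated LCN candidate sets (hundreds to a few thousand
  transcripts), not raw assemblies.
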
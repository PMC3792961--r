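---
title: "Alignment refinement, threshold calling, and mutation simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment refinement, threshold calling, and mutation simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `alnrefine` computes and why its defaults
are what they are. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` compute.

## The problem

Short reads from polymerase-based sequencers carry errors that rise
toward the 3' end and cluster in error-prone genomic contexts;
seed-based gapped aligners additionally mis-place reads around indels
and, when reads are aligned against a local reference segment
("targeted" alignment), attract reads that originate elsewhere. A
threshold caller that consumes such an alignment directly converts
these artifacts into false positive SNPs and indels. `alnrefine`
intervenes between aligner and caller: it repairs what can be repaired
(re-gapping around indels, rewriting isolated low-quality mismatch
bases) and removes what cannot (mismatch-heavy, discordant, degenerate
reads).

## The mismatch model

All decisions rest on one counting rule. A read's differences against
the reference are recomputed from its sequence and CIGAR — the MD tag is
ignored, so alignments from any tool are treated identically, and `=`/`X`
operations are re-verified rather than trusted. The count is then:

* each substituted base: 1 (optionally only when its Phred quality is
  below `minq`, which biases the filter toward error-like mismatches);
* each indel, of any length: 1;
* each soft-clipped read end, of any length: 1.

So a two-mismatch threshold becomes a one-mismatch threshold for a read
already carrying one indel. Positions where the reference holds `N` are
excluded from comparison entirely (consistently, no variant is ever
called on an ambiguous reference base); a read `N` over a differing
reference base *does* count, since an uncalled base is evidence against
the alignment. Adjacent substitutions stay separate events; there is no
MNP merging. Hard clips and `N` (skip) CIGAR operations contribute
nothing; skips advance the reference.

## Local realignment

Indels present in any input read are catalogued by (chromosome,
position, type, length, sequence). A read is eligible for realignment
when it has at most one indel or one soft-clipped end (more complex
reads are left alone and subsequently filtered), and — if it is gapless
and unclipped — carries at least one substitution, because realigning
already-clean reads only degrades calls. For each catalogued indel
overlapping the read's span (widened by the indel length), two
candidates are formed: the 5' portion anchored and the 3' portion
shifted by the indel length, and vice versa. The candidate with the
fewest mismatches is accepted only when its count is less than or equal
to the original's. The choice between equal-count candidates was left
open by the procedure's description, so the package breaks ties
deterministically: fewest substitution events first, then leftmost gap
position. Sequence and qualities are never altered by realignment, only
position and CIGAR.

## Error correction

Error-correction mode first discards reads whose mismatch count exceeds
10% of their read length (`precorrection_rate = 0.10`, counting indels
and clips as one each) — such reads are beyond repair and would poison
the column statistics. After realignment, a pileup with per-read
backlinks is built and every column with a non-reference base is
examined:

* **quality rule** — a non-reference allele whose *mean* Phred quality is
  below `minq` (default 10) is rewritten to the reference base in every
  read carrying it;
* **frequency rule** — likewise when its allele frequency (allele
  observations / base observations at the column) is below `mfreq`
  (default 0, i.e. disabled);
* **multi-allele rule** — when several non-reference alleles co-occur,
  only the most frequent survives; the minority alleles are rewritten.
  Exact ties are left untouched (no principled winner);
* **pooled mode** (`msamp`) — frequencies are computed per read group,
  and a sample's non-reference bases are corrected below 0.8 for a
  homozygous sample or 0.3 for a heterozygous one. Whether a sample is
  homozygous or heterozygous cannot be inferred from the alignment, so
  it is a required per-sample user input.

Corrected bases keep their original quality scores; a base equal to the
reference is never modified; indels and soft clips are never
"corrected", only counted and filtered. The same `minq` name covers the
counting threshold and the correction threshold in the original
description; since their roles differ, the package exposes them as two
parameters (`minq_count`, unset by default, and `minq_correct`,
default 10).

## Filtering

Removal reasons, applied in order (one reason is logged per read):
mismatch count > `num` (default 2); pair total > `fnum` (default
`floor(1.7 * num)`, the only integerization consistent with the printed
defaults 2 and 3); mismatch fraction > `mrate` (unset by default — the
10% pre-filter of error-correction mode is a separate fixed stage, as
the two rules are described separately); more than two indels; soft
clips at both termini; discordant pair (mate unmapped, or |insert| >
mean + 5 SD, with mean and SD estimated from all properly oriented
input pairs); and, **only when realignment is disabled**, any
substitution within the terminal 2 bp of the read — with realignment on,
terminal mismatches are usually repaired instead. `fpair` (default on in
error-correction mode) removes the surviving mate of every removed
paired read.

## The caller

SNPs: individual non-reference bases below `qual_base` (default 3) are
discarded before the majority non-reference allele is chosen — filtering
first, then majority, keeps a handful of low-quality bases from deciding
the allele. A tie between two alleles yields no call. The call requires
frequency ≥ `freq` (default 0.8) over the column depth, mean alt base
quality ≥ `qual_ave` (default 20), and support ≥ `num` (default 2) when
the frequency is at least 0.9 (homozygous) or ≥ `tnum` (default 3) below
it (heterozygous). `maxr`, when set, caps the reads covering the
non-reference allele — a guard against collapsed repeats; a practical
setting is 3× the mean depth. Deletion placeholders (`*`) count toward
depth but never toward SNP support.

Indels: support is the count of reads carrying the *identical* indel
(type, length, sequence); the gates are `num` and `freq`. The stated
frequency adjustment for indels parses ambiguously in its source; the
package implements the only reading that keeps frequencies ≤ 1 and
raises support in low-coverage regions: the denominator is the column
depth minus the number of reads whose 3' termini (including soft-clipped
ends) lie at the site, because a read ending exactly there cannot attest
an indel beginning past its end. Finally, SNPs within 3 bp of a
homozygous indel call are suppressed (mis-gapped reads around real
indels generate exactly such satellite SNPs); heterozygous indels do not
suppress.

Calling from SAM/BAM builds the pileup internally and is exactly
equivalent to calling from a parsed text pileup of the same reads (a
tested invariant). Both classic 10-column consensus pileup (depth in
column 8) and 6-column mpileup (depth in column 4) dialects are parsed;
the dialect must be stated explicitly because short lines are
column-ambiguous. Base qualities default to Phred+33 with a Phred+64
switch.

## The simulator

`mutate_genome()` introduces SNPs and 1–6 bp indels at defaults of 0.2%
and 0.02% of genome positions. Counts are spread over chromosomes
proportionally to length with largest-remainder integerization (ties by
input order), so totals are exact and seed-independent.

*Substitutions.* "Transitions 4-fold more frequent than transversions"
is encoded per site as P(transition) = r/(r+1) with r = `titv_ratio` =
4, each transversion partner taking half the remainder — this makes the
genome-wide transition:transversion **count ratio** exactly r, the
literal reading of the claim. Users preferring the 2:1 convention (r
counted against each transversion separately) can set `titv_ratio`
accordingly; the encoding is a parameter precisely because the
convention is ambiguous in the field.

*Indel lengths.* The table 66/17/7/7/2/1% for 1–6 bp is applied by
largest-remainder apportionment rather than sampling, so the realized
histogram over n indels is deterministic and testable exactly (10,000
indels give precisely 6,600/1,700/700/700/200/100); a sampling mode is
available behind `length_sampling = "sample"`. Reference edits are split
50/50 between insertions and deletions, a choice the package documents
here because no direction was specified. Inserted sequence is uniform
over A/C/G/T.

*Placement.* Mutations avoid `N` bases and their immediate
neighbourhood and are spaced at least one base apart — implemented
conservatively as a minimum gap of the largest indel footprint plus one,
so no two edits can interact. How colliding mutations should be handled
was unstated; rejection-plus-respacing is this package's choice. An
optional clustered mode places a requested fraction of variants in
groups of three within one read length, for stressing the pair-total
(`fnum`) trade-off on clustered variants.

*The truth table frame.* The mutated genome serves as the alignment
reference, and the reads come from the unmutated sample — so the caller
observes the *complement* of each reference edit (an insertion written
into the reference manifests as a sample deletion, and vice versa). The
truth table therefore records the caller-frame variant (type, ref, alt,
position in mutated coordinates), with the original coordinate and the
applied reference edit kept as provenance columns. This is the only
frame in which exact matching of calls against truth — same chromosome,
position, type, and alleles — is well defined. `apply_variants()` applied
to the mutated genome with its truth table reproduces the original
genome byte-exactly, a tested invariant.

*Evaluation.* TPR = 100 × matched truth records / truth records;
FPR = 100 × unmatched calls / total calls; SNPs and indels are scored
separately. Zero calls give FPR 0 with a warning; an empty truth table
makes TPR undefined and is an error.

## The synthetic read generator

`generate_reads()` emits paired-end reads (defaults: 75 bp, insert
270 ± 20 bp, depth 20 — a typical paired-end resequencing configuration)
pre-aligned at their true positions, with substitution errors injected
at a per-base rate that ramps toward the 3' end (default 0.12% rising to
~0.8%, matching the error regime of the heterozygous-calling simulations
this design targets) and matching low quality scores (q5 errors against
q35 correct bases). A cluster mode forces a fixed per-read error count
inside a chosen region, emulating clustered low-quality errors around
low-coverage regions. `lift_reads()` plays the role of a perfect
aligner, re-expressing original-genome reads as gapped alignments on the
mutated reference via the truth table; read ends falling inside removed
reference sequence are soft-clipped, exactly as an aligner would.
`inject_foreign_reads()` forges coordinates of donor-genome reads into a
target region with a guaranteed minimum mismatch count, reproducing the
targeted-alignment failure mode.

What the generator does **not** emulate: sequence-context-specific error
hotspots (e.g. GGC-motif errors), quality mis-calibration, PCR
duplicates, coverage–GC bias, and genuine mapping ambiguity from
repetitive sequence. Passing tests therefore demonstrate the
correctness of the algorithms under controlled error structure, not
performance on real libraries; on real data the relative sizes of the
effects (how many reads are removed, how many bases corrected) will
differ.

## Numerical and degenerate-input choices

* Coordinates are 1-based and intervals closed everywhere user-visible.
* All randomness flows from explicit seeds; identical seed and
  parameters give byte-identical simulator and generator output.
* Realignment ties: fewest mismatches, then fewest substitutions, then
  leftmost gap.
* Caller allele ties: no call.
* Indel-frequency denominator ≤ 0: no call.
* Frequencies reported are capped at 1.
* Empty inputs: an empty alignment writes a valid header-only SAM; an
  empty pileup yields an empty, well-formed variant table.

## Problem sizes

The test suite exercises genomes of 0.3–60 kb at depths 4–20 for the
pipeline stages (thousands of reads, which the pure-R row-level engines
handle in seconds) and 4–10 Mb genomes for the simulator's
distributional checks (60,000 SNPs for the transition/transversion
ratio, 10,000 indels for the length histogram, and the default-rate
densities on 10 Mb). These sizes were chosen so each statistical check
has negligible Monte-Carlo slack while the whole suite stays
desk-scale.

## Known limitations

* The refiner is designed for DNA resequencing; RNA-seq (spliced, `N`
  CIGAR) reads pass through the mismatch model but splice-aware
  realignment is not attempted.
* Reads with two or more indels are never realigned (and are removed by
  filtering) — joint multi-indel realignment is out of scope.
* The caller is a single-sample threshold filter: no genotype
  likelihoods, no joint calling, and indels beyond a few bp are untested
  policy even though the code is length-agnostic.
* BAM sorting/indexing and duplicate removal are delegated to external
  tools (`samtools sort/rmdup`); CRAM and VCF output are not supported
  (tabular variant output only).
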
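---
title: "Detecting repeat-mediated mitogenome recombination from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting repeat-mediated mitogenome recombination from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorecomb)
```

## The biological problem

Plant mitochondrial genomes are usually assembled as a single "master circle",
but in many species that circle is only one of several coexisting
conformations. Pairs of large direct repeats (kilobases long, often with 100%
copy identity) act as substrates for intramolecular homologous recombination:
recombining at one direct repeat splits the master circle into two
sub-genomic circles, and recombining at both exchanges the order of the
segments between them. A genome carrying two independent two-copy direct
repeats therefore has four possible isomers — two master-circle arrangements
and two pairs of sub-circles — and a DNA preparation from living tissue is a
mixture of them.

Long reads settle which conformations are present. Around each repeat copy
there are four possible flank pairings (two native, two recombinant); a read
that is long enough to cover the repeat *plus both flanks* pins down one
pairing unambiguously. `mitorecomb` implements this junction-support
statistic together with the descriptive analyses that routinely accompany an
organelle genome report: microsatellite (SSR) detection, dispersed-repeat
detection, relative synonymous codon usage (RSCU), and plastid-to-
mitochondrion transfer (MTPT) detection.

## Junction references and the p1..p8 convention

For a repeat `R` with copies `a` and `b`, `build_path_references()` extracts

* `p1 = left(a) + R + right(a)` and `p2 = left(b) + R + right(b)` — native;
* `p3 = left(a) + R + right(b)` and `p4 = left(b) + R + right(a)` — recombinant,

with 500 bp flanks by default; the second repeat gets `p5..p8` analogously.
Published figures label these paths per-figure, so the package fixes its own
deterministic convention: path labels attach to *flank pairings* ordered
native-first. Any agreement with a drawing's numbering beyond that is
coincidental, which is harmless because the recombination statistics only use
the native/recombinant partition.

## What "completely spanned" means here

A read supports a path if it aligns to that path's reference end to end. The
package operationalises this with a bit-parallel semi-global (infix) edit
distance (Myers' algorithm, blocked to arbitrary reference lengths): the
whole reference must be consumed against some substring of the read, and the
full-reference identity `1 - dist/|ref|` must reach `min_identity`
(default 0.80).

Full-reference identity alone is not discriminative, and this is worth
spelling out. A 500 bp flank is only ~12% of a reference built around a
multi-kilobase repeat; aligning the flank-swapped reference against a read
that actually covers the *native* junction costs roughly
`0.5 x flank_len` extra edits (random DNA against random DNA), which leaves
the identity far above 0.80. Counting with identity alone therefore pushes
every read onto native *and* recombinant paths. For this reason the spanning
test additionally requires both *end anchors* — windows of up to 250 bp at
each reference end — to align at `min_identity` at read positions consistent
with the full alignment. A native read fails the recombinant reference's
swapped-flank anchor (unrelated sequence cannot reach 0.80 identity over
250 bp), while a genuine recombinant read passes it. In the error-free limit
(`min_identity = 1`, `max_end_slack = 0`) the whole criterion reduces exactly
to substring containment, which is how the test suite validates the aligner
against a brute-force oracle.

Exposed knobs, with defaults: `flank_len` (500 bp, as junction references are
conventionally built), `min_identity` (0.80, conservative for noisy long
reads), `max_end_slack` (0 bp; positive values trim the reference before
alignment for data where read ends are unreliable). `summarize_recombination()`
calls a repeat *recombinationally active* when all four of its paths have at
least `min_support` (default 1) spanning reads, and reports the recombinant
fraction `(p3+p4)/(p1+p2+p3+p4)` with an exact binomial confidence interval.

## Isomer enumeration

`enumerate_isomers()` treats the assembly as a segment/link graph in which a
two-copy repeat node has two entries and two exits. Each repeat contributes
two entry-to-exit pairings, so `k` repeats give `2^k` pairing combinations;
each combination decomposes into circles, and results are deduplicated up to
rotation and reverse complement of each circle (a DNA circle has no intrinsic
origin or strand). Two direct repeats yield the canonical four isomers.
Only forward (`+/+`) links are accepted: inverted-repeat pairings produce
segment inversions rather than circle splits, and the package reports them as
an unsupported-orientation error rather than guessing at classifications —
an explicit extension point.

## The synthetic-data generator

`sim_config()` defaults encode the study system the package models: a
515,187 bp circular genome at GC 44.05% with planted direct repeats of
9026 bp and 7040 bp (copies 100% identical), and Nanopore-like reads with
mean length 17,520 bp at 75-fold depth. Choices the data do not pin down,
made once and kept:

* **Segment lengths.** The four unique segments split the non-repeat residue
  40/25/20/15%. The real unitig lengths of such assemblies are unpublished;
  the split is a stand-in that preserves the six-contig topology, not a
  reconstruction.
* **Read-length distribution.** Truncated normal (sd 9000 bp, minimum
  200 bp, capped at the source circle length). Only the mean and N50 of the
  emulated data are known; a truncated normal with this sd reproduces the
  right order of dispersion without claiming to match the empirical shape.
* **Error model.** Total per-base error 5%, split
  substitution:insertion:deletion = 2:1:1 — a coarse long-read-like profile,
  fully configurable. No quality-score realism is attempted; FASTQ output
  carries constant dummy qualities.
* **Isomer weights.** Default `A = 0.37, B = C = D = 0.21`: the master
  arrangement dominates while all recombinant conformations are present, the
  pattern junction support shows for recombinationally active repeats.

Reads carry truth labels (source circle, interval, strand, junction windows
fully contained), so parameter-recovery tests can compare alignment-based
counts against interval arithmetic. With a fixed `seed`, all outputs are
byte-identical across runs.

What passing tests on this generator does *not* show: robustness to
basecaller-specific error profiles, chimeric reads, coverage biases, or
heteroplasmy below the configured mixture weights. The generator produces
i.i.d. base composition, so it also underestimates the SSR and short-repeat
density of real organellar DNA.

## Repeat finders

`find_ssrs()` reports maximal perfect tandem runs of 1-6 bp motifs with
MISA-style minimum copy numbers (10, 5, 4, 3, 3, 3 for mono- through
hexanucleotides). A run's motif must be primitive (not itself a repetition of
a shorter motif), so a dinucleotide run is never double-reported as a
tetranucleotide; copies are complete repetitions only.

`find_dispersed_repeats()` reports maximal repeat pairs of the four
REPuter kinds — forward, reverse, palindromic, complementary — with at most
`max_mismatch` Hamming mismatches (default 3) and length at least `min_len`
(default 30 bp). Candidates come from exact k-mer seeding with
`k = ceiling((min_len - max_mismatch)/(max_mismatch + 1))`, which the
pigeonhole principle makes complete: any qualifying window contains an exact
run of at least that length. (The naive `ceiling(min_len/(max_mismatch+1))`
is *not* a valid bound — splitting a 30 bp window across 3 mismatches can
leave a longest exact run of 7 < 8 — hence the subtracted numerator.) Seeds
are extended along their diagonal to the `(max_mismatch+1)`-th mismatch on
each side; the maximal windows are read off the mismatch positions, and only
the leftmost seed of each exact run triggers an extension, which is what
keeps the self-comparison of a half-megabase genome in seconds.

E-values follow a two-position Bonferroni bound on the binomial match
probability: `E = n^2 * C(len, mm) * (1/4)^(len-mm) * (3/4)^mm`, filtered at
`1e-5` by default. This documented model is *stricter* near the boundary
than REPuter's statistic — a 30 bp pair with 3 mismatches on a ~515 kb
genome scores around 2e-2 and is filtered — so counts of borderline records
are not comparable across tools; the cutoff and the model are configurable.

**Circularity.** Both finders accept origin-wrapping repeats by scanning the
doubled sequence and canonicalising records back to `[1, n]`; windows clipped
at the unrolled ends are dropped because every true circular window also
appears unclipped in another image. Linear tools are reproduced exactly by
passing `circular = FALSE`.

## Codon usage

`extract_cds()` parses GenBank flat files directly (LOCUS/FEATURES/ORIGIN),
evaluating arbitrarily nested `join`/`complement` locations by recursive
descent; `complement(join(...))` reverse-complements the spliced
concatenation, per the GenBank convention. Duplicated gene copies each
contribute a sequence. Trans-spliced genes are assembled only when annotated
as a single joined feature — stitching separate features together would
require gene-name heuristics this package deliberately avoids.

`compute_rscu()` computes `RSCU(c) = count(c) * k / family_total` over each
amino acid's `k` synonymous codons. Stop codons are excluded by default
(the MEGA convention; toggle with `include_stop`), codons containing `N` are
skipped, and a trailing partial codon is dropped. RNA-edited start codons
are counted as written in the DNA, since RSCU here describes the genomic
sequence. The standard genetic code is the default; plant mitochondria use
it, and other tables are available via `genetic_code`.

## MTPT detection

`find_homologous_fragments()` drives NCBI BLAST+ (`-task blastn
-word_size 7 -evalue 1e-10`, tabular output) with the mitogenome as database
and the plastome as query — the standard protocol for MTPT surveys — then
collapses hits to unique mitogenome locations: two hits whose mitogenome
intervals overlap at least 95% of the shorter one (typically the plastome's
inverted repeat hitting one insertion twice) are merged, keeping the better
E-value. Fragments are ranked by length (`MTPT1` is the longest), and
`summarize_mtpt()` totals fragment lengths *summed over unique locations*,
not a positional union — the accounting under which MTPT content is
conventionally reported as a percentage of the mitogenome.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data, at
sizes chosen so each check finishes in seconds to a couple of minutes on one
CPU: full-scale composition checks on the 515 kb default genome; junction
parameter recovery on a 50 kb genome with 3 kb and 2 kb repeats, 400 reads at
5% error (≈450 junction-spanning events, enough for binomial intervals of
half-width ≈ 0.05); oracle-equivalence sweeps on sequences of 300-2000 bp
over 100 seeds. Ties and degeneracies are handled deterministically
throughout: circles linearise at their lexicographically least rotation
(Booth's algorithm), dispersed pairs are stored with `start_a <= start_b`,
and `N` bases match nothing — including other `N`s — so ambiguity never
creates a repeat.

## Known limitations

* Short-repeat-mediated, low-frequency recombination is out of scope: with
  default flanks the statistic needs reads spanning repeat + 1 kb.
* Inverted-repeat recombination (inversion isomers) is detected only as a
  structural error, not enumerated.
* The dispersed-repeat E-value model is deliberately simple; counts near the
  cutoff will differ from REPuter's.
* BLAST+ must be on `PATH` for MTPT detection; there is no pure-R fallback.
* GenBank parsing covers the feature-table subset organelle annotations use;
  exotic location operators (`gap`, remote accessions) are rejected with a
  warning rather than guessed.
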
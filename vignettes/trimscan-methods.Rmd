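---
title: "Discovering and annotating TRIM and TRIMp3 retrotransposons with trimscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and annotating TRIM and TRIMp3 retrotransposons with trimscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

Terminal repeat retrotransposons in miniature (TRIMs) are short
(typically under 1 kb) non-autonomous LTR retrotransposons. They keep
the full structural grammar of their autonomous relatives — two
identical long terminal repeats (LTRs), a primer-binding site (PBS)
just inside the 5' LTR, a polypurine tract (PPT) just before the 3'
LTR, and a 4–6 bp target site duplication (TSD) created at integration
— but encode no proteins, so they are mobilized in trans. A subset of
TRIMs additionally carries a small-RNA-derived sequence inside the LTRs
that works as an internal RNA polymerase III promoter: either a
tRNA-like segment (a type-2 promoter with box A and box B) or a partial
5S rRNA segment (a type-1 internal control region with box A, the
intermediate element IE, and box C). trimscan calls pol III
promoter-bearing families *TRIMp3* (subdivided into `TRIMp3_tRNA` and
`TRIMp3_5S`) and canonical families *TRIMp2*.

trimscan implements the complete discovery-and-annotation workflow for
these elements: seeded genome scanning, family clustering, consensus
construction with iterative flank extension to the element termini,
structural annotation (LTR pair, TSD, PBS, PPT, promoter boxes),
classification, full-length and solo-LTR copy counting, and a
Jukes–Cantor/BioNJ phylogeny stage for promoter-derived sequences. A
synthetic-genome generator with a complete truth table makes every
stage testable end to end.

## The discovery procedure

`run_discover()` wires the stages in the order a repeat-library
curator would apply them:

1. **Scan.** Each seed sequence (a known consensus or a representative
   copy) is searched against the genome by seed-and-extend local
   alignment: exact 11-mers of the query are located with a
   precompiled dictionary, chained into candidate windows on both
   strands, and each window is verified by Smith–Waterman alignment
   (+1 match, −1 mismatch, −5 gap open, −1 gap extension; `N` and
   ambiguity codes score as mismatches). Hits overlapping more than
   50% reciprocally are merged.
2. **Cluster.** Hit copies are clustered by single linkage under the
   predicate "the local alignment covers ≥ 75% of the shorter
   sequence at ≥ 75% identity" — the classic thresholds for
   delimiting repeat families.
3. **Elongate.** For each cluster, up to 10 of the best copies are
   re-extracted with 500 bp genomic flanks, aligned center-star (the
   center is the copy with the greatest total alignment score to the
   others), and summarized by the 50% majority rule: columns that are
   half gaps are dropped, a base is emitted when it reaches half of
   the non-gap characters, ties fall back to the fixed order
   A < C < G < T, and sub-majority columns become `N`. The consensus
   is then searched for an LTR pair and per-copy TSDs; element
   boundaries are refined (see below) and the loop repeats until the
   per-copy boundaries are stable within 2 nt across rounds.
4. **Annotate and classify.** The trimmed consensus is partitioned
   into LTR–internal–LTR; the internal 5' 50 nt are searched for a
   PBS, the internal 3' end for a PPT, and both LTRs for the two
   promoter architectures; the family class follows from the promoter
   scan.
5. **Count.** The genome is re-scanned separately with the LTR
   consensus and the internal consensus; a hit is full length when its
   aligned length exceeds 90% of the respective consensus *and* its
   identity exceeds 90% (both strict, by the literal counting rule).
   Solo LTRs — single LTRs left behind by LTR–LTR recombination —
   are called when an LTR hit covers ≥ 90% of the LTR consensus, has
   no internal hit within 50 nt, and is directly flanked by a 4–6 bp
   TSD.

## Boundary refinement: why TSD evidence is a vote, not a veto

The element termini are determined jointly by the LTR pair and the
TSDs. A windowed local alignment of the two element ends can wander a
few bases into flanking sequence whenever the local match density is
above one half, so the LTR call alone fixes the boundaries only to
within a few nucleotides. trimscan therefore refines boundaries with a
per-copy shift search (±8 nt on each end) that enumerates every exact
flank duplication of length 4–6 at every candidate boundary, and then
decides the family TSD length by *support maximization*: the length
found in the most copies wins, with ties resolved toward the longer
length. Two systematic artifacts motivate this exact rule:

* a boundary shifted *into* the element truncates every copy's TSD by
  the same amount, so truncated lengths reach full support — they are
  eliminated only by the longer-ties rule;
* a boundary shifted *outward* gains a one-base-longer pseudo-TSD in
  the ~1/4 of copies whose element edge base happens to equal the
  background base beyond the TSD — chance agreement that cannot reach
  full support, so it loses the vote.

A third, rarer ambiguity arises when the element's terminal bases
coincide with the background beyond the TSD: boundaries shifted by the
length of the coincidence carry an equally valid TSD. Those cases are
resolved by terminal agreement — among equal-length candidates, the
boundary whose first and last six bases best match the element
consensus termini wins. Finally, after the elongation loop converges,
the consensus is rebuilt once from the refined per-copy intervals with
tight (50 bp) flanks and polished by realigning all copies against it
until it no longer changes. The polish step removes the star center's
private indels, whose inconsistent gap placements can otherwise spread
homologous bases over sub-majority columns.

## Primer-binding-site typing

Two priming modes occur in nature and are both modelled. Most LTR
retrotransposons prime reverse transcription at the 3' end of a mature
tRNA, so the PBS is the reverse complement of the tRNA 3' terminus
including the post-transcriptionally added CCA. A minority — notably
several fungal lineages mobilized by Copia-superfamily partners —
prime at the anticodon loop of a 3'-truncated tRNA; because several of
the tRNAs used this way carry introns just downstream of the
anticodon, a contiguous match to the *spliced* tRNA across the splice
junction is diagnostic of priming by the mature molecule.

`detect_pbs()` searches the first 50 nt of the internal region for
both modes against a tRNA library and reports the longest
complementary stretch with at most one mismatch. A stretch must start
and end on paired bases, and each internal mismatch must be
compensated by two extra paired positions beyond the 8 nt minimum;
without these two conditions a chance match carrying a terminal or
barely-compensated mismatch can outrank a genuine perfect pairing, and
the empirical false-positive rate on random sequence rises well above
the 5% design bound.

## Promoter motif models

The tRNA-type (type 2) promoter is modelled as bipartite box A —
`TRGCY`, a 2–8 nt linker, then `YGG` — with at most one mismatch
across both parts, followed by an exact box B `GGTTC` starting 25–55
nt after the box A start. The spacing window follows the anatomy of
tRNA genes, where box A sits near position +10 and box B near +55;
widening the window to 80 nt (or allowing a box B mismatch) pushes the
false-positive rate on random 300-mers above 10%, while the chosen
window keeps it near 6% with family-level sensitivity at 5% divergence
above 90% (a family is scanned through both LTR copies, so a promoter
degraded in one LTR is usually still seen in the other).

The 5S-type (type 1) internal control region is three IUPAC motifs in
order — box A, IE, box C — with per-box mismatch budgets and spacings
read from a plain-text configuration
(`inst/extdata/motifs_5s.txt`). The shipped default motifs were drawn
from a synthetic canonical internal-control-region sequence
(`inst/extdata/synthetic_5s_rDNA.fasta`, labelled synthetic; it is not
a natural 5S gene) and can be replaced wholesale by the user's own
configuration — motif strings are data, not code.

Classification applies the promoter scans to both LTRs; ties between
the two architectures are left unclassified with a warning. The
canonical sub-1 kb TRIM length bound is treated as soft: families of
1000–1300 bp keep their class with a `long_trim` flag, since natural
families slightly above 1 kb are on record; beyond 1300 bp the TRIM
label is withheld.

## The phylogeny stage

Promoter-derived or tRNA-like segments are compared with Jukes–Cantor
distances, d = −(3/4)·ln(1 − 4p/3), where p is the mismatch
proportion over columns where both rows carry a base (pairwise
deletion). At p ≥ 0.75 the formula is undefined; such pairs are
capped at 5 substitutions/site and flagged saturated — divergent
promoter alignments do reach that regime. Trees are built with BioNJ
(variance-weighted neighbor joining; negative branch lengths are
clamped to zero) and supports come from 100 seeded column bootstrap
replicates, reported as the percentage of replicates containing each
bipartition of the reference tree.

## The synthetic-data generator

`plant_elements()` is the package's test bed, not a fixture: it
emulates exactly the observables the annotation stack measures. A
family ancestor is LTR + internal + LTR with identical LTRs, the
requested promoter boxes at randomized but recorded offsets, a PBS
complementary to a chosen tRNA in the chosen mode (16 nt across the
anticodon stem-loop for anticodon priming, 12 nt including CCA for
3'-end priming), and a ≥ 10 nt purine-rich PPT at the internal 3'
end. Copies descend from the ancestor by a star phylogeny with i.i.d.
substitutions (default 2% per site), short 1–3 nt indels at one fifth
of the substitution rate, random strands, and a duplicated 4–6 bp
target sequence at both flanks; a configurable fraction of copies is
collapsed to a single LTR that keeps the outer TSD pair, modelling
LTR–LTR recombination. The background is i.i.d. nucleotides with
configurable GC.

What the generator deliberately does *not* model — nested insertions,
segmental duplications, tandem arrays, 5' truncations, non-uniform
background composition, phylogenetically structured copy histories —
bounds what passing tests show: they demonstrate correctness of the
detectors and of the discovery loop under clean repeat biology, not
robustness to the full texture of real assemblies, where masking and
manual curation still matter.

## Study sizes and numerical choices

The validation study (`run_planted_study()`) plants three families in
a 2 Mb genome — tRNA-promoter/anticodon-loop/5 bp TSD,
tRNA-promoter/3'-end/4 bp TSD, and 5S-promoter/3'-end/5 bp TSD — with
10 copies each at 2% divergence and 30% solo LTRs, and requires
consensus identity ≥ 99%, boundaries within 2 nt, exact TSD lengths,
exact PBS calls, correct classes, and counts equal to the truth table.
Twenty seeded replicates form the validation batch. Per family, full
recovery succeeds in roughly 92-97% of draws; per twenty-seed batch
this typically means two to five seeds with at least one imperfect
family. The residual failures have two known causes: the strict
>90%/>90% counting rule occasionally excludes a legitimately planted
copy that drew an unusually heavy mutation load, and a boundary
coincidence in a repeat-like flank context can survive all cross-copy
votes.

Other fixed numerical choices: alignment scoring +1/−1/−5/−1
(configurable); seed k-mer 11 with candidate windows requiring ≥ 3
seeds for queries of 100 bp and longer; LTR pair detection at ≥ 80 bp
aligned length and ≥ 80% identity within end windows of `max_ltr` +
100 bp; TSDs exact with the longest of 4–6 winning; solo-LTR boundary
correction from the hit's query coordinates with up to ±6 nt of
jitter, preferring the family's known TSD length. Coordinates are
0-based half-open internally and 1-based inclusive in GFF3 output.

## Known limitations

Single-linkage clustering at 75/75 can chain families that share a
long homologous segment; the cluster boundary then depends on
transitive links exactly as it does for the clustering tools the
thresholds come from. Tandem or near-adjacent copies closer than one
query length can merge into one candidate window during scanning and
be reported as one hit. Families whose two LTRs have diverged below
80% identity are returned unpartitioned. The BioNJ stage takes any
alignment the caller supplies; choosing the promoter segment to align
is left to the user.
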
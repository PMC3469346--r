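---
title: "Methods: from gliadin transcripts to a per-locus CD-epitope census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gliadin transcripts to a per-locus CD-epitope census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliascan)
```

## The analysis in one paragraph

Bread wheat is an allohexaploid: its γ-gliadin storage proteins are encoded
by gene clusters on three homoeologous loci (*Gli-A1*, *Gli-B1*, *Gli-D1*)
inherited from three diploid ancestors. Because celiac-disease (CD) T-cell
epitopes are 9-mer peptides embedded in the gliadin repeat domains, the CD
burden of a wheat line is a product of (i) which gliadin isoforms are
transcribed and at what depth, (ii) which genome each isoform derives from,
and (iii) the immediate sequence context of each epitope core, which decides
TG2 deamidation and protease resistance. `gliascan` reconstructs that chain
from a transcript FASTA: transcripts → contigs → deduced proteins → genome
assignment → epitope scan → depth-weighted per-locus census.

## Contig assembly

Transcripts are clustered by **single linkage** over the graph whose edges
connect pairs with pairwise identity ≥ `identity_threshold` (default 0.98)
across an aligned overlap of ≥ `min_overlap` nucleotides (default 300, the
scale of the shortest contigs the analysis is meant to retain). Single
linkage was chosen deliberately: an identity *band* such as "98–99%" implies
transitive merging, and it makes the partition refine monotonically as the
threshold rises (a property the tests assert). Clusters with fewer than
`min_members` transcripts (default 4) are diverted to a reported minor bin —
the census describes reproducibly observed isoforms, not singletons.

Pairwise identity uses a **fitting (glocal) alignment** (match +1, mismatch
−1, gap −2, linear): all of the shorter sequence must align, while the
longer sequence's overhangs are free terminal gaps, and identity is matches
over aligned columns only. This is the natural geometry for partial ESTs
inside full-length cDNAs. We do not use a dovetail overlap alignment: with
end gaps free in *both* sequences, the optimum clips terminal mismatches
outright (a 4-mer differing in its last base would score as 100% identical),
which corrupts identity near the clustering threshold. The aligner is
implemented in C++ (`src/align.cpp`) because clustering needs all-vs-all
alignments; an independent pure-R dynamic program serves as its oracle in
the tests. Exact duplicate sequences are collapsed before the quadratic
stage, which is what makes realistic depths (hundreds of transcripts per
gene) cheap.

**Consensus calling** star-aligns members to the longest member and takes
the strict per-column majority, ties broken in the fixed order A<C<G<T, and
majority-gap columns dropped. Terminal gaps — i.e. columns a partial EST
simply does not cover — do not vote; otherwise EST-dominated contigs would
have their consensus ends voted away by "absent" majorities.

## Translation, pseudogenes, and domain segmentation

Inputs are coding-strand by contract, so translation is frame-fixed with no
reverse-complement search. A codon containing `N` or any other IUPAC
ambiguity translates to `X`. An internal stop truncates the protein and
marks the record; those **pseudogene** contigs are excluded from the census
by default (the census describes expressed protein) with the exclusion count
reported, and a flag re-includes them. The pseudogene report carries the 12
residues preceding the stop because the recurrent natural truncation in
A-genome gliadins arises from C→T transitions after a characteristic
`QPQ(Q/L)QFPQPQQP` motif.

γ-Gliadins have the canonical architecture S–I–R1–NR1–R2–NR2: a signal
peptide, a short unique N-terminal domain, a P/Q-rich repeat domain, a
conserved domain with six cysteines, a second repeat domain, and a terminal
conserved domain with two cysteines. Segmentation anchors on the two motifs
that are empirically invariant: NR1 begins at the first `NPC`; NR2 ends
after the last `MCN`. The signal peptide is a fixed-length prefix
(`signal_length`, default 19 residues) rather than a prediction — no
predictor is assumed, and 19 is the conventional γ-gliadin signal length.
The repeat/non-repeat boundaries use a windowed composition rule: a repeat
domain starts at the first position that (a) itself is P or Q and (b) opens
an 8-residue window with ≥ 50% P/Q; it ends at the first non-P/Q position
whose window drops below 50%. Condition (a)/(the non-P/Q mirror) is a
deliberate refinement of a bare window rule: windows that merely straddle a
boundary otherwise pull it several residues into the neighbouring domain.
With this rule the segmentation recovers the synthetic generator's
construction intervals exactly, which the tests assert. Missing anchors
degrade gracefully (domains III–V reported absent, never an error).
Coordinates are 0-based half-open throughout.

## Distances, neighbor joining, genome assignment

Distances are p, JC69 or K2P (default **K2P**) with pairwise or complete gap
deletion. The published census was built with MEGA's Maximum Composite
Likelihood distances; we do not replicate that model bit-exactly — it is
tool-specific — and document K2P as the approximation, which is why distance
figures should be compared on a tolerance, not exactly. Saturated pairs
(correction logarithm undefined) are capped at 5 substitutions/site with a
warning and recorded, never emitted as infinities. Neighbor joining is the
Saitou–Nei Q-criterion agglomeration with deterministic tie-breaking (lowest
label-index pair) and negative branch lengths clamped to zero with the
deficit moved to the sister branch; on additive matrices it provably
recovers the generating topology, which the tests check exhaustively at
small n against `ape::nj` as an independent implementation. Bootstrap
supports resample alignment columns with a single integer seed.

Genome assignment replaces visual tree inspection with an explicit rule:
each contig consensus is compared against every diploid reference over the
**domain III–V region** (the region all partial transcripts share), the mean
distance per reference genome is taken, and the contig is assigned to the
nearest genome's locus only if the margin to the second-nearest exceeds
`min_margin` (default 0.01 substitutions/site); otherwise it is
`unassigned`, with the evidence (per-genome means, margin) reported. Two
implementation choices matter here. First, the contig is aligned *pairwise*
to each reference rather than profile-inserted into a maintained multiple
alignment — equivalent evidence with far less machinery. Second, those
alignments use a stiff gap penalty (−8): gliadin repeats are low-complexity,
and with cheap gaps an optimal alignment can re-register repeat units
between unrelated lineages and erase the genome signal; expensive gaps
reserve indels for genuine repeat-count differences. At the divergence
scales seen among real γ-gliadin clones (within-genome means of ~0.2–0.8
substitutions/site, i.e. a between/within ratio near 2) some contigs are
genuinely ambiguous under a margin rule — the original analysis also needed
an auxiliary homology step for part of the B-genome transcripts — so
`unassigned` is an expected, honest outcome there; at a 3× ratio assignment
is essentially perfect (the acceptance suite requires ≥ 95%).

## Epitope screening, deamidation, digestion

The registry ships the nine canonical γ-gliadin 9-mer cores in both
nomenclatures; scanning is **exact and overlap-counting** — fuzzy matching is
deliberately excluded because the census semantics count canonical cores,
and overlapping instances are all counted because the repeats genuinely
stack them (a single 17-mer repeat carries four instances of three types).
Both instance counts and distinct-type counts are always reported.

TG2 deamidation uses three rules, each recorded with its classification:
a Q followed-but-one by P (QxP) with the intervening residue not P is a
*primary* target; a Q immediately before P is not deamidated; and *moderate*
targets are looked up in a curated list of centred 7-residue contexts
(3 left + Q + 3 right, `-`-padded) shipped as
`inst/extdata/moderate_contexts.tsv` and user-replaceable. The moderate
class is data-driven on purpose: published annotations of natural variant
peptides distinguish Qs with identical local trigram contexts, so no
position-free short rule can generate them; a 3+3 window is the smallest
symmetric context that is internally consistent across all thirteen
published variants, and the tests verify every one. `deamidate_peptide()`
emits the Q→E-substituted peptide (moderate targets optionally included).

Digestion rules follow the standard specificity tables: trypsin after K/R,
chymotrypsin (high) after F/Y/W, chymotrypsin (low) after F/L/M/W/Y/H, all
blocked before proline, with H additionally blocked before M/W; the table is
overridable (e.g. to add pepsin, which is omitted from the defaults because
the annotated digestion maps use only trypsin/chymotrypsin).
Proteolysis-resistant fragments are the maximal intervals between
consecutive cleavage sites; fragments containing at least
`min_epitope_instances` fully-contained matches are reported, and with a
threshold of 0 the fragments exactly tile the protein (a conservation the
tests assert).

## The census

Every transcript of a contig contributes the contig's deduced-protein
matches, so a census cell is `instances × depth`; per-group and per-locus
totals, per-transcript frequencies (rounded half-away-from-zero to one
decimal) and integer-percent shares follow. Half-away-from-zero is chosen —
rather than R's banker's rounding — because it reproduces the printed
percentages of the published table from their underlying ratios.
`aggregate_printed_counts()` performs the same arithmetic on an external,
already-printed count matrix; where printed row/grand totals are supplied it
*flags* disagreements (the published table's γ-I row and grand total are
internally inconsistent with its own group cells) in a `discrepancies`
attribute and never silently corrects either side. Shares are computed from
the recomputed totals, which is the choice consistent with the published
percentage figures. Scanning defaults to the full deduced protein; a flag
restricts it to the epitope-bearing R1 + NR2 regions.

## What the synthetic generator does and does not emulate

The generator builds per-genome ancestral genes from a repeat-unit grammar
on the S–I–R1–NR1–R2–NR2 scaffold, derives genes by seeded substitution
(transition:transversion 2:1), samples transcript depths, and injects
pseudogenes as C→T stops in R1 CAA codons. Fixed defaults, chosen once as
the study conditions: within-genome pairwise divergence 0.216
substitutions/site (the scale measured among D-genome genomic clones, the
tightest of the three reported groups), between-genome 0.45 (so that loci
separate clearly, as the published tree shows), transcript depth log-uniform
on 4–220 (the reported depth range; the skew shape is unstated, so the
standard scale-free choice), pseudogene rate 0.1 (between the reported 6.9%
per-clone and 14.5% per-unique-sequence figures), 5′ truncation of 30% of
transcripts in codon-aligned 10-codon steps always preserving the domain
III–V region plus 300 nt. Cysteine codons and the NPC/MCN anchors are held
invariant, emulating their observed absolute conservation; substitutions
that would create a stop or a cysteine are re-drawn to the next admissible
base so the realised rate stays close to nominal (verified binomially in the
tests on unconstrained sequence).

What it does **not** emulate: per-base indel evolution inside repeats (only
whole-repeat-unit count variation), 3′ truncation, sequencing error
structure beyond uniform per-base substitution, expression regulation beyond
the depth distribution, and biologically tuned codon usage (reverse
translation uses one fixed common codon per amino acid). Passing the
recovery tests therefore demonstrates the pipeline's correctness under
substitution-dominated divergence with idealised domain composition — not
robustness to indel-rich repeats or real EST error profiles.

## Problem sizes and numerical choices

The test and acceptance suites run on deliberately modest sizes chosen as
adequate for their statistical purpose: oracle comparisons on 30-mers,
NJ consistency on all random additive matrices with up to 8 taxa,
assignment accuracy on ~200 synthetic contigs against 9 references at a 3×
divergence ratio, and end-to-end census recovery on families of 6 genes with
depths 4–30 across multiple seeds. All randomness flows from single integer
seeds; pipelines rerun byte-identically and record a parameter/output hash
manifest. Tie-breaks are fixed everywhere (base order in consensus,
label-index pairs in NJ, descending depth then lexicographic member id for
contig naming) so outputs are stable across platforms.

## Known limitations

Assignment accuracy degrades gracefully but genuinely as between/within
divergence approaches 1 — ambiguity there is a property of the data, not the
method, and is surfaced as `unassigned`. K2P is an approximation to the
distance model used for the published figures, so distance summaries agree
on a tolerance only. Exact-match scanning will undercount epitope variants
with amino-acid substitutions inside the core (by design — variant discovery
is what `extract_epitope_context()` is for). The moderate-deamidation list
is only as complete as its curated contexts; peptides outside that context
space classify as `none` rather than guessing.
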
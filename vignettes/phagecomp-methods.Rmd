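---
title: "Methods: comparative genomics of T4-like phage genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of T4-like phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecomp)
```

This vignette records the models, conventions and design choices behind the
package, in the spirit of a methods section: what each stage computes, which
tunable parameters matter and why their defaults are what they are, what the
synthetic-genome generator does and does not emulate, and where the known
limitations lie.

## Genome representation

A `GenomeRecord` holds one nucleotide sequence plus a feature table of CDS
and tRNA annotations. All coordinates are 1-based inclusive, the GenBank
convention, everywhere a user sees them; phage genomes are circular by
default because T4-like genomes are deposited as single closed sequences. A
feature crossing the circular junction is stored with `start > end` and a
`wraps` flag rather than being split, so its length is
`L - start + 1 + end`. Translation uses NCBI genetic code table 11
(bacterial/plastid): the hosts are bacteria, and although the code's codon
assignments match the standard table, table 11's wider initiator set
matters — GTG and TTG starts are recoded to Met at position 1. Codons
containing N translate to `X` and are excluded from codon-usage counts.
Internal stop codons are flagged, never silently dropped, because split and
frameshifted genes are precisely the interesting cases in phage comparative
genomics.

## ORF scanning and the RBS score

A CDS candidate is a stop-bounded run in one of six frames starting at
ATG/GTG/TTG with a product of at least `min_aa = 30` amino acids (the stop
codon belongs to the ORF, not to the product). The 30-aa floor is the
smallest product the annotation conventions for these genomes accept. The
ribosome-binding-site score is the length of the longest contiguous match to
the Shine–Dalgarno consensus `AGGAGGT` whose 3' end sits 4–18 nt upstream of
the start codon; matches shorter than 3 score 0. Annotation practice asks only for a
"putative RBS at a convenient distance" without quantifying it, so the
window defaults to the standard prokaryotic SD spacing and is configurable. `scan_orfs`
deliberately never filters on the RBS score — the three validity criteria
(length, start codon, RBS) stay independently observable, with
`longest_per_stop` and a score threshold available as explicit filters.
De-novo scanning is not expected to reproduce a curated annotation (those
come from gene finders plus manual inspection); accession-based statistics
are computed from deposited features, not from `scan_orfs`.

`genome_stats` reports coding percentage as the span-union of CDS intervals
(overlaps counted once, wrapped features split at the junction). Published
tables for these genomes are ambiguous between union and summed-length
conventions — the same genome is quoted at 93.6% and 93.9% in different
places — so the package picks the union, which is well defined, and leaves
the convention visible in the documentation.

## GC skew and origin prediction

The cumulative skew is the per-base running sum of +1 for G and −1 for C,
independent of the plotting window (default 1000 nt window, 500 nt step,
windows wrapping on circular genomes; windows without G or C get skew 0).
Two-replichore replication makes leading strands G-rich, so the cumulative
curve falls along one replichore and rises along the other: its global
minimum marks the origin and its maximum the terminus. The min = origin
assignment follows the usual GenSkew-style convention but is a switch
(`origin_at`), because annotation practice varies.

One numerical subtlety: when a genome's total G and C counts differ, the
plain cumulative curve has a linear drift, and its extrema depend on where
coordinate 1 happens to sit — rotating the genome moves them. Extremum
positions are therefore taken from the detrended curve
`C(i) − i·C(L)/L`, which is exactly equivariant under rotation (the
detrended curve shifts by an additive constant) and reduces to the plain
curve when G and C balance. The plain cumulative profile is still reported
for plotting. Ties are broken toward the smallest position, and a constant
curve (no G/C at all) yields an explicit `no_signal` status instead of an
arbitrary coordinate.

## Codon usage, optimal codons, tRNA decoding

Codon counts are taken in reading frame over all CDSs, *including* the
terminal stop codon. The stop-inclusive convention is adopted because the
published total for the motivating genome (52,152 codons over 256 genes,
~203.7 codons per gene) is consistent with 203-aa average products plus one
stop each. The "optimal codon" of an amino acid is its most frequent
synonymous codon over the whole gene set — the only definition consistent
with marking exactly one codon per amino acid — with lexicographic
tie-breaks so results are deterministic.

A tRNA anticodon written 5'→3' decodes the codon equal to its reverse
complement. The headline optimality statistic uses exact Watson–Crick
decoding; wobble expansion (anticodon 5' G also reading a T-ending codon,
5' U also reading G-ending) is available but kept out of the headline
number, since wobble would let one tRNA claim several codons and blur the
one-tRNA-one-codon bookkeeping. Suppressor and pyrrolysine tRNAs decode stop
codons; they count in the denominator but can never be optimality-related.
CAI is the geometric mean of w(codon) = count/count(best synonym) over
scorable codons, excluding stops and single-codon amino acids, with w
floored at 0.01 for unobserved codons so a single rare codon cannot zero
the index.

tRNA-to-tRNA homology is scored by local nucleotide alignment (match +2,
mismatch −3, gap open 5, extend 2) and reported as query-coverage/identity
pairs with >50%/≥70% defaults. Identity-plus-coverage is used instead of a
nucleotide E-value model because published tRNA comparisons report exactly
those two numbers and identity is deterministic.

## Alignment, E-values, homologs, core genome

Pairwise alignment is affine-gap dynamic programming via Biostrings
(BLOSUM62 with gap open 11/extend 1 for proteins; +2/−3 with 5/2 for
nucleotides; a gap of length L costs open + L·extend). Identity is counted
over aligned columns excluding gaps; query and subject coverage are reported
separately, and "coverage" unqualified means query coverage. Scores are
converted to Karlin–Altschul expect values E = K·m·n·e^(−λS) with the
gapped-BLOSUM62 constants λ = 0.267, K = 0.041. These constants reproduce
BLAST-like significance behaviour in spirit; exact BLAST hit counts are
version- and heuristic-dependent, so published shared-homolog counts are
treated as approximate context, not as targets, and the correctness claim
for the engine is exact agreement with a brute-force DP oracle on small
instances (enforced in the test suite).

Homolog calling is best-hit (smallest E ≤ 10⁻⁶ per query), the convention
of CoreGenes-style proteome comparisons; a stricter identity/coverage
profile can be layered on. A reference gene is core when every other genome
contains a qualifying homolog. Self-comparisons exclude same-name pairs
automatically only when query and subject are literally the same proteome
object; `core_genome` disables that exclusion so genuinely identical genomes
compare correctly. One known asymmetry is inherent to best-hit calling:
shared counts A→B and B→A can differ slightly; the tests bound that
asymmetry at 10% of the smaller proteome on generator data.

Synteny is chained on gene-order indices, not nucleotide coordinates,
because rearrangement maps of these genomes are gene-order diagrams. Blocks
must be strictly monotone on both sides, strand-consistent (colinear blocks
pair like strands, inverted blocks opposite strands), and may skip at most
`max_gap = 3` intervening genes; pairs in no block of length ≥ 2 are
reported as relocated.

## Duplication vs convergence, split genes

Within-genome paralog candidates use a looser protein threshold
(E ≤ 10⁻³) than cross-genome homologs because real T4-like paralogs sit at
25–30% identity. The verdict then hinges on DNA: duplicates descended from
a common ancestral gene retain nucleotide identity, so a candidate is a
`duplication` only when the CDSs align at ≥65% identity over ≥50% of the
shorter CDS, `convergent` when the protein signal is significant but the
DNA signal fails, `ambiguous` otherwise — the thresholds operationalise
"significant" vs "negligible" nucleotide identity, are configurable, and
are echoed into every report. The three verdicts partition all candidates.

A split call requires two or more genes of one genome whose aligned
segments on a single target protein overlap pairwise by at most 20% of the
shorter segment while jointly covering at least 50% of the target. The 20%
slack accommodates alignment jitter around an exactly-disjoint split (the
canonical Alt-like case: segments 1–217 and 409–643 of a 682-aa protein,
66% combined coverage).

## The synthetic-genome generator

Defaults are chosen to emulate the genomes this toolkit targets: 50 kb
circular sequence at 34.5% GC, 1.5 genes/kbp (~90% coding), products
averaging 200 aa (SD 40, minimum 34), eight minus-strand tRNAs with the
anticodon set typical of a low-GC T4-like phage, a planted origin at 0.486·L
with the terminus at coordinate 1, and `skew_bias = 0.08`. Genes are built
by sampling a protein and back-translating it under per-amino-acid codon
weights; the amino-acid marginal is proportional to summed codon mass so
composition tracks the target base composition, and the sampling GC is
calibrated (1-D root find) so realised genomic GC hits the target within
about one percentage point despite the stop codons being excluded from the
codon pool.

Two generator choices deserve explanation. First, strand asymmetry is
applied both to intergenic bases and to synonymous codon choice, because at
~90% coding an intergenic-only bias would leave no recoverable skew signal;
genes are co-oriented with the leading strand 85% of the time, as in real
two-replichore genomes. Second, `skew_bias` is defined as the
*differential* G-excess of the leading strand over the genome's baseline
skew: the codon table is itself slightly C-rich on the coding strand, and
forcing an absolute target would distort codon choice enough to corrupt the
planted codon-preference experiments. The internal codon bias is calibrated
by root-finding so the replichore differential equals `skew_bias`; the
common-mode baseline is exactly what the detrended cumulative curve
removes. A Shine–Dalgarno `AGGAGG` is written 5–10 nt upstream of every
planted start, and tRNA genes carry their anticodon at positions 33–35.

Evolution applies substitutions first and structural events second, so
divergence targets always refer to pre-event orthologs and manifest-based
recall is unambiguous. Amino-acid divergence mutates residues and resamples
only the affected codons; nucleotide divergence uses a two-parameter
(rate + transition:transversion) model that never touches start/stop codons
and reverts substitutions creating internal stops, keeping reading frames
intact. There is no indel model inside genes — indels arise only through
structural events — which keeps alignment-based tests interpretable.
Everything is deterministic under the spec seed, and the caller's RNG state
is left untouched.

What the generator does not emulate: real protein families (sequences are
random, so substitution-matrix structure is only partially exercised),
mobile elements and introns, promoter/terminator architecture, rate
heterogeneity across sites, and compositional heterogeneity beyond the
two-replichore split. Passing the recovery tests therefore demonstrates
correctness of the *detection machinery* under known truth, not performance
on real proteomes; conversely, published BLAST-derived counts for real
genome pairs are not reproduced here by design.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on generated data:
genomes of 8–50 kb with 10–75 genes, 10–20 seeds per property, alignment
oracle checks on pairs of up to 30 residues. These sizes were chosen so the
extremum-localisation, recall and classification estimates are stable from
seed to seed while a full run stays comfortable on a single CPU. Statistics
that require the deposited 167-kb phage record (total codon count, start
and stop tallies, the skew extremum near nt 81009, the 5-of-8 tRNA
statistic) are asserted in an acceptance test that reads a locally
downloaded copy of the record and fails visibly when it is absent, since
the record is too large to ship and is fetched once from NCBI.

## Known limitations

* The GenBank parser is deliberately minimal (LOCUS topology, CDS/tRNA
  features with `complement`/`join` locations, a handful of qualifiers);
  rich qualifier preservation is out of scope.
* Alignment is exact DP, not seeded heuristic search: all-vs-all proteome
  comparison is quadratic and sized for phage proteomes (hundreds of genes),
  not bacterial ones.
* Karlin–Altschul constants are fixed, not estimated per composition;
  E-values on strongly biased compositions are approximate, which is one
  more reason published BLAST hit counts are context rather than targets.
* Terminal repeats, tRNA secondary structure and de-novo tRNA finding are
  not modelled; tRNAs come from annotations or synthetic manifests.
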
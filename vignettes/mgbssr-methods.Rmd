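---
title: "Methods: multiple-genome screening for polymorphic SSR markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple-genome screening for polymorphic SSR markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Microsatellite (SSR) markers are short tandem repeats whose allele length
varies by repeat count. Developing a usable marker panel traditionally
means detecting thousands of candidate repeats in one genome and then
testing polymorphism by PCR across many accessions — slow and expensive.
When two or more closely related genome assemblies are available, the
wet-lab polymorphism test can largely be replaced by a comparative
computation: a locus whose repeat count already differs *among every
assembly*, while its flanking sequence stays conserved, is very likely
polymorphic in the wider germplasm, and its conserved flanks are reliable
primer territory. `mgbssr` implements that comparative screen together
with the downstream marker toolkit (primer criteria, diversity
statistics, digital identity cards, trees and ordination).

# The screening model

Candidates are perfect SSRs with primitive motifs of 3–6 nt detected in a
designated *anchor* genome. Each candidate is carried as its repeat core
plus up to 300 bp of flank on each side, and passes five stages in order:

1. **Self-uniqueness.** The flanked sequence is searched against the
   anchor itself; candidates with more than one near-co-optimal hit sit
   in repetitive context and are dropped (`dropped_nonunique`).
2. **Ortholog matching.** The remaining candidates are searched in every
   other genome. No qualifying hit, or flank identity below the 0.90
   threshold, drops the candidate (`dropped_low_identity`); an ambiguous
   multi-hit drops it as non-unique.
3. **Repeat-count comparison.** The repeat count of the same motif is
   re-detected at each matched site. Counts equal in all genomes drop the
   candidate (`dropped_monomorphic`).
4. **Flank-mutation filter.** Substitutions or indels inside the 50 bp
   flank windows adjacent to the core — the likely primer sites — drop
   the candidate (`dropped_flank_mutation`). The default tolerance is
   zero mutations.
5. **All-genomes requirement.** Candidates whose counts differ between
   only two genomes are dropped (`dropped_two_way_only`). Retained loci
   have pairwise-distinct repeat counts in every screened genome. With
   exactly two genomes this stage is vacuous and any repeat-count
   difference is retained; the screen then degenerates to an ordinary
   pairwise comparison, which is documented behaviour.

Counts of survivors after each stage are reported as a funnel, so a run
on real assemblies can be audited the same way the synthetic tests are.

## Why identity is computed over flank columns only

A repeat-count difference is itself a long indel inside the aligned
candidate. If identity were computed over the whole alignment, strongly
polymorphic loci — exactly the ones the screen wants — would depress
their own identity and be discarded by the conservation filter. The two
signals are therefore separated: the core is excised before comparison,
identity is matches over flank columns only, and core variation is
assessed in stage 3 by re-running the repeat detector on the matched
target window (core ± one motif length). Re-detection, rather than
inferring the count from alignment length, is robust to alignment
ambiguity inside the repeat; motif rotations are accepted when matching
the target run, since the orthologous array may enter the window at a
different phase.

## The search

`search_genome()` is a seed-and-extend aligner specialised for this
contract ("find the orthologous flank block"): non-overlapping 15-mer
exact seeds are tiled along each flank and looked up in a hash index of
the target; each candidate placement is scored by gapless comparison,
taking the best over diagonal shifts of up to ±3 bp (small indels in a
flank surface as a shifted diagonal or as a mismatch stretch, both of
which the identity threshold and window filter register); left and right
placements on the same record and strand are then paired across the
target core gap. Both strands are searched by reverse-complementing the
query; minus-strand hits are reported in forward target coordinates and
their repeat counts computed on the reverse complement. A second hit
counts against uniqueness only when its identity is within 0.05 of the
best hit — a weak secondary hit is not evidence of repetitive context.

# Repeat detection

`detect_ssrs()` reports every maximal run of whole copies of a primitive
motif (one that is not itself a repetition of a shorter motif — `ATAT`
is a dinucleotide array, never a 4-mer motif). Maximality is in whole
motif units; partial trailing copies are excluded, and runs containing N
split at the N. Per motif length the scan is left-to-right and reports
the leftmost spelling of each array, so `T(GTT)₁₂` is reported as
`(TGT)₁₂` from the earlier start; an array shared boundary characters
with a following distinct array is handled by resuming the scan k−1
characters before each match end, so both arrays are reported. Loci carry
the motif as spelled in the genome (the screen compares loci by position,
not motif class); `canonical_motif()` provides a rotation/strand
canonical key for deduplication when needed.

The default threshold is four whole copies for every motif length 3–6.
Repeat arrays shorter than that are common enough in random sequence to
be useless as markers, and four copies is the smallest count among
validated markers in the jujube panel this package's defaults are
modelled on. The threshold is a plain argument, so a more permissive
reading is one flag away. Mono- and dinucleotide repeats and
compound/interrupted arrays are out of scope: no marker in the reference
panel needs them, and imperfect-repeat models would change the
polymorphism contract (allele length would no longer be a linear function
of repeat count).

# Primer criteria and panels

`evaluate_primer_pair()` reports six independent booleans: primers wholly
inside the conserved flanks; amplicon within 50–300 bp; |ΔTm| ≤ 5 °C;
no inter-primer complementary run ≥ 8 nt nor any 3′-anchored run ≥ 5 nt;
exactly one amplifiable site per genome (both primers in convergent
orientation within 2 kb, exact matching); and a correctly prepended
18 bp M13 tail (default the M13(−21) universal primer
`TGTAAAACGACGGCCAGT`, configurable because assay kits differ). Tm is
nearest-neighbor with the SantaLucia unified parameter set at 50 mM
monovalent salt and 250 nM primer, entropy-corrected for salt; the test
suite pins it against values frozen from an independent implementation.
Primer *generation* is deliberately not implemented — the criteria work
on externally designed primers, which is how such panels are built in
practice.

`assign_panels()` packs accepted pairs onto dyes greedily by descending
amplicon length with a 20 bp minimum expected-size separation per dye.
Real panels sometimes tolerate closer expected sizes when observed allele
ranges do not overlap; the separation is an argument for that reason.
Dye names are opaque labels — dye/colour pairings vary between vendors
and even within publications.

# Diversity statistics

For allele frequencies \(p_i\) at a marker (each typed sample
contributing its observed copies up to its ploidy):

* \(N_a\): observed alleles; \(N_e = 1/\sum p_i^2\): effective alleles;
* \(H_e = 1 - \sum p_i^2\) (Nei's gene diversity). The default is the
  plain estimator; a `C/(C-1)` copy-count-corrected variant is a flag,
  because upstream genotyping software reports both and published tables
  rarely say which was used.
* \(H_o\): fraction of typed samples with ≥ 2 distinct alleles. A
  triploid is heterozygous unless all three alleles are identical, and
  contributes three copies to the frequencies; a flag restricts to
  diploids for strict diploid statistics.
* \(PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2\) (Botstein's
  polymorphism information content; > 0.5 is conventionally "highly
  informative").

Panel summaries are unweighted across markers. Allele binning from
capillary traces is out of scope: genotype tables already hold integer
fragment sizes.

# Identity cards

Per marker, each distinct genotype pattern (the sorted allele multiset)
receives a two-digit code `01`–`99` in ascending lexicographic order of
the sorted allele tuple (shorter tuples first); `00` is reserved for
missing typing. Coding per *pattern* rather than per allele is what
yields exactly two digits per marker and hence a 24-digit ID over a
12-marker panel. The sort key is a choice — published descriptions say
only "ascending order" — so a frequency-rank ordering is available as an
option, and marker order is user-configurable. Codes are stable under
adding samples whose patterns already exist, and `check_uniqueness()`
reports collision groups explicitly rather than a bare count.

# Trees and ordination

The 0/1 matrix scores allele presence (not dosage). Jaccard distance and
neighbor joining are the defaults for dominant/binary SSR band data;
both are arguments. For rows with no scored bands, Jaccard/Dice are
undefined, so the package defines distance 0 between two all-zero rows
and 1 to any other row, which keeps wholly untyped samples maximally
distant instead of propagating NaN. NJ is delegated to `ape::nj`;
negative branch lengths (possible on non-additive input) are clamped to
zero with the deficit moved to the adjacent branch, preserving total
tree length. PCoA is classical scaling — Gower double-centering of
−d²/2 and eigendecomposition — with negative eigenvalues reported and
their axes omitted, and axis signs canonicalized (largest-magnitude
loading positive) for reproducible output. Group-cutting of the tree is
a presentation utility with no analytical claims attached.

# The synthetic-data generator

`generate_genomes()` plants loci of six classes — retainable three-way
polymorphic, two-way-only, monomorphic, duplicated-flank decoys,
heavily diverged flanks (15% substitutions), and flanks with
substitutions planted inside the 50 bp primer windows — separated by
neutral spacers. Motif lengths are drawn at 71.1/20.1/5.5/3.25% for
3/4/5/6-mers, matching the composition reported for jujube assemblies;
repeat counts are 4–12; flanks are 300 bp and spacers 1 kb, giving
~115 kb per genome at the default ten loci per class. Spacers and flanks
are rejection-sampled free of qualifying repeat runs and flank boundary
bases never continue the motif, so the planted truth table is provably
the complete detection truth; the generator verifies this by running the
detector on every assembled genome and deterministically re-derives its
randomness in the (rare) event a pathological draw slips through. The
same seed always yields identical genomes.

What the generator does *not* emulate: indel processes and structural
variation in flanks, compound/interrupted repeats, sequencing and
assembly error, and genome-scale repeat families beyond the planted
decoys. Passing the synthetic suite therefore demonstrates that the
screen's logic is exact under its stated model — flank conservation with
substitution noise, core variation in whole repeat units — not that real
assemblies will yield any particular candidate count. Published counts
from real jujube assemblies (which depend on assembly versions and
unstated filter thresholds) are accordingly treated as data, not as
reproduction targets.

`generate_genotypes()` draws alleles independently per chromosome copy
(Hardy–Weinberg) from specified per-marker frequencies, with a
configurable ploidy plan (default 26 diploids plus 4 triploids, the
composition of the reference panel's validation set), optional missing
data, and an optional pairwise-distinct mode for identity-card cohorts.

# Numerical and testing notes

Internal coordinates are 0-based half-open; exported tables are 1-based
inclusive with a header note. Detection equivalence is tested against an
independent brute-force oracle built on the periodicity array
(`s[i] == s[i+k]` run-length encoding) — a different mechanism from the
scanner's backreference regex — on hundreds of random 2–5 kb sequences
with spiked repeat insertions. Screen correctness is asserted as exact
truth-table recovery (100% precision and recall, funnel equal to planted
class sizes) on seeded trios of ~115 kb genomes with ten loci per class;
NJ is checked to 10⁻⁹ path-length error on additive distances from 50
random trees of up to 12 taxa, PCoA to 10⁻⁸ on Euclidean round-trips,
and frequency recovery within 3 standard errors at 500 diploids (with
moderate allele counts and frequencies bounded away from zero, keeping
the per-allele normal approximation sound). These problem sizes keep the
full suite under a minute while leaving every assertion exact rather
than approximate.

# Known limitations

* The flank aligner is substitution-oriented; flanks diverged mainly by
  large indels may fail to pair even above 90% column identity. An
  external BLAST-compatible tool can be substituted upstream by feeding
  its hits through the same staging logic, but is not required.
* Repeat counts are compared as integers; two genomes differing by a
  partial motif copy are treated as equal-count.
* `Ho`/`He` make no correction for null alleles or genotyping dropout.
* With two genomes the screen cannot distinguish "polymorphic in two"
  from "polymorphic in all" — three or more assemblies are the intended
  use.
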
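---
title: "Methods: comparative metagenomics against a finished reference genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative metagenomics against a finished reference genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ventcomp)
```

# The analysis problem

A shotgun metagenome dominated by one genotypically uniform population,
moderately diverged (here ~70% nucleotide identity) from a finished
reference genome, supports a family of comparative analyses that need no
assembly of the population's own genome: fragment recruitment, per-contig
characterization, synteny and gene-fusion mapping, prophage-insertion
dating, mate-pair linkage of mobile elements, and a tiered homolog
census. `ventcomp` implements each as a pure function over explicit
tables, joined by two interchange formats: FASTA and the 12/13-column
tabular alignment-hit layout. Any stage accepts externally produced hit
tables (e.g. from BLAST with tabular output), in which case downstream
statistics inherit that tool's alignment semantics.

# The seeded local aligner

The built-in aligner exists so the pipeline runs self-contained; it is a
classical three-stage design:

1. **Exact word seeds** — shared words of length 11 (nucleotide) or 3
   (translated/protein), found by rolling exact encoding over the shorter
   sequence's hash index. Words containing ambiguity codes never seed.
2. **Ungapped X-drop triage** — seeds grouped into diagonal bands
   (±16 nt / ±12 aa) and subject-local clusters; a cluster survives when
   one of up to eight probed seeds extends ungapped (X-drop 20/18) to at
   least 16 (nucleotide) or 40 (translated). The translated floor must
   exceed single-word scores: one exact BLOSUM62 3-mer can score above 20
   on its own.
3. **Banded affine-gap Smith–Waterman** with full traceback over the
   cluster's diagonal band, scoring +1/−2 with gap cost 5 + 2·L
   (nucleotide) or BLOSUM62 with 11 + 1·L (translated). Percent identity
   is matches over all alignment columns, gap columns included.

Bit scores use the published Karlin–Altschul parameters for these schemes
(λ = 1.28, K = 0.46 and λ = 0.267, K = 0.041), and
`E = m·n·2^(−bits)` with the raw m×n product as search space — no length
correction, which shifts absolute E-values slightly but not orderings;
the census thresholds are tiered orders of magnitude, so this is
immaterial there.

Two practical limits follow from the design and are worth stating.
First, *seeding bounds detectable divergence*: a 600 bp segment at 30%
divergence carries no exact 11-mer in a few percent of random draws, so
occasional reads near the divergence tail recruit nothing — exactly as
with BLASTN at word size 11. Second, *local alignments trim*: at ~70%
identity the expected score drift under +1/−2 is only +0.1 per column,
so the optimal local alignment of a read covers ~85–90% of it and sits a
point or two above the planted identity. Both effects are visible in the
recruitment profile: total cross-bin coverage lands around 0.6–0.7× the
simulated fold coverage, and the modal bin sits at 71–72% for a planted
70%.

Equivalence with unrestricted Smith–Waterman (the `Biostrings`
`pairwiseAlignment` oracle) is property-tested on random pairs with
planted homology drawn inside the seeding regime (0–25% divergence); the
top hit's raw score equals the full dynamic-programming optimum in well
over 95% of trials, since the band (±16 around seed diagonals) dwarfs
the gap content of substitution-dominated alignments.

# Fragment recruitment

Each read contributes its single best hit (lowest E-value, ties to the
higher bit score) — per-HSP accumulation would double-count read bases
and inflate coverage. Hits must be strictly longer than 500 bp. Reads
are binned by the hit's percent identity into 1-point bins `[k, k+1)`
(100% in the top bin; the bin width is configurable, as the width used
in the original figure is not stated), and per-bin coverage is the bin's
aligned bp divided by the reference length.

# Contig statistics

Fold coverage is defined from assembly membership — summed member-read
bp over contig length — not from alignment depth, because the
coverage of interest is the sequencing redundancy behind each contig.
Best reference-protein hits are classed at strict thresholds 10⁻¹⁰⁰ /
10⁻⁵⁰ / 10⁻¹⁰ ("better than" is strict less-than throughout the
package). Size filters are strict too ("contigs >7 kb" excludes 7000).

# Synteny, breaks, fusions, orientation flags

Anchoring is best-hit, not reciprocal-best-hit, mirroring directional
protein-vs-translated-contig searching; anchors need E ≤ 10⁻⁵. Blocks
extend while reference midpoints advance ≤ 20 kb (default) in a
consistent direction; larger jumps or sense flips close a block and log
a break with the reference distance between flanking anchors. The 20 kb
default tolerates local indels while remaining far below the
rearrangement scale of interest (tens of kb); it is configurable because
no principled universal cutoff exists between "local noise" and
"rearrangement".

A fusion call requires two query ORFs *consecutive in query order on one
contig* whose hits each cover ≥ 25% of the same reference protein with
≤ 30 residues of covered-span overlap. Orientation flags require both an
anchoring failure (or a better hit to a supplied "other taxa" set) and
strand discordance with both neighbors; when per-read contig spans are
available, each flag reports the number of reads covering the flagged
ORF together with an anchored neighbor — three or more marks the flag
assembly-supported, the read-level check that distinguishes a real
inserted ORF from a misassembly.

# Prophage insertions and direct repeats

A candidate insertion is a reference interval (annotated, or discovered
de novo as a ≥ 5 kb reference gap between query-adjacent anchors) whose
flanking anchors are adjacent on one query contig (≤ 2 kb apart) and
whose interior ORFs anchor nowhere in the query. The repeat test aligns
the two reference windows (500 bp) flanking the element boundaries; a
direct repeat needs ≥ 20 aligned bp at ≥ 80% identity **and** a chance
expectation ≤ 10⁻³ within the window-pair search space. The significance
floor matters: two random 500 bp windows produce ~20 bp matches at ~80%
identity by chance alone, so the length/identity floor by itself would
manufacture repeats on null data. A 26 bp exact repeat scores E ≈ 4·10⁻¹⁰
and an 88%-identical copy ≈ 4·10⁻⁵, so realistic repeats pass easily.

The verdict is a pure function of two outcomes: repeat present in the
reference and absent at the query junction → the element inserted into
the reference lineage *after* divergence; repeat surviving in the query
→ the element was deleted from the query lineage; no reference repeat →
indeterminate. For annotated elements whose interval is the element
proper, the repeat copies sit flush against the flanking windows' inner
edges, which is why exact planted repeats are recovered at exact
coordinates; de novo candidates have looser boundaries, and their repeat
search may stay indeterminate — refining de novo boundaries is a known
limitation.

# Transposase linkage

A read or contig is transposase-bearing when any hit from the
transposase protein set reaches E < 10⁻¹⁰ (the criterion the original
analysis used for "contains a transposase" is not stated; this default
is documented, not inferred). For contigs above 10 kb (strict), a member
read is linked when its clone mate is flagged — the mate may be
unassembled, in another contig, or in the same contig (a documented
switch excludes same-contig mates). The linked-read percentage is
rounded to one decimal. The conservative spacing estimate assumes one
transposase per linked contig: summed linked-contig kb over the linked
count, rounded to integer kb with the unrounded value retained, plus the
reference genome's own spacing when its transposase count is supplied.

# Homolog census

One row per reference protein; best contig hit and best singlet
(unassembled read) hit are kept separately and merged for the tier. Tier
tallies are cumulative (a 10⁻¹⁰⁰ hit counts at 10⁻⁵⁰ and 10⁻¹⁰ too),
which the published tallies' ordering strongly implies; the monotone
nesting n(10⁻¹⁰⁰) ≤ n(10⁻⁵⁰) ≤ n(10⁻¹⁰) and the identity
total − n(10⁻¹⁰) = n(none) are enforced as validation rules. The
missing-gene report counts "hypothetical" annotations among tier-none
proteins and groups the remainder by a crude product keyword.

# The synthetic data generator

The generator's defaults *are* the study conditions: a 150 kb reference
at 43% GC with 100 backbone ORFs (300–3000 bp, strand runs with a 0.15
switch probability, ~75% coding), an 8 kb prophage with its own ORFs and
an exact 26 bp direct repeat duplicated flush at both ends; a query
lineage at 30% planted nucleotide divergence with GC drifted to 38%, a
translocation joining two regions separated by 50 kb, two fusions
(reference ORFs split mid-frame into two adjacent query ORFs), ten
transposase copies (960 bp, lightly mutated per copy), three
reverse-orientation foreign ORFs; Sanger-style read pairs of mean 755 bp
(sd 100) from 3 kb (sd 300) clone inserts at 6× coverage. The clone
insert size is not documented for the original pUC18 libraries; 3 kb is
the conventional default and is a parameter.

Substitutions are codon-aware with synonymous third positions mutated at
3× the first/second-position rate (configurable), so that ~70%
nucleotide identity coexists with per-ORF amino-acid identities around
0.65–0.70. Site counts are exact per ORF (not binomial draws), which
makes divergence recovery tight. GC drift is achieved in three layers:
intergenic replacement bases are drawn toward an analytically derived
composition; synonymous third-position choices are steered by a
genome-wide G+C countdown (third-position swaps are otherwise
GC-neutral, because two-fold degenerate sites exchange within purine or
pyrimidine pairs); and a final pass swaps replacement bases at mutated
intergenic sites — never restoring an original base, so the planted
divergence is untouched — until the G+C count is exact.

Assembly is simulated, not performed: contigs are windows tiling the
query genome, mostly 0.6–2.5 kb with ~12% at 10–18 kb, and every sixth
small window withheld as unassembled singlets. Window boundaries snap
forward into intergenic space, and loci whose recovery the analyses are
meant to test — the prophage excision junction ± 1.5 kb, fusion spans,
foreign ORFs with their neighborhoods — are never split or withheld;
insertions likewise avoid the excision junction's gap. This encodes the
modeling position that the observed assembly presented these loci intact
on single contigs; a fixture that randomly destroyed them would test the
fixture, not the method. Correspondingly, passing tests say nothing
about how often a *real* assembly presents such loci intact.

Stage RNG streams are derived from the base seed (seed, +1, +2, +3 for
reference/evolution/reads/fixtures) so each stage is independently
reproducible; the base seed is recorded in the truth-ledger header. What
the generator does **not** emulate: sequencing error and quality values,
indel mutations, chimeric clones, repeat-induced misassembly, strain
mixtures, and compositional heterogeneity beyond the single GC shift.

# Problem sizes and determinism

The packaged analyses run the full default simulation (~150 kb genome,
~1230 reads) end to end in well under a minute; tests use a 60 kb
variant for simulator-level properties and the full default conditions
for parameter-recovery checks. All writers emit deterministic bytes
(Unix newlines, fixed numeric formats); identical configurations produce
byte-identical artifacts, which the pipeline manifest exploits by
skipping stages whose artifacts still match their recorded checksums and
recomputing a tampered stage together with all its descendants.

# Known limitations

- The aligner has no two-hit seeding, composition-based statistics, or
  HSP chaining across frames; absolute E-values therefore differ from
  BLAST's, though threshold *orderings* are preserved.
- De novo insertion candidates have anchor-bounded intervals, so their
  direct-repeat search is less sensitive than with annotated elements.
- Orientation flags without a secondary protein set are orientation-only
  evidence, and transposase copies legitimately satisfy the same
  criteria as foreign ORFs (unanchored, often discordant), so flags are
  a candidate list, not a lateral-transfer call — phylogenetic
  confirmation is out of scope.
- Membership-based coverage equals alignment-depth coverage only for the
  idealized window fixtures; on real assemblies the two differ at contig
  edges and repeats.
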
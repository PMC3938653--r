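---
title: "mirpipe: models and methods of the small RNA-seq miRNA pipeline"
author: "mirpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirpipe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mirpipe` re-implements, at desk scale and fully reproducibly, the classic
two-library small RNA sequencing workflow used for miRNA discovery in
non-model organisms: read cleaning and accounting, exact genome mapping of
unique tags, hierarchical annotation, known-miRNA profiling with isomiR and
editing analysis, hairpin-based novel miRNA prediction, count-based
differential expression, and rule-based target prediction. This vignette
documents the underlying models, the parameters that matter, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## Read cleaning and accounting

Reads are insert + 3' adapter (+ downstream noise). The 3' adapter is
located at the leftmost position where the adapter prefix matches with at
least 6 nt of overlap and at most one mismatch; the insert is everything
before that position. Each read lands in exactly one accounting category,
with a fixed precedence chosen to make the categories disjoint (the
underlying bookkeeping is standard but its order is conventionally left
unstated): polyA (insert at least 90% A) first, then 5'-adapter
contaminants (insert begins with the first 8 nt of the 5' adapter), then
missing 3' adapter, empty insert, too-short insert (< 18 nt), and finally
clean (18-30 nt). No base-quality model is applied — every read counts as
high quality, because quality filtering algorithms in this pipeline family
are typically unspecified and our simulated reads carry constant qualities.
The conservation identity `high_quality = sum of the six categories` is
property-tested on arbitrary input.

Clean inserts are collapsed to unique tags with per-library counts
(`collapse_tags()`, `merge_tag_tables()`); all downstream analysis operates
on tags, never on individual reads.

## Genome mapping

`build_index()` hashes every genomic k-mer (default k = 12); `map_tags()`
reports every exact, full-length match of a tag on either strand. There is
no mismatch tolerance in mapping — mismatch handling is confined to edit
detection, where it is explicitly one substitution. Tags with more than 10
genomic hits are retained but flagged; novel-miRNA prediction excludes
them. Counts are attributed once per tag (class level), never split across
loci, because per-locus attribution of multi-mapping small RNAs is not
identifiable from the data.

## Annotation

Tags are classified by at-least-1-nt overlap with annotated features, with
a single configurable priority order (default: miRNA > rRNA > tRNA >
snRNA > snoRNA > scRNA > srpRNA > repeat > exon > intron > unknown).
Non-coding RNA and repeat classes require strand agreement; exon and intron
overlaps split into sense/antisense. The priority resolves multi-feature
overlaps deterministically; a monotonicity property (raising a class never
loses it tags) is tested. Known miRNAs are identified by exact substring
match within a reference precursor, with the matched span required to
overlap the annotated mature position within +-4 nt at each end so that
templated isomiRs accumulate to their mature.

## Variant profiling

*End variants (isomiRs).* Only templated variants are classified: the tag
must occur exactly within the precursor, and its signed 5'/3' offsets are
measured against the annotated mature span. Non-templated additions fall
through to the unannotated pool — with single-end short reads, a
non-templated tail is not distinguishable from sequencing error without a
model we do not have.

*Single-base edits.* Unannotated tags are aligned to equal-length reference
matures; a tag with exactly one substitution yields an edit record with
1-based position, from/to bases, and a seed flag for positions 2-8. The
equal-length restriction (end tolerance 0) keeps the edit/isomiR pools
disjoint and the assignment unambiguous; a combined shifted-and-edited tag
is rarer than either event alone and is deliberately left unclassified.
When a tag is one mismatch from several matures it is assigned to the more
expressed mature, ties broken lexicographically — a convention chosen for
determinism.

*Families.* Family names parse from the name stem (species prefix, arm
suffix and paralog letters stripped), e.g. `bta-let-7a` and `bta-let-7b`
both map to `let-7`; the dominant member is the highest-count one.

## The folding engine

Novel-miRNA prediction and target scoring both need secondary-structure
energies, so the package ships a deterministic nearest-neighbour folding
engine (Zuker-style dynamic programming in C++): stacking energies for
adjacent Watson-Crick and G:U pairs (6x6 table shipped as TSV), logarithmic
hairpin/bulge/internal loop penalties, a linear multiloop model
(a + b x branches, no per-nucleotide cost), minimum hairpin loop 3 nt,
interior loops capped at 30 unpaired nt, no dangles or terminal-AU terms.
Energies are in kcal/mol at 37 degrees C; more negative is more stable.
Ties resolve to the 5'-most pairing, so folding is bit-reproducible.

The published thermodynamic parameters differ slightly between tables and
none of the upstream tools expose theirs, so all energy thresholds in this
package are interpreted relative to this engine; the synthetic truth is
rejection-sampled under the same engine, which makes the thresholds
meaningful by construction. Correctness is established differently:
exhaustive enumeration of every pseudoknot-free structure (sequences up to
14 nt) and of every monotone intermolecular pairing (15-nt duplexes) must
reproduce the DP optimum exactly; these oracle tests run on every check.

Derived quantities: AMFE = -MFE/length x 100, and the minimal free energy
index MFEI = AMFE / GC%, the classic discriminator between miRNA
precursors (typically > 0.85) and tRNA/rRNA/mRNA fragments (~0.6-0.65).

`duplex()` computes optimal intermolecular hybridisation under the same
parameters with no intramolecular structure and no initiation term, so two
unpairable strands score exactly 0 and any pairing is ≤ 0.

## Novel miRNA prediction

Candidate loci are built from genome-mapped tags that are not assigned to a
known miRNA, not in a known ncRNA/repeat/sense-exon class (intronic and
antisense-exonic tags remain eligible), and not multi-hit (> 10 genomic
hits). 150 nt of flank is taken on each side; overlapping same-strand
windows merge. Only tags with at least 3 supporting reads seed a window —
sporadic singletons are overwhelmingly sequencing noise and folding every
one of them would dominate runtime without adding credible candidates
(read-depth floors are standard in hairpin predictors).

Within a window, the most abundant tag is the mature candidate. Rather than
trusting a single fold of the whole window — where spurious long-range
pairings can distort the local hairpin — a small grid of candidate
precursor extents is folded with the tag anchored as the 5' or 3' arm
(40-85 nt beyond the tag), each fold trimmed to its paired span (+2 nt so
the star overhang stays inside), and the best-scoring extent kept. Seven
criteria are then evaluated:

1. the mature is contained in one arm (>= 60% of its bases paired, all
   partners on one side);
2. a star sequence exists under the 2-nt 3' overhang rule (star span =
   partner(mature_end - 2) .. partner(mature_start) + 2, the Dicer
   signature);
3. no bulge or internal loop larger than 4 nt inside the mature:star duplex
   (the size quantifies "no large bulges", which is conventionally left
   unquantified; configurable);
4. precursor MFE <= -18 kcal/mol;
5. MFEI > 0.85;
6. mature length 20-22 nt;
7. mature:star hybridisation energy < -20 kcal/mol.

The first energy gate (-18) applies at the candidate stage and the stricter
hybridisation gate (-20) at the final call, reflecting the two stages at
which such thresholds conventionally appear. A candidate passing all seven
is reported; star-supporting reads raise its tier to "high" but their
absence does not reject (star reads are sampled stochastically and shallow
loci would otherwise be lost). Tightening any threshold can only shrink the
prediction set (tested).

## Differential expression

With one library per condition there is no replication, so expression
differences are assessed with an exact conditional count test: normalized
expression NE = count / total clean reads x 10^6 (transcripts per million);
conditional on the total x + y, the count y follows
Binomial(x + y, N2/(N1 + N2)) under the null of equal relative expression,
and the two-sided P-value doubles the smaller tail (capped at 1). Tail
sums are computed in log space via log-gamma, so counts in the millions do
not overflow. The suite verifies exact agreement with an independently
computed conditional binomial over the full x, y <= 50 grid.

Fold changes are log2(NE1/NE2) with a pseudo-NE of 0.01 substituted for
zero counts (flagged); classes follow the conventional colour scheme: up
for ratio > 2, down for <= 1/2, intermediate otherwise. Significance
requires an adjusted P-value (Benjamini-Hochberg by default, Bonferroni
optional) below 0.01 *and* a non-intermediate class. These thresholds are
explicit configuration, since "significantly different" conventions vary.
`ddct()` supplies the 2^-ddCt arithmetic for qPCR validation data.

An important caveat: with single libraries the test sees only sampling
noise, not biological variability, so P-values on real data overstate
certainty. This matches the design being emulated; for replicated designs
use a dispersion-aware tool instead.

## Target prediction

Sites are scored with an ungapped antiparallel alignment: miRNA position i
(1-based from the 5' end) faces site position L - i + 1; each position is a
Watson-Crick match, a G:U wobble, or a mismatch. G:U counts 0.5 toward the
weighted totals but is treated as a non-mismatch in adjacency and position
rules — the weighting applies only where counts are involved. Six rules:
weighted total <= 4; no more than two adjacent mismatches; no adjacent
mismatches in positions 2-12; no mismatch at positions 10-11; weighted
total over positions 1-12 <= 2.5; duplex MFE at least 75% of the MFE
against the miRNA's perfect complement (computed with the same duplex
engine). The ungapped model is implied by the rules' fixed position
indexing; bulged sites are out of scope. Every transcript window of miRNA
length is evaluated; the cheap counting rules run vectorised first, and the
duplex energies are computed only for surviving windows.

## The synthetic study generator

`build_genome()` + `simulate_reads()` produce a complete study with known
truth: random chromosomes; planted precursors built from a stem-loop
template (mature, 10-14 nt loop, complementary arm with 1-3 mutations, 2-nt
pads) and rejection-sampled until they pass *all seven* prediction criteria
under the package's own engine, so recoverability is guaranteed by
construction; decoy ncRNA/repeat/exon/intron loci; transcripts with planted
perfect-complement target sites; and two adapter-ligated libraries.
Default study conditions: 2 chromosomes x 100 kb, 30 hairpins, 20 decoys,
~10^5 reads per library; per-mature counts are Poisson around log-uniform
means; 15% of mature reads carry templated end offsets (mostly 3'), 3%
carry one random substitution, star reads are 8% of mature means; 30% of
miRNAs are differentially expressed four-fold (half up, half down); mature
lengths are drawn 20/21/22 nt with weights 0.15/0.25/0.60 so inserts peak
at 22 nt; 70% of hairpins are included in the miRBase-style reference
("known"), the rest are the novel loci a run should rediscover. Junk
categories (adapterless, empty-insert, 5'-contaminant, short, polyA) are
planted at fractions of a few per mille, like real libraries after size
selection.

Every simulated read is validated through the package's own trimmer:
variants whose reads would trim differently than planted (e.g. an insert
that happens to contain an adapter-like subsequence) are resampled. This is
what makes the recovery tests *exact*: planted category counts, isomiR
offset tables and edit tables are recovered identically, not
approximately. All randomness flows from one integer seed;
regeneration is byte-identical, and derived seeds stay within the 32-bit
integer range.

What the generator does *not* emulate: base-call errors and quality
variation, non-templated additions, adapter dimers beyond the empty-insert
class, expression-dependent sequence biases, RNA modification chemistry,
and multi-locus mature miRNAs (unless repeats are planted explicitly).
Passing recovery tests therefore demonstrates that the pipeline's logic is
correct and self-consistent, not that it is robust to every artefact of
real sequencing data.

## Numerical and design choices

- Sequences are stored internally in the DNA alphabet; U is accepted
  everywhere on input and mature/edit outputs are reported in RNA.
- Coordinates are 0-based half-open internally (BED convention); rendered
  reports are 1-based inclusive.
- The folding DP uses a fixed case order and 5'-most tie-breaking, making
  all structure output deterministic across platforms.
- Degenerate inputs: empty read sets, empty tag tables, and windows with no
  pairable bases return empty results rather than errors; zero totals and
  invalid alphabets error loudly.
- The dinucleotide shuffle used for null genomes is the Altschul-Erickson
  Euler-walk construction, preserving exact dinucleotide counts.
- Problem sizes in the test suite: oracle folding up to 14 nt (exhaustive
  enumeration stays in the thousands of structures), duplex oracles at
  15 nt, rule oracles over all <= 3-edit variants of a 21-nt site, and the
  default 2 x 100 kb / 10^5-read study for end-to-end recovery. These sizes
  were chosen so each claim is verified exhaustively where enumeration is
  possible and at full default scale where it is not.

## Known limitations

- Exact-match mapping means SNPs between sample and reference genome
  convert mapped tags into unmapped or edit-candidate tags.
- The edit detector reports any single substitution; it cannot separate
  post-transcriptional editing from SNPs or sequencing error (the emulated
  workflow could not either).
- MFEI and energy thresholds are engine-relative; plugging in a different
  thermodynamic parameter set shifts the scale and the thresholds should be
  recalibrated.
- The exact conditional test assumes Poisson sampling within one library;
  it is anticonservative in the presence of biological replication
  variance.
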
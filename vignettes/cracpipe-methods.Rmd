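---
title: "cracpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cracpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`cracpipe` implements the quantitative core of a CRAC (UV cross-linking
and analysis of cDNAs) analysis: from multiplexed, linkered FASTQ reads
to transcript-class distributions, spliced/unspliced junction
statistics, strand-specific reads-per-million (RPM) coverage,
pseudocounted log2 enrichment of a cross-linked factor relative to
total RNA polymerase II, reproducibility-filtered per-feature
statistics, and TSS/pA-anchored metagene profiles.  The motivating
biology is the binding of chromatin-modifying factors to nascent
RNAPII transcripts: a 5'-enriched factor (Set1-like, binding from the
TSS to roughly +500 nt) and a body-distributed factor (Set2-like,
binding from about +150 nt after the TSS to about 150 nt before the pA
site), measured against the polymerase itself so that enrichment
reflects binding beyond transcription rate.

Read alignment itself is out of scope: any splice-aware aligner can
produce the SAM/BAM consumed by `load_alignments()`, and the synthetic
generator can emit truth alignments that bypass the aligner entirely.

# The measurement model

## Library structure and preprocessing

Each read begins with a 5' linker composed of a random tag (default
3 nt) followed by the sample barcode; the cDNA insert follows, then the
3' sequencing adapter.  The random tag is the device that separates PCR
duplicates from independent cross-linking events: two reads with
identical inserts but different tags are distinct molecules.

Preprocessing applies, in order:

1. **Demultiplexing** (`demultiplex()`): exact barcode match by
   default; a configurable Hamming tolerance assigns near-matches and
   sends reads ambiguous between two samples to the unassigned stream.
   Reads shorter than tag + barcode are unassigned with their own
   reason code.
2. **Trimming** (`trim_reads()`): the adapter is removed at its
   leftmost exact occurrence, or at a 3'-flush prefix of at least
   `min_overlap` nt (default 3); trailing bases below the quality
   threshold (default Phred 30) are then dropped; finally reads shorter
   than 17 nt or with more than 3 uncalled bases are discarded.  These
   four thresholds are the pipeline's contract; no attempt is made to
   be bit-compatible with any particular trimming tool's windowed
   algorithms.
3. **Low-complexity filtering** (`filter_low_complexity()`): a read is
   dropped when strictly more than 80% of its bases are one nucleotide
   (N counts toward the denominator, never as the majority base).  This
   guards against non-templated oligo(A) tails mapping to A-rich
   genomic regions.  Filtering runs after trimming and before
   collapsing; the order is a package decision, recorded here because
   the converse order would count duplicate low-complexity reads
   differently in the fate summary.
4. **Collapsing** (`collapse_identical()`): one record per distinct
   (tag, sequence) pair, keeping first occurrence, recording the copy
   count.  The operation is idempotent, and multiplicities always sum
   to the pre-collapse read count.

## Genomic deduplication

PCR duplicates that survive sequence-level collapsing (in real data:
sequencing errors, differential 3' trimming) are removed after
alignment: reads sharing the random tag and the genomic coordinate of
their 5' end (leftmost base on the plus strand, rightmost on the minus
strand) on the same strand of the same chromosome collapse to the
first-seen representative (`deduplicate()`).  Representatives are
interchangeable for every downstream counting operation.

A 3-nt tag has only 64 values, so distinct molecules sharing a 5'
coordinate can collide and be merged; this is a property of the assay,
not of the implementation, and the synthetic truth tables quantify it
exactly (the post-dedup count equals the number of distinct (tag,
locus) molecules in the truth, which is slightly below the molecule
count at high local depth).

## Transcript classes and junction statistics

Each read receives exactly one transcript class: the highest-priority
class among same-strand features overlapping any aligned block by at
least 1 nt.  The default priority — rRNA > tRNA > other Pol III >
snoRNA > snRNA > mRNA > SUT > CUT > XUT > Ty > IGS — puts abundant
structured-RNA classes first, so a read on a snoRNA nested inside an
mRNA is credited to the snoRNA.  No priority is claimed to be canonical;
the order is configurable and results should state the one used.  Reads
with no sense overlap are `antisense` if an opposite-strand mRNA
overlaps (configurable), else `intergenic`.

Splicing status is summarised by the ratio EE / (EI + IE) per
replicate, where EE counts gapped reads whose blocks flank an annotated
intron exactly, and EI/IE count contiguous reads crossing the
exon→intron or intron→exon boundary, each with at least `min_overhang`
(default 3) aligned nt on each side.  The overhang rule is this
package's explicit definition; 3 nt mirrors the adapter-overlap
threshold of the trimming stage.  A read covering an entire intron plus
flanks counts once for EI and once for IE — it is evidence of unspliced
transcript at both junctions.  Nascent-transcript data are expected to
give low EE/(EI+IE) for polymerase-associated factors, since
co-transcriptional RNA is substantially unspliced.

## Coverage, enrichment and feature statistics

Coverage tracks are strand-specific per-base counts over aligned blocks
(intronic gaps of spliced reads contribute nothing).  Reads classified
to rRNA, tRNA or other Pol III transcripts, or aligned to an excluded
(e.g. mitochondrial) chromosome, are excluded from both the track and
the library size; RPM normalisation divides by the included read count
only.  Replicates are averaged per base after normalisation.

Enrichment relative to the reference factor is computed per base as

    E(x) = log2( (protein_RPM(x) + c) / (reference_RPM(x) + c) )

with pseudocount `c = 5` RPM.  The pseudocount keeps the ratio finite
and shrinks low-coverage positions toward zero; it is applied to
RPM-normalised values.  `E` is antisymmetric under operand swap and
bounded by `±log2((max + c)/c)`.

Per-feature statistics sum RPM signal over the feature's exonic bases
on its strand (intron coverage is excluded so that spliced and
unspliced genes are summarised on comparable mature coordinates), and
count reads per feature under the same priority rule as
classification.  Two filters select features for factor-versus-
polymerase comparisons:

* reproducibility: the coefficient of variation of the per-replicate
  coverage totals — sample SD (n−1) over mean — strictly below 0.5;
* abundance: RPKM (reads per kilobase of mature length per million
  included reads, averaged over replicates) strictly above 30.

## Metagene analysis

Anchored matrices align features at the TSS or pA site in transcript
orientation (minus-strand features mirrored), with default windows
−100..+1500 nt (TSS) and −1500..+100 nt (pA).  Cells beyond the
transcript plus a 100-nt flank, or beyond chromosome ends, are masked
and excluded from aggregation; short features are masked rather than
dropped, which avoids biasing profiles toward long genes (a
`min_length` drop mode exists).  Absolute profiles aggregate by sum
(total coverage across transcripts); enrichment profiles aggregate by
mean, and the per-base enrichment is computed *before* aggregation —
the mean of ratios, not the ratio of means.  The order matters at low
coverage, where the pseudocount shrinks individual transcripts toward
zero, and is fixed and documented rather than configurable.

Expression-matched subsets (`expression_match()`) pair features across
classes (default mRNA/SUT/CUT) by total reference signal over the first
300 transcribed nt: greedy nearest-neighbour matching without
replacement in log10 signal, tolerance 0.05 log10 units, ties broken by
lowest feature id, and any group spanning more than the tolerance
discarded.  The matcher is this package's definition of the procedure;
it is deliberately simple and auditable.

# The synthetic study design

`synthetic_genome_spec()` + `generate_genome()` lay out a miniature
two-chromosome genome (60 kb + 40 kb by default) with 12 mRNAs, 4
two-exon mRNAs (introns ≥ 30 nt), SUTs/CUTs/XUTs, snoRNAs, rRNA and
tRNA exclusion classes, a Ty-like element and two rDNA-IGS-like
ncRNAs, non-overlapping with random intergenic gaps, over uniform
random sequence.

`simulate_library()` draws unique molecules from a binding model:

* `tss_peaked` — inserts confined to [TSS, +500) (clipped per
  transcript), the Set1-like shape;
* `body` — inserts confined to [+150, pA − 150), the Set2-like shape;
* `uniform` — the polymerase-like baseline and the shape used for the
  untagged background control (background reads are drawn uniformly
  over all annotated transcripts).

Molecules from intron-containing genes derive from the mature
transcript with probability `spliced_fraction` (default 0.5; windows
then live in mature coordinates and junction-spanning molecules map to
two genomic blocks) and from the pre-mRNA otherwise.  Expression
weights are log-normal(0, 1) per feature with a higher scale for rRNA
(5x) and tRNA (2x), mimicking the structured-RNA background of
cross-linking libraries; per-feature molecule counts are multinomial in
these weights.  Insert sizes are uniform on 20–80 nt, matching typical
CRAC cDNA inserts.

PCR duplication is a truncated geometric draw per molecule
(`min(rgeom(0.5) + 1, 10)`, mean ≈ 1.9); duplication rates are not a
published quantity, so these defaults are labelled synthetic choices.
Reads are assembled as tag + barcode + insert and padded with
concatenated adapter copies to a fixed read length of 112 nt, chosen so
that the full 21-nt adapter is always sequenced even for the largest
insert — trimming is then exactly invertible, which keeps the
preprocessing truth predictions exact.  Sequencing errors are off by
default (an optional uniform substitution rate exists); with errors off
every preprocessing outcome is predictable from the truth table alone
(`predict_collapsed_counts()`).  A configurable fraction of oligo(A)
contaminant reads exercises the low-complexity filter.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: realistic base composition,
cross-link-induced deletions/mutations at the protein-binding site,
size-selection effects of gel excision, chimeric or multi-mapping
reads, and overlapping gene annotation (features never overlap, so a
read's true feature is always its assigned feature; the priority rule
is exercised by dedicated unit fixtures instead).

# Numerical and coordinate conventions

Internally, all intervals are `GenomicRanges` objects — 1-based, closed,
the Bioconductor convention — and every external format keeps its own
convention through the standard writers: GFF3 and SAM 1-based
(rtracklayer/Rsamtools), bedGraph 0-based half-open (rtracklayer).
The 5' coordinate of a minus-strand read is the rightmost aligned base.
Ties in deduplication resolve to first input order; ties in expression
matching to lowest feature id; `heatmap_export()` writes rows in
descending sort-key order with `NA` for masked cells, byte-identically
on re-export.  All randomness flows from explicit integer seeds
(`with_seed` restores the caller's RNG state), and a single pipeline
seed expands deterministically into per-stage seeds, so a full
`run_pipeline()` re-run is byte-identical on every TSV and bedGraph.

Degenerate inputs are handled as contracts, not surprises: an empty
window after clipping falls back to the whole transcript; `EI + IE = 0`
makes the splice ratio undefined for that replicate (excluded from the
mean with a warning); zero library size is an error; a zero mean
coverage total gives an undefined CV that fails the reproducibility
filter.

# Problem sizes used in the validation suite

The test suite validates each stage against independent oracles:
brute-force all-pairs duplicate collapse on instances up to 1,000
segments; exhaustive enumeration of all 1,024 length-10 {A,C} reads for
the complexity boundary; an enumeration of the generator's junction
geometry (insert-length × start-position) for the expected
spliced/unspliced ratio at planted fractions 0.2/0.5/0.8 with 5,000
junction-focused molecules; a planted 8-fold over-bound IGS-like
feature at 10,000 molecules per library (the expectation accounts for
the weight-share renormalisation that library-size scaling introduces
and for the pseudocount); metagene shape recovery over 20 library
seeds at 60,000 molecules (~115,000 emitted reads) per factor; and a
truth-side recomputation of the CV/RPKM filter by plain arithmetic on
truth blocks.  These sizes are the package's chosen study conditions:
large enough that binomial noise bands are tight, small enough that the
whole suite runs in minutes on one CPU.

# Known limitations

* Multi-mapping reads are not modelled; only primary alignments are
  used, and the random-placement strategy some aligners offer is
  explicitly out of scope.
* The junction-overhang rule and the expression-matching algorithm are
  this package's explicit definitions of procedures that published
  pipelines describe only by reference; results depending sharply on
  either should report the parameters used.
* Feature-level enrichment uses pseudocounted totals; for features with
  totals near the pseudocount (a few RPM) the estimate is strongly
  shrunk toward zero by design.
* The relative metagene is a mean of per-base log-ratios across
  transcripts of different lengths; positions beyond a short
  transcript's body window legitimately contribute negative values
  (its factor coverage is zero there), so profile tails should be read
  together with the `n_features` column.
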
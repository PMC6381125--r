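---
title: "Detecting miRNAs, isomiRs and miRNA-offset RNAs with moRseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNAs, isomiRs and miRNA-offset RNAs with moRseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Bulk small RNA sequencing of a tumour cohort yields tens of millions of
short adapter-ligated reads per library. Beyond quantifying the annotated
mature miRNAs, such data carry three further layers of signal that standard
miRNA counters ignore:

* **isomiRs** — sequence variants of a mature miRNA with small 5'/3'
  boundary shifts (alternative Drosha/Dicer processing) and/or a few
  substitutions (SNPs, editing). In typical libraries the annotated "exact"
  sequence carries well under half of a miRNA's total signal, and some
  matures are expressed *only* as variants.
* **sister miRNAs** — the mature species from the opposite hairpin arm of a
  miRNA annotated on one arm only. The hairpin's secondary structure
  predicts where the sister must sit: the region pairing with the annotated
  mature, offset by the 2-nt 3' overhangs that Dicer leaves on each strand
  of the duplex.
* **moRNAs (miRNA-offset RNAs)** — ~20-nt species deriving from the hairpin
  region immediately *adjacent* to a mature: upstream of the 5p mature
  (5'-moRNA) or downstream of the 3p mature (3'-moRNA). They are rare and
  mostly weakly expressed, but individual moRNAs can reach high abundance
  and show subgroup-specific regulation, which makes them candidate markers
  in molecularly stratified cohorts such as multiple myeloma
  (translocation/CCND1 classes).

moRseq implements the complete path from raw FASTQ to these calls, their
per-sample quantification, exact-test differential expression between
molecular subgroups, and a constrained scan for candidate moRNA target
sites — together with a seeded synthetic-data generator, so that every
stage is testable against a planted ground truth without any external
download.

## Pipeline stages and their parameters

### Read filtering (`preprocess_fastq`)

1. **Adapter removal.** The leftmost occurrence of the 3' adapter — a full
   internal match or a read-end overlap of at least `min_overlap = 3` nt —
   ends the insert; up to 10% mismatches of the aligned length are
   tolerated. Reads starting with the adapter ("adapter-only") and reads
   without any adapter occurrence ("unclipped") are discarded: the first
   carry no insert, the second are almost always artefacts of failed
   ligation. The adapter defaults to the Illumina TruSeq small-RNA 3'
   adapter and is configurable.
2. **Length window 15–30 nt**, covering annotated human matures, moRNAs and
   modestly shifted isomiRs.
3. **Quality**: mean base quality strictly above Q30 and at most 2 bases
   under Q20. The mean is the arithmetic mean of Phred scores — the common
   read-QC convention and the plain reading of the thresholds.
4. **Abundance**: after collapsing identical inserts per sample, unique
   sequences with fewer than 10 reads are removed as ground noise. The
   filter is applied per sample, before any cross-sample merging, because
   collapsing is a per-library operation and the merged matrix is built
   from already-denoised tables.

Every input read is attributed to exactly one outcome (a rejection reason,
the noise bin, or the retained table); the testsuite asserts this
conservation and checks all four filters read-by-read against an
independent brute-force implementation.

### Mapping (`build_index`, `map_sequence`)

Retained unique sequences are mapped ungapped (substitutions only) to both
strands of the genome and to the forward strand of every *extended hairpin*
(the precursor plus 30 nt of genomic flank on each side — moRNAs and 5'/3'
isomiR overhangs live partly in this flank). The mapper is an exact k-mer
seed index with pigeonhole verification: a query of length L with at most m
substitutions must contain an exact segment of length `floor(L/(m+1))`, so
`k = 5` supports 15-nt queries at 2 mismatches. The mismatch budget is 2 —
the classifier tolerates up to two substitutions (3' half), and a tighter
mapping budget would silently exclude those isomiRs before classification.

Sequences mapping to more than 5 genomic loci *outside* annotated hairpins
are discarded as repeat-derived noise; placements inside hairpins never
count against this budget, so multi-copy precursor families (identical
hairpins at several loci) are retained. "Different loci" means distinct
(contig, start, strand) triples.

### Secondary structure (`fold_hairpin`, `duplex_fold`)

Sister discovery and target scanning need stem-level energetics, not a full
thermodynamic ensemble. moRseq ships a versioned, simplified
nearest-neighbour model (`extdata/stack_energies.tsv`): the 10 canonical
Watson–Crick stack free energies, a reduced set of G:U-containing stacks,
and a single helix-initiation penalty of +4.1 kcal/mol charged once per
helix (subsuming loop and duplex initiation). Structure energy is the sum
of stack terms over stacked pairs plus the initiation charges; the empty
structure scores 0, so isolated pairs are never optimal. `fold_hairpin`
finds the exact optimum of this model over all nested structures by
dynamic programming (minimum hairpin loop 3 nt; deterministic tie-breaking
that prefers extending a stem); `duplex_fold` finds the optimal monotone
antiparallel pairing of two strands under the same table. Dangling ends,
multiloop terms, pseudoknots and the partition function are deliberately
out of scope. The testsuite proves the DP equal to exhaustive enumeration
of all nested structures on hundreds of short sequences and checks the
strand-exchange symmetry `duplex_fold(a,b) == duplex_fold(b,a)`.

### Classification (`classify_placement`, `discover_sister`)

All coordinates are 1-based and closed. For a hairpin placement the class
precedence is:

1. **exact miRNA** — interval identical to a mature, no mismatches;
2. **isomiR** — both boundary shifts within ±3 nt of a mature and at most
   1 substitution anywhere or 2 both in the 3' half of the read (positions
   strictly after `ceiling(len/2)`); assigned to the mature minimising
   |shift5| + |shift3|, ties resolved towards the 5p arm;
3. **moRNA** — the read's central nucleotide, defined for even lengths as
   the left-of-centre position `start + floor((len-1)/2)`, lies strictly
   upstream of the 5p mature region (5'-moRNA) or strictly downstream of
   the 3p mature region (3'-moRNA). The central-nucleotide rule is the
   single authority; reads overlapping a mature without satisfying it are
   reported unclassified (e.g. loop-derived);
4. otherwise **unclassified**.

For hairpins with a single annotated mature, the predicted structure
locates the sister: if at least 60% of the mature's bases are paired, the
partner region shifted by the 2-nt 3' overhang convention becomes a
predicted sister mature, and expressed sequences matching it (same
shift/mismatch tolerances) are emitted as new miRNAs. Multi-copy families
are counted once at the family level; a miRNA's signal is the sum of its
exact and isomiR members. moRNA species are named `moR-<family>-5p/3p`,
sisters `<mature>-sister`.

### Statistics (`size_factors`, `nb_exact_test`, `de_test`, `correlate_pairs`)

Normalization is median-of-ratios (the DESeq size-factor definition).
Differential expression between each molecular group and all remaining
samples uses an exact conditional negative-binomial test: per-sample
counts are first equalized to a common library size (scaled by the
geometric-mean size factor over the sample's own, rounded half-to-even),
group sums are formed, and the test conditions on their total, with
NB(size = n/φ) group-sum distributions under a common dispersion φ
estimated by a pooled within-group method-of-moments ratio estimator.
Two-sided p-values sum all outcomes no more likely than the observed one;
at φ = 0 this reduces exactly to the conditional binomial test.
Benjamini–Hochberg controls the FDR per contrast, and reported hits carry
the upper-quartile expression flag (species whose total normalized signal
exceeds the third quartile of all totals). The original analysis fitted a
negative-binomial GLM and then computed exact tests; since the exact test
is the small-sample decision path, moRseq implements the common-dispersion
exact test directly and validates it by parameter-recovery and calibration
simulations (uniform null p-values; nominal type-I error; ≥80% power for a
4-fold change at 8-vs-22 samples) rather than by equivalence with any
external package. moRNA–miRNA co-expression uses Kendall's tau-b with a
one-tailed (positive association) p-value: exact permutation enumeration
up to n = 8 profiles, normal approximation beyond. Profiles as short as
n = 3 are accepted so that the exact enumeration path is exercisable on
tiny inputs, though correlations on fewer than ~10 samples carry little
evidence either way.

log2 fold changes are computed from normalized group means with a +0.5
pseudocount to keep zero-count species finite.

### Target scanning (`scan_transcript`)

Candidate moRNA target sites are found by sliding a window of moRNA length
+ 6 nt along the transcript and folding the heteroduplex in every window.
A hit requires (i) a seed: some contiguous block of 7 moRNA positions
fully paired with consecutive target bases — no unpaired base, no bulge —
with at most one G:U wobble, the block lying within the moRNA's 5' 10 nt
by default (the seed's position is not fixed by convention for offset
RNAs, so it is configurable to the whole molecule); (ii) at least 14 base
pairs in total, G:U counted; and (iii) duplex free energy at most −20
kcal/mol under the embedded table. Overlapping hit windows are merged
keeping the lowest-energy one. This scanner is a transparent,
parameterized stand-in for the published pattern-discovery tool whose run
was characterized by exactly this constraint set; it makes no attempt to
reproduce that tool's pattern-learning stage. Tightening any parameter
provably shrinks the hit set, and the scanner is tested window-by-window
against a brute-force enumeration.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed once and the tests are run under them.

* **Reference**: 50 hairpin records on a 100-kb contig. Each hairpin is
  arm + loop + reverse-complement arm (stem ≥ 30 bp, loop 4–12 nt, total
  60–120 nt), so the designed duplex is known exactly. 30% of families
  carry only the 5p mature (sister discovery must find the other arm); one
  family is replicated at 4 loci (family-level counting); one 22-nt decoy
  is planted at 6 loci (the multimap filter must remove it).
* **Expression**: 30 samples in five molecular groups (8 samples in the
  group used for the planted moRNA effect, mirroring an 8-vs-22 contrast).
  Mature baselines are log-normal (meanlog = log 150, sdlog = 1.5, floored
  at 170 so every planted species stays detectable above the count-10
  noise filter in expectation) — a heavy-tailed law under which a handful
  of species dominate the library. Each mature expresses an isomiR mixture
  (exact 40%, three shift variants 45%, two substitution variants 15%);
  five moRNAs are planted (one at the 98th abundance percentile, the rest
  at ~5% of a typical mature, floored at 40); three sisters are expressed
  on single-mature hairpins. Planted effects: the abundant moRNA at
  log2FC = 2 in "MAF", a second moRNA at 1.5 in "CCND1", and two miRNAs at
  ∓1.5 in the remaining aberration groups.
* **Reads**: per-sample counts are negative binomial (φ = 0.2) around the
  expected values; each 50-nt read is insert + adapter + random pad, with
  per-position mean quality declining 38 → 31 plus Gaussian jitter
  (sd 2.5). Injected noise: 3% adapter-only, 2% unclipped, 2% low-quality
  reads, 30 random singleton inserts under 10 copies, and ~30 decoy reads
  per sample. Everything is reproduced byte-identically from one integer
  seed.

What the generator does *not* emulate — indel sequencing errors, ligation
bias, cross-mapping between homologous real miRNA families, multi-contig
genomes, minus-strand hairpins — bounds what passing tests show: they
demonstrate correctness of the stated rules and calibration of the
statistics under the planted model, not performance on any particular real
library. In particular, per-precursor transcriptional co-variation is not
modelled: a planted moRNA and its cognate miRNA vary independently across
samples, so their Kendall correlation is near zero by construction, unlike
the positive co-expression expected for species sharing a precursor in
real data. The correlation machinery is therefore validated by direct
oracle tests, not by the simulated study.

## Numerical choices and degenerate inputs

* Strict inequalities follow the stated thresholds exactly: mean quality
  > 30, central nucleotide strictly upstream/downstream, energy ≤ −20,
  pairs ≥ 14, extra loci > 5 to discard.
* An even-length read's centre is the left-of-centre base; the "3' half"
  starts strictly after `ceiling(len/2)`.
* `fold_hairpin` accepts any sequence from `min_loop + 2` nt up to 300 nt
  (short inputs return the empty structure), so the enumeration oracle is
  applicable at small n.
* Zero totals give p = 1 by convention; constant profiles make tau
  undefined and are reported as not applicable; an all-zero count matrix
  and a matrix without an all-positive species row are errors (the
  pseudo-reference fallback is deliberately off by default).
* Simulation sizes in the testsuite (e.g. 6 samples × 50 hairpins for
  recovery, 5,000 null species for calibration, 100 replicates for power,
  2,000 × 30 for parameter recovery) are the package's chosen validation
  scales; they keep each property measurable with tight Monte-Carlo error.

## Known limitations

* The energy model is stem-level: no dangling ends, loop-length terms, or
  ensemble quantities; predicted energies are comparable within this
  package, not against full thermodynamic folders.
* The exact test uses a single common dispersion; per-species (tagwise)
  shrinkage is out of scope.
* The caller only scans annotated stem-loops (plus flanks); it does not
  discover novel hairpins genome-wide.
* moRNA biogenesis is not modelled; the central-nucleotide rule is applied
  as the single classification authority, and the per-moRNA overlap with
  the adjacent mature is reported for inspection rather than filtered on.
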
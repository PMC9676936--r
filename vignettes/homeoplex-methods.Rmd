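---
title: "Methods: homoeolog-resolved analysis of multiplexed long-amplicon reads"
author: "homeoplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog-resolved analysis of multiplexed long-amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

Hexaploid wheat carries three homoeologous copies of the vernalization
gene *VRN1*, on chromosomes 5A, 5B and 5D, at roughly 92% pairwise
sequence identity. A single long-range PCR with one barcoded primer pair
amplifies all three homoeologs (about 13 kbp of gene body plus 700 bp of
promoter) from each cultivar of a multiplexed panel, and the pooled
amplicons are sequenced on a nanopore instrument. The analytical problem
this package addresses is the downstream interpretation of such data:
separating reads by cultivar (barcode) and by homoeolog, calling
structural variants (SVs, at least 30 bp), SNPs and small indels against
the homoeolog references, phasing heterozygous sites into haplotypes with
single molecules, converting haplotype counts and allele-dosage skew into
gene copy numbers, grouping cultivars by their variant vectors, scanning
for G-quadruplex (QGRS) motifs, and testing groups against quantitative
traits.

Because the real sequencing data are not redistributable, the package is
organised around a synthetic-data generator that plants all of the
published allele classes with known ground truth. The generator is
first-class, tested code: every downstream claim in the test suite is a
planted-truth recovery statement.

# Synthetic references and planted alleles

`generateReferences()` builds one random ancestor amplicon and derives
three homoeolog references by independent per-branch mutation, 90%
substitutions and 10% short (1–5 bp) indels. The per-branch event rate is
initialised at $(1 - t)/2.4$ for a target pairwise identity $t$ (each
event costs about 1.2 alignment columns and two branches separate a
pair) and then calibrated by direct measurement, so the reported pairwise
identity lands within ±0.02 of the target; the measurement itself is a
full global alignment and is cross-checked in the tests against
`Biostrings::pairwiseAlignment` as an independent quadratic-time oracle.
G-rich quadruplex-eligible motifs are planted in the promoter and first
intron of the ancestor and kept mutation-free so every reference carries
scannable targets.

The feature map fixes a 700 bp promoter stub, a long first intron
(everything not taken by the fixed-size exons and introns — about 70% of
the gene body, as in the real amplicon) and seven further exon/intron
pairs; all positions in the package are 1-based and counted from the
amplicon start, i.e. the 3' end of the forward primer. Internal
arithmetic is 0-based half-open only inside the compiled alignment core.

`vrnPanelReferences()` additionally pins the bases at every published
variant position to the reference allele and rewrites the ±4 bp
neighbourhood so that (i) adjacent bases always differ — indel placement
at planted sites is then unambiguous — and (ii) the alternate alleles of
the site do not occur in the window, which prevents alternate-allele read
bases from pairing with a neighbouring reference base and being absorbed
into a gap (a reference-bias mode we observed with indel-noisy reads).
The published variant definitions themselves (the five large SV alleles,
the 51-site variant table over six genotype groups, the six-site B-genome
haplotype table, the three defining D-genome variants) are shipped as
code; insertion payloads for which only a length is published are
synthetic stand-ins (a foldback-style sequence joined to its reverse
complement for the 231 bp promoter insertion, a random sequence for the
163 bp insertion), generated from fixed RNG streams.

Two sites of the 51-site table print a deletion allele for the
reference-type groups although positions are given in that reference's
coordinates; the synthetic reference uses the divergent-group base at
those positions and the reference-type templates carry a 1 bp deletion,
which keeps all 51 columns polymorphic within the panel.

# Error model and read simulation

The default error model is substitution 0.03, insertion 0.02, deletion
0.04 per base, with indel rates multiplied by 3 inside single-base runs
of length ≥ 4 — an approximation of R9.4.1-era nanopore behaviour with
its homopolymer-inflated indel error. Chimera probability (default as
configured per scenario; 0.152 reproduces the published chimeric-read
fraction) fuses a read with an independently drawn barcoded molecule, so
the second barcode ends up mid-read; barcode-loss probability emits
molecules without barcodes. Molecules carry the cultivar barcode at the
head and its reverse complement at the tail, as PCR barcoding does; half
of all reads are emitted reverse-complemented. Per-base qualities follow
the aggregate error rate (Phred of the total per-base error probability)
with Gaussian per-read and per-base jitter, so mean-Q filtering at the
published threshold (Q ≥ 8) removes a realistic minority of reads.
A fraction of reads (15% by default) is partial rather than full-length,
uniformly placed, with a 500 bp minimum.

`simulatePanel()`'s `meanCoverage` is the expected spanning depth; read
counts per template copy follow a multinomial over the copy amplification
weights, which is what makes dosage skew (e.g. two of three copies
carrying one allele) visible in read counts. Everything is deterministic
under the seed, to the byte, including the FASTQ output.

# Demultiplexing

Barcodes are matched by banded edit distance (pigeonhole-seeded scan in
compiled code) with at most 3 edits on 24-base barcodes, both
orientations. A qualifying hit within 150 bases of either read end is
terminal; a qualifying hit anywhere else marks the read chimeric, as do
conflicting barcodes at the two ends. Assigned reads are barcode-trimmed
before alignment — without trimming, the constant barcode sequence
pseudo-aligns near template ends and creates systematic pileup artifacts.
Mean quality uses probability averaging,
$-10\log_{10}(\overline{10^{-q/10}})$, and the read filter applies
length 2,000–16,000 and mean Q ≥ 8 (the workflow's published thresholds;
an alternative Q 7 appears in parts of the source material and remains
configurable).

# Alignment

The aligner is a two-pass seed-chain-and-refine design. 15-mers of the
read are matched against a per-reference index (seeds occurring more than
10 times are dropped), co-diagonal runs are merged into maximal exact
anchors, and the best colinear chain is found by dynamic programming with
a gap penalty linear in the diagonal difference — cheap enough that both
orientations are chained against all three references for every read.
The best reference is refined: inter-anchor segments are closed with
affine-gap Needleman–Wunsch (match 2, mismatch 4, gap open 4, gap extend
2), with pure-gap segments emitted directly, so a 6.8 kb deletion or an
838 bp tandem-duplication insertion survives as a single edit operation —
the property the SV caller depends on. Other references are refined only
when their chain score is close enough to matter for the uniqueness
decision.

Per-read identity is gap-compressed (a contiguous indel counts one
column): with full gap-column counting a read spanning the 6,851 bp
deletion would have identity 0.5 and fail the 0.80 identity filter, which
would contradict the SV-calling path itself; gap compression is the
long-read mapper convention. Sequence-level identity (reference pairs,
consensus comparison, sequence typing) counts all gap columns and matches
the Needleman–Wunsch oracle. Assignment requires identity ≥ 0.80 and
aligned fraction ≥ 0.50; uniqueness requires the best-minus-second score
margin to reach 50 score units (the mapping-quality analogue), with gap
penalties capped at the SV-length threshold so SV-spanning reads still
outscore the wrong homoeolog. Ties (e.g. identical references) are
ambiguous and excluded downstream.

# Consensus, SV and small-variant calling

The reference-guided consensus is a column-wise majority vote including
gap columns, ties broken toward the reference base; insertions are taken
when a majority of spanning reads carries one, using the modal inserted
sequence (lexicographic tie-break). Samples with fewer than 3 reads fail
with an explicit low-coverage condition.

SV calling collects per-read indel operations ≥ 30 bp, clusters them by
position within ±100 bp, and emits calls with ≥ 10 supporting reads,
reporting median position and length (robust to nanopore indel noise).
Insertions whose sequence matches a flanking reference window of the same
length at ≥ 0.9 identity are reclassified tandem duplications; both
flanks are checked because the chain may place the inserted copy on
either side of a tandem repeat. Cross-sample merging collapses same-type
calls within 500 bp (single linkage) into carrier lists. The cluster and
merge windows are our choices — the published workflow names its tools
but not their parameters — sized to keep the 37 bp deletion separate from
the nearby large-deletion breakpoints.

The pileup caller emits a candidate at any site with ≥ 2 non-reference
reads at ≥ 2% frequency and depth ≥ 11 (the published minimum coverage),
and passes it at count ≥ 3, frequency ≥ 0.20 and site quality ≥ 30. Site
quality is the Phred-scaled binomial tail of the allele count under a 5%
per-base error rate — the published "quality ≥ 30" is a caller-specific
scale, so the package fixes its own defined score with the same threshold
value. The 0.20 heterozygous-frequency floor tolerates dosage imbalance
up to 4:1, which the three-copy 2:1 case requires. Deletion alleles must
reach 0.45 frequency: nanopore deletion noise stacks at homopolymer-flank
positions (two adjacent 3-base runs can put ~20% deletion support on one
position), and in this design planted deletion alleles are homozygous
within a cultivar, so the higher floor removes a systematic
false-positive mode without touching the planted truth. Calls inside or
immediately adjacent to single-base runs of ≥ 4 are flagged and excluded
downstream — the published workflow excludes "most" homopolymer SNPs
without stating the retained exceptions, so this implementation excludes
all flagged sites and keeps the flag visible. Small indels (1–29 bp) are
recovered on the consensus-versus-reference alignment, below the SV
threshold.

# Phasing, dosage and copy number

Reads spanning all heterozygous sites of an amplicon contribute one
allele vector each; vectors with ≥ 10 supporting reads become haplotypes
(the same support floor as the SV caller, suppressing error-chimera
vectors), reads with a non-called allele at any site count as ambiguous,
and the haplotype count is a minimum copy number. Sites in G/C-repeat
context (the promoter-quadruplex SNP analogue) are excluded from phasing
input, mirroring the published difficulty of reading that site from
nanopore data.

Allele dosage at the diagnostic exon-4 site is the alternate-read
fraction with a Wilson 95% interval and a two-sided binomial test against
0.5. For sequence-level data the package also provides realignment-based
dosage (`dosageFromAlignments()`): each spanning read is locally
re-aligned against the two allele contexts and assigned to the better
score, which removes the residual reference bias of raw pileup counting
(alternate-allele mismatches being absorbed into nearby indel
representations). The cluster rule calls skewed (the three-copy analogue)
when the interval excludes 0.5 and the frequency is ≥ 0.6, balanced when
the interval contains 0.5 or the frequency is within [0.4, 0.6], else
indeterminate. The 0.6/0.4 split is the midpoint between the theoretical
two-of-three (0.667) and one-of-two (0.5) dosages. The copy-number rule
is then: homozygous with one haplotype = 1; two haplotypes balanced = 2;
two haplotypes skewed = 3; four haplotypes = 4; anything else keeps the
haplotype minimum with the dosage noted as uncorroborated, and
contradictions (four haplotypes with skewed dosage) are flagged but never
lower the count below the phased minimum.

The classifier-recovery grid in the tests (copy numbers 1–4 at depth 300,
50 seeds each) runs on read-level allele-vector simulation — the error
model applied at the het sites — rather than full read alignment per
seed; this keeps the grid a test of the phasing/dosage/copy-number logic
at the stated depth while two full sequence-level scenarios (the
three-copy skewed and four-haplotype configurations) are additionally run
through simulation, demultiplexing, alignment and calling.

# Grouping and sequence typing

Genotype grouping is exact matching on the variant vector: heterozygous
calls are unordered allele pairs, missing values match nothing (a sample
with missing data forms its own group — the published material does not
state how partially covered cultivars were grouped, and this choice is
reproducible), and labels are ordered by descending group size. Sequence
typing assigns a consensus to the best reference-panel hit by
full-column global identity, discarding hits below 0.99, ties broken
alphabetically.

# QGRS scanning

A quadruplex motif is four equal-length all-G tracts (tract ≥ 2)
separated by three loops within a 30 bp window. The scanner enumerates
every placement and scores
$\mathrm{score} = c\,(\mathrm{maxLen} - \overline{\mathrm{loop}}) + 2\,(x - \mathrm{minTract})$
with $c = 1$ — shorter, more even loops and longer tracts score higher,
the qualitative ordering of the published mapper, whose scoring internals
are not specified; the constant is fixed so the score is
oracle-checkable. Non-overlapping motifs are selected greedily by
descending score with deterministic tie-breaks (leftmost, longer tract,
shorter span). Only the sense strand is scanned by default, matching the
published analysis; the reverse strand sits behind a flag. The test suite
checks the scanner against a brute-force enumerator (direct position
loops, independent code path) on 1,000 random 200-mers.

# Association

Two-level groupings are tested with the Wilcoxon rank-sum test (exact
when the combined n ≤ 50 and untied, else normal approximation with
continuity correction) plus Student and Welch t-tests, two-sided;
disagreements at α are flagged. Multi-level groupings use Tukey HSD with
a compact letter display built by insert-and-absorb over the significant
pairs. No multiple-testing correction is applied by default, matching the
per-trait α ≤ 0.05 convention of the source analysis across 20 traits; a
Benjamini–Hochberg option exists. Degenerate comparisons (identical
zero-variance groups) return p = 1 with a flag.

# Numerical and scale choices

Simulated problem sizes in the tests are chosen to exercise the stated
study conditions while remaining desk-scale: 50 error-free full-length
reads for exact SV-length recovery, 200x default-error coverage for the
51-site panel, depth 300 for the dosage/copy-number work, 10,000 reads
for rate-recovery checks, and 1,000 random 200-mers for the scanner
equivalence. The phenotype generator's 20 traits use central-European
winter wheat baselines (e.g. grain yield 95 ± 6 dt/ha) chosen once as
realistic scales; planted effects in the tests (−9.5 dt/ha on yield, i.e.
about −10%) are recovered with > 0.8 power at n = 20 per group.

# What the synthetic data do and do not show

The generator reproduces homoeolog-style divergence, amplification-weight
dosage, nanopore-like substitution/indel error with homopolymer
inflation, chimeras, barcode loss, strand mixture and partial reads. It
does not reproduce basecaller-specific error correlations, systematic
strand biases, PCR jackpotting beyond fixed weights, or the real
*VRN1* sequences themselves (references are random backbones with planted
structure). Passing tests therefore demonstrate that the implementation
recovers planted truth under a faithful error geometry — not that any
specific biological claim about real cultivars would be reproduced;
real-data reuse requires only standard FASTQ/FASTA inputs through the
same functions.

# Known limitations

The aligner is intentionally not a production long-read mapper: it
assumes amplicon reads from a known small reference set, and its
uniqueness margin is a score-gap analogue of mapping quality, not a
probabilistic MAPQ. Phasing requires single reads to span all
heterozygous sites (true for this amplicon; not general). Copy numbers
above four are reported only as haplotype minima. The VCF writer emits a
minimal, valid 4.2 subset (SVTYPE/SVLEN/END/SUPPORT; DP/AC), not a full
spec implementation.
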
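---
title: "Models and methods behind miRcurate"
author: "miRcurate maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind miRcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRcurate)
```

## The annotation problem

Plant miRNA annotations disagree across databases and prediction tools:
the same genome can carry hundreds of loci annotated in one resource and
absent from another, and sRNA-Seq-based predictors add further candidates
of very mixed quality. miRcurate implements a compile–select–curate
workflow for this situation: aggregate every candidate precursor from all
sources onto one genome coordinate system, score each candidate against
structural and read-evidence criteria plus a novelty detector trained on
trusted annotations, and emit per-candidate summaries a human curator can
accept or delete deterministically.

Throughout the package, coordinates are 1-based inclusive, on the genome
and on the precursor. Precursor sequences are always stored as the
transcribed strand in the U alphabet; minus-strand loci are
reverse-complemented at parse time, and precursor-local offsets count from
the transcribed 5' end.

## Compilation

`parseAnnotationSource()` reads one GFF3 + genome pair per source; mature
features must be contained in a precursor on the same strand or parsing
aborts naming the offender. `locatePrecursor()` places coordinate-free
records (FASTA-only sources) by exhaustive both-strand search with at most
`maxMismatch` substitutions (default 2, no indels). Mismatch-tolerant
substring search is deterministic and sufficient for intra-species
placement of ~40–300 nt precursors; indel-tolerant spliced alignment is
deliberately out of scope.

`aggregateCandidates()` merges same-strand records whose intervals
reciprocally overlap at least `minOverlapFraction` (default 0.5 of both
widths) into one record by union–find, so the result is transitive and
independent of input order. The merged record keeps the longest member
sequence (ties broken by smallest id), unions the source tags, and
deduplicates matures by (offset, length) after projecting them through
genome coordinates. Reciprocal 50% is our choice of merge rule; no single
published criterion exists, and the parameter is exposed. Records a
predictor places at several genome positions stay as sibling records and
become lettered members of one family during naming.

`assignUniformNames()` preserves database names and names novel
(predicted-only) loci `<prefix>-MIR_N<k><letter>`, with `k` a running
family index (families = identical dominant mature sequence, or identical
precursor sequence when no mature exists) and the letter a member suffix;
matures get `-5p`/`-3p` suffixes from their arm.

## Read processing and expression

Alignments enter as SAM (through Rsamtools; collapsed-read multiplicities
are read from `name_xN` query names) or as a plain 6-column TSV. A read
stack keeps exactly the reads fully contained in a precursor interval on
its strand, flipped into precursor-local coordinates on minus-strand loci
and aggregated by (offset, length, sample).

Expression is TPM with the library total defined as **all** mapped reads
of the sample, not only miRNA-assigned reads, matching common usage when a
study quantifies one RNA class against whole-library depth; the totals are
a plain argument, so a caller can substitute any denominator.
Multi-mapped reads count fully at each placement — small RNAs from
repeat-derived families are otherwise systematically under-counted — and
this is a documented, configurable policy rather than a claim about the
single right answer. Expression breadth is the fraction of samples at or
above `tpmMin` (default 1 TPM), and "broad" requires strictly more than
`fracMin` (default 0.5) so that exactly half the samples does not count.

`discoverLoci()` replaces external predictors with a transparent
read-cluster stage: same-strand reads within `maxGap` (200 nt) cluster,
clusters longer than `maxLocusLen` (300 nt, the upper end of plant
precursor norms) are dropped, the rest are excised with `flank` (100 nt)
context. Candidates without an annotated mature get one inferred from the
most abundant 20–24 nt read form.

## Folding and duplex geometry

The built-in folder is a weighted Nussinov dynamic program over nested
pairings: GC pairs score −3, AU −2, GU −1 (model units), minimum hairpin
loop 3 nt. These toy weights order hairpin structures the way
stacking-free thermodynamic folding does at precursor scale while keeping
the global optimum exactly enumerable, which is what makes the folder
testable: the suite checks the DP against a brute-force enumeration oracle
on hundreds of short random sequences. Traceback is deterministic (pairing
beats leaving a base unpaired; smallest partner wins ties), so identical
inputs give identical dot-brackets. A thermodynamic folder can be plugged
in by passing its dot-bracket to `secondaryStructure()`, which derives the
pair table and, if no energy is supplied, recomputes one under the active
weights so the energy/pair-table invariant always holds. AMFE normalizes
energy per 100 nt.

Duplex statistics assume canonical DCL1 geometry: the star is the set of
pair-table partners of the mature (excluding the mature's own 2-nt 3'
overhang), extended 2 nt at its 3' end; unpaired anchors are projected
from the nearest paired position. Mismatches count mature positions that
are unpaired or paired outside the star span; asymmetric-bulge nt sum the
absolute difference of unpaired run lengths between the strands across the
duplex; overhangs are measured back from the pair table, so a perfect stem
reports exactly 2/2. A mature whose span contains its own partner
straddles the terminal loop and is rejected.

Processing precision is the fraction of stacked read counts whose two ends
both fall within `tol` nt (default 1) of a mature or star end — the
classic read-stack signature of genuine DCL processing.

## Feature registry and selection

The feature vector is fixed-order and versioned by `featureRegistry()`:
84 k-mer frequencies (mono/di/tri), GC content, precursor and mature
length, paired fraction, energy, AMFE, stem and loop size, the four duplex
statistics, a 20-bin pairing profile, and three expression summaries (max
TPM, mean TPM, breadth). We use expression *summaries* rather than raw
per-sample TPM columns by default: raw columns make the model's dimension
depend on the dataset shape, which breaks model reuse across studies;
callers who want per-sample features can extend the matrix themselves.

The high-throughput criteria are independent boolean rules (mature length
20–24 nt, precursor ≤ 300 nt, ≤ 5 duplex mismatches, ≤ 3 nt asymmetric
bulge, 2 ± 1 nt overhangs, precision ≥ 0.75, ≥ 2 libraries, star reads or
replication), conjoined for the overall pass. The defaults encode
consensus plant miRNA calling practice and every threshold is an argument;
candidates without read evidence fail the evidence rules rather than
erroring, so database-only entries flow through to the SVM route.

The machine-learning route is a one-class RBF SVM (e1071) trained on
trusted positives only. Standardization center/scale are learned from the
training set and frozen in the model; zero-variance features are dropped
with a warning and recorded. `nu` (default 0.05) bounds the
training-outlier fraction — the suite verifies this ν-property
empirically — and `gamma` defaults to 1/n_features after dropping. The
decision threshold defaults to the SVM boundary (0) and is exposed, since
whether a published threshold was tuned is usually unknowable. The final
set defaults to the **union** of the two routes: union is the only set
relation consistent with published counts in which the selected total
exceeds both routes (e.g. 588 and 704 route passes yielding 886 selected
implies 406 shared and a union combination). Training defaults to
database-annotated records; `trainOn = "ht_pass"` exists for the case
where the annotation source itself is untrusted — this is what the
end-to-end tests use, because their synthetic "database" deliberately
contains decoys.

## Curation analytics

IsomiR calls are template-only coordinate shifts (add5/sub5/add3/sub3)
relative to the nearest same-arm mature; non-templated tailing is out of
scope. The call is invertible: mature interval plus the four amounts
reconstructs the read interval exactly, and the suite tests this inverse
mapping over random offsets. Arm switching is called when one sample has
the 5p arm dominant by at least `ratioMin` (default 2) with both arms at
or above `floor` (default 1 TPM) while another sample shows the mirror
pattern; published examples are typically shown visually, so this pairwise
dominance rule is our explicit operationalization, with both knobs
exposed. Genomic context takes the highest-precedence feature label
covering ≥ 50% of the precursor (default precedence: TE subclasses first,
then TE, lncRNA, intron, exon; `intergenic` otherwise).

`buildSummary()`/`exportAnnotation()` regenerate the summary TSV, GFF3,
FASTA and per-candidate markdown+JSON reports byte-identically for
identical inputs, so a curator's removal list is the only thing that
changes an export.

## Polyploid homoeolog analytics

Subgenome labels come from chromosome-name patterns (wheat-style trailing
A/B/D by default). Homolog groups are single-linkage clusters of mature
sequences under Levenshtein distance ≤ 2 — homology on matures rather than
precursors because mature sequences are the conserved, functional unit;
the grouping rule is a declared substitute for unpublished practice and
both the distance and the linkage are parameters. Configurations are the
per-subgenome copy-count strings (1:1:1 = triad); any group with a copy
count above 1 or an unplaced member is "others". The subgenome bias test
is a plain χ² goodness-of-fit without continuity correction against equal
expectations (configurable to size-proportional), and for three labels the
suite checks it against the closed form p = exp(−χ²/2). Ternary
coordinates are the componentwise shares of (A, B, D) expression.

## The synthetic fixture generator

`makeFixture()` plants perfect hairpins (stem + loop + reverse-complement,
default 30 + 8 + 30 nt, 21-nt mature on the 5' arm, star at the canonical
2-nt-overhang partner) on separate contigs with 100-nt flanks, alternating
strands and wheat-style contig suffixes; decoys are dinucleotide-shuffled
copies of true hairpins — composition preserved, structure destroyed — the
hardest negatives constructible without external data. Reads are drawn per
locus and sample: a binomial `precision` fraction at exact mature/star
ends split by `armDominance` (flipped between sample halves for arm-switch
loci), isomiR classes with 1–2 nt template shifts, and the remainder at
uniform offsets. Decoy loci get no reads. All randomness flows from one
seed; two runs with the same config are byte-identical on disk.

Because non-canonical reads are shifted by 1–2 nt, they fall inside the
default precision tolerance (`tol = 1`); when a test needs to recover the
*planted* precision it therefore measures at `tol = 0`, which is how the
generator defines precision (exact ends).

What the fixtures do not emulate: sequencing error, adapter contamination,
expression heterogeneity across loci, multi-mapping between loci, and
genome-scale intergenic background. Passing the recovery tests therefore
demonstrates the correctness of the pipeline's logic, not its ROC on real
tissue libraries.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the folder against the
enumeration oracle on 200 sequences of length ≤ 12, recover precision at
depth 1000, check the ν-property at n = 1000 training points, and run the
end-to-end recovery on 50 true + 50 decoy loci at depth 50 over 4
libraries — sizes at which every check completes in seconds while the
binomial error bars are already tight. Degenerate inputs are handled
explicitly: empty stacks and zero library totals error; unlocatable
precursors and zero-sum ternary points are flagged rather than dropped
silently; zero-variance features are removed with a record in the model.

## Known limitations

The toy energy model has no stacking, dangles or temperature dependence;
absolute energies are not thermodynamic (use the dot-bracket plug-in path
when calibrated MFEs matter). Mismatch-only placement cannot locate
precursors across indel-bearing genome revisions. Multi-mapping is
all-or-nothing per placement (no fractional weights). Target prediction,
SNP/trait association, and interactive HTML reports are outside the
package's scope.
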
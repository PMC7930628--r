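---
title: "Benchmarking variant detection in ancient mitochondrial DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking variant detection in ancient mitochondrial DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomt)
```

## The problem

DNA recovered from archaeological remains is short (often ~50--150 bp),
present in low copy number, mixed with present-day human contamination, and
chemically altered: post-mortem cytosine deamination produces C>T
misincorporations at the 5' ends of reads and, in double-stranded
libraries, the complementary G>A at 3' ends. Mitochondrial DNA (mtDNA) is
the usual target because of its high copy number, but it brings two extra
complications: the genome is circular (the rCRS reference is 16,569 bp,
with an `N` placeholder at position 3107), and nuclear copies of
mitochondrial segments (NumtS) attract reads that do not come from the
mitochondrion at all.

Against this background, calling mtDNA variants -- and especially
*heteroplasmies*, sites where two alleles coexist within an individual at
some allele fraction (AF) -- requires aggressive filtering, and the filters
themselves need calibration. `paleomt` packages the whole loop: a
ground-truthed simulator of damaged, contaminated mtDNA sequencing; a
circular-aware mapper with NumtS exclusion; a pileup variant caller with
allele-depth, allele-fraction and likelihood evidence; the multilevel
filter grid used to build consensus sequences and heteroplasmy profiles;
and a whole-genome confusion-matrix scorer.

## The simulator and what it emulates

`simulation_config()` defaults encode the benchmark's study conditions:

* single-end reads of 101 bp from fragments of fixed length 110 bp
  (minimum 30 bp), at 100-fold endogenous coverage;
* fragment starts uniform on the circle, strands uniform -- no GC or
  fragmentation-site bias;
* deamination damage confined to 12 bp windows at each fragment end, with
  probability `delta_max * decay^i` at offset `i`; the defaults
  `delta5_max = delta3_max = 0.3`, `decay = 0.5` give the ~30% terminal
  C>T rate typical of non-UDG-treated ancient libraries. An explicit
  per-offset rate table can be supplied instead to mimic an empirical
  misincorporation matrix;
* a present-day contaminant mixed in at a configurable fraction of
  fragments. Contaminant reads are **undamaged** -- a deliberate modelling
  assumption (a modern contaminant has no post-mortem damage); NumtS decoy
  reads, by contrast, *do* receive damage, since endogenous nuclear DNA is
  as ancient as the mitochondrial fraction;
* an optional second endogenous haplotype for heteroplasmy designs: a
  30:70 mixture of a mutant and the reference haplotype with 2%
  contamination gives an expected AF of 0.30 x (1 - 0.02) = 0.294 at the
  mutant's private sites;
* uniform sequencing errors at `1e-3` per base; base qualities Q30
  perturbed by up to +/-2 for realism.

Coverage is *fragment*-based (`n = round(coverage * L / fragment_length)`
fragments), matching the conventions of aDNA fragment simulators. Because
reads are truncated to 101 of the 110 fragment bases, read-level pileup
depth is about `101/110` of the nominal coverage, and PCR-duplicate
collapsing (fragments sharing start, end and strand are inevitable on a
16.6 kb circle at 100X) removes a further ~20% of reads. Depth checks in
the test-suite therefore use the matching oracle for each level: fragment
depth against the configured coverage, pileup depth against
`n_reads * read_length / L`.

The simulator is deterministic given a seed: every stage draws from a
stream derived from the master seed, and identical configurations produce
byte-identical FASTQ output.

What the generator does *not* emulate -- and hence what passing tests do
not certify about real data: length-distributed fragments, platform error
profiles, adapter chemistry and paired-end merging, UDG treatment, indel
sequencing errors, depurination-driven G>T transversions, or strand-biased
library artifacts. The simulated genome is a synthetic random sequence
with mtDNA-like base composition (shipped in `inst/extdata`), not the real
rCRS; a user-supplied rCRS FASTA is accepted transparently.

## Mapping

Fragments this short almost never require gapped alignment, so the mapper
is ungapped (substitutions only) with a placement budget of
`max_mismatch = 4`. Rather than a heuristic, the search is exact over the
budget: each read is split into `max_mismatch + 1` disjoint chunks, and by
pigeonhole any placement with at most `max_mismatch` mismatches must match
one chunk exactly, so exact k-mer lookup of the chunks enumerates *every*
qualifying placement on both strands of all targets. The test suite checks
this against a plain brute-force minimum-mismatch scan. Circular targets
are scanned over all L start positions via a doubled copy, which is
equivalent to mapping against an elongated reference and canonicalizing
placements back onto the circle -- reads spanning the origin get a single
contiguous placement.

Admission mirrors standard aDNA preprocessing: reads shorter than 30 bp or
with mean base quality below 30 are rejected. Because the simulator emits
Q30 qualities jittered by +/-2, a strict mean >= 30 test would reject half
of all perfectly good reads on rounding noise, so the mean is rounded to
the nearest integer before the comparison.

Mapping quality encodes ambiguity, not error probability: 37 for a unique
best placement with fewer than 2 mismatches, 30 for a unique best
placement with 2--4 mismatches, 0 for ties. Unique placements therefore
always survive the MQ >= 30 retention rule, as with BWA's unique-hit
quality. We considered demoting many-mismatch unique placements below the
retention threshold and rejected it: it selectively discards exactly the
damaged and variant-carrying reads, biasing the measured damage profile
downward (0.22 vs a true 0.29 terminal rate in our simulations) and
depressing recovered allele fractions in mixture designs well below their
design value. The ambiguity filter then keeps only mitochondrial-target
alignments whose best placement is unique with no equal-best secondary hit
(`delta = 0`; any tie -- e.g. against a NumtS decoy -- disqualifies), and
flags PCR duplicates by (target, start, end, strand) identity, keeping the
highest-quality copy.

## Damage estimation and quality rescaling

The damage profile is estimated from retained alignments only:
`rate5_CT[i]` is the fraction of reference-C sites at read offset `i`
(from the 5' end, in read orientation) observed as T, and symmetrically
`rate3_GA[i]` from the 3' end. Offsets with no reference-C (or -G)
coverage report `NA`, never 0. Rescaling then downscales exactly the
bases that look like damage -- T over reference C within the 5' window, A
over reference G within the 3' window -- to
`q' = -10 log10(d + 10^(-q/10))`, floored to an integer, where `d` is the
estimated rate at that offset. `q'` can never exceed `q`. With the default
pileup floor of Q20, rescaling silently removes damage-lookalike bases at
high-rate offsets from the pileup, which is what makes terminal damage
nearly invisible to the caller; the cost is a mild depression of AF at
true C>T and G>A variant sites, visible in the mixture design as a mean AF
a point or two below the design value.

## Variant calling and per-call filters

For every non-reference allele with at least one supporting base the
caller computes AD, RD (reads supporting the reference allele
specifically, not `DP - AD`), DP, the plug-in allele fraction
`AF = AD/DP`, and a log10 likelihood ratio comparing "allele present at
AF" against "sequencing errors only", using each base's own error
probability (`e = 10^(-q/10)`, misread probability `e/3`). A candidate is
emitted iff the ratio is non-negative; the plug-in AF (rather than
marginalizing over AF) and the 0 threshold mirror the permissive emission
settings of somatic callers run in mitochondrial mode. Sites whose
reference base is `N` are not callable; the evaluation blacklist covers
them.

Filter tags are cumulative and never rescind each other: `low_af`
(AF < 5%, the emission floor -- nothing below it is ever reported),
`position_bias` (median distance of variant bases from the nearer read
end < 3), `strand_bias` (two-sided exact conditional test on the strand
2x2 table at p < 1e-3, guarded so it only fires when alt support sits
entirely on one strand), `weak_evidence` (negative likelihood ratio), and
`contamination`: AF within two binomial standard errors of the supplied
contamination rate. The contamination rule applies to minor alleles only
(AF < 0.5) -- a majority allele is never discarded as contaminant, because
majority alleles go into the consensus regardless of the contamination
estimate. The contamination rate itself is an *input* (in practice an
estimate from a dedicated contamination-profiling tool); estimating it is
out of scope.

## The filter grid, consensus and heteroplasmy profile

`pattern_grid()` reproduces the 30 tested filter combinations: minimum AD
in {none, 2, 3, 5, 10} crossed with minimum AF in {5%, 50%} and the
historically paired DP thresholds ({3, 4, 5, 10, 20}), plus mean- and
highest-contamination-rate variants at AF 50. The AD/DP pairings follow
the original grid but are implemented as independent thresholds, so any
combination is accepted (expert mode lifts the grid restriction entirely).

Consensus rules: a site enters the consensus only through a retained call
with AF >= 0.5 (inclusive, so an exact 0.50/0.50 biallelic tie sends both
alleles to the multiallelic rule, which reports the reference -- the
documented tie-break). Sites with several surviving alternatives report
the reference; sites with zero post-filter depth are written as `N`;
everything else keeps the reference base. Indels are inserted after SNPs
in descending position order so reference coordinates stay valid
throughout. Coverage percentage (sites with depth >= 1) and mean depth are
reported separately so fragmented samples remain quantifiable.

Potential heteroplasmies are the `PASS` calls with AD >= 10 *and*
RD >= 10 (both inclusive); profiles bin them into AF ranges
`[5,10), [10,20), ..., [80,90), [90,100]` -- half-open interiors with a
closed top bin, so "low heteroplasmy" is AF < 10% and "quasi-homoplasmy"
is AF >= 90%. The interior bin edges are our reading of the standard
10-point profile; only the two extreme definitions are fixed by
convention. Indel calls are profiled along with SNPs and flagged by their
`vclass`. The transition/transversion ratio returns an `NA` sentinel when
no transversions are present (common in small ancient call sets), never a
division by zero.

## Evaluation conventions

`classify_calls()` classifies every one of the 16,569 sites exactly once,
so TP + TN + FP + FN always equals the genome length; this invariant is
property-tested. Exclusion lists -- the artifact blacklist (3107) and the
rCRS rare-polymorphism sites (1189, 4769, 7028, 8860; user-extensible,
since the full list of seven is not enumerated in our sources) -- are
removed from *both* sets before classification, so excluded sites count as
true negatives. A shared position where the two sets disagree on the
allele is counted as a single FP (the test set called a wrong variant
there), with the missed reference allele noted in a side report; counting
it as FP *and* FN would break the sums-to-genome invariant. The
convention is configurable. Display rounding (two decimals; FPR and FOR
in scientific notation) happens only at format time; all stored values
keep full precision, and the metric identities FDR = 1 - PPV and
FNR = 1 - SN hold exactly.

Aggregation over samples takes the arithmetic mean and median of the
per-sample statistics, never recomputed from pooled counts.

## Problem sizes and numerical choices

The shipped test-suite and the acceptance script run the full pipeline at
the benchmark's own scale -- 36 SNPs at 100X on the 16,569 bp genome, ~15
thousand reads per replicate, 20 independent seeds per design -- which
takes a few seconds per replicate; unit tests use 1--4 kb toy circles.
Sub-stage seeds are derived deterministically from the master seed and
kept below 2^31. Ties in deduplication break lexicographically by read
id; the exact conditional strand-bias test uses `stats::fisher.test`; the
rescaled quality floor is 0; damage saturates rather than erroring when a
window exceeds the fragment length.

## Known limitations

* Ungapped mapping means indels are neither simulated nor called from the
  internal pileup; indel records are fully supported when ingested from
  external VCF/SAM, through normalization (left-alignment, multiallelic
  splitting), the filter grid, consensus insertion and evaluation.
* The caller's likelihood uses the plug-in AF and ignores mapping
  uncertainty; with the MQ >= 30 unique-placement filter upstream this is
  benign on mtDNA but would not transfer to repetitive nuclear targets.
* The contamination filter needs an externally supplied rate; a wrong
  input reproduces the false-discovery inflation seen in the benchmark's
  mis-specified runs, which is intended behaviour, not a defect.
* Inverted-repeat end artifacts (clipped automatically by some somatic
  callers) are neither generated nor specially handled.
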
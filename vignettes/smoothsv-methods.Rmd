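---
title: "Models and methods behind smoothsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smoothsv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoothsv)
library(dplyr)
```

smoothsv implements the downstream analysis of sparse single-cell long-read
whole-genome sequencing: libraries made by low-density, one-adaptor Tn5
tagmentation of a single cell's genome, amplified and sequenced as
high-fidelity circular-consensus (CCS/HiFi) reads with a fragment mode near
6 kb and a per-cell depth well below 1x. At that depth a single cell cannot
be genotyped conventionally; what long reads buy instead is direct,
single-read evidence for structural variants (SVs) and extrachromosomal
circular DNA (ecDNA), plus window-level copy number. This vignette explains
the models, the parameters that matter, and the choices made where the design
was genuinely open.

## The data model

All stages operate on tibbles. The central one is the segment-level alignment
table (one row per aligned segment of a read, primary or supplementary), with
0-based half-open coordinates everywhere inside the package; conversion to
1-based coordinates happens only at the SAM and VCF boundaries. Keeping a
single coordinate convention internally eliminates off-by-one drift between
modules; the property tests check that the VCF boundary conversion
round-trips exactly.

## ecDNA detection from chiastic reads

A circular template that receives exactly one Tn5 cut is linearized into a
molecule covering the full circle, starting at the cut. Mapped back to the
linear reference, such a read has exactly **two** aligned segments, on the
same chromosome and strand, whose order on the read is the reverse of their
order on the genome — a *chiastic* pair. The inferred circle runs from the
start of the read-later segment to the end of the read-earlier segment, and
the read length equals the circle length, so distinct copies of the same
circle yield reads of exactly the same length (a feature tandem repeats do
not share, recorded by `same_length_evidence()`).

The pipeline is fixed: detect, then filter, then merge; each stage only
removes or merges candidates.

1. `detect_chiastic_reads()`: exactly two segments, same chromosome and
   strand, chiastic order, at most 50 bp of unaligned read at the junction,
   at most 50 bp of genomic overlap between the segments. Minus-strand reads
   are normalized to genome orientation before the test (a reverse-complement
   read swaps the roles of the two segments). We allow up to `junction_tol`
   genomic overlap because circle-junction reads may carry a few doubly
   aligned bases; requiring strict disjointness would discard real evidence.
2. `filter_tandem_repeats()`: a junction breakpoint inside (or within 50 bp
   of) a tandem-repeat tract longer than 1 kb is unmappable evidence and the
   candidate is removed. Only the junction is tested, not the whole interval:
   a circle may legitimately contain a repeat internally; only a junction
   placed in a repeat is suspect.
3. `filter_duplications()`: a candidate whose two coordinates both lie within
   100 bp of a duplication call supported by at least 4 cells is removed —
   at that point the head-to-tail duplication interpretation wins. There is
   no general way to distinguish a circle junction from a tandem-duplication
   junction read by read; this consensus-based arbitration is the method's
   answer.
4. `merge_ecdna()`: single-linkage clustering of candidates whose junction
   coordinates agree within 50 bp; clusters must be supported by at least two
   distinct cells (one read in each of two cells suffices). Candidates on the
   mitochondrial contig — the natural positive control, being an abundant
   ~16.6 kb circle — are reported separately, never merged with nuclear
   candidates.

The duplication evidence consumed by stage 3 is extracted from the same
alignments (`extract_cell_svs()` then `merge_across_cells(min_cells = 4)`),
**without** a per-cell read-support floor: at a fraction of 1x coverage a
junction is rarely spanned twice in the same cell, so duplication evidence is
single-read by nature and its specificity comes from the 4-cell consensus
requirement instead. A chiastic pair whose segments extend beyond the
inferred junction span cannot come from a simple circle and is emitted as a
DUP call; a pair confined within the span is circle-shaped and left to the
ecDNA stage. This split keeps the two interpretations from feeding on the
same reads.

## Multi-cell SV consensus and benchmarking

Per-cell SV calls (from an external caller, or from the package's own
split-read/CIGAR extractor) pass three filters mirroring standard practice
for this data type: only calls whose FILTER is exactly PASS; at least 2
supporting reads per cell; for bulk call sets, at least 4 reads *and* a
supporting-read ratio strictly greater than 15%. Deletions and insertions
shorter than 100 bp are excluded before benchmarking (`filter_short_indels()`)
because small indel artifacts dominate that length range on long-read
platforms.

`merge_across_cells()` performs single-linkage clustering per SV type: two
calls link when **both** breakpoints lie within 1 kb (translocations: both
paired breakpoints within 50 kb, chromosome pair matching). Each cluster
becomes one consensus call at the member-median breakpoints with the union of
supporting cells; clusters below the cell floor (default 2) are dropped. We
require both breakpoint distances, not just one, and we interpret the
translocation rule as *both* breakpoints within 50 kb — the stricter of the
two available readings. Median consensus coordinates make the merge invariant
under permutation of the input cells; idempotence (re-merging the merged
output changes nothing) holds whenever distinct consensus calls stay farther
apart than the merge distance, which the tests enforce on separated clusters
— single-linkage can in principle chain two clusters whose medians drift
within range.

The rationale for multi-cell support: amplification and chimera artifacts
are private to the cell in which they arose, while genuine variants recur
across cells. The synthetic-data generator encodes exactly this mechanism
(spurious calls are private to single cells), which is why consensus
precision rises steeply from 1-cell to 2-cell support in the tests while
recall falls — the trade the method is designed around.

Benchmarking (`benchmark_svs()`) declares a test call a true positive when a
truth call of the same type has both breakpoints within 1 kb (50 kb for
translocations), with many-to-one matching allowed by default; FN counts
truth calls matched by no test call. The metric set is
precision = TP/(TP+FP), recall = TP/(TP+FN), FPR = FP/(TP+FP),
FNR = FN/(TP+FN), HM = 2·FPR·FNR/(FPR+FNR) and
F1 = 2·precision·recall/(precision+recall), with 0/0 denominators reported
as NA rather than silently zeroed, and HM defined as 0 when both rates are 0.
For comparisons against short-read call sets, `match_ngs_style()` uses the
reciprocal-overlap rule for deletions (both quotients strictly greater than
10%) and a ±1 kb breakpoint rule for insertions; the strict inequality
follows the wording of the underlying protocols. Insertions are compared by
position only — length agreement is deliberately not required, since the
distance-based matching convention this mirrors is position-based at
tolerance 1000.

`duplication_telomere_test()` maps each duplication to a relative position
r in [0,1) along its chromosome arm (0 at the centromere, 1 at the telomere),
pools all arms, bins r into 100 equal windows and tests the counts against
the uniform multinomial with a chi-square goodness-of-fit test
(df = 99). The underlying uniformity test is not otherwise pinned down; the
chi-square choice is calibrated in the acceptance suite (null p-values pass a
KS uniformity check) and has ample power against a 60%-telomeric-decile
alternative.

## CNV profiling

Reads are counted in fixed windows (default 1 Mb) by the leftmost reference
position of their primary segment — at 1 Mb windows and ~6 kb reads,
overlap-fraction assignment would change almost nothing and costs
determinism. Window ratios are scaled so that their mean over unmasked
windows equals the cell's nominal ploidy (3 for a triploid line, 2 for
diploid cells). Note the consequence: when part of the genome is genuinely
lost, forcing the mean to the nominal ploidy inflates every window by
ploidy/true-mean-copy; the planted-arm recovery tests keep the lost arm small
relative to the genome for this reason, and the same caveat applies to real
profiles.

The noise measure is the coefficient of variation of the per-window quotient
cell/baseline over unmasked windows — sample standard deviation (n−1) divided
by the mean. Whether the population or sample denominator was intended is not
stated by the conventions this follows; we use the sample form and say so
here. The same formula serves both baselines in use: the mean profile of all
cells, or a bulk profile. Windows overlapping an assembly-gap interval are
masked entirely and excluded from normalization, CV and correlation.

Segmentation is circular binary segmentation in its basic form: for each
chromosome, the arc (i, j] maximizing the two-sample t-statistic between the
arc and its complement is tested by permutation (default 1000 permutations,
alpha 0.01); an accepted split recurses into the pieces. Each recursion
node's permutation stream is seeded from the node's position alone, so the
p-value at a node is a pure function of its data — this makes the accepted
splits nested across alpha (lowering alpha can only remove splits) and the
whole fit reproducible. No pruning or undo heuristics are applied: the
package's target is planted-breakpoint recovery, not equivalence with any
particular production implementation. Profiles shorter than 3 windows return
a single segment. `profile_correlation()` computes Pearson r on per-window
segment means with gap windows removed pairwise.

## SNV benchmarking

Candidate SNVs present with an identical alternative allele in at least k
cells are compared against a bulk reference set keyed by (chromosome,
position, alt): matching position with a different alt is a false positive.
Detection efficiency is TP divided by the bulk set size and precision
TP/(TP+FP); the per-cell false-positive rate divides the cell's
non-bulk-backed calls by its covered bases. The spectrum classifier collapses
strand-complementary substitutions into the six base-pair classes (CG>TA,
CG>AT, CG>GC, TA>AT, TA>CG, TA>GC), so C>T and G>A land in the same class.

## The synthetic-data generator

`sim_config()` + `simulate_dataset()` emulate the data-generating process so
every stage is testable without deposited data. What is modeled:

- **Tn5 fragmentation** as a homogeneous Poisson process at rate
  1/`mean_fragment_bp` (default 1/6000); the description of the chemistry
  gives only a low-density insertion with a ~6 kb mode, and a memoryless cut
  model is the natural minimal choice. One-adaptor chemistry means *all*
  fragments are retained; fragments under 1 kb are dropped at the sequencing
  step (reads of this type are longer than 1 kb), not at fragmentation.
- **Sparse coverage**: fragments are sampled without replacement in random
  order until the per-cell target (default 0.4x) is reached, so attainable
  depth is bounded by ploidy x genome; requesting more is a config error, not
  silent resampling.
- **Planted variants**: each cell is `ploidy` haplotype copies per
  chromosome; a planted SV is applied to every haplotype of a carrier cell
  (carriers are a random `cell_fraction` subset, at least one cell).
  Homozygosity in carriers is a deliberate simplification — the subclonal
  structure the generator must express lives *across* cells, and homozygous
  events make read-support accounting predictable. Deletions and insertions
  inside a read become CIGAR D/I runs; duplication, inversion and
  translocation junctions become split alignments with the geometry forced by
  the rearrangement. Translocations are represented by a short fusion
  molecule (default ±50 kb around the junction) so they contribute junction
  reads without doubling the copy number of two half-chromosomes.
  Copy-number steps are realized as region presence/absence per haplotype
  (plus region-only molecules for gains), so they never fabricate deletion
  junction reads.
- **Circles**: per carrier cell, `copies` circular molecules; a circle with
  exactly one cut yields the full-length chiastic read, more cuts yield one
  wrap-junction fragment plus ordinary fragments.
- **Noise**: emitted per-cell call sets add Poisson(`fp_sv_per_cell`)
  spurious calls at uniform random loci, each private to one cell with
  support drawn from {1, 2}, and an optional IMPRECISE fraction. CCS errors
  are modeled as uniform substitutions only (when sequences are emitted at
  all); read accuracy near Q30 makes indel-error realism irrelevant to a
  pipeline that filters sub-100 bp indels anyway.
- **Reference**: i.i.d. uniform ACGT with explicitly planted tandem-repeat
  tracts (1.2–3 kb, density `repeat_per_mb`) and a centromere at 45% of each
  chromosome defining p/q arms. No attempt is made to mimic human base
  composition, GC structure, or mappability.

What the generator does *not* model — and hence what green tests do **not**
show about real data: alignment ambiguity in repetitive sequence, PCR
chimeras with non-private structure, coverage bias (GC, mappability,
amplification), genuine breadth/depth relationships (the generator exposes
depth as the control and makes no claim about breadth), heterozygosity, and
indel sequencing errors. The per-read geometry is exact by construction, so
recovery tests certify the downstream logic, not the mapper.

By default reads are emitted with `SEQ="*"` in SAM (`emit_sequences = FALSE`):
every downstream stage consumes alignment geometry only, and substitution
errors at the modeled 0.1% rate do not perturb that geometry. Sequences are
generated on request for spectrum work and fixture realism.

## Problem sizes used by the tests and the acceptance script

The packaged experiments run at desk scale, chosen once as a faithful
miniature of the study conditions: 30 cells at 0.4x with ~6 kb fragments
throughout; a 60 Mb genome (3 x 20 Mb) for ecDNA recovery with 20 circles of
5–200 kb at 2 copies per cell; the same genome for the confounder experiment
(10 head-to-tail duplications, 20 repeat-junction artifacts, 5 true
circles); and a 500 Mb genome (3 x 167 Mb) with 500 planted SVs and 50
private false calls per cell for the consensus experiment. The larger genome
for the consensus run matters: chance collisions between private false calls
scale with calls²/genome, and 1500 private calls on a toy 60 Mb genome would
collide at a rate no real genome exhibits, making the experiment
unrepresentative rather than merely small. SV density (~1/Mb) is of the same
order as deep bulk long-read call sets. CNV experiments use a 100 Mb diploid
or triploid genome with a 15 Mb arm at one copy less — kept deliberately
small relative to the genome because of the normalization bias described
above. The placement-statistic calibration uses 200 replicates of 500
duplications.

## Numerical conventions and degenerate inputs

- 0/0 metric denominators yield NA, surfaced in the report; HM and F1 are 0
  when their component rates are all 0.
- Consensus coordinates are rounded medians; ties in single-linkage
  clustering are irrelevant because linkage is a symmetric predicate.
- An all-zero profile cannot be normalized (error), CV needs at least 2
  unmasked windows, and correlation of a zero-variance segmented profile is
  an error rather than NA.
- `same_length_evidence()` groups read lengths greedily around successive
  modes with a ±20 bp tolerance; a candidate with no full-length reads keeps
  junction-only status (NA annotation).
- The simulator drops a circle copy that receives zero cuts (no adaptor, no
  amplification) — such copies are invisible to sequencing, which is faithful
  to the chemistry.

## Known limitations

Circles longer than a read are detectable only through their junction, and
nothing in the method distinguishes them from large tandem duplications
beyond the ±100 bp duplication-consensus filter; candidates with complex
multi-segment structure are out of scope (the detector requires exactly two
segments). The consensus merge can in principle chain distinct events through
intermediate calls (single linkage); the CBS implementation has no
edge-effect corrections or undo step; and the SNV layer benchmarks call sets
— it does not model calling from reads.
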
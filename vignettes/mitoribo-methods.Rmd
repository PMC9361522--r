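---
title: "Methods: mitoribosome profiling analysis in mitoribo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitoribosome profiling analysis in mitoribo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and design choices behind
the package. It is the reference for *why* each stage works the way it does;
the README shows *how* to run it.

## Coordinate and strand conventions

All internal coordinates are 0-based, half-open; GFF3 I/O converts to and
from 1-based closed coordinates. The mitochondrial genome is circular with a
single linearization origin: every windowed computation takes positions
modulo the genome length. The heavy strand is `+`, the light strand `-`, and
light-strand features are first class — tracks are kept per strand, and the
"biological" coordinate of a position on the light strand is `L - 1 - p`, so
that 5'→3' arithmetic is identical on both strands. A read's biological
3' end is its rightmost aligned base on `+` and its leftmost on `-`.

ORF scanning uses the vertebrate mitochondrial code (AUA = Met, UGA = Trp).
AGA and AGG are treated as termination codons by default: both appear once
in a mammalian mitochondrial genome at the ends of ORFs, and ribosomes
accumulate there whether termination is direct or preceded by a −1
frameshift to UAG. Because the frameshift mechanism is out of scope, the
terminator reading is the default and `agag_stop = FALSE` restores the
arginine reading; no coordinate arithmetic depends on the choice.

## Read processing

PCR duplicates are collapsed on the key (genome, start, end, strand, UMI);
since read length is determined by the alignment span, keying on both ends
is equivalent to start + length. The retained set depends only on key
equality, so it is independent of input order.

Soft clips are dropped from the read length and end coordinates at ingest,
with one exception: a 3'-side clip consisting entirely of A (after
reverse-complementing for light-strand reads) is re-appended to the length
and the 3' end, because mitochondrial mRNAs are polyadenylated and such
clips are part of the molecule's 3' end, which the offset calibration
anchors on. The all-A rule is strict by default; `polyA_rule = "majority"`
relaxes it. The spike-in normalization factor is the number of deduplicated
reads longer than 20 nt overlapping the spike genome's mRNA CDSs.

## A-site offset calibration

Footprints of 30–34 nt are calibrated; shorter reads have ambiguous offsets
because neither end is held fixed at a given ribosome position, and they are
excluded from A-site transformation (initiation half-footprints are analyzed
separately from raw reads). The offset for length `l` is the signed value
`o(l)` such that `3' end + o(l)` is the **middle base** of the A-site codon.
The middle-base convention is used everywhere — it matches the scoring
module, which assigns A-site reads on a codon's second position to that
codon's frame reference. Calibration is two-step:

1. **Anchor.** For the modal read length, reads near the start codons of the
   anchor genes (mRNAs with leaders of at least `min_leader = 10` nt, where
   initiating footprints are full length and unclamped) pile at a single
   3'-end position; the offset is set so that peak maps the A site to the
   middle base of codon 2, i.e. the P site to the start codon.
2. **Per-length refinement.** For every other length, the modal subcodon
   class of in-CDS 3' ends fixes the offset modulo 3; among candidates the
   one nearest the anchor offset is chosen, then the smaller magnitude.
   Lengths with fewer than `min_reads = 50` reads, or whose top two subcodon
   bins differ by less than 10% relative (`clarity = 0.1`), are excluded
   with a warning rather than guessed.

This recovers generator offsets exactly in the test suite both noise-free
and at 20% positional noise, and shifting all true offsets by +1 shifts all
recovered offsets by +1.

## Codon occupancy and pausing

Relative occupancy of a codon is its 3-nt A-site density divided by the
overall CDS density, so the length-weighted mean over a covered CDS is
exactly 1. Pause tables average occupancy per codon identity (termination
codons included; single-occurrence identities are flagged) and flag
identities above 3× expected. Replicates aggregate by the mean with a
min–max range rather than a standard deviation, since two or three
replicates support a range, not a dispersion estimate.

Because occupancy is normalized within each CDS, an injected dwell
multiplier is *not* recovered as the raw mean occupancy: the per-CDS average
itself rises with the pause, and initiation-derived A sites add to the
denominator. The multiplier estimator used in the tests and the acceptance
script is therefore the identity's mean occupancy divided by the
genome-wide **median** codon occupancy, which cancels both distortions.

## Initiation analysis

Start-codon-aligned end profiles bin raw read 5' and 3' ends (lengths
15–40) within ±40 nt of a start codon. A read enters the profile only when
both ends fall in the window, making the 5'- and 3'-end matrices sum to the
same total. On leaderless and short-leader messages the profile shows 5'
ends clamped at the message start with 3' ends forming a length diagonal —
the 15-nt half-footprints growing to full length as the mRNA channel fills.

At the bicistronic processing junction, RNA-level fractions are estimated
from informative RNA-seq reads only: 5' end exactly at the downstream
message start (processed) versus spanning the junction with at least
`k = 1` nt on each side (unprocessed); `k` is configurable because the
required overhang is a judgment call. Initiation-level counts are: 5' end
exactly at the start codon (initiation on the processed, leaderless
message) versus an inferred P site on the start codon — middle base
`3' end + offset − 3` within the start codon's three positions, i.e. the
calibrated position ±1 nt of jitter — with the 5' end upstream of the start
(initiation on the precursor, footprint spanning the junction). The
fold-preference `(init_u/init_p)/(rna_u/rna_p)` is invariant to uniform
depth scaling. Elongating ribosomes one codon past initiation satisfy the
unprocessed signature and initiation-adjacent elongation can place 5' ends
at the start; the two contaminations enter numerator and denominator
similarly and largely cancel in the ratio, which is why the recovery
tolerance is set at the sampling scale (±15% at 10^5 reads) rather than
tighter.

The read-through index is a derived metric (no published formula exists for
the quantity): in-frame A-site density over the 3' UTR in the CDS reading
frame, excluding the stop codon, divided by the in-frame CDS density with
the stop likewise excluded; it requires at least 5 in-frame UTR codons.

## Start-codon scoring

Every AUG, AUA, AUU, and GUG on the heavy strand is scored as the sum of
three parts computed from A-site counts with pseudocount 1 (the data contain
many zero codons, and the pseudocount gives a clean null):

- **part 1** — P-site pausing: with `N(x)` the in-frame (middle-base) count
  of codon `x` and `c` the candidate, `(N(c+1)+1)/(N(c)+1) +
  (N(c+1)+1)/(N(c+2)+1)`. The comparison codons are read as the immediate
  neighbors of the P-site signal (the candidate codon itself and two codons
  downstream); this reading makes part 1 equal exactly 2 on uniform
  coverage, a clean null.
- **part 2** — in-frame gain: pooled in-frame percentage over codons
  `c+1..c+20` minus the pooled percentage over `c−16..c−1`; windows with
  zero total contribute 0. Pooling (rather than per-codon means) is robust
  at low coverage. Downstream windows start at `c+1` and upstream at `c−1`;
  the inclusive/exclusive choice at the boundary is configurable.
- **part 3** — occupancy gain: `2·log2` of total reads (all frames) over
  codons `c+1..c+5` versus `c−5..c−1`, candidate codon excluded from both
  windows. The log base is 2; doubling keeps the part commensurate with the
  others.

Candidates in frame within known ORFs are marked `excluded_in_frame` and
never enter histograms; candidates inside rRNA/tRNA genes are dropped
(profiling data are rRNA/tRNA-filtered, so those positions have no
meaningful signal); the light strand is not scored by default but can be
requested. Known starts are labeled by leader class (none / 1–3 nt / long
5' UTR). An independent brute-force implementation of the formula is kept
in the test suite and must agree to 1e−9. No statistical calibration (FDR)
is attached to scores: the inference is comparison with the known-start
distribution.

## Relative synthesis and mitonuclear balance

Counting follows shifted-end assignment: mitochondrial footprints count at
their 3' end shifted 14 nt upstream; cytosolic footprints at their 5' end
shifted 17 nt downstream; RNA-seq fragments by unstranded CDS overlap of at
least 22 nt. The mitochondrial mask removes the first 6 codons of every gene
(leader-dependent and initiation-footprint-distorted) and all pairwise CDS
overlaps; the RNA mask removes overlaps only; the nuclear mask is empty by
default. RPK uses the unmasked CDS length. Mitochondrial relative synthesis
is RPK over the mitochondrial protein-coding RPK sum × 10,000 (tpm/100,
summing to 10,000 exactly); nuclear values are tpm over the supplied gene
universe. The two compartments carry distinct unit tags and are never
compared in absolute terms. Paralog families (interchangeable isoforms) sum
their tpm values into one row. Multimapping is an aligner concern: the
package counts the alignments it is given.

Complex summaries are arithmetic means over subunits, with an optional
core-subunit filter for the nuclear side (the core set is data, not code:
callers pass the gene list). The balance statistic is Pearson's r over
per-complex (mito average, nuclear average) pairs, at least 3 complexes,
computed on the linear scale by default with a log10 option — figure axes
in this field are usually log-scaled and r differs between the two, so the
scale is an explicit argument rather than a hidden default. Stoichiometry
rescales complex averages so a reference complex (Complex III by
convention) equals 3. The within-complex spread statistic is each subunit's
log2 difference from its complex median and the fraction within 2-fold.

## Start-codon SNV conservation

The background set for conservation ranking is every ATG (either strand)
antisense to known-ORF codons in the same phase as the dORF-style geometry:
covering positions 2–3 of a sense codon and position 1 of the next. This
equalizes the protein-coding constraint acting on the compared sites. Each
SNV at a site is applied to the codon; ATT, ATA, and GTG count as
conservative alternative starts, ACG is tallied separately (initiation-
capable in vitro but not observed in vivo), everything else as
non-conservative. Sites need at least 2 SNVs. Variants are weighted one SNV
type per observation by default, with a carrier-count mode; the conservation
rank uses a strict inequality (ties count against the target), the
conservative choice for a "smaller fraction" claim — both choices are
exposed because the descriptive statistic is sensitive to them.

## The synthetic-data generator

The generator is the package's ground truth, and its defaults are the study
conditions the estimators are tested under: 30–34-nt footprints distributed
(10/35/30/15/10)% with 3'-end offsets −13/−14/−15/−15/−15; 80% of A sites
on the true codon middle (the remainder split ±1 nt); 8% initiation
footprints; a junction with unprocessed fraction 0.3 and initiation
fold-preference 4; a 4-codon dORF at offset 10 in a 60-nt 3' UTR with its
stop (like every UTR-bearing stop in the toy) followed by C; read-through
probability 0.1 with geometric continuation 0.5 per codon; a 5% spike-in
fraction; 10-nt UMIs; and a variant catalog whose target ATG receives 255
carriers at conservative bias 219/255 with 35/36 of the non-conservative
remainder yielding ACG — the carrier structure reported for the
population catalog this emulates.

Structural choices worth noting:

- Ten genes spanning leader classes (leaderless, 1–3 nt, three long-UTR
  anchors), one light-strand gene, tRNA spacers between messages, and one
  rRNA region; all non-coding sequence is drawn from {C,G,T} so that start
  triplets containing A cannot arise outside coding regions (GTG still can,
  providing zero-coverage baseline candidates).
- The junction pair abuts with a 2-nt 3' UTR on the upstream gene so the two
  ORFs are in different reading frames, as in the real bicistronic locus;
  in-frame neighbors would make the downstream start's in-frame-gain score
  component vanish by construction, which is not the geometry being modeled.
- Initiation footprints on messages with enough upstream sequence (long
  leaders, the unprocessed precursor, the dORF within its host's UTR) are
  full length with the P site on the start codon; on leaderless and
  short-leader messages they are clamped at the message start and ramp from
  15 nt to full length (uniform length weights — the per-length dwell of the
  ramp is unquantified, so it is a free knob, not an estimate). A
  consequence: only the 30–34-nt tail of the clamped ramp survives A-site
  transformation, so initiation-proximal signal is captured more completely
  for UTR-class genes than for leaderless ones, and initiation-window
  comparisons should be made within a leader class.
- Elongation dwell is uniform across codons except for configured pause
  multipliers and geometric read-through extensions, so a gene's RPK is
  proportional to its expression weight — the truth against which synthesis
  recovery is tested.
- RNA-seq molecules are fragmented completely into consecutive 30–70-nt
  pieces (sub-30 remainders lost to size selection), so each processed
  downstream-gene molecule yields exactly one fragment starting at the
  processing site and each precursor molecule exactly one junction-spanning
  fragment — the property that makes the informative-read fractions estimate
  the molecular unprocessed fraction. A precursor cut exactly at the
  junction (probability ≈ 1/40 per molecule) is counted as processed, a
  small conservative bias also present in real data.
- PCR duplicates are Poisson-distributed fresh copies sharing UMI and
  coordinates; the truth records the exact number of distinct
  (coordinates, UMI) keys, so deduplication is tested exactly even in the
  presence of rare UMI collisions.
- Optional ±1 nt digestion jitter on both ends (off by default) reproduces
  the V-shaped initiation profiles of over/under-digested footprints.

What the generator does **not** model: sequencing errors and quality
scores, rRNA/tRNA contamination, NUMT-like multimapping, processing
kinetics of the polycistronic precursor beyond a single junction, ribosome
drop-off, and tRNA-protected fragments (test comparisons construct those
directly). Passing the suite therefore demonstrates correctness of the
estimators under the stated generative model, not robustness to every
artifact of real libraries.

## Problem sizes and tolerances

The test suite runs the shared study at 2×10^5 footprints and individual
recoveries at 10^4–10^6, chosen so that each stochastic tolerance sits at
roughly 3σ of its sampling error: exact recovery for offsets and the
10,000-sum identity (tolerance 1e−6), 10% for pause multipliers at 10^6
reads, 15% for the junction fold-preference at 10^5, 0.05 for the balance
correlation at 10^6 per compartment, binomial 3σ bounds for spike-in and
variant-bias recovery, and 1e−9 agreement with the brute-force scoring
oracle. The acceptance script simulates at 5×10^5 footprints.

## Known limitations

- Offset calibration assumes at least one anchor-class gene with clean
  initiation peaks; genomes without long-leader mRNAs need `anchor_genes`
  supplied explicitly.
- Occupancy, scoring, and read-through all condition on the calibrated
  middle-base convention; data calibrated to a different base convention
  must be re-transformed, not reinterpreted.
- The scoring module reports raw scores without a significance model, by
  design; users should compare candidates against the known-start
  distribution as the figures do.
- Nuclear counting treats each gene as one contiguous CDS interval list per
  gene; spliced isoform structure beyond that is out of scope.
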
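# mitoribo

Analysis of human-style **mitoribosome profiling** (Ribo-seq of the
mitochondrial ribosome) from aligned footprint reads onward. The 13
mtDNA-encoded OXPHOS core subunits are translated by mitoribosomes on mostly
leaderless mRNAs excised from two polycistronic transcripts; mitoribosome
footprints are 31–34 nt with 15-nt "half footprints" during initiation. This
package turns aligned footprint and RNA-seq reads into the quantities that
describe that biology:

- **Read processing** — UMI-based PCR-duplicate collapsing, length filtering,
  soft-clip handling (3′ poly(A) tails are retained), and the spike-in
  normalization factor from reads of a second genome.
- **A-site calibration** — per-read-length signed offsets from the 3′ end to
  the A-site codon (e.g. 31 nt → −14), anchored on the initiation peaks of
  the genes with real 5′ UTRs and refined per length from the modal subcodon
  position of 3′ ends; A-site tracks and triplet-periodicity QC.
- **Translation features** — relative codon occupancy
  `occ(c) = (counts in codon c / 3) / (CDS counts / CDS length)` and
  per-codon-identity pause tables; start-codon-aligned footprint-end
  profiles that reveal the 15-nt → full-length initiation ramp on leaderless
  messages; quantification of translation initiation on processed vs
  unprocessed bicistronic transcripts, summarized as a fold-preference
  `(init_u/init_p) / (rna_u/rna_p)`; stop-codon read-through indices; and
  read-length KS comparisons for candidate ORF support.
- **Start-codon scoring** — an additive three-part initiation score for every
  AUG/AUA/AUU/GUG on the heavy strand: P-site pause fold-change (inferred
  from A-site counts one codon downstream), in-frame percent gain (20 codons
  downstream vs 16 upstream), and doubled log2 occupancy gain (5 codons
  downstream vs upstream). Known starts score high regardless of leader
  class; candidate small ORFs (a 4-codon dORF in a 3′ UTR) are nominated by
  scoring among them.
- **Synthesis balance** — featureCounts-style shifted-end counting with the
  first 6 codons and all CDS overlaps masked; relative synthesis as tpm/100
  (mitochondrial values sum to 10,000) and tpm (nuclear); paralog-family
  summing; per-complex averages, Pearson correlation of mitochondrial vs
  cytosolic complex averages (mitonuclear balance), synthesis stoichiometry
  relative to Complex III = 3, and within-complex 2-fold spread.
- **SNV conservation** — classification of population variants at start
  codons (ATT/ATA/GTG are conservative alternative starts, ACG is tallied
  separately), restricted to ATGs antisense to known-ORF codons in the same
  phase as the dORF's start, and a conservation rank of a target ATG against
  that background.
- **Synthetic data** — a first-class generator producing toy circular
  genomes, annotations (GFF3), aligned reads (SAM), and variant catalogs
  with serialized ground truth, so every estimator above is tested against
  known generating parameters.

## Worked example

```r
library(mitoribo)

cfg   <- sim_config(seed = 7, depth = 2e5)   # default study conditions
study <- simulate_study(cfg)                 # genome + reads + variants

reads    <- dedup_umi(study$footprints$reads)
fp30_34  <- filter_lengths(reads, 30, 34)
offsets  <- calibrate_offsets(fp30_34, study$sim$genome, study$sim$annotation)
offsets
#>   length offset
#> 1     30    -13
#> 2     31    -14
#> 3     32    -15
#> 4     33    -15
#> 5     34    -15

track <- asite_transform(fp30_34, offsets, study$sim$genome)
round(periodicity_report(track, study$sim$annotation, study$sim$genome)$percent, 1)
#> pos1 pos2 pos3
#>  9.8 80.4  9.8

rna  <- junction_rna_fractions(study$rnaseq$reads, study$sim$annotation)
init <- junction_initiation(reads, study$sim$annotation, study$sim$genome,
                            offsets, rna)
sprintf("unprocessed RNA: %.1f%%; initiation fold-preference: %.2f",
        100 * rna$unprocessed_frac, init$fold_preference)
#> "unprocessed RNA: 30.8%; initiation fold-preference: 3.86"

first_start_in_utr3(study$sim$genome, study$sim$annotation, "mtg07")
#> <mt_orf> 3210 strand +: 4 codons, ATG..TAA, peptide MPTS
```

The calibrated offsets recover the generator's truth exactly; 80% of A sites
fall on codon middle positions (the configured periodicity); RNA-level
unprocessed fraction (30%) and the 4-fold initiation preference for the
unprocessed junction transcript are recovered; and the 3′-UTR scan finds the
injected 4-codon downstream ORF.

`run_pipeline(study, out_dir = "out")` chains all stages and writes TSV,
bedGraph, and JSON outputs.

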
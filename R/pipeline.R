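# End-to-end orchestration over the module functions.

#' Simulate a complete study (genome, footprints, RNA-seq, variants)
#'
#' Convenience wrapper around the synthetic-data generators. When \code{dir}
#' is given, all inputs are also serialized to standard formats (FASTA, GFF3,
#' SAM, TSV, truth JSON).
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Optional output directory.
#' @return list(sim, footprints, rnaseq, variants) where \code{sim} holds the
#'   genomes/annotations and each data element carries its truth record.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  sim <- make_toy_genome(config)
  fp <- simulate_footprints(sim, config)
  rna <- simulate_rnaseq(sim, config)
  var <- simulate_variant_catalog(sim, config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(list(sim$genome, sim$spike_genome),
                       file.path(dir, "genomes.fasta"))
    write_annotation_gff3(sim$annotation, file.path(dir, "annotation.gff3"),
                          seqid = sim$genome$id)
    write_junctions(sim$annotation$junctions, file.path(dir, "junctions.tsv"))
    write_sam(fp$reads, list(sim$genome, sim$spike_genome),
              file.path(dir, "footprints.sam"))
    write_sam(rna$reads, list(sim$genome), file.path(dir, "rnaseq.sam"))
    utils::write.table(var$variants, file.path(dir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(footprints = fp$truth, rnaseq = rna$truth, variants = var$truth),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  list(sim = sim, footprints = fp, rnaseq = rna, variants = var,
       config = config)
}

#' Run the full analysis pipeline on a simulated or ingested study
#'
#' Executes the stages in dependency order: UMI deduplication, spike-in
#' factor, length filtering, A-site offset calibration and transformation,
#' periodicity QC, codon occupancy and pause table, junction RNA/initiation
#' analysis, genome-wide start-codon scoring, relative synthesis, and
#' start-codon SNV conservation. Results (and TSV outputs when
#' \code{out_dir} is given) are returned in a manifest list.
#'
#' @param study Output of \code{\link{simulate_study}}, or a compatible list
#'   with elements \code{sim} (genome, annotation, spike_genome,
#'   spike_annotation), \code{footprints$reads}, \code{rnaseq$reads},
#'   \code{variants$variants}.
#' @param out_dir Optional directory for TSV/bedGraph outputs.
#' @param synthesis_genes Genes quantified for relative synthesis (default:
#'   all CDS genes except the dORF).
#' @return Manifest list with one element per stage.
#' @export
run_pipeline <- function(study, out_dir = NULL, synthesis_genes = NULL) {
  sim <- study$sim
  genome <- sim$genome
  ann <- sim$annotation

  reads <- dedup_umi(study$footprints$reads)
  spike_n <- spike_in_factor(reads, sim$spike_annotation,
                             sim$spike_genome$id)
  flt <- filter_lengths(reads, 30L, 34L)
  offsets <- calibrate_offsets(flt, genome, ann)
  track <- asite_transform(flt, offsets, genome)
  period <- periodicity_report(track, ann, genome, reads = flt)

  occ <- codon_occupancy(track, ann, genome)
  pauses <- pause_table(occ)

  rna_frac <- junction_rna_fractions(study$rnaseq$reads, ann)
  jx_init <- junction_initiation(reads, ann, genome, offsets, rna_frac)

  scores <- score_genome(track, genome, ann)

  synthesis_genes <- synthesis_genes %||%
    grep("\\.dorf$", gene_ids(ann, "CDS"), value = TRUE, invert = TRUE)
  counts <- count_gene(reads, ann, genome, mito_footprint_spec(),
                       genes = synthesis_genes)
  synth <- relative_values(counts, "mito")

  sites <- find_phase_matched_atgs(genome, ann)
  snv <- NULL
  if (nrow(sites) && nrow(study$variants$variants)) {
    snv <- classify_all_atgs(sites, study$variants$variants, genome)
  }

  manifest <- list(
    n_reads_in = nrow(study$footprints$reads),
    n_reads_dedup = nrow(reads),
    spike_in_factor = spike_n,
    offsets = offsets,
    periodicity = period,
    pause_table = pauses,
    junction_rna = rna_frac,
    junction_initiation = jx_init,
    start_scores = scores,
    synthesis = synth,
    snv_sites = snv
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_offsets(offsets, file.path(out_dir, "offsets.tsv"))
    write_track_bedgraph(track, file.path(out_dir, "asite"))
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(occ, "codon_occupancy.tsv")
    wt(pauses, "pause_table.tsv")
    wt(scores, "start_scores.tsv")
    wt(as.data.frame(synth), "synthesis.tsv")
    if (!is.null(snv)) wt(snv, "snv_sites.tsv")
    jsonlite::write_json(
      manifest[c("n_reads_in", "n_reads_dedup", "spike_in_factor")],
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE
    )
  }
  manifest
}
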
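# Read-level processing: UMI deduplication, length filtering, spike-in factor.

#' Collapse PCR duplicates by UMI and alignment coordinates
#'
#' Exactly one read is retained per (genome, start, end, strand, UMI) key; the
#' retained set is independent of input order. Reads without UMIs pass
#' through unchanged with a warning.
#'
#' @param reads data.table with \code{genome_id}, \code{start}, \code{end},
#'   \code{strand}, and a \code{umi} column.
#' @return Deduplicated data.table (same columns).
#' @export
dedup_umi <- function(reads) {
  reads <- data.table::as.data.table(reads)
  if (is.null(reads$umi) || all(is.na(reads$umi))) {
    warnf("no UMIs present; returning reads unchanged")
    return(reads)
  }
  keys <- c("genome_id", "start", "end", "strand", "umi")
  out <- data.table::copy(reads)
  data.table::setorderv(out, keys)
  unique(out, by = keys)
}

#' Filter reads by length
#'
#' Footprint lengths below the calibrated range have ambiguous offsets and are
#' excluded before A-site transformation.
#'
#' @param reads Read table with a \code{length} column.
#' @param min,max Inclusive length bounds.
#' @return Filtered read table.
#' @export
filter_lengths <- function(reads, min = 30L, max = 34L) {
  if (min > max) stopf("min > max")
  reads <- data.table::as.data.table(reads)
  reads[reads$length >= min & reads$length <= max]
}

#' Spike-in normalization factor
#'
#' Number of deduplicated reads longer than 20 nt mapping to the spike
#' genome's mRNA coding sequences; used as an absolute normalization factor
#' for global shifts in mitochondrial translation.
#'
#' @param reads Read table (deduplicated beforehand or here: dedup is applied
#'   when UMIs are present, and is idempotent).
#' @param spike_annotation \code{mt_annotation} of the spike genome.
#' @param spike_genome_id Contig id of the spike genome.
#' @param min_len Minimum read length, exclusive bound 20 nt by default.
#' @return Integer count (0 with a warning when no spike reads are found).
#' @export
spike_in_factor <- function(reads, spike_annotation, spike_genome_id,
                            min_len = 21L) {
  reads <- data.table::as.data.table(reads)
  if (!is.null(reads$umi) && !all(is.na(reads$umi)))
    reads <- dedup_umi(reads)
  sp <- reads[reads$genome_id == spike_genome_id & reads$length >= min_len]
  if (!nrow(sp)) {
    warnf("no spike-in reads found; factor is 0")
    return(0L)
  }
  cds <- ann_features(spike_annotation, "CDS")
  hit <- rep(FALSE, nrow(sp))
  for (i in seq_len(nrow(cds))) {
    hit <- hit | (sp$start < cds$end[i] & sp$end > cds$start[i] &
                  sp$strand == cds$strand[i])
  }
  sum(hit)
}
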
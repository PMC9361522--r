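# Codon-level occupancy, initiation profiles, junction initiation,
# read-through and dORF-support statistics.

track_counts_at <- function(track, genomic, strand) {
  v <- if (strand == "+") track$plus else track$minus
  v[wrap_pos(genomic, track$length, track$circular) + 1L]
}

#' Relative codon occupancy along a CDS
#'
#' Occupancy of a codon is the A-site density in its 3-nt window divided by
#' the overall density of the coding sequence, so the length-weighted mean
#' over a covered CDS is 1. Zero-count CDSs yield NA occupancies and are
#' flagged.
#'
#' @param track An \code{asite_track}.
#' @param annotation An \code{mt_annotation}.
#' @param genome The matching \code{mt_genome}.
#' @param genes Gene ids (default: all CDS genes).
#' @return data.table(gene_id, codon_index, codon, counts, occupancy) with
#'   attribute \code{zero_genes}.
#' @export
codon_occupancy <- function(track, annotation, genome, genes = NULL) {
  genes <- genes %||% gene_ids(annotation, "CDS")
  out <- list()
  zero <- character(0)
  for (g in genes) {
    pos <- feature_positions(annotation, g, "CDS")
    strand <- gene_strand(annotation, g)
    cnt <- track_counts_at(track, pos, strand)
    n <- length(pos) %/% 3L
    csum <- colSums(matrix(cnt, nrow = 3L))
    total <- sum(csum)
    base_chars <- genome$bases[wrap_pos(pos, genome$length, TRUE) + 1L]
    if (strand == "-") base_chars <- comp_base(base_chars)
    trip <- apply(matrix(base_chars, nrow = 3L), 2L, paste, collapse = "")
    occ <- if (total == 0) {
      zero <- c(zero, g)
      rep(NA_real_, n)
    } else {
      (csum / 3) / (total / length(pos))
    }
    out[[g]] <- data.table::data.table(
      gene_id = g, codon_index = seq_len(n), codon = trip,
      counts = csum, occupancy = occ
    )
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "zero_genes", zero)
  res
}

#' Mean occupancy per codon identity, with pause flags
#'
#' Averages relative occupancy over all instances of each of the 64 codon
#' identities (termination codons included; identities present only once,
#' like the single AGA/AGG putative stops, are flagged). Replicates may be
#' supplied as a list; they are aggregated by mean with min-max range.
#'
#' @param occ A \code{\link{codon_occupancy}} table, or a list of them
#'   (replicates).
#' @param threshold Flag identities whose mean exceeds this multiple of the
#'   expected occupancy 1 (default 3).
#' @return data.table(codon, mean_occupancy, min, max, n_instances,
#'   single_instance, flagged).
#' @export
pause_table <- function(occ, threshold = 3) {
  if (data.table::is.data.table(occ) || is.data.frame(occ)) occ <- list(occ)
  per_rep <- lapply(occ, function(tab) {
    tab <- data.table::as.data.table(tab)
    tab <- tab[!is.na(tab$occupancy)]
    tab[, list(mean_occ = mean(occupancy), n = .N), by = "codon"]
  })
  codons <- sort(unique(unlist(lapply(per_rep, `[[`, "codon"))))
  m <- sapply(per_rep, function(r) r$mean_occ[match(codons, r$codon)])
  m <- matrix(m, nrow = length(codons))
  inst <- per_rep[[1]]$n[match(codons, per_rep[[1]]$codon)]
  res <- data.table::data.table(
    codon = codons,
    mean_occupancy = rowMeans(m, na.rm = TRUE),
    min = apply(m, 1L, min, na.rm = TRUE),
    max = apply(m, 1L, max, na.rm = TRUE),
    n_instances = inst
  )
  res[, "single_instance" := res$n_instances == 1L]
  res[, "flagged" := res$mean_occupancy > threshold]
  res
}

#' Start-codon-aligned footprint end profile
#'
#' Counts of raw (unfiltered; initiation half-footprints of 15-29 nt must
#' still be present) read 5' and 3' ends near a gene's start codon,
#' stratified by read length. A read enters both matrices when both of its
#' ends fall inside the window, so the two matrices have equal totals.
#'
#' @param reads Read table (not length-filtered).
#' @param annotation,genome Annotation and genome.
#' @param gene_id Gene whose start codon anchors the profile.
#' @param window Half-window in nt (default 40).
#' @param lengths Read lengths retained (default 15-40).
#' @return list(end5, end3: length-by-position count matrices; n).
#' @export
initiation_profile <- function(reads, annotation, genome, gene_id,
                               window = 40L, lengths = 15:40) {
  if (!gene_id %in% gene_ids(annotation, "CDS")) stopf("unknown gene %s", gene_id)
  s_bio <- cds_start_bio(annotation, genome, gene_id)
  strand <- gene_strand(annotation, gene_id)
  reads <- data.table::as.data.table(reads)
  reads <- reads[reads$genome_id == genome$id & reads$strand == strand &
                 reads$length %in% lengths]
  rel5 <- bio_pos(genome, read_end5_genomic(reads), strand) - s_bio
  rel3 <- bio_pos(genome, read_end3_genomic(reads), strand) - s_bio
  keep <- abs(rel5) <= window & abs(rel3) <= window
  reads <- reads[keep]; rel5 <- rel5[keep]; rel3 <- rel3[keep]
  posn <- seq.int(-window, window)
  mk <- function(rel) {
    m <- matrix(0L, nrow = length(lengths), ncol = length(posn),
                dimnames = list(lengths, posn))
    if (nrow(reads)) {
      t2 <- table(factor(reads$length, levels = lengths),
                  factor(rel, levels = posn))
      m[] <- as.integer(t2)
    }
    m
  }
  list(end5 = mk(rel5), end3 = mk(rel3), n = nrow(reads))
}

junction_info <- function(annotation, junction) {
  jx <- annotation$junctions
  row <- jx[jx$name == junction | jx$position == suppressWarnings(
    as.integer(junction))[1], , drop = FALSE]
  if (!nrow(row)) stopf("junction %s not annotated", junction)
  mr <- ann_features(annotation, "mRNA")
  dn <- mr[mr$start == row$position[1] & mr$strand == "+", ]
  strand <- if (nrow(dn)) "+" else "-"
  list(name = row$name[1], position = row$position[1], strand = strand)
}

#' Processed / unprocessed transcript fractions at a junction
#'
#' RNA-seq reads with their 5' end precisely at the downstream message start
#' come from processed transcripts; reads spanning the junction with at least
#' \code{k} nt on each side come from the unprocessed precursor. Fractions
#' are over these informative reads only.
#'
#' @param rna_reads RNA-seq read table.
#' @param annotation Annotation holding the junction.
#' @param junction Junction name (or position).
#' @param k Minimum overhang on each side for a spanning read (default 1).
#' @return list(processed_frac, unprocessed_frac, n_at_start, n_spanning,
#'   n_informative, defined).
#' @export
junction_rna_fractions <- function(rna_reads, annotation, junction = NULL, k = 1L) {
  junction <- junction %||% annotation$junctions$name[1]
  jx <- junction_info(annotation, junction)
  j <- jx$position
  r <- data.table::as.data.table(rna_reads)
  r <- r[r$strand == jx$strand]
  p5 <- read_end5_genomic(r)
  at_start <- p5 == j
  spanning <- if (jx$strand == "+") r$start <= j - k & r$end >= j + k
              else r$end >= j + k & r$start <= j - k
  spanning <- spanning & !at_start
  n1 <- sum(at_start); n2 <- sum(spanning)
  if (n1 + n2 == 0L) {
    warnf("no informative reads at junction %s", jx$name)
    return(list(processed_frac = NA_real_, unprocessed_frac = NA_real_,
                n_at_start = 0L, n_spanning = 0L, n_informative = 0L,
                defined = FALSE))
  }
  list(processed_frac = n1 / (n1 + n2), unprocessed_frac = n2 / (n1 + n2),
       n_at_start = n1, n_spanning = n2, n_informative = n1 + n2,
       defined = TRUE)
}

#' Initiation preference on unprocessed vs processed transcripts
#'
#' Footprints initiating on the processed message have their 5' end precisely
#' at the downstream gene start; footprints initiating on the unprocessed
#' precursor have an inferred P site (3' end + offset - 3) on the start codon
#' while their 5' end reaches upstream across the junction. The
#' fold-preference normalizes the initiation ratio by the RNA-level
#' unprocessed/processed ratio.
#'
#' @param reads Footprint read table (deduplicated, unfiltered).
#' @param annotation,genome Annotation and genome.
#' @param offsets Calibrated \code{offset_table}.
#' @param rna RNA fractions from \code{\link{junction_rna_fractions}}.
#' @param junction Junction name (default: first annotated).
#' @return list(init_processed_frac, init_unprocessed_frac, fold_preference,
#'   n_processed, n_unprocessed, defined).
#' @export
junction_initiation <- function(reads, annotation, genome, offsets, rna,
                                junction = NULL) {
  junction <- junction %||% annotation$junctions$name[1]
  jx <- junction_info(annotation, junction)
  s_bio <- bio_pos(genome, jx$position, jx$strand)
  r <- data.table::as.data.table(reads)
  r <- r[r$genome_id == genome$id & r$strand == jx$strand]
  p5_bio <- bio_pos(genome, read_end5_genomic(r), jx$strand)
  n_proc <- sum(p5_bio == s_bio)
  idx <- match(r$length, offsets$length)
  ok <- !is.na(idx)
  p_mid <- bio_pos(genome, read_end3_genomic(r), jx$strand)[ok] +
    offsets$offset[idx[ok]] - 3L
  n_unproc <- sum(p_mid - s_bio >= 0L & p_mid - s_bio <= 2L & p5_bio[ok] < s_bio)
  defined <- n_proc > 0L && n_unproc >= 0L && isTRUE(rna$defined) &&
    rna$unprocessed_frac > 0 && n_unproc > 0L
  fold <- if (defined) {
    (n_unproc / n_proc) / (rna$unprocessed_frac / rna$processed_frac)
  } else NA_real_
  if (!defined) warnf("junction initiation fold-preference undefined")
  list(
    init_processed_frac = n_proc / (n_proc + n_unproc),
    init_unprocessed_frac = n_unproc / (n_proc + n_unproc),
    fold_preference = fold,
    n_processed = n_proc, n_unprocessed = n_unproc, defined = defined
  )
}

#' Stop-codon read-through index
#'
#' In-frame A-site density (counts on codon middle bases) over the 3' UTR in
#' the CDS reading frame, excluding the stop codon, divided by the in-frame
#' density over the CDS (stop excluded). A derived summary of the read-through
#' visible past C-context stop codons; the gene needs a 3' UTR of at least 5
#' in-frame codons.
#'
#' @param track An \code{asite_track}.
#' @param annotation,genome Annotation and genome.
#' @param gene_id Gene with an annotated 3' UTR.
#' @return list(index, cds_density, utr_density, n_utr_codons, defined).
#' @export
readthrough_index <- function(track, annotation, genome, gene_id) {
  pos <- feature_positions(annotation, gene_id, "CDS")
  strand <- gene_strand(annotation, gene_id)
  utr <- feature_positions(annotation, gene_id, "UTR3")
  J <- length(utr) %/% 3L
  if (J < 5L) stopf("gene %s: 3' UTR shorter than 5 codons", gene_id)
  n_cod <- length(pos) %/% 3L
  cds_mid <- pos[seq(2L, by = 3L, length.out = n_cod - 1L)]  # stop excluded
  utr_mid <- utr[seq(2L, by = 3L, length.out = J)]
  cds_d <- mean(track_counts_at(track, cds_mid, strand))
  utr_d <- mean(track_counts_at(track, utr_mid, strand))
  if (cds_d == 0) {
    warnf("gene %s has no in-frame CDS signal; index undefined", gene_id)
    return(list(index = NA_real_, cds_density = 0, utr_density = utr_d,
                n_utr_codons = J, defined = FALSE))
  }
  list(index = utr_d / cds_d, cds_density = cds_d, utr_density = utr_d,
       n_utr_codons = J, defined = TRUE)
}

#' Compare read-length distributions between two regions
#'
#' Two-sample Kolmogorov-Smirnov test on the lengths of reads overlapping
#' each region -- used to ask whether reads over a candidate ORF look like
#' ribosome footprints (vs, e.g., tRNA-protected fragments).
#'
#' @param reads Read table.
#' @param region_a,region_b list(start, end, strand = NULL): 0-based
#'   half-open genomic intervals.
#' @param min_reads Minimum reads per region (default 5).
#' @return list(statistic, p_value, n_a, n_b).
#' @export
length_dist_compare <- function(reads, region_a, region_b, min_reads = 5L) {
  reads <- data.table::as.data.table(reads)
  pick <- function(rg) {
    sel <- reads$start < rg$end & reads$end > rg$start
    if (!is.null(rg$strand)) sel <- sel & reads$strand == rg$strand
    reads$length[sel]
  }
  la <- pick(region_a); lb <- pick(region_b)
  if (length(la) < min_reads || length(lb) < min_reads)
    stopf("underpowered regions: %d and %d reads (need >= %d)",
          length(la), length(lb), min_reads)
  ks <- suppressWarnings(stats::ks.test(la, lb))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n_a = length(la), n_b = length(lb))
}

#' Initiation-proximal relative synthesis
#'
#' Sums A-site-transformed reads over each gene's earliest codons with
#' signal -- codons 2-5 for genes with a 5' UTR of at least \code{leader_cut}
#' nt (where initiating footprints place A sites on codon 2), codons 6-9 for
#' genes with a very short or no leader (where clamped initiation footprints
#' place A sites) -- and normalizes by the total of such sums across genes.
#'
#' @param track An \code{asite_track}.
#' @param annotation,genome Annotation and genome.
#' @param leader_cut Leader length separating the two window classes
#'   (default 4 nt).
#' @return data.table(gene_id, leader_len, window_first, window_sum, value).
#' @export
early_codon_synthesis <- function(track, annotation, genome, leader_cut = 4L) {
  genes <- gene_ids(annotation, "CDS")
  rows <- lapply(genes, function(g) {
    pos <- feature_positions(annotation, g, "CDS")
    strand <- gene_strand(annotation, g)
    lead <- leader_length(annotation, g)
    w1 <- if (lead >= leader_cut) 2L else 6L
    n_cod <- length(pos) %/% 3L
    cods <- seq(w1, min(w1 + 3L, n_cod))
    idx <- unlist(lapply(cods, function(k) (3L * (k - 1L) + 1L):(3L * k)))
    data.table::data.table(
      gene_id = g, leader_len = lead, window_first = w1,
      window_sum = sum(track_counts_at(track, pos[idx], strand))
    )
  })
  res <- data.table::rbindlist(rows)
  tot <- sum(res$window_sum)
  res[, "value" := if (tot > 0) res$window_sum / tot else NA_real_]
  res
}
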
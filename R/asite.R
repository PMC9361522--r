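# A-site offset calibration from 3' ends, A-site transformation, periodicity.

#' Calibrate per-read-length A-site offsets from 3' ends
#'
#' Two-step procedure. (1) Anchor: among reads of the modal length, the
#' initiation peak at the start codons of the anchor genes (the CDSs with
#' significant 5' UTRs, where initiating footprints are full length) fixes
#' the offset that places the A site on the middle base of codon 2 (P site on
#' the start codon). (2) Per-length refinement: for every other length, the
#' modal subcodon position of in-CDS 3' ends determines the offset, choosing
#' the candidate consistent with that subcodon class that is nearest the
#' anchor offset (then smallest in magnitude). Lengths with too few reads or
#' an ambiguous (near-bimodal) subcodon distribution are excluded with a
#' warning.
#'
#' @param reads Deduplicated read table (sample genome only is used).
#' @param genome An \code{mt_genome}.
#' @param annotation An \code{mt_annotation}.
#' @param anchor_genes Gene ids with unambiguous initiation peaks; default:
#'   every mRNA whose leader is at least \code{min_leader} nt.
#' @param lengths Candidate read lengths to calibrate (default 30-34; shorter
#'   reads have ambiguous offsets).
#' @param min_leader Leader length defining an anchor gene (default 10 nt).
#' @param min_reads Minimum reads per length (default 50).
#' @param clarity Relative margin required between the top two subcodon bins
#'   (default 0.1).
#' @return An \code{offset_table}: data.frame(length, offset) with the anchor
#'   length/offset as attributes.
#' @export
calibrate_offsets <- function(reads, genome, annotation, anchor_genes = NULL,
                              lengths = 30:34, min_leader = 10L,
                              min_reads = 50L, clarity = 0.1) {
  reads <- data.table::as.data.table(reads)
  reads <- reads[reads$genome_id == genome$id & reads$length %in% lengths]
  if (!nrow(reads)) stopf("calibration error: no reads in the length range")
  if (is.null(anchor_genes)) {
    mr <- ann_features(annotation, "mRNA")
    mr <- mr[!is.na(mr$leader_len) & mr$leader_len >= min_leader, ]
    anchor_genes <- setdiff(unique(mr$gene_id), character(0))
  }
  if (!length(anchor_genes)) stopf("calibration error: no anchor genes")

  p3_bio <- bio_pos(genome, read_end3_genomic(reads), reads$strand)

  # step 1: anchor on the modal length's initiation peak
  ltab <- table(reads$length)
  modal_len <- as.integer(names(ltab)[which.max(ltab)])
  rel <- integer(0)
  for (g in anchor_genes) {
    s_bio <- cds_start_bio(annotation, genome, g)
    gs <- gene_strand(annotation, g)
    sel <- reads$length == modal_len & reads$strand == gs
    r <- p3_bio[sel] - (s_bio + 4L)   # relative to middle base of codon 2
    rel <- c(rel, r[abs(r) <= modal_len])
  }
  if (!length(rel)) stopf("calibration error: no anchor-gene reads")
  rtab <- table(rel)
  anchor_offset <- -as.integer(names(rtab)[which.max(rtab)])

  # step 2: per-length refinement by modal subcodon class of in-CDS 3' ends
  cls <- cds_frame_classes(annotation, genome)
  p3_cls <- ifelse(reads$strand == "+",
                   cls$plus[wrap_pos(read_end3_genomic(reads), genome$length,
                                     genome$circular) + 1L],
                   cls$minus[wrap_pos(read_end3_genomic(reads), genome$length,
                                      genome$circular) + 1L])
  res <- list()
  for (l in sort(unique(reads$length))) {
    sel <- reads$length == l & !is.na(p3_cls)
    if (sum(sel) < min_reads) {
      warnf("length %d excluded: %d reads < min_reads", l, sum(sel))
      next
    }
    if (l == modal_len) {
      res[[as.character(l)]] <- anchor_offset
      next
    }
    bins <- tabulate(p3_cls[sel] + 1L, 3L)
    srt <- sort(bins, decreasing = TRUE)
    if ((srt[1] - srt[2]) / srt[1] < clarity) {
      warnf("length %d excluded: ambiguous subcodon distribution (%s)",
            l, paste(bins, collapse = "/"))
      next
    }
    m <- which.max(bins) - 1L
    # candidates place the A site (3' end + offset) on a codon middle base
    cand <- seq.int(-l + 1L, 0L)
    cand <- cand[(cand %% 3L) == ((1L - m) %% 3L)]
    cand <- cand[order(abs(cand - anchor_offset), abs(cand))]
    res[[as.character(l)]] <- cand[1L]
  }
  if (!length(res)) stopf("calibration error: no length calibrated")
  out <- data.frame(length = as.integer(names(res)),
                    offset = as.integer(unlist(res)))
  out <- out[order(out$length), ]
  rownames(out) <- NULL
  structure(out, class = c("offset_table", "data.frame"),
            anchor_length = modal_len, anchor_offset = anchor_offset)
}

#' A-site transformation of footprint reads
#'
#' Each read of a calibrated length contributes one count at its A-site
#' position, \code{3' end + offset[length]} in biological coordinates, on its
#' strand (modular when circular). Reads of uncalibrated lengths are dropped
#' and counted.
#'
#' @param reads Deduplicated read table.
#' @param offsets An \code{offset_table} from \code{\link{calibrate_offsets}}
#'   (or any data.frame with \code{length}, \code{offset}).
#' @param genome The sample \code{mt_genome}.
#' @return An \code{asite_track}: list(genome_id, length, circular, plus,
#'   minus, n_reads, n_dropped) with per-strand integer count vectors.
#' @export
asite_transform <- function(reads, offsets, genome) {
  reads <- data.table::as.data.table(reads)
  reads <- reads[reads$genome_id == genome$id]
  idx <- match(reads$length, offsets$length)
  n_drop <- sum(is.na(idx))
  keep <- !is.na(idx)
  reads <- reads[keep]
  off <- offsets$offset[idx[keep]]
  a_bio <- bio_pos(genome, read_end3_genomic(reads), reads$strand) + off
  a_gen <- genomic_pos(genome, a_bio, reads$strand)
  if (any(a_gen < 0L | a_gen >= genome$length))
    stopf("A-site position outside linear genome; check offsets")
  L <- genome$length
  track <- list(
    genome_id = genome$id, length = L, circular = genome$circular,
    plus = tabulate(a_gen[reads$strand == "+"] + 1L, L),
    minus = tabulate(a_gen[reads$strand == "-"] + 1L, L),
    n_reads = nrow(reads), n_dropped = n_drop
  )
  class(track) <- "asite_track"
  track
}

#' @export
print.asite_track <- function(x, ...) {
  cat(sprintf("<asite_track> %s (%d nt): %d reads (+: %d, -: %d), %d dropped\n",
              x$genome_id, x$length, x$n_reads, sum(x$plus), sum(x$minus),
              x$n_dropped))
  invisible(x)
}

#' Subcodon periodicity report
#'
#' Percentage of A sites on each subcodon position (1 = first, 2 = middle,
#' 3 = third base) over all CDS positions, excluding regions where CDSs
#' overlap on the same strand. Optionally also reports, per read length, the
#' modal subcodon position of raw 3' ends. Flags datasets whose dominant
#' share falls below \code{qc_threshold}.
#'
#' @param track An \code{asite_track}.
#' @param annotation An \code{mt_annotation}.
#' @param genome The matching \code{mt_genome}.
#' @param reads Optional read table for the per-length 3'-end summary.
#' @param qc_threshold Minimum dominant-position share (default 0.6).
#' @return list(percent = named numeric (pos1..pos3, sums to 100),
#'   dominant, qc_pass, by_length = optional data.frame).
#' @export
periodicity_report <- function(track, annotation, genome, reads = NULL,
                               qc_threshold = 0.6) {
  cls <- cds_frame_classes(annotation, genome)
  counts <- numeric(3)
  for (k in 0:2) {
    counts[k + 1L] <- sum(track$plus[which(cls$plus == k)]) +
      sum(track$minus[which(cls$minus == k)])
  }
  tot <- sum(counts)
  if (tot == 0) stopf("QC error: no in-CDS A-site counts")
  pct <- 100 * counts / tot
  names(pct) <- c("pos1", "pos2", "pos3")
  by_length <- NULL
  if (!is.null(reads)) {
    reads <- data.table::as.data.table(reads)
    reads <- reads[reads$genome_id == genome$id]
    p3 <- wrap_pos(read_end3_genomic(reads), genome$length, genome$circular)
    pcls <- ifelse(reads$strand == "+", cls$plus[p3 + 1L], cls$minus[p3 + 1L])
    ok <- !is.na(pcls)
    by_length <- do.call(rbind, lapply(sort(unique(reads$length[ok])), function(l) {
      b <- tabulate(pcls[ok & reads$length == l] + 1L, 3L)
      data.frame(length = l, modal_subcodon = which.max(b),
                 n = sum(b))
    }))
  }
  list(percent = pct, dominant = which.max(pct),
       qc_pass = max(pct) / 100 >= qc_threshold, by_length = by_length)
}

#' Offset-table and track serialization
#'
#' Offset tables round-trip through 2-column TSV; A-site tracks are written
#' as one bedGraph per strand.
#' @param offsets An \code{offset_table}.
#' @param path TSV path.
#' @export
write_offsets <- function(offsets, path) {
  utils::write.table(as.data.frame(offsets)[, c("length", "offset")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_offsets
#' @export
read_offsets <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(out, class = c("offset_table", "data.frame"))
}

#' @rdname write_offsets
#' @param track An \code{asite_track}.
#' @param prefix Output path prefix; writes \code{<prefix>.plus.bedGraph} and
#'   \code{<prefix>.minus.bedGraph}.
#' @export
write_track_bedgraph <- function(track, prefix) {
  for (s in c("plus", "minus")) {
    v <- track[[s]]
    nz <- which(v > 0L)
    gr <- GenomicRanges::GRanges(
      seqnames = track$genome_id,
      ranges = IRanges::IRanges(start = nz, width = 1L),
      score = v[nz]
    )
    GenomeInfoDb::seqlengths(gr) <- track$length
    rtracklayer::export(gr, sprintf("%s.%s.bedGraph", prefix, s),
                        format = "bedGraph")
  }
  invisible(prefix)
}
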
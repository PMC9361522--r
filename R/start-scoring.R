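# Ad hoc start-codon initiation scoring: nominates translated ORFs from
# A-site tracks by combining P-site pausing, in-frame signal gain, and
# occupancy gain around each candidate start codon.

#' In-frame and total A-site counts per codon around a position
#'
#' The genome is split into three frame references per strand; A-site reads
#' falling on the second (middle) base of a codon are that codon's in-frame
#' count, the total is the sum over its three bases.
#'
#' @param track An \code{asite_track}.
#' @param position 0-based position of a codon's first base (in translation
#'   order on \code{strand}).
#' @param strand \code{"+"} or \code{"-"}.
#' @param codon_offsets Integer codon offsets relative to the candidate codon
#'   (0 = the codon at \code{position}).
#' @return data.frame(offset, inframe, total).
#' @export
inframe_counts <- function(track, position, strand = "+", codon_offsets = 0L) {
  step <- if (strand == "+") 1L else -1L
  firsts <- position + step * 3L * codon_offsets
  v <- if (strand == "+") track$plus else track$minus
  at <- function(p) v[wrap_pos(p, track$length, track$circular) + 1L]
  data.frame(
    offset = codon_offsets,
    inframe = at(firsts + step),
    total = at(firsts) + at(firsts + step) + at(firsts + 2L * step)
  )
}

#' Score a candidate start codon
#'
#' Three additive parts, computed from A-site counts with pseudocount 1:
#' \enumerate{
#'   \item summed fold-change of P-site in-frame reads (inferred from A-site
#'     reads one codon downstream of the candidate) versus one codon upstream
#'     and one codon downstream of that P-site signal;
#'   \item percent of in-frame reads over the 20 codons downstream minus the
#'     percent over the 16 codons upstream (pooled within each window;
#'     zero-total windows contribute 0);
#'   \item doubled log2 ratio of total reads (all frames) five codons
#'     downstream over five codons upstream.
#' }
#' On uniform coverage the score is 2 (part1 = 2, part2 = part3 = 0).
#'
#' @param track An \code{asite_track}.
#' @param genome The matching \code{mt_genome}.
#' @param position 0-based first base of the candidate codon (translation
#'   order).
#' @param strand Strand of the candidate.
#' @param starts Permitted candidate triplets.
#' @param pseudocount Pseudocount used in the ratios (default 1).
#' @return list(position, strand, codon, part1, part2, part3, total).
#' @export
score_start <- function(track, genome, position, strand = "+",
                        starts = c("ATG", "ATA", "ATT", "GTG"),
                        pseudocount = 1) {
  codon <- genome_triplet(genome, position, strand)
  if (!codon %in% starts)
    stopf("triplet %s at %d is not a permitted start codon", codon, position)
  ic <- inframe_counts(track, position, strand, codon_offsets = -16:20)
  N <- function(k) ic$inframe[ic$offset == k]
  ps <- pseudocount
  part1 <- (N(1) + ps) / (N(0) + ps) + (N(1) + ps) / (N(2) + ps)
  dw <- ic[ic$offset >= 1 & ic$offset <= 20, ]
  up <- ic[ic$offset >= -16 & ic$offset <= -1, ]
  pct <- function(w) 100 * sum(w$inframe) / max(sum(w$total), 1)
  part2 <- pct(dw) - pct(up)
  t_dw <- sum(ic$total[ic$offset >= 1 & ic$offset <= 5])
  t_up <- sum(ic$total[ic$offset >= -5 & ic$offset <= -1])
  part3 <- 2 * log2((t_dw + ps) / (t_up + ps))
  list(position = position, strand = strand, codon = codon,
       part1 = part1, part2 = part2, part3 = part3,
       total = part1 + part2 + part3)
}

#' Score every permitted start codon across the genome
#'
#' Scores each occurrence of the permitted triplets on the requested strand
#' (heavy strand by default, matching the rRNA/tRNA-filtered heavy-strand
#' data the score distribution is built from). Candidates lying in-frame
#' inside a known ORF are classed \code{excluded_in_frame} (they never enter
#' histograms); candidates inside rRNA/tRNA genes are dropped; known gene
#' starts are labeled by their leader class.
#'
#' @param track An \code{asite_track}.
#' @param genome,annotation Genome and annotation.
#' @param strand Strand to score (default heavy, \code{"+"}).
#' @param starts Permitted triplets (default AUG/AUA/AUU/GUG).
#' @param exclude_rna Drop candidates inside rRNA/tRNA features (default
#'   TRUE).
#' @param pseudocount Passed to \code{\link{score_start}}.
#' @return data.table(position, strand, codon, part1, part2, part3, total,
#'   class, gene_id).
#' @export
score_genome <- function(track, genome, annotation, strand = "+",
                         starts = c("ATG", "ATA", "ATT", "GTG"),
                         exclude_rna = TRUE, pseudocount = 1) {
  L <- genome$length
  # candidate positions: triplet matches on the requested strand
  if (strand == "+") {
    tri <- paste0(genome$bases,
                  genome$bases[wrap_pos(seq_len(L), L, TRUE) + 1L],
                  genome$bases[wrap_pos(seq_len(L) + 1L, L, TRUE) + 1L])
  } else {
    tri <- paste0(comp_base(genome$bases),
                  comp_base(genome$bases[wrap_pos(seq_len(L) - 2L, L, TRUE) + 1L]),
                  comp_base(genome$bases[wrap_pos(seq_len(L) - 3L, L, TRUE) + 1L]))
  }
  pos <- which(tri %in% starts) - 1L
  if (!genome$circular) {
    pos <- pos[pos + 2L < L & pos >= 0L]  # windows would wrap: not scored
    pos <- pos[pos - 48L >= 0L & pos + 62L < L]
  }
  if (!length(pos)) {
    return(data.table::data.table(position = integer(), strand = character(),
                                  codon = character(), part1 = numeric(),
                                  part2 = numeric(), part3 = numeric(),
                                  total = numeric(), class = character(),
                                  gene_id = character()))
  }

  # classification scaffolding
  cds <- ann_features(annotation, "CDS")
  cds_genes <- unique(cds$gene_id[cds$strand == strand])
  start_of <- vapply(cds_genes, function(g)
    feature_positions(annotation, g, "CDS")[1L], integer(1))
  frame_arr <- rep(NA_integer_, L)  # in-CDS subcodon class on this strand
  for (g in cds_genes) {
    p <- feature_positions(annotation, g, "CDS")
    frame_arr[p + 1L] <- (seq_along(p) - 1L) %% 3L
  }
  rna_mask <- rep(FALSE, L)
  if (exclude_rna) {
    rr <- ann_features(annotation, c("rRNA", "tRNA"))
    for (i in seq_len(nrow(rr)))
      rna_mask[(rr$start[i] + 1L):rr$end[i]] <- TRUE
  }
  leader_of <- vapply(cds_genes, function(g)
    leader_length(annotation, g), integer(1))

  rows <- lapply(pos, function(p) {
    if (rna_mask[p + 1L]) return(NULL)
    sc <- score_start(track, genome, p, strand, starts, pseudocount)
    gi <- match(p, start_of)
    if (!is.na(gi)) {
      lead <- leader_of[gi]
      cl <- if (lead == 0L) "known_start_no_leader"
            else if (lead <= 3L) "known_start_short_leader"
            else "known_start_long_utr"
      gene <- cds_genes[gi]
    } else if (!is.na(frame_arr[p + 1L]) && frame_arr[p + 1L] == 0L) {
      cl <- "excluded_in_frame"; gene <- NA_character_
    } else {
      cl <- "candidate"; gene <- NA_character_
    }
    data.table::data.table(
      position = p, strand = strand, codon = sc$codon, part1 = sc$part1,
      part2 = sc$part2, part3 = sc$part3, total = sc$total, class = cl,
      gene_id = gene
    )
  })
  data.table::rbindlist(rows)
}
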
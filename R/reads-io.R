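# SAM / BED I/O for aligned footprint and RNA-seq reads.

#' Write a read table to SAM
#'
#' Reads are emitted as ungapped single-end alignments; the UMI travels as a
#' read-name suffix (\code{..._<UMI>}) and as an \code{RX} tag.
#'
#' @param reads data.table with \code{genome_id}, \code{start}, \code{end}
#'   (0-based half-open), \code{strand}, optional \code{umi}.
#' @param genomes named list of \code{mt_genome} (for header lengths and SEQ).
#' @param path Output SAM path.
#' @export
write_sam <- function(reads, genomes, path) {
  if (inherits(genomes, "mt_genome")) genomes <- list(genomes)
  names(genomes) <- vapply(genomes, `[[`, character(1), "id")
  if (any(reads$end <= reads$start))
    stopf("cannot write origin-wrapping reads to SAM")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(genomes, function(g)
             sprintf("@SQ\tSN:%s\tLN:%d", g$id, g$length), character(1)))
  umi <- if (!is.null(reads$umi)) reads$umi else rep("NA", nrow(reads))
  qname <- sprintf("r%08d_%s", seq_len(nrow(reads)), umi)
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  seqs <- vapply(seq_len(nrow(reads)), function(i) {
    g <- genomes[[reads$genome_id[i]]]
    substr(g$sequence, reads$start[i] + 1L, reads$end[i])
  }, character(1))
  rec <- paste(qname, flag, reads$genome_id, reads$start + 1L, 255L,
               sprintf("%dM", reads$end - reads$start), "*", 0L, 0L,
               seqs, "*", paste0("RX:Z:", umi), sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

parse_cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(n = as.integer(sub("[A-Z=]$", "", ops)),
       op = sub("^\\d+", "", ops))
}

#' Read aligned footprints from SAM/BAM
#'
#' Applies the soft-clip policy at ingest: clipped bases are dropped from the
#' read length and end coordinates, unless the 3'-side clip consists entirely
#' of A and thus appears to be a poly(A) tail, in which case it is re-appended
#' to the read's length and 3' end (\code{polyA_rule = "all"}; use
#' \code{"majority"} to relax the all-A requirement).
#'
#' @param path SAM or BAM file.
#' @param umi_from \code{"qname"} (suffix after the last underscore),
#'   \code{"tag"} (the \code{umi_tag} field), or \code{"none"}.
#' @param umi_tag SAM tag holding the UMI (default \code{"RX"}).
#' @param polyA_rule All clipped 3' bases must be A (\code{"all"}, default) or
#'   only a majority (\code{"majority"}).
#' @return data.table with \code{genome_id}, \code{start}, \code{end},
#'   \code{strand}, \code{length}, \code{umi}, \code{soft_clip_5},
#'   \code{soft_clip_3}.
#' @export
read_footprints <- function(path, umi_from = c("qname", "tag", "none"),
                            umi_tag = "RX", polyA_rule = c("all", "majority")) {
  umi_from <- match.arg(umi_from)
  polyA_rule <- match.arg(polyA_rule)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  par <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = if (umi_from == "tag") umi_tag else character(0),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = par)[[1]]
  n <- length(x$pos)
  strand <- ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+")
  ref_w <- integer(n); q_w <- integer(n)
  clipL <- integer(n); clipR <- integer(n)
  for (i in seq_len(n)) {
    co <- parse_cigar_ops(x$cigar[i])
    ref_w[i] <- sum(co$n[co$op %in% c("M", "D", "N", "=", "X")])
    q_w[i] <- sum(co$n[co$op %in% c("M", "I", "=", "X")])
    if (co$op[1] == "S") clipL[i] <- co$n[1]
    if (co$op[length(co$op)] == "S") clipR[i] <- co$n[length(co$op)]
  }
  start <- x$pos - 1L
  end <- start + ref_w
  len <- q_w
  seqs <- as.character(x$seq)
  # 3'-side soft clip: right end for "+" reads, left end for "-" reads
  clip3_w <- ifelse(strand == "+", clipR, clipL)
  clip5_w <- ifelse(strand == "+", clipL, clipR)
  for (i in which(clip3_w > 0L)) {
    cs <- if (strand[i] == "+") {
      substr(seqs[i], nchar(seqs[i]) - clip3_w[i] + 1L, nchar(seqs[i]))
    } else {
      revcomp(substr(seqs[i], 1L, clip3_w[i]))
    }
    nA <- sum(strsplit(cs, "")[[1]] == "A")
    keep <- if (polyA_rule == "all") nA == nchar(cs) else nA > nchar(cs) / 2
    if (keep) {
      len[i] <- len[i] + clip3_w[i]
      if (strand[i] == "+") end[i] <- end[i] + clip3_w[i]
      else start[i] <- start[i] - clip3_w[i]
      clip3_w[i] <- 0L
    }
  }
  umi <- switch(umi_from,
    qname = sub("^.*_", "", x$qname),
    tag = as.character(x$tag[[umi_tag]]),
    none = NA_character_
  )
  data.table::data.table(
    genome_id = as.character(x$rname), start = start, end = end,
    strand = strand, length = len, umi = umi,
    soft_clip_5 = clip5_w, soft_clip_3 = clip3_w
  )
}

#' Read aligned reads from BED (BED12 fallback)
#'
#' Block structure is ignored beyond the overall span; the UMI, if any, is
#' taken from the name field suffix.
#' @param path BED file.
#' @return data.table like \code{\link{read_footprints}} (no clip columns).
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  umi <- if (is.null(nm)) NA_character_ else sub("^.*_", "", nm)
  data.table::data.table(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length = GenomicRanges::width(gr),
    umi = umi
  )
}
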
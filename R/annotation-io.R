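# GFF3 and junction-table I/O. Internal coordinates are 0-based half-open;
# GFF3 is written/read 1-based closed via rtracklayer.

gff_type_map <- c(
  mRNA = "mRNA", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
  UTR5 = "five_prime_UTR", UTR3 = "three_prime_UTR"
)

#' Write an annotation to GFF3
#'
#' Package-specific attributes (\code{leader_len}, \code{complex_id},
#' \code{stoichiometry}, \code{family}) are carried as GFF3 attributes.
#'
#' @param annotation An \code{mt_annotation}.
#' @param path Output GFF3 path.
#' @export
write_annotation_gff3 <- function(annotation, path, seqid = "genome") {
  f <- annotation$features
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand
  )
  S4Vectors::mcols(gr)$type <- unname(gff_type_map[f$kind])
  # phase: nt to skip to the next codon boundary, accumulated over parts
  phase <- rep(NA_integer_, nrow(f))
  for (g in unique(f$gene_id[f$kind == "CDS"])) {
    rows <- which(f$kind == "CDS" & f$gene_id == g)
    rows <- rows[order(f$part[rows])]
    done <- 0L
    for (r in rows) {
      phase[r] <- (3L - done %% 3L) %% 3L
      done <- done + f$end[r] - f$start[r]
    }
  }
  S4Vectors::mcols(gr)$phase <- phase
  S4Vectors::mcols(gr)$ID <- paste0(f$gene_id, ".", gff_type_map[f$kind], ".", f$part)
  S4Vectors::mcols(gr)$gene_id <- f$gene_id
  S4Vectors::mcols(gr)$part <- f$part
  S4Vectors::mcols(gr)$leader_len <- f$leader_len
  S4Vectors::mcols(gr)$complex_id <- f$complex_id
  S4Vectors::mcols(gr)$stoichiometry <- f$stoichiometry
  S4Vectors::mcols(gr)$family <- f$family
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an annotation from GFF3
#'
#' @param path GFF3 file written by \code{\link{write_annotation_gff3}} or
#'   compatible (attributes \code{gene_id}, \code{leader_len},
#'   \code{complex_id}, \code{stoichiometry}, \code{family} are honored).
#' @param junctions Optional junction table (data.frame or TSV path).
#' @param families Optional named list of paralog families.
#' @return An \code{mt_annotation}.
#' @export
read_annotation_gff3 <- function(path, junctions = NULL, families = list()) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  kind <- names(gff_type_map)[match(as.character(m$type), gff_type_map)]
  keep <- !is.na(kind)
  num_or_na <- function(x, n) {
    if (is.null(x)) rep(NA_real_, n) else suppressWarnings(as.numeric(as.character(x)))
  }
  chr_or_na <- function(x, n) {
    if (is.null(x)) rep(NA_character_, n) else as.character(x)
  }
  n <- sum(keep)
  features <- data.frame(
    gene_id = as.character(m$gene_id)[keep],
    kind = kind[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    start = GenomicRanges::start(gr)[keep] - 1L,
    end = GenomicRanges::end(gr)[keep],
    part = {
      p <- num_or_na(m$part, length(gr))[keep]
      ifelse(is.na(p), 1L, as.integer(p))
    },
    leader_len = num_or_na(m$leader_len, length(gr))[keep],
    complex_id = chr_or_na(m$complex_id, length(gr))[keep],
    stoichiometry = num_or_na(m$stoichiometry, length(gr))[keep],
    family = chr_or_na(m$family, length(gr))[keep],
    stringsAsFactors = FALSE
  )
  if (is.character(junctions)) junctions <- read_junctions(junctions)
  mt_annotation(features, junctions = junctions, families = families)
}

#' Read / write processing-junction tables
#'
#' Two-column TSV: \code{name}, \code{position} (0-based first base of the
#' downstream message).
#' @param path TSV path.
#' @export
read_junctions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_junctions
#' @param junctions data.frame with columns \code{name}, \code{position}.
#' @export
write_junctions <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
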
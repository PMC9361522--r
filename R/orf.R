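#' Scan an open reading frame from a candidate start codon
#'
#' Extends in frame from \code{start} until the first termination codon of the
#' vertebrate mitochondrial code. AGA and AGG are treated as terminators by
#' default (they close \emph{MT-CO1}- and \emph{MT-ND6}-like ORFs); set
#' \code{agag_stop = FALSE} to read them as arginine instead.
#'
#' @param genome An \code{mt_genome}.
#' @param start 0-based genome position of the start codon's first base in
#'   translation order (for the light strand this is the highest coordinate of
#'   the triplet).
#' @param strand \code{"+"} or \code{"-"}.
#' @param start_codons Permitted start triplets (precondition).
#' @param agag_stop Treat AGA/AGG as terminators.
#' @return An object of class \code{mt_orf}: \code{start}, \code{strand},
#'   \code{codons} (count before the stop), \code{start_codon},
#'   \code{stop_codon}, \code{peptide}.
#' @export
scan_orf <- function(genome, start, strand = "+",
                     start_codons = c("ATG", "ATA", "ATT"),
                     agag_stop = TRUE) {
  strand <- match.arg(strand, c("+", "-"))
  if (start < 0L || start >= genome$length)
    stopf("start position out of range [0, %d)", genome$length)
  first <- genome_triplet(genome, start, strand)
  if (!first %in% start_codons)
    stopf("triplet %s at %d is not a permitted start codon (%s)",
          first, start, paste(start_codons, collapse = ","))
  stops <- mito_stop_codons(agag_stop)
  tab <- mito_codon_table(agag_stop)
  step <- if (strand == "+") 3L else -3L
  max_codons <- genome$length %/% 3L + 1L
  peptide <- character(0)
  pos <- start
  for (i in seq_len(max_codons)) {
    if (!genome$circular && (pos < 0L || pos + (if (strand == "+") 2L else -2L) < 0L ||
                             pos >= genome$length ||
                             pos + (if (strand == "+") 2L else -2L) >= genome$length))
      stopf("ORF runs off the end of linear genome %s", genome$id)
    cod <- genome_triplet(genome, pos, strand)
    if (cod %in% stops) {
      return(structure(
        list(start = start, strand = strand, codons = length(peptide),
             start_codon = first, stop_codon = cod,
             peptide = paste(peptide, collapse = "")),
        class = "mt_orf"
      ))
    }
    peptide <- c(peptide, unname(tab[cod]))
    pos <- wrap_pos(pos + step, genome$length, genome$circular)
  }
  stopf("no termination codon before traversing the whole genome from %d (%s)",
        start, strand)
}

#' @export
print.mt_orf <- function(x, ...) {
  cat(sprintf("<mt_orf> %s strand %s: %d codons, %s..%s, peptide %s\n",
              format(x$start), x$strand, x$codons, x$start_codon, x$stop_codon,
              x$peptide))
  invisible(x)
}

#' First ORF starting in a gene's 3' UTR
#'
#' Scans the annotated 3' UTR nucleotide by nucleotide, 5' to 3' on the gene's
#' strand, and returns the ORF at the first triplet found in
#' \code{start_set} -- the operation that locates an \emph{MT-ND5-dORF}-like
#' downstream ORF.
#'
#' @param genome An \code{mt_genome}.
#' @param annotation An \code{mt_annotation}; the gene must have a UTR3
#'   feature.
#' @param gene_id Host gene.
#' @param start_set Start triplets to look for (default AUG only).
#' @param ... Passed to \code{\link{scan_orf}}.
#' @return An \code{mt_orf}, or \code{NULL} when the UTR holds no start
#'   triplet.
#' @export
first_start_in_utr3 <- function(genome, annotation, gene_id,
                                start_set = "ATG", ...) {
  utr <- tryCatch(feature_positions(annotation, gene_id, "UTR3"),
                  error = function(e) NULL)
  if (is.null(utr)) stopf("gene %s has no annotated 3' UTR", gene_id)
  strand <- gene_strand(annotation, gene_id)
  if (length(utr) < 3L) return(NULL)
  for (i in seq_len(length(utr) - 2L)) {
    if (genome_triplet(genome, utr[i], strand) %in% start_set) {
      return(scan_orf(genome, utr[i], strand, start_codons = start_set, ...))
    }
  }
  NULL
}
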
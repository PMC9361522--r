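#' Genome container for a single (usually circular) contig
#'
#' Holds one contig such as a mitochondrial genome. All coordinates in this
#' package are 0-based, half-open, and taken modulo the genome length when the
#' genome is circular. The heavy strand is \code{"+"}, the light strand
#' \code{"-"}.
#'
#' @param id Contig identifier.
#' @param sequence Nucleotide string (A/C/G/T, N tolerated outside CDS).
#' @param circular Logical; mtDNA is circular.
#' @return An object of class \code{mt_genome} with fields \code{id},
#'   \code{sequence}, \code{length}, \code{circular}.
#' @export
mt_genome <- function(id, sequence, circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stopf("empty genome sequence")
  if (grepl("[^ACGTN]", sequence)) stopf("genome alphabet restricted to ACGTN")
  structure(
    list(
      id = as.character(id),
      sequence = sequence,
      bases = strsplit(sequence, "", fixed = TRUE)[[1]],
      length = nchar(sequence),
      circular = isTRUE(circular)
    ),
    class = "mt_genome"
  )
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf(
    "<mt_genome> %s: %d nt, %s\n",
    x$id, x$length, if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file.
#' @param circular Logical, recycled across records.
#' @return A list of \code{mt_genome} objects, named by record id.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  circular <- rep_len(circular, length(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    id <- sub("\\s.*$", "", names(seqs)[i])
    mt_genome(id, as.character(seqs[[i]]), circular[i])
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes A single \code{mt_genome} or list of them.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "mt_genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "sequence"))
  names(set) <- vapply(genomes, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Bases at 0-based positions (vectorized, wrapped when circular).
genome_base <- function(genome, pos) {
  if (any(pos < 0L | pos >= genome$length) && !genome$circular)
    stopf("position out of range on linear genome %s", genome$id)
  genome$bases[wrap_pos(pos, genome$length, genome$circular) + 1L]
}

# Triplet whose first base in translation order sits at `pos` on `strand`.
# On the light strand the triplet occupies genomic positions pos, pos-1, pos-2.
genome_triplet <- function(genome, pos, strand) {
  if (strand == "+") {
    paste(genome_base(genome, pos + 0:2), collapse = "")
  } else {
    paste(comp_base(genome_base(genome, pos - 0:2)), collapse = "")
  }
}

#' Reading-frame index of a genome position
#'
#' Frames partition each strand into three references used by the start-codon
#' scoring. On the heavy strand the frame of a position is \code{pos mod 3};
#' on the light strand it is computed on the reverse-complement coordinate
#' system, \code{(L - 1 - pos) mod 3}.
#'
#' @param position 0-based genome position(s).
#' @param strand \code{"+"} or \code{"-"}.
#' @param genome An \code{mt_genome} (needed for its length).
#' @return Integer frame id(s) in 0..2.
#' @export
frame_of <- function(position, strand, genome) {
  if (any(position < 0L | position >= genome$length))
    stopf("position out of range [0, %d)", genome$length)
  strand <- match.arg(strand, c("+", "-"))
  if (strand == "+") position %% 3L else (genome$length - 1L - position) %% 3L
}

# Vertebrate mitochondrial codon table. AGA/AGG are terminators in this code;
# when `agag_stop` is FALSE they revert to arginine (the frameshift reading).
mito_codon_table <- function(agag_stop = TRUE) {
  tab <- Biostrings::getGeneticCode("2")
  if (!agag_stop) tab[c("AGA", "AGG")] <- "R"
  tab
}

mito_stop_codons <- function(agag_stop = TRUE) {
  if (agag_stop) c("TAA", "TAG", "AGA", "AGG") else c("TAA", "TAG")
}

#' Translate a nucleotide string with the vertebrate mitochondrial code
#'
#' @param seq Nucleotide string, length a multiple of 3.
#' @param agag_stop Treat AGA/AGG as terminators (\code{"*"})?
#' @return Amino-acid string.
#' @export
translate_mito <- function(seq, agag_stop = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stopf("sequence length %d not a multiple of 3", n)
  tab <- mito_codon_table(agag_stop)
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(tab[codons]), collapse = "")
}
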
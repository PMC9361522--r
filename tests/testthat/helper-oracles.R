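# Independent brute-force oracles shared across test files.

# Independent re-implementation of the scoring formula, used as the oracle.
oracle_score <- function(plus, L, pos) {
  at <- function(p) plus[(p %% L) + 1L]
  Ncod <- function(k) at(pos + 3 * k + 1)
  Tcod <- function(k) at(pos + 3 * k) + at(pos + 3 * k + 1) + at(pos + 3 * k + 2)
  part1 <- (Ncod(1) + 1) / (Ncod(0) + 1) + (Ncod(1) + 1) / (Ncod(2) + 1)
  dwN <- sum(sapply(1:20, Ncod)); dwT <- sum(sapply(1:20, Tcod))
  upN <- sum(sapply(-16:-1, Ncod)); upT <- sum(sapply(-16:-1, Tcod))
  part2 <- 100 * dwN / max(dwT, 1) - 100 * upN / max(upT, 1)
  part3 <- 2 * log2((sum(sapply(1:5, Tcod)) + 1) /
                    (sum(sapply(-5:-1, Tcod)) + 1))
  c(part1 = part1, part2 = part2, part3 = part3,
    total = part1 + part2 + part3)
}

# Brute-force oracle for phase-matched antisense ATG discovery: scan every
# triplet on both strands and check the antisense-phase condition directly
# against each gene's translated position list.
oracle_phase_atgs <- function(genome, annotation) {
  L <- genome$length
  seq2 <- paste0(genome$sequence, genome$sequence)
  hits <- list()
  for (g in mitoribo:::gene_ids(annotation, "CDS")) {
    pos <- mitoribo:::feature_positions(annotation, g, "CDS")
    sense <- mitoribo:::gene_strand(annotation, g)
    anti <- if (sense == "+") "-" else "+"
    idx_of <- integer(L); idx_of[] <- NA_integer_
    idx_of[pos + 1L] <- seq_along(pos)
    # every genomic position p0 where the antisense strand reads ATG
    for (p0 in 0:(L - 1L)) {
      tri_pos <- if (anti == "+") p0 + 0:2 else p0 - 0:2
      tri_pos <- tri_pos %% L
      bases <- substring(seq2, tri_pos + 1L, tri_pos + 1L)
      if (anti == "-") bases <- chartr("ACGT", "TGCA", bases)
      if (paste(bases, collapse = "") != "ATG") next
      k <- idx_of[tri_pos + 1L]
      if (any(is.na(k))) next
      # antisense order visits sense indices in decreasing order; the phase
      # requires them to be (3i+1, 3i, 3i-1) for some codon i
      if (k[1] %% 3L == 1L && k[1] > 1L && k[2] == k[1] - 1L &&
          k[3] == k[1] - 2L) {
        hits[[length(hits) + 1L]] <- c(p0, tri_pos)
      }
    }
  }
  m <- do.call(rbind, hits)
  unique(m[order(m[, 1]), , drop = FALSE])
}

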
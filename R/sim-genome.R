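# Toy-genome construction for the synthetic-data module.

CODON_SET <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all64
}
NONSTOP_CODONS <- setdiff(CODON_SET, c("TAA", "TAG", "AGA", "AGG"))

random_coding <- function(n_codons) {
  paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

# Sequence without adenines: guarantees no start triplet can occur.
random_noA <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build the toy genome, annotation, and spike genome for a simulation
#'
#' Lays the configured genes on a circular genome in order, separated by
#' tRNA spacers (mRNAs are excised from the polycistron through flanking
#' tRNAs), with one rRNA region, one junction pair with no spacer between its
#' two messages, one light-strand gene, and a 3' UTR hosting the configured
#' dORF. Stop codons of UTR-bearing genes are followed by a C, the context
#' that promotes stop-codon read-through. Deterministic given
#' \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return list with \code{genome}, \code{annotation}, \code{spike_genome},
#'   \code{spike_annotation}, and \code{layout} (per-gene truth coordinates,
#'   dORF and junction positions).
#' @export
make_toy_genome <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, build_toy_genome(config))
}

build_toy_genome <- function(cfg) {
  gs <- cfg$gene_specs
  trna_len <- 70L
  rrna_len <- 300L
  jx_up <- cfg$junction_spec$upstream
  jx_dn <- cfg$junction_spec$downstream
  dorf <- cfg$dorf_spec

  segs <- list()
  add_seg <- function(kind, id, seq) {
    segs[[length(segs) + 1L]] <<- list(kind = kind, id = id, seq = seq)
  }

  add_seg("rRNA", "rrn1", random_noA(rrna_len))
  add_seg("tRNA", "trn0", random_noA(trna_len))
  for (i in seq_len(nrow(gs))) {
    g <- gs[i, ]
    coding <- paste0(g$start_codon, random_coding(g$n_codons - 1L), g$stop_codon)
    utr3 <- ""
    if (g$utr3_len > 0L) {
      if (identical(g$gene_id, dorf$host)) {
        if (g$utr3_len < dorf$offset + 3L * (dorf$n_codons + 1L) + 1L)
          stopf("config error: host 3' UTR too short for the dORF")
        dorf_seq <- paste0("ATG", random_coding(dorf$n_codons - 1L), "TAA")
        tail_len <- g$utr3_len - dorf$offset - nchar(dorf_seq) - 1L
        utr3 <- paste0("C", random_noA(dorf$offset - 1L), dorf_seq, "C",
                       random_noA(tail_len))
      } else {
        utr3 <- paste0("C", random_noA(g$utr3_len - 1L))
      }
    }
    body <- paste0(random_noA(g$leader_len), coding, utr3)
    if (g$strand == "-") body <- revcomp(body)
    add_seg("mRNA", g$gene_id, body)
    if (!identical(g$gene_id, jx_up))  # junction pair abuts: no spacer after
      add_seg("tRNA", sprintf("trn%d", i), random_noA(trna_len))
  }

  seqs <- vapply(segs, `[[`, character(1), "seq")
  lens <- nchar(seqs)
  total <- sum(lens)
  if (total > cfg$genome_len)
    stopf("config error: genes (%d nt) overflow genome_len (%d)",
          total, cfg$genome_len)
  filler <- random_noA(cfg$genome_len - total)
  genome <- mt_genome("mito_toy", paste(c(seqs, filler), collapse = ""),
                      circular = TRUE)

  starts <- cumsum(c(0L, lens))[seq_along(lens)]
  feats <- list()
  layout_rows <- list()
  for (j in seq_along(segs)) {
    s <- segs[[j]]
    a <- starts[j]; b <- a + lens[j]
    if (s$kind %in% c("tRNA", "rRNA")) {
      feats[[length(feats) + 1L]] <- data.frame(
        gene_id = s$id, kind = s$kind, strand = "+", start = a, end = b,
        part = 1L, leader_len = NA_real_, complex_id = NA_character_,
        stoichiometry = NA_real_, family = NA_character_,
        stringsAsFactors = FALSE
      )
      next
    }
    g <- gs[gs$gene_id == s$id, ]
    # mRNA-local layout: leader | CDS (incl stop) | UTR3, in translation order
    cds_nt <- 3L * (g$n_codons + 1L)
    if (g$strand == "+") {
      cds_a <- a + g$leader_len; cds_b <- cds_a + cds_nt
      utr_a <- cds_b; utr_b <- utr_a + g$utr3_len
    } else {
      cds_b <- b - g$leader_len; cds_a <- cds_b - cds_nt
      utr_b <- cds_a; utr_a <- utr_b - g$utr3_len
    }
    row <- function(kind, s0, e0) data.frame(
      gene_id = g$gene_id, kind = kind, strand = g$strand, start = s0, end = e0,
      part = 1L, leader_len = as.numeric(g$leader_len),
      complex_id = g$complex_id, stoichiometry = g$stoichiometry,
      family = NA_character_, stringsAsFactors = FALSE
    )
    feats[[length(feats) + 1L]] <- row("mRNA", a, b)
    feats[[length(feats) + 1L]] <- row("CDS", cds_a, cds_b)
    if (g$leader_len > 0L) {
      if (g$strand == "+") feats[[length(feats) + 1L]] <- row("UTR5", a, cds_a)
      else feats[[length(feats) + 1L]] <- row("UTR5", cds_b, b)
    }
    if (g$utr3_len > 0L)
      feats[[length(feats) + 1L]] <- row("UTR3", utr_a, utr_b)
    layout_rows[[length(layout_rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, strand = g$strand, mrna_start = a, mrna_end = b,
      cds_start = cds_a, cds_end = cds_b, leader_len = g$leader_len,
      utr3_len = g$utr3_len, n_codons = g$n_codons, weight = g$weight,
      complex_id = g$complex_id, stringsAsFactors = FALSE
    )
  }

  lay <- do.call(rbind, layout_rows)
  # dORF: annotated as its own CDS (+ mRNA stub carrying its leader context)
  host <- lay[lay$gene_id == dorf$host, ]
  if (host$strand != "+")
    stopf("config error: dORF host must be heavy-strand in the toy layout")
  utr_start <- host$cds_end
  dorf_start <- utr_start + dorf$offset
  dorf_end <- dorf_start + 3L * (dorf$n_codons + 1L)
  dorf_id <- paste0(dorf$host, ".dorf")
  dorf_rows <- data.frame(
    gene_id = dorf_id, kind = c("mRNA", "CDS"), strand = "+",
    start = dorf_start, end = dorf_end, part = 1L,
    leader_len = as.numeric(dorf$offset),
    complex_id = NA_character_, stoichiometry = NA_real_,
    family = NA_character_, stringsAsFactors = FALSE
  )
  feats[[length(feats) + 1L]] <- dorf_rows

  jx_row <- lay[lay$gene_id == jx_dn, ]
  junctions <- data.frame(name = "jx1", position = jx_row$mrna_start)

  annotation <- mt_annotation(do.call(rbind, feats), junctions = junctions)

  spike <- build_spike_genome()

  list(
    genome = genome, annotation = annotation,
    spike_genome = spike$genome, spike_annotation = spike$annotation,
    layout = list(
      genes = lay,
      dorf = list(gene_id = dorf_id, host = dorf$host, start = dorf_start,
                  end = dorf_end, n_codons = dorf$n_codons,
                  weight = dorf$weight),
      junction = list(name = "jx1", position = jx_row$mrna_start,
                      upstream = jx_up, downstream = jx_dn)
    )
  )
}

build_spike_genome <- function() {
  trna <- random_noA(60L)
  g1 <- paste0("ATG", random_coding(79L), "TAA")
  g2 <- paste0("ATG", random_coding(69L), "TAG")
  seq <- paste0(trna, g1, random_noA(60L), g2, random_noA(60L))
  genome <- mt_genome("spike_toy", seq, circular = TRUE)
  a1 <- 60L; b1 <- a1 + nchar(g1)
  a2 <- b1 + 60L; b2 <- a2 + nchar(g2)
  feats <- data.frame(
    gene_id = rep(c("spk01", "spk02"), each = 2L),
    kind = rep(c("mRNA", "CDS"), 2L),
    strand = "+",
    start = c(a1, a1, a2, a2), end = c(b1, b1, b2, b2),
    part = 1L, leader_len = 0, complex_id = NA_character_,
    stoichiometry = NA_real_, family = NA_character_,
    stringsAsFactors = FALSE
  )
  list(genome = genome, annotation = mt_annotation(feats))
}
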
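# Cytosolic (nuclear-encoded) toy compartment: a transcript contig with
# OXPHOS subunit genes, used for mitonuclear balance analyses.

#' Default nuclear-encoded OXPHOS subunit complement
#'
#' Seventeen toy cytosolic genes across the four dual-origin complexes, with
#' per-gene synthesis weights whose complex averages rise in the order
#' CI < CIII < CIV < CV, mirroring the relative complex abundances. One
#' paralog family (alternative isoforms ncx4a/ncx4b) and a core-subunit flag
#' are included.
#'
#' @return data.frame(gene_id, n_codons, complex_id, weight, core, family).
#' @export
default_cyto_specs <- function() {
  data.frame(
    gene_id = c(sprintf("nci%02d", 1:6), sprintf("nc3%02d", 1:3),
                c("ncx4a", "ncx4b", "nc401", "nc402"),
                sprintf("ncv%02d", 1:4)),
    n_codons = c(180L, 140L, 220L, 160L, 200L, 150L,
                 190L, 170L, 210L,
                 120L, 110L, 230L, 140L,
                 160L, 180L, 150L, 170L),
    complex_id = c(rep("CI", 6), rep("CIII", 3), rep("CIV", 4), rep("CV", 4)),
    weight = c(0.40, 0.50, 0.60, 0.50, 0.45, 0.55,
               0.90, 1.00, 1.10,
               0.60, 0.70, 1.40, 1.30,
               1.60, 1.80, 1.70, 1.90),
    core = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
             TRUE, TRUE, FALSE,
             TRUE, TRUE, TRUE, FALSE,
             TRUE, TRUE, FALSE, TRUE),
    family = c(rep(NA_character_, 9), "ncx4", "ncx4",
               NA_character_, NA_character_, rep(NA_character_, 4)),
    stringsAsFactors = FALSE
  )
}

#' Build a toy cytosolic transcript contig
#'
#' Genes are laid on one linear contig with 30-nt leaders and spacers; each
#' gene gets mRNA + CDS features carrying its complex assignment, and paralog
#' families are registered on the annotation.
#'
#' @param specs Gene table (default \code{\link{default_cyto_specs}}).
#' @param seed RNG seed.
#' @return list(genome, annotation, layout).
#' @export
make_toy_cyto <- function(specs = default_cyto_specs(), seed = 101L) {
  with_seed(seed, {
    leader <- 30L; spacer <- 20L
    segs <- character(0)
    rows <- list()
    cursor <- 0L
    for (i in seq_len(nrow(specs))) {
      g <- specs[i, ]
      coding <- paste0("ATG", random_coding(g$n_codons - 1L), "TAA")
      body <- paste0(random_noA(leader), coding, random_noA(spacer))
      a <- cursor + leader
      b <- a + nchar(coding)
      rows[[i]] <- data.frame(
        gene_id = g$gene_id, kind = c("mRNA", "CDS"), strand = "+",
        start = c(cursor, a), end = c(b, b), part = 1L,
        leader_len = leader, complex_id = g$complex_id,
        stoichiometry = NA_real_, family = g$family,
        stringsAsFactors = FALSE
      )
      segs <- c(segs, body)
      cursor <- cursor + nchar(body)
    }
    genome <- mt_genome("cyto_toy", paste(segs, collapse = ""),
                        circular = FALSE)
    fam_ids <- unique(stats::na.omit(specs$family))
    families <- lapply(fam_ids, function(f)
      specs$gene_id[!is.na(specs$family) & specs$family == f])
    names(families) <- fam_ids
    annotation <- mt_annotation(do.call(rbind, rows), families = families)
    lay <- specs
    lay$cds_start <- vapply(specs$gene_id, function(g)
      feature_positions(annotation, g, "CDS")[1L], integer(1))
    list(genome = genome, annotation = annotation, layout = lay)
  })
}

#' Simulate cytosolic ribosome footprints
#'
#' Elongation-only footprints over the cytosolic toy contig: gene by weight,
#' codon uniform, A-site middle-base jitter and per-length 3'-end offsets as
#' in the mitochondrial simulator.
#'
#' @param cyto Output of \code{\link{make_toy_cyto}}.
#' @param depth Number of footprints.
#' @param config A \code{\link{sim_config}} supplying length_dist,
#'   offset_truth, and periodicity.
#' @param seed RNG seed.
#' @return data.table of reads (genome_id, start, end, strand, length, umi).
#' @export
simulate_cyto_footprints <- function(cyto, depth, config = sim_config(),
                                     seed = 202L) {
  with_seed(seed, {
    lay <- cyto$layout
    mids <- list(); genes <- list(); w <- list()
    for (i in seq_len(nrow(lay))) {
      pos <- feature_positions(cyto$annotation, lay$gene_id[i], "CDS")
      m <- pos[seq(2L, length(pos), by = 3L)]
      mids[[i]] <- m
      genes[[i]] <- rep(lay$gene_id[i], length(m))
      w[[i]] <- rep(lay$weight[i], length(m))
    }
    mids <- unlist(mids); w <- unlist(w)
    idx <- sample.int(length(mids), depth, replace = TRUE, prob = w)
    p <- config$periodicity
    a <- mids[idx] + sample(c(-1L, 0L, 1L), depth, replace = TRUE,
                            prob = c((1 - p) / 2, p, (1 - p) / 2))
    lens <- as.integer(names(config$length_dist))
    l <- lens[sample.int(length(lens), depth, replace = TRUE,
                         prob = config$length_dist)]
    off <- as.integer(config$offset_truth[as.character(l)])
    p3 <- a - off
    data.table::data.table(
      genome_id = cyto$genome$id, start = p3 - l + 1L, end = p3 + 1L,
      strand = "+", length = l,
      umi = random_umis(depth, config$umi_width)
    )
  })
}
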
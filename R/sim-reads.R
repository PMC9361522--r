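# Footprint / RNA-seq read simulation with known truth.

# Genomic coordinates of read ends. The biological 3' end of a light-strand
# read is its lowest genomic coordinate.
read_end3_genomic <- function(reads) {
  ifelse(reads$strand == "+", reads$end - 1L, reads$start)
}
read_end5_genomic <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

# Per-gene codon table used by the simulator: A-site middle positions in
# biological coordinates plus dwell weights, including geometric read-through
# extensions into C-context 3' UTRs.
sim_codon_pool <- function(sim, cfg) {
  lay <- sim$layout$genes
  genome <- sim$genome
  L <- genome$length
  pools <- list()
  for (i in seq_len(nrow(lay))) {
    g <- lay[i, ]
    s_bio <- if (g$strand == "+") g$cds_start else L - g$cds_end
    ncod <- g$n_codons + 1L  # coding codons + stop
    firsts_bio <- s_bio + 3L * (seq_len(ncod) - 1L)
    firsts_gen <- genomic_pos(genome, firsts_bio, g$strand)
    trip <- vapply(firsts_gen, function(p) genome_triplet(genome, p, g$strand),
                   character(1))
    w <- rep(1, ncod)
    if (length(cfg$pause_mult)) {
      hit <- match(trip, names(cfg$pause_mult))
      w[!is.na(hit)] <- unname(cfg$pause_mult[hit[!is.na(hit)]])
    }
    mid_bio <- firsts_bio + 1L
    # read-through: stop followed by C promotes in-frame extension
    if (g$utr3_len >= 3L) {
      after_stop <- genomic_pos(genome, s_bio + 3L * ncod, g$strand)
      base_after <- if (g$strand == "+") genome_base(genome, after_stop)
                    else comp_base(genome_base(genome, after_stop))
      if (base_after == "C" && cfg$readthrough_prob > 0) {
        next_j <- seq_len(g$utr3_len %/% 3L)
        w <- c(w, cfg$readthrough_prob *
                 cfg$readthrough_continue^(next_j - 1L))
        mid_bio <- c(mid_bio, s_bio + 3L * ncod + 3L * (next_j - 1L) + 1L)
      }
    }
    pools[[g$gene_id]] <- list(gene_id = g$gene_id, strand = g$strand,
                               mid_bio = mid_bio, w = g$weight * w)
  }
  d <- sim$layout$dorf
  s_bio <- d$start  # dORF host is heavy-strand
  ncod <- d$n_codons + 1L
  pools[[d$gene_id]] <- list(gene_id = d$gene_id, strand = "+",
                             mid_bio = s_bio + 3L * (seq_len(ncod) - 1L) + 1L,
                             w = rep(d$weight, ncod))
  pools
}

random_umis <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate aligned mitoribosome footprints with known truth
#'
#' Draws elongating footprints (gene by expression weight, codon by dwell
#' multiplier, A-site jittered per the configured periodicity, per-length
#' 3'-end offsets), initiation footprints (P-site on the start codon;
#' 15-nt-to-full-length half-footprints clamped at the message start on
#' leaderless and short-leader genes, full-length footprints where upstream
#' message is available, including the unprocessed junction precursor with
#' the configured fold-preference), read-through ribosomes past C-context stop
#' codons, spike-in genome reads, and UMI-sharing PCR duplicates.
#'
#' @param sim Output of \code{\link{make_toy_genome}}.
#' @param config A \code{\link{sim_config}}.
#' @param seed RNG seed for the read draw (default \code{config$seed + 1}).
#' @return list(\code{reads} = data.table with columns genome_id, start, end,
#'   strand, length, umi, src, gene_id; \code{truth} = list of generating
#'   parameters and bookkeeping counts).
#' @export
simulate_footprints <- function(sim, config, seed = NULL) {
  validate_sim_config(config)
  with_seed(seed %||% (config$seed + 1L),
            sim_footprints_impl(sim, config))
}

sim_footprints_impl <- function(sim, cfg) {
  genome <- sim$genome
  L <- genome$length
  lay <- sim$layout$genes
  if (!nrow(lay) || all(lay$weight <= 0)) stopf("config error: empty expression weights")
  pools <- sim_codon_pool(sim, cfg)

  lens <- as.integer(names(cfg$length_dist))
  lprob <- as.numeric(cfg$length_dist)
  offs <- cfg$offset_truth

  n_spike <- stats::rbinom(1L, cfg$depth, cfg$spike_fraction)
  n_main <- cfg$depth - n_spike
  n_init <- stats::rbinom(1L, n_main, cfg$init_frac)
  n_elong <- n_main - n_init

  draw_lengths <- function(n) {
    l <- lens[sample.int(length(lens), n, replace = TRUE, prob = lprob)]
    list(len = l, off = as.integer(offs[as.character(l)]))
  }
  jitter <- function(n) {
    p <- cfg$periodicity
    sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c((1 - p) / 2, p, (1 - p) / 2))
  }

  # --- elongation: one global codon pool across genes ------------------------
  all_mid <- unlist(lapply(pools, `[[`, "mid_bio"), use.names = FALSE)
  all_w <- unlist(lapply(pools, `[[`, "w"), use.names = FALSE)
  all_gene <- rep(vapply(pools, `[[`, character(1), "gene_id"),
                  vapply(pools, function(p) length(p$w), integer(1)))
  all_strand <- rep(vapply(pools, `[[`, character(1), "strand"),
                    vapply(pools, function(p) length(p$w), integer(1)))
  idx <- sample.int(length(all_w), n_elong, replace = TRUE, prob = all_w)
  el <- draw_lengths(n_elong)
  a_bio <- all_mid[idx] + jitter(n_elong)
  p3 <- a_bio - el$off
  p5 <- p3 - el$len + 1L
  elong <- data.table::data.table(
    genome_id = genome$id, strand = all_strand[idx],
    p5 = p5, p3 = p3, length = el$len,
    src = "elong", gene_id = all_gene[idx]
  )

  # --- initiation ------------------------------------------------------------
  gene_w <- c(lay$weight, sim$layout$dorf$weight)
  gene_ids_i <- c(lay$gene_id, sim$layout$dorf$gene_id)
  gi <- sample.int(length(gene_w), n_init, replace = TRUE, prob = gene_w)
  init_list <- vector("list", length(gene_ids_i))
  full_need <- max(lens + as.integer(offs[as.character(lens)]) - 5L)
  jx <- sim$layout$junction
  uf <- cfg$junction_spec$unprocessed_fraction
  fold <- cfg$junction_spec$init_preference_fold
  p_unproc <- if (uf > 0) (uf * fold) / (uf * fold + (1 - uf)) else 0
  for (k in seq_along(gene_ids_i)) {
    n_k <- sum(gi == k)
    if (n_k == 0L) next
    gid <- gene_ids_i[k]
    if (gid == sim$layout$dorf$gene_id) {
      strand <- "+"
      s_bio <- sim$layout$dorf$start
      msg_bio <- lay$mrna_start[lay$gene_id == sim$layout$dorf$host]
      upstream <- s_bio - msg_bio
    } else {
      g <- lay[lay$gene_id == gid, ]
      strand <- g$strand
      s_bio <- if (strand == "+") g$cds_start else L - g$cds_end
      msg_bio <- if (strand == "+") g$mrna_start else L - g$mrna_end
      upstream <- s_bio - msg_bio
    }
    is_jx_dn <- identical(gid, jx$downstream)
    mode_full <- if (is_jx_dn) stats::runif(n_k) < p_unproc
                 else rep(upstream >= full_need, n_k)
    n_full <- sum(mode_full); n_ramp <- n_k - n_full
    parts <- list()
    if (n_full) {
      dl <- draw_lengths(n_full)
      p3f <- (s_bio + 4L) - dl$off
      parts$full <- data.table::data.table(
        genome_id = genome$id, strand = strand,
        p5 = p3f - dl$len + 1L, p3 = p3f, length = dl$len,
        src = "init_full", gene_id = gid
      )
    }
    if (n_ramp) {
      rl <- cfg$init_ramp_lengths[
        sample.int(length(cfg$init_ramp_lengths), n_ramp, replace = TRUE,
                   prob = cfg$init_ramp_weights)]
      parts$ramp <- data.table::data.table(
        genome_id = genome$id, strand = strand,
        p5 = msg_bio, p3 = msg_bio + rl - 1L, length = rl,
        src = "init_ramp", gene_id = gid
      )
    }
    init_list[[k]] <- data.table::rbindlist(parts)
  }
  init <- data.table::rbindlist(init_list)

  # --- spike-in --------------------------------------------------------------
  spike <- NULL
  if (n_spike > 0L) {
    sp_ann <- sim$spike_annotation
    sp_gen <- sim$spike_genome
    sp_cds <- ann_features(sp_ann, "CDS")
    sp_mid <- unlist(lapply(unique(sp_cds$gene_id), function(g) {
      pos <- feature_positions(sp_ann, g, "CDS")
      pos[seq(2L, length(pos), by = 3L)]
    }), use.names = FALSE)
    sp_gene <- rep(unique(sp_cds$gene_id),
                   vapply(unique(sp_cds$gene_id),
                          function(g) cds_length(sp_ann, g) %/% 3L, integer(1)))
    si <- sample.int(length(sp_mid), n_spike, replace = TRUE)
    sl <- draw_lengths(n_spike)
    a_bio <- sp_mid[si] + jitter(n_spike)
    p3 <- a_bio - sl$off
    spike <- data.table::data.table(
      genome_id = sp_gen$id, strand = "+",
      p5 = p3 - sl$len + 1L, p3 = p3, length = sl$len,
      src = "spike", gene_id = sp_gene[si]
    )
  }

  reads <- data.table::rbindlist(list(elong, init, spike))
  if (cfg$end_jitter) {
    reads[, "p5" := reads$p5 + sample(-1L:1L, nrow(reads), replace = TRUE)]
    reads[, "p3" := reads$p3 + sample(-1L:1L, nrow(reads), replace = TRUE)]
    reads[, "length" := reads$p3 - reads$p5 + 1L]
  }
  # biological -> genomic coordinates
  glen <- ifelse(reads$genome_id == genome$id, L, sim$spike_genome$length)
  reads[, "start" := ifelse(reads$strand == "+", reads$p5, glen - 1L - reads$p3)]
  reads[, "end" := ifelse(reads$strand == "+", reads$p3, glen - 1L - reads$p5) + 1L]
  reads[, c("p5", "p3") := NULL]
  reads[, "umi" := random_umis(nrow(reads), cfg$umi_width)]

  n_unique <- nrow(reads)
  if (cfg$pcr_dup_rate > 0) {
    ndup <- stats::rpois(n_unique, cfg$pcr_dup_rate)
    if (sum(ndup) > 0L) {
      reads <- reads[c(seq_len(n_unique), rep(seq_len(n_unique), ndup))]
    }
  }
  key <- paste(reads$genome_id, reads$start, reads$end, reads$strand, reads$umi)
  data.table::setcolorder(reads, c("genome_id", "start", "end", "strand",
                                   "length", "umi", "src", "gene_id"))

  truth <- list(
    depth = cfg$depth,
    n_unique_molecules = n_unique,
    n_unique_keys = length(unique(key)),
    n_emitted = nrow(reads),
    n_spike = n_spike, spike_fraction = cfg$spike_fraction,
    offsets = as.list(cfg$offset_truth),
    periodicity = cfg$periodicity,
    pause_mult = as.list(cfg$pause_mult),
    gene_weights = stats::setNames(as.list(lay$weight), lay$gene_id),
    dorf = sim$layout$dorf,
    junction = c(sim$layout$junction,
                 list(unprocessed_fraction = uf, init_preference_fold = fold,
                      p_init_unprocessed = p_unproc)),
    readthrough = list(prob = cfg$readthrough_prob,
                       continue = cfg$readthrough_continue)
  )
  list(reads = reads, truth = truth)
}

#' Simulate RNA-seq fragments over mature and precursor transcripts
#'
#' Transcript molecules are allocated to genes by expression weight; molecules
#' of the junction's downstream gene arise from the unprocessed bicistronic
#' precursor with probability \code{unprocessed_fraction}. Each molecule is
#' fragmented into consecutive 30-70-nt pieces (terminal remainders below
#' 30 nt are lost to size selection), so each processed downstream molecule
#' yields exactly one fragment whose 5' end sits at the processing site and
#' each precursor molecule yields one junction-spanning fragment.
#'
#' @param sim Output of \code{\link{make_toy_genome}}.
#' @param config A \code{\link{sim_config}} (\code{rna_depth} molecules).
#' @param seed RNG seed (default \code{config$seed + 2}).
#' @return list(\code{reads} = data.table(genome_id, start, end, strand,
#'   length, precursor), \code{truth}).
#' @export
simulate_rnaseq <- function(sim, config, seed = NULL) {
  validate_sim_config(config)
  with_seed(seed %||% (config$seed + 2L), sim_rnaseq_impl(sim, config))
}

sim_rnaseq_impl <- function(sim, cfg) {
  genome <- sim$genome
  L <- genome$length
  lay <- sim$layout$genes
  jx <- sim$layout$junction
  uf <- cfg$junction_spec$unprocessed_fraction

  gi <- sample.int(nrow(lay), cfg$rna_depth, replace = TRUE, prob = lay$weight)
  n_by_gene <- tabulate(gi, nrow(lay))
  frag_groups <- list()
  up <- lay[lay$gene_id == jx$upstream, ]
  for (i in seq_len(nrow(lay))) {
    g <- lay[i, ]
    n <- n_by_gene[i]
    if (n == 0L) next
    if (identical(g$gene_id, jx$downstream) && uf > 0) {
      n_pre <- stats::rbinom(1L, n, uf)
      if (n_pre > 0L)
        frag_groups[[paste0(g$gene_id, ".pre")]] <-
          list(start = up$mrna_start, end = g$mrna_end, strand = "+",
               n = n_pre, precursor = TRUE)
      n <- n - n_pre
      if (n == 0L) next
    }
    frag_groups[[g$gene_id]] <-
      list(start = g$mrna_start, end = g$mrna_end, strand = g$strand,
           n = n, precursor = FALSE)
  }

  out <- list()
  n_pre_mol <- 0L
  for (nm in names(frag_groups)) {
    fg <- frag_groups[[nm]]
    if (fg$precursor) n_pre_mol <- n_pre_mol + fg$n
    Lt <- fg$end - fg$start
    maxf <- ceiling(Lt / 30) + 1L
    lens <- matrix(sample(30:70, fg$n * maxf, replace = TRUE), nrow = fg$n)
    cums <- t(apply(lens, 1L, cumsum))
    relstart <- cbind(0L, cums[, -maxf, drop = FALSE])
    relend <- pmin(cums, Lt)
    keep <- relstart < Lt & (relend - relstart) >= 30L
    rs <- relstart[keep]; re <- relend[keep]
    if (fg$strand == "+") {
      st <- fg$start + rs; en <- fg$start + re
    } else {
      st <- fg$end - re; en <- fg$end - rs
    }
    out[[nm]] <- data.table::data.table(
      genome_id = genome$id, start = as.integer(st), end = as.integer(en),
      strand = fg$strand, length = as.integer(en - st),
      precursor = fg$precursor
    )
  }
  reads <- data.table::rbindlist(out)
  truth <- list(
    rna_depth = cfg$rna_depth,
    unprocessed_fraction = uf,
    n_precursor_molecules = n_pre_mol,
    junction = jx
  )
  list(reads = reads, truth = truth)
}
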
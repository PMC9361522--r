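test_that("codon occupancy is the 3-nt density over the CDS density", {
  w <- tiny_world(n_codons = 10L)
  cc <- codon_coords(w$annotation, "g1")
  plus <- integer(w$genome$length)
  plus[unlist(cc[3L, c("p1", "p2", "p3")]) + 1L] <- 10L  # 30 counts on codon 3
  occ <- codon_occupancy(manual_track(w$genome, plus = plus),
                         w$annotation, w$genome)
  expect_equal(occ$occupancy[occ$codon_index == 3L], 10)
  expect_equal(sum(occ$occupancy), 10)
  # uniform counts -> occupancy 1 everywhere
  plus_u <- integer(w$genome$length)
  plus_u[unlist(cc[, c("p1", "p2", "p3")]) + 1L] <- 4L
  occ_u <- codon_occupancy(manual_track(w$genome, plus = plus_u),
                           w$annotation, w$genome)
  expect_true(all(occ_u$occupancy == 1))
  # zero-count CDS flagged
  occ_0 <- codon_occupancy(manual_track(w$genome), w$annotation, w$genome)
  expect_true(all(is.na(occ_0$occupancy)))
  expect_equal(attr(occ_0, "zero_genes"), "g1")
})

test_that("occupancy normalization invariant holds on simulated data", {
  st <- default_pipeline_state()
  occ <- codon_occupancy(st$track, st$sim$annotation, st$sim$genome)
  occ <- occ[!is.na(occ$occupancy)]
  for (g in unique(occ$gene_id)) {
    o <- occ[occ$gene_id == g]
    expect_equal(sum(o$occupancy * 3) / (3 * nrow(o)), 1, tolerance = 1e-9)
  }
})

test_that("pause_table aggregates identities, flags pauses and singletons", {
  occ <- data.table::data.table(
    gene_id = "g", codon_index = 1:6,
    codon = c("GAC", "GAC", "CTA", "AAA", "AAA", "AGA"),
    counts = 1L, occupancy = c(3.6, 3.4, 1.9, 0.5, 0.6, 2.0)
  )
  pt <- pause_table(occ)
  expect_equal(pt$mean_occupancy[pt$codon == "GAC"], 3.5)
  expect_equal(pt$codon[pt$flagged], "GAC")
  expect_true(pt$single_instance[pt$codon == "AGA"])
  expect_false("TTT" %in% pt$codon)  # absent identity -> omitted row
  # replicates aggregate by mean with min-max range
  occ2 <- data.table::copy(occ); occ2$occupancy <- occ2$occupancy + 1
  pt2 <- pause_table(list(occ, occ2))
  expect_equal(pt2$mean_occupancy[pt2$codon == "CTA"], 2.4)
  expect_equal(pt2$min[pt2$codon == "CTA"], 1.9)
  expect_equal(pt2$max[pt2$codon == "CTA"], 2.9)
  # all-uniform occupancies: no flags
  occ_u <- data.table::copy(occ); occ_u$occupancy <- 1
  expect_false(any(pause_table(occ_u)$flagged))
})

test_that("initiation profiles show the clamped 15-nt-to-full-length ramp", {
  study <- default_study()
  prof <- initiation_profile(study$footprints$reads, study$sim$annotation,
                             study$sim$genome, "mtg01")
  expect_equal(sum(prof$end5), sum(prof$end3))
  m5 <- prof$end5
  sub30 <- rownames(m5)[as.integer(rownames(m5)) < 30L]
  # 5' ends of half footprints pile at the message start (relative 0)
  expect_gt(sum(m5[sub30, "0"]), 0.9 * sum(m5[sub30, ]))
  # 3' ends form a length diagonal: length l ends at l-1
  m3 <- prof$end3
  for (l in c(15L, 20L, 25L)) {
    expect_gt(m3[as.character(l), as.character(l - 1L)],
              0.9 * sum(m3[as.character(l), ]))
  }
  expect_error(initiation_profile(study$footprints$reads,
                                  study$sim$annotation, study$sim$genome,
                                  "nope"), "unknown gene")
})

test_that("no sub-30-nt enrichment without the initiation ramp", {
  cfg <- sim_config(seed = 41L, depth = 2e4L, init_frac = 0)
  sim <- make_toy_genome(cfg)
  fp <- simulate_footprints(sim, cfg)
  prof <- initiation_profile(fp$reads, sim$annotation, sim$genome, "mtg01")
  sub30 <- rownames(prof$end5)[as.integer(rownames(prof$end5)) < 30L]
  expect_equal(sum(prof$end5[sub30, ]), 0L)
})

test_that("junction RNA fractions count at-start vs spanning reads", {
  study <- default_study()
  ann <- study$sim$annotation
  j <- ann$junctions$position[1]
  r <- data.table::data.table(
    genome_id = "mito_toy",
    start = c(rep(j, 70), rep(j - 20L, 30)),
    end = c(rep(j + 40L, 70), rep(j + 20L, 30)),
    strand = "+"
  )
  r$length <- r$end - r$start
  fr <- junction_rna_fractions(r, ann)
  expect_equal(fr$processed_frac, 0.7)
  expect_equal(fr$unprocessed_frac, 0.3)
  expect_warning(f0 <- junction_rna_fractions(r[0], ann), "no informative")
  expect_false(f0$defined)
  # spanning requires k nt on both sides
  r_edge <- data.table::data.table(genome_id = "mito_toy", start = j - 3L,
                                   end = j + 3L, strand = "+", length = 6L)
  expect_warning(
    f_edge <- junction_rna_fractions(r_edge, ann, k = 4L),
    "no informative")
  expect_equal(f_edge$n_spanning, 0L)
})

test_that("junction initiation fold-preference matches hand arithmetic", {
  study <- default_study()
  ann <- study$sim$annotation
  genome <- study$sim$genome
  j <- ann$junctions$position[1]
  offs <- data.frame(length = 31L, offset = -14L)
  # processed: 5' end exactly at the start (short clamped footprints)
  proc <- data.table::data.table(
    genome_id = genome$id, start = j, end = j + 20L, strand = "+",
    length = 20L
  )[rep(1L, 40L)]
  # unprocessed: full-length, P site on the start codon, 5' end upstream
  unproc <- data.table::data.table(
    genome_id = genome$id, start = j + 18L - 30L, end = j + 19L,
    strand = "+", length = 31L
  )[rep(1L, 20L)]
  rna <- list(processed_frac = 0.7, unprocessed_frac = 0.3, defined = TRUE)
  res <- junction_initiation(rbind(proc, unproc), ann, genome, offs, rna)
  expect_equal(res$n_processed, 40L)
  expect_equal(res$n_unprocessed, 20L)
  expect_equal(res$fold_preference, (20 / 40) / (30 / 70), tolerance = 1e-12)
  # no unprocessed RNA -> fold undefined
  rna0 <- list(processed_frac = 1, unprocessed_frac = 0, defined = TRUE)
  expect_warning(res0 <- junction_initiation(proc, ann, genome, offs, rna0),
                 "undefined")
  expect_true(is.na(res0$fold_preference))
})

test_that("fold-preference is invariant to uniform read-depth scaling", {
  st <- default_pipeline_state()
  rna <- junction_rna_fractions(st$study$rnaseq$reads, st$sim$annotation)
  r1 <- junction_initiation(st$reads, st$sim$annotation, st$sim$genome,
                            st$offsets, rna)
  doubled <- rbind(st$reads, st$reads)
  r2 <- junction_initiation(doubled, st$sim$annotation, st$sim$genome,
                            st$offsets, rna)
  expect_equal(r1$fold_preference, r2$fold_preference, tolerance = 1e-12)
})

test_that("readthrough index is the in-frame UTR/CDS density ratio", {
  w <- tiny_world(n_codons = 20L, utr3_len = 21L)
  cc <- codon_coords(w$annotation, "g1")
  plus <- integer(w$genome$length)
  plus[cc$p2 + 1L] <- 6L                      # uniform in-frame CDS signal
  rt0 <- readthrough_index(manual_track(w$genome, plus = plus),
                           w$annotation, w$genome, "g1")
  expect_equal(rt0$index, 0)
  utr_mid <- mitoribo:::feature_positions(w$annotation, "g1", "UTR3")
  utr_mid <- utr_mid[seq(2L, 21L, by = 3L)]
  plus[utr_mid + 1L] <- 6L                     # UTR equals CDS density
  rt1 <- readthrough_index(manual_track(w$genome, plus = plus),
                           w$annotation, w$genome, "g1")
  expect_equal(rt1$index, 1)
  w_short <- tiny_world(n_codons = 20L, utr3_len = 9L)
  expect_error(readthrough_index(manual_track(w_short$genome),
                                 w_short$annotation, w_short$genome, "g1"),
               "shorter than 5")
})

test_that("simulated read-through recovers the geometric closed form", {
  cfg <- sim_config(seed = 43L, depth = 5e5L)
  sim <- make_toy_genome(cfg)
  fp <- simulate_footprints(sim, cfg)
  flt <- filter_lengths(dedup_umi(fp$reads))
  off <- calibrate_offsets(flt, sim$genome, sim$annotation)
  tr <- asite_transform(flt, off, sim$genome)
  rt <- readthrough_index(tr, sim$annotation, sim$genome, "mtg02")
  J <- 15L
  expected <- cfg$readthrough_prob *
    sum(cfg$readthrough_continue^(seq_len(J) - 1L)) / J
  expect_lt(abs(rt$index - expected) / expected, 0.4)
})

test_that("read-length distributions discriminate footprints from short fragments", {
  r_same <- data.table::data.table(genome_id = "g", start = 0L, end = 31L,
                                   strand = "+", length = rep(31L, 50))
  reg <- list(start = 0L, end = 31L)
  same <- length_dist_compare(rbind(r_same, r_same), reg, reg)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  r_b <- data.table::copy(r_same); r_b$length <- 15L
  r_b$start <- 100L; r_b$end <- 115L
  both <- rbind(r_same, r_b)
  dis <- length_dist_compare(both, reg, list(start = 100L, end = 115L))
  expect_equal(dis$statistic, 1)
  expect_error(length_dist_compare(r_same[1:2], reg, reg), "underpowered")
  # dORF-overlapping simulated reads vs constructed tRNA-protected fragments
  study <- default_study()
  d <- study$sim$layout$dorf
  trna <- mitoribo:::ann_features(study$sim$annotation, "tRNA")[3, ]
  frag <- data.table::data.table(
    genome_id = study$sim$genome$id,
    start = trna$start + 5L, end = trna$start + 5L + 22:25,
    strand = "+", length = 22:25
  )[rep(1:4, 60)]
  ks <- length_dist_compare(
    rbind(study$footprints$reads[, c("genome_id", "start", "end", "strand",
                                     "length")], frag),
    list(start = d$start, end = d$end, strand = "+"),
    list(start = trna$start, end = trna$end, strand = "+")
  )
  expect_lt(ks$p_value, 0.05)
})

test_that("early-codon synthesis uses leader-dependent windows and normalizes", {
  w <- tiny_world(n_codons = 20L)
  cc <- codon_coords(w$annotation, "g1")
  plus <- integer(w$genome$length)
  # leaderless gene: window is codons 6-9
  idx <- unlist(cc[6:9, c("p1", "p2", "p3")])
  plus[idx + 1L] <- 1L
  ec <- early_codon_synthesis(manual_track(w$genome, plus = plus),
                              w$annotation, w$genome)
  expect_equal(ec$window_first, 6L)
  expect_equal(ec$value, 1)
  st <- default_pipeline_state()
  ec2 <- early_codon_synthesis(st$track, st$sim$annotation, st$sim$genome)
  expect_equal(sum(ec2$value), 1)
  expect_equal(ec2$window_first[ec2$gene_id == "mtg05"], 2L)
  expect_equal(ec2$window_first[ec2$gene_id == "mtg07.dorf"], 2L)
  expect_equal(ec2$window_first[ec2$gene_id == "mtg01"], 6L)
})

test_that("a dORF weighted like a UTR-class gene shows comparable early synthesis", {
  cfg <- sim_config(seed = 47L, depth = 3e5L,
                    dorf_spec = list(host = "mtg07", offset = 10L,
                                     n_codons = 4L, weight = 1.6))
  sim <- make_toy_genome(cfg)
  fp <- simulate_footprints(sim, cfg)
  flt <- filter_lengths(dedup_umi(fp$reads))
  off <- calibrate_offsets(flt, sim$genome, sim$annotation)
  tr <- asite_transform(flt, off, sim$genome)
  ec <- early_codon_synthesis(tr, sim$annotation, sim$genome)
  v_dorf <- ec$value[ec$gene_id == "mtg07.dorf"]
  v_ref <- ec$value[ec$gene_id == "mtg05"]  # UTR-class gene, equal weight
  expect_lt(abs(v_dorf / v_ref - 1), 0.3)
})
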
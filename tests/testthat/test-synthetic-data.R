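test_that("toy genome generation is deterministic and byte-stable", {
  cfg <- sim_config(seed = 7L, depth = 1000L)
  s1 <- make_toy_genome(cfg)
  s2 <- make_toy_genome(cfg)
  expect_identical(s1$genome$sequence, s2$genome$sequence)
  expect_identical(s1$annotation$features, s2$annotation$features)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  for (d in c(d1, d2)) dir.create(d, showWarnings = FALSE)
  write_genome_fasta(s1$genome, file.path(d1, "g.fa"))
  write_genome_fasta(s2$genome, file.path(d2, "g.fa"))
  write_annotation_gff3(s1$annotation, file.path(d1, "a.gff3"))
  write_annotation_gff3(s2$annotation, file.path(d2, "a.gff3"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "a.gff3")),
                   readLines(file.path(d2, "a.gff3")))
  f1 <- simulate_footprints(s1, cfg)
  f2 <- simulate_footprints(s2, cfg)
  expect_identical(f1$reads, f2$reads)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(gene_specs = default_gene_specs()[0, ]),
               "zero genes")
  expect_error(sim_config(length_dist = c("31" = 0.5)), "sum to 1")
  expect_error(sim_config(length_dist = c("28" = 1),
                          offset_truth = c("31" = -14L)), "cover every length")
  expect_error(sim_config(spike_fraction = 1.2), "\\[0, 1\\]")
})

test_that("genes overflowing the genome are a config error", {
  cfg <- sim_config(genome_len = 4000L)
  expect_error(make_toy_genome(cfg), "overflow")
})

test_that("the injected dORF round-trips through ORF scanning", {
  study <- default_study()
  sim <- study$sim
  orf <- first_start_in_utr3(sim$genome, sim$annotation, "mtg07")
  expect_equal(orf$start, sim$layout$dorf$start)
  expect_equal(orf$codons, sim$layout$dorf$n_codons)
  expect_equal(orf$start_codon, "ATG")
  # dORF stop context promotes read-through: followed by C
  after <- mitoribo:::genome_base(sim$genome,
                                  sim$layout$dorf$end)
  expect_equal(after, "C")
})

test_that("perfect periodicity forces every elongation A-site onto a middle base", {
  cfg <- sim_config(seed = 3L, depth = 3000L, periodicity = 1,
                    init_frac = 0, spike_fraction = 0,
                    length_dist = c("31" = 1),
                    offset_truth = c("31" = -14L))
  sim <- make_toy_genome(cfg)
  fp <- simulate_footprints(sim, cfg)
  r <- fp$reads
  expect_true(all(r$length == 31L))
  cls <- mitoribo:::cds_frame_classes(sim$annotation, sim$genome)
  a_bio <- mitoribo:::bio_pos(sim$genome, mitoribo:::read_end3_genomic(r),
                              r$strand) - 14L
  a_gen <- mitoribo:::genomic_pos(sim$genome, a_bio, r$strand)
  acls <- ifelse(r$strand == "+", cls$plus[a_gen + 1L], cls$minus[a_gen + 1L])
  # read-through A-sites sit in UTRs (class NA); all in-CDS ones are middles
  expect_true(all(acls[!is.na(acls)] == 1L))
  expect_gt(mean(!is.na(acls)), 0.95)
})

test_that("spike-in fraction matches the binomial expectation", {
  cfg <- sim_config(seed = 9L, depth = 2e4L, spike_fraction = 0.05)
  sim <- make_toy_genome(cfg)
  fp <- simulate_footprints(sim, cfg)
  frac <- mean(fp$reads$genome_id == sim$spike_genome$id)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2e4))
})

test_that("PCR duplicate bookkeeping is exact", {
  cfg <- sim_config(seed = 13L, depth = 5000L, pcr_dup_rate = 0.5)
  sim <- make_toy_genome(cfg)
  fp <- simulate_footprints(sim, cfg)
  expect_equal(fp$truth$n_unique_molecules, 5000L)
  expect_equal(nrow(fp$reads), fp$truth$n_emitted)
  expect_gt(fp$truth$n_emitted, 5000L)
  dd <- dedup_umi(fp$reads)
  expect_equal(nrow(dd), fp$truth$n_unique_keys)
})

test_that("RNA fragments respect size selection and junction structure", {
  cfg0 <- sim_config(seed = 21L, rna_depth = 3000L,
                     junction_spec = list(upstream = "mtg03",
                                          downstream = "mtg04",
                                          unprocessed_fraction = 0,
                                          init_preference_fold = 1))
  sim <- make_toy_genome(cfg0)
  rna0 <- simulate_rnaseq(sim, cfg0)
  expect_true(all(rna0$reads$length >= 30L & rna0$reads$length <= 70L))
  j <- sim$layout$junction$position
  spanning <- rna0$reads$start <= j - 1L & rna0$reads$end >= j + 1L
  expect_equal(sum(spanning), 0L)

  cfg3 <- sim_config(seed = 21L, rna_depth = 20000L)
  rna3 <- simulate_rnaseq(sim, cfg3)
  fr <- junction_rna_fractions(rna3$reads, sim$annotation)
  expect_lt(abs(fr$unprocessed_frac - 0.3),
            4 * sqrt(0.3 * 0.7 / fr$n_informative))
})

test_that("variant catalog honors rate zero and full conservative bias", {
  study <- default_study()
  cfg <- study$config
  cfg$variant_spec$rate <- 0
  cfg$variant_spec$target_bias <- 1
  v <- simulate_variant_catalog(study$sim, cfg)
  # only the target ATG carries variants
  sites <- find_phase_matched_atgs(study$sim$genome, study$sim$annotation)
  tgt <- sites[sites$position == v$truth$target_position, ]
  expect_true(all(v$variants$position %in%
                  c(tgt$pos1, tgt$pos2, tgt$pos3)))
  filled <- classify_snvs(tgt, v$variants, study$sim$genome,
                          weight = "carrier")
  expect_equal(filled$conservative_fraction, 1)
  expect_equal(filled$n_snvs, 255L)
  # determinism
  v2 <- simulate_variant_catalog(study$sim, cfg)
  expect_identical(v$variants, v2$variants)
})

test_that("initiation half-footprints are clamped at leaderless message starts", {
  study <- default_study()
  r <- study$footprints$reads
  ramp <- r[r$src == "init_ramp" & r$gene_id == "mtg01"]
  lay <- study$sim$layout$genes
  expect_gt(nrow(ramp), 50L)
  expect_true(all(ramp$start == lay$mrna_start[lay$gene_id == "mtg01"]))
  expect_true(all(ramp$length >= 15L & ramp$length <= 34L))
  # long-leader anchors initiate with full-length footprints only
  full <- r[r$src == "init_full" & r$gene_id == "mtg05"]
  expect_true(all(full$length >= 30L))
  expect_equal(nrow(r[r$src == "init_ramp" & r$gene_id == "mtg05"]), 0L)
})
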
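two_gene_ann <- function(s1 = 0L, n1 = 100L, s2 = 400L, n2 = 100L,
                         strand2 = "+") {
  mt_annotation(data.frame(
    gene_id = c("a", "b"), kind = "CDS", strand = c("+", strand2),
    start = c(s1, s2), end = c(s1 + 3L * n1, s2 + 3L * n2),
    complex_id = c("CI", "CIII"), stoichiometry = 1
  ))
}

test_that("build_mask excludes first-6-codon spans and CDS overlaps", {
  ann <- two_gene_ann()
  m <- build_mask(ann, "footprint")
  expect_equal(nrow(m), 2L)
  expect_true(all(m$end - m$start == 18L))
  # effective lengths after masking: 300 - 18
  g <- mt_genome("g", strrep("A", 800))
  cnt <- count_gene(data.table::data.table(
    genome_id = "g", start = integer(0), end = integer(0),
    strand = character(0), length = integer(0)),
    ann, g, mito_footprint_spec())
  expect_equal(cnt$eff_length, c(282L, 282L))
  # overlap of 30 nt masked for both genes
  ann_ov <- two_gene_ann(s1 = 0L, s2 = 270L)
  m_ov <- build_mask(ann_ov, "footprint")
  expect_true(any(m_ov$start == 270L & m_ov$end == 300L))
  # rna mode: overlaps only; nuclear mask empty
  expect_equal(nrow(build_mask(ann_ov, "rna")), 1L)
  expect_equal(nrow(build_mask(ann, "rna")), 0L)
  expect_equal(nrow(build_mask(ann, "footprint", compartment = "nuclear")), 0L)
  expect_equal(nrow(build_mask(mt_annotation(
    data.frame(gene_id = character(), kind = character(),
               strand = character(), start = integer(),
               end = integer())), "footprint")), 0L)
})

test_that("footprint counting lands at the shifted 3' end outside the mask", {
  ann <- two_gene_ann()
  g <- mt_genome("g", strrep("A", 800))
  # mito spec: count position = 3' end - 14 -> 86, inside unmasked CDS of a
  r <- data.table::data.table(genome_id = "g", start = 70L, end = 101L,
                              strand = "+", length = 31L)
  cnt <- count_gene(r, ann, g, mito_footprint_spec())
  expect_equal(cnt$counts[cnt$gene_id == "a"], 1)
  # a read whose count position falls in the first-6-codon mask is dropped
  r_mask <- data.table::data.table(genome_id = "g", start = 0L, end = 31L,
                                   strand = "+", length = 31L)
  cnt2 <- count_gene(r_mask, ann, g, mito_footprint_spec())
  expect_equal(sum(cnt2$counts), 0)
  # strand specificity
  r_minus <- data.table::copy(r); r_minus$strand <- "-"
  expect_equal(sum(count_gene(r_minus, ann, g,
                              mito_footprint_spec())$counts), 0)
})

test_that("RNA counting requires the minimum CDS overlap", {
  ann <- two_gene_ann()
  g <- mt_genome("g", strrep("A", 800))
  mk <- function(start, end) data.table::data.table(
    genome_id = "g", start = start, end = end, strand = "+",
    length = end - start)
  mask <- build_mask(ann, "rna")
  # CDS of a spans [0,300); overlap 22 vs 21 around the downstream edge
  expect_equal(sum(count_gene(mk(278L, 340L), ann, g, rna_counting_spec(),
                              mask = mask)$counts), 1)
  expect_equal(sum(count_gene(mk(279L, 340L), ann, g, rna_counting_spec(),
                              mask = mask)$counts), 0)
})

test_that("relative values are RPK shares on the compartment scale", {
  cnt <- data.table::data.table(
    gene_id = c("a", "b"), counts = c(30, 30), eff_length = c(300L, 600L),
    complex_id = c("CI", "CIII"), stoichiometry = 1
  )
  sv <- relative_values(cnt, "mito")
  expect_equal(sv$value, c(10000 * 2 / 3, 10000 / 3), tolerance = 1e-9)
  expect_equal(sum(sv$value), 10000)
  expect_equal(attr(sv, "unit"), "tpm/100")
  one <- relative_values(cnt[1], "mito")
  expect_equal(one$value, 10000)
  nuc <- relative_values(cnt, "nuclear")
  expect_equal(sum(nuc$value), 1e6)
  expect_equal(attr(nuc, "unit"), "tpm")
  cnt0 <- data.table::copy(cnt); cnt0$counts <- 0
  expect_error(relative_values(cnt0, "mito"), "zero total RPK")
  cntL <- data.table::copy(cnt); cntL$eff_length[1] <- 0L
  expect_error(relative_values(cntL, "mito"), "effective lengths")
})

test_that("paralog families are summed into single rows", {
  tab <- data.table::data.table(
    gene_id = c("a", "b", "c"), counts = c(5, 7, 2),
    eff_length = c(100L, 200L, 50L), complex_id = "CIV", stoichiometry = 1,
    rpk = c(50, 35, 40), value = c(5, 7, 2), compartment = "nuclear"
  )
  out <- sum_paralogs(tab, list(ab = c("a", "b")))
  expect_equal(sort(out$gene_id), c("ab", "c"))
  expect_equal(out$value[out$gene_id == "ab"], 12)
  expect_equal(out$eff_length[out$gene_id == "ab"], 300L)
  expect_identical(sum_paralogs(tab, list()), tab)
  expect_error(sum_paralogs(tab, list(x = c("a", "b"), y = c("b", "c"))),
               "overlapping")
  expect_warning(sum_paralogs(tab, list(az = c("a", "zzz"))), "members present")
})

test_that("complex averages, correlation, stoichiometry, and spread", {
  tab <- data.table::data.table(
    gene_id = sprintf("g%d", 1:7),
    complex_id = c("CI", "CI", "CI", "CIII", "CIII", "CIV", "CV"),
    value = c(2, 4, 6, 1, 3, 8, 5)
  )
  avg <- complex_averages(tab)
  expect_equal(avg$average[avg$complex_id == "CI"], 4)
  expect_equal(avg$average[avg$complex_id == "CV"], 5)
  # permutation invariance
  avg2 <- complex_averages(tab[sample(7)])
  expect_equal(avg, avg2)

  mk_avg <- function(v) data.table::data.table(
    complex_id = c("CI", "CIII", "CIV"), average = v)
  expect_equal(balance_correlation(mk_avg(c(1, 2, 3)), mk_avg(c(2, 4, 6))), 1)
  expect_equal(balance_correlation(mk_avg(c(1, 2, 3)), mk_avg(c(6, 4, 2))), -1)
  expect_error(balance_correlation(mk_avg(c(1, 2, 3))[1:2],
                                   mk_avg(c(1, 2, 3))[1:2]), ">= 3")
  # invariance to positive rescaling of either compartment
  set.seed(1)
  a <- mk_avg(runif(3)); b <- mk_avg(runif(3))
  b2 <- data.table::copy(b); b2$average <- b2$average * 42
  expect_equal(balance_correlation(a, b), balance_correlation(a, b2),
               tolerance = 1e-12)

  st <- stoichiometry_of_averages(data.table::data.table(
    complex_id = c("CI", "CIII", "CIV"), average = c(2, 6, 8)))
  expect_equal(unname(st[c("CI", "CIII", "CIV")]), c(1, 3, 4))
  st_eq <- stoichiometry_of_averages(data.table::data.table(
    complex_id = c("CI", "CIII"), average = c(6, 6)))
  expect_true(all(st_eq == 3))
  expect_error(stoichiometry_of_averages(data.table::data.table(
    complex_id = "CI", average = 1)), "reference complex")

  sp <- fold_spread(data.table::data.table(
    gene_id = c("x", "y", "z"), complex_id = "CI", value = c(1, 2, 4)))
  expect_equal(sort(sp$per_gene$log2_diff), c(-1, 0, 1))
  expect_equal(sp$within_2fold_share, 1)
  sp8 <- fold_spread(data.table::data.table(
    gene_id = c("x", "y", "z"), complex_id = "CI", value = c(1, 1, 8)))
  expect_equal(max(sp8$per_gene$log2_diff), 3)
  expect_equal(sp8$within_2fold_share, 2 / 3)
})

test_that("simulated counts recover the expression weights", {
  st <- default_pipeline_state()
  sim <- st$sim
  genes <- setdiff(mitoribo:::gene_ids(sim$annotation, "CDS"), "mtg07.dorf")
  cnt <- count_gene(st$reads, sim$annotation, sim$genome,
                    mito_footprint_spec(), genes = genes)
  sv <- relative_values(cnt, "mito")
  expect_equal(sum(sv$value), 10000, tolerance = 1e-6)
  lay <- sim$layout$genes
  # codon sampling is uniform within genes, so RPK is proportional to the
  # expression weight alone
  truth <- lay$weight / sum(lay$weight) * 1e4
  got <- sv$value[match(lay$gene_id, sv$gene_id)]
  expect_lt(max(abs(got - truth) / truth), 0.12)
})

test_that("mitonuclear balance recovers the preset complex structure", {
  st <- default_pipeline_state()
  sim <- st$sim
  genes <- setdiff(mitoribo:::gene_ids(sim$annotation, "CDS"), "mtg07.dorf")
  sv_m <- relative_values(count_gene(st$reads, sim$annotation, sim$genome,
                                     mito_footprint_spec(), genes = genes),
                          "mito")
  cyto <- cached("cyto", make_toy_cyto())
  cr <- cached("cyto_reads",
               simulate_cyto_footprints(cyto, 2e5, st$study$config))
  sv_n <- sum_paralogs(
    relative_values(count_gene(cr, cyto$annotation, cyto$genome,
                               cyto_footprint_spec(),
                               mask = build_mask(cyto$annotation,
                                                 compartment = "nuclear")),
                    "nuclear"),
    cyto$annotation$families
  )
  am <- complex_averages(sv_m)
  an <- complex_averages(sv_n)
  # complex-average order rises CI < CIII < CIV < CV in both compartments
  ord <- c("CI", "CIII", "CIV", "CV")
  expect_equal(am$complex_id[order(am$average)], ord)
  expect_equal(an$complex_id[order(an$average)], ord)
  expect_gt(balance_correlation(am, an), 0.9)
  # nuclear core-subunit filter restricts the averages
  core <- default_cyto_specs()
  an_core <- complex_averages(sv_n, core_genes = core$gene_id[core$core])
  expect_true(all(an_core$n_subunits <= an$n_subunits))
})
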
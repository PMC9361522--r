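# Shared fixtures. The default simulated study is computed once per test run
# and reused across files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# Moderate-depth default study shared by several files.
default_study <- function() {
  cached("default_study", {
    cfg <- sim_config(depth = 2e5, seed = 11L)
    simulate_study(cfg)
  })
}

default_pipeline_state <- function() {
  cached("default_state", {
    study <- default_study()
    sim <- study$sim
    reads <- dedup_umi(study$footprints$reads)
    flt <- filter_lengths(reads)
    offsets <- calibrate_offsets(flt, sim$genome, sim$annotation)
    track <- asite_transform(flt, offsets, sim$genome)
    list(study = study, sim = sim, reads = reads, flt = flt,
         offsets = offsets, track = track)
  })
}

# Minimal single-gene genome/annotation for constructed-track tests:
# one heavy-strand CDS of `n_codons` codons starting at `cds_start`.
tiny_world <- function(n_codons = 10L, cds_start = 30L, genome_len = 200L,
                       seed = 5L, utr3_len = 0L) {
  set.seed(seed)
  cds_nt <- 3L * n_codons
  seq <- paste(sample(c("C", "G", "T"), genome_len, replace = TRUE),
               collapse = "")
  coding <- paste0("ATG",
                   paste(sample(setdiff(mitoribo:::NONSTOP_CODONS, "ATG"),
                                n_codons - 2L, replace = TRUE), collapse = ""),
                   "TAA")
  substr(seq, cds_start + 1L, cds_start + cds_nt) <- coding
  genome <- mt_genome("tiny", seq, circular = TRUE)
  feats <- data.frame(
    gene_id = "g1", kind = c("mRNA", "CDS"), strand = "+",
    start = cds_start, end = cds_start + cds_nt + c(utr3_len, 0L),
    part = 1L, leader_len = 0, complex_id = NA_character_,
    stoichiometry = NA_real_, family = NA_character_
  )
  if (utr3_len > 0L) {
    feats <- rbind(feats, data.frame(
      gene_id = "g1", kind = "UTR3", strand = "+",
      start = cds_start + cds_nt, end = cds_start + cds_nt + utr3_len,
      part = 1L, leader_len = 0, complex_id = NA_character_,
      stoichiometry = NA_real_, family = NA_character_
    ))
  }
  list(genome = genome, annotation = mt_annotation(feats),
       cds_start = cds_start, n_codons = n_codons)
}

# Bare A-site track with given count vectors.
manual_track <- function(genome, plus = NULL, minus = NULL) {
  L <- genome$length
  structure(list(
    genome_id = genome$id, length = L, circular = genome$circular,
    plus = if (is.null(plus)) integer(L) else plus,
    minus = if (is.null(minus)) integer(L) else minus,
    n_reads = sum(plus %||% 0L) + sum(minus %||% 0L), n_dropped = 0L
  ), class = "asite_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pause-multiplier estimate: mean occupancy of a codon identity normalized by
# the genome-wide median codon occupancy (the unpaused baseline).
pause_estimate <- function(pt, codon) {
  pt$mean_occupancy[pt$codon == codon] / stats::median(pt$mean_occupancy)
}
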
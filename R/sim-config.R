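#' Simulation configuration for synthetic mitoribosome-profiling studies
#'
#' Describes a toy circular genome and the footprint/RNA/variant data
#' simulated on it. Defaults emulate the study conditions the pipeline is
#' designed for: 30-34-nt footprints with per-length 3'-end offsets
#' (30:-13, 31:-14, 32:-15, 33:-15, 34:-15), strong but imperfect 3-nt
#' periodicity, 15-nt-to-full-length initiation half-footprints on leaderless
#' messages, one unprocessed bicistronic junction, a translated 4-codon dORF
#' in a 3' UTR, a 5\% spike-in genome fraction, and UMI-tagged PCR duplicates.
#'
#' @param seed Integer seed; all generator output is deterministic given the
#'   seed and config.
#' @param genome_len Toy genome length (nt).
#' @param gene_specs data.frame describing the mRNA genes (see
#'   \code{\link{default_gene_specs}}).
#' @param dorf_spec list(host, offset, n_codons, weight): downstream ORF
#'   injected into the host gene's 3' UTR at \code{offset} nt.
#' @param junction_spec list(upstream, downstream, unprocessed_fraction,
#'   init_preference_fold): the bicistronic processing junction.
#' @param length_dist Named probabilities over elongation read lengths.
#' @param offset_truth Named signed 3'-end offsets per read length (nt to add
#'   to the 3'-end coordinate to reach the A-site middle base).
#' @param periodicity Probability that an A-site lands on the true codon
#'   middle base; the remainder is split evenly over the flanking bases.
#' @param pause_mult Named per-codon dwell multipliers (e.g.
#'   \code{c(GAC = 3)}); unlisted codons have multiplier 1.
#' @param init_frac Fraction of footprints that are initiation footprints.
#' @param init_ramp_lengths,init_ramp_weights Length distribution of clamped
#'   initiation half-footprints on leaderless / short-leader messages.
#' @param readthrough_prob Probability that a terminating ribosome reads
#'   through a stop codon followed by C.
#' @param readthrough_continue Per-codon continuation probability of the
#'   geometric read-through extension.
#' @param spike_fraction Fraction of footprints drawn from the spike genome.
#' @param pcr_dup_rate Expected number of PCR duplicate copies per molecule.
#' @param depth Total unique footprint molecules.
#' @param rna_depth RNA-seq transcript molecules to fragment.
#' @param umi_width UMI width in nt.
#' @param end_jitter Add +/-1 nt uniform digestion noise to both read ends
#'   (off by default).
#' @param variant_spec list(rate, target_bias, target_mean_snvs,
#'   target_carriers, background_mean_carriers): variant-catalog generator
#'   settings (see \code{\link{simulate_variant_catalog}}).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       genome_len = 6200L,
                       gene_specs = default_gene_specs(),
                       dorf_spec = list(host = "mtg07", offset = 10L,
                                        n_codons = 4L, weight = 0.5),
                       junction_spec = list(upstream = "mtg03",
                                            downstream = "mtg04",
                                            unprocessed_fraction = 0.3,
                                            init_preference_fold = 4),
                       length_dist = c("30" = 0.10, "31" = 0.35, "32" = 0.30,
                                       "33" = 0.15, "34" = 0.10),
                       offset_truth = c("30" = -13L, "31" = -14L, "32" = -15L,
                                        "33" = -15L, "34" = -15L),
                       periodicity = 0.8,
                       pause_mult = c(),
                       init_frac = 0.08,
                       init_ramp_lengths = 15:34,
                       init_ramp_weights = NULL,
                       readthrough_prob = 0.1,
                       readthrough_continue = 0.5,
                       spike_fraction = 0.05,
                       pcr_dup_rate = 0,
                       depth = 1e5,
                       rna_depth = 2e4,
                       umi_width = 10L,
                       end_jitter = FALSE,
                       variant_spec = list(rate = 0.25, target_bias = 219 / 255,
                                           target_carriers = 255L,
                                           background_mean_carriers = 4)) {
  cfg <- list(
    seed = as.integer(seed), genome_len = as.integer(genome_len),
    gene_specs = as.data.frame(gene_specs, stringsAsFactors = FALSE),
    dorf_spec = dorf_spec, junction_spec = junction_spec,
    length_dist = length_dist, offset_truth = offset_truth,
    periodicity = periodicity, pause_mult = pause_mult,
    init_frac = init_frac,
    init_ramp_lengths = as.integer(init_ramp_lengths),
    init_ramp_weights = init_ramp_weights %||%
      rep(1, length(init_ramp_lengths)),
    readthrough_prob = readthrough_prob,
    readthrough_continue = readthrough_continue,
    spike_fraction = spike_fraction, pcr_dup_rate = pcr_dup_rate,
    depth = as.integer(depth), rna_depth = as.integer(rna_depth),
    umi_width = as.integer(umi_width), end_jitter = isTRUE(end_jitter),
    variant_spec = variant_spec
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (nrow(cfg$gene_specs) == 0L) stopf("config error: zero genes")
  if (abs(sum(cfg$length_dist) - 1) > 1e-8)
    stopf("length_dist must sum to 1")
  nz <- names(cfg$length_dist)[cfg$length_dist > 0]
  if (!all(nz %in% names(cfg$offset_truth)))
    stopf("offset_truth must cover every length with nonzero probability")
  probs <- c(cfg$periodicity, cfg$init_frac, cfg$readthrough_prob,
             cfg$readthrough_continue, cfg$spike_fraction,
             cfg$junction_spec$unprocessed_fraction)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$spike_fraction >= 1) stopf("spike_fraction must be < 1")
  if (cfg$pcr_dup_rate < 0) stopf("pcr_dup_rate must be >= 0")
  if (cfg$junction_spec$init_preference_fold <= 0)
    stopf("init_preference_fold must be > 0")
  invisible(cfg)
}

#' Default toy gene complement
#'
#' Ten heavy/light-strand mRNA genes emulating the mitochondrial gene
#' repertoire: leaderless genes, 1-3-nt short leaders, three genes with long
#' 5' UTRs (the offset-calibration anchors), a bicistronic junction pair
#' (mtg03/mtg04), a 3'-UTR-bearing gene hosting the dORF (mtg07), and one
#' light-strand gene (mtg08). \code{n_codons} excludes the stop codon;
#' \code{weight} is the relative synthesis (expression) weight.
#'
#' @return data.frame of gene specifications.
#' @export
default_gene_specs <- function() {
  data.frame(
    gene_id = sprintf("mtg%02d", 1:10),
    strand = c("+", "+", "+", "+", "+", "+", "+", "-", "+", "+"),
    n_codons = c(140L, 110L, 90L, 120L, 100L, 95L, 130L, 90L, 85L, 100L),
    leader_len = c(0L, 2L, 1L, 0L, 24L, 30L, 0L, 0L, 21L, 3L),
    utr3_len = c(0L, 45L, 2L, 0L, 0L, 0L, 60L, 0L, 0L, 0L),
    complex_id = c("CI", "CI", "CV", "CIV", "CV", "CIV", "CI", "CI",
                   "CIII", "CIII"),
    stoichiometry = c(1, 1, 1, 2, 1, 1, 1, 1, 1, 2),
    weight = c(1.0, 0.7, 1.4, 1.3, 1.6, 1.5, 0.9, 0.6, 1.2, 0.8),
    start_codon = c("ATG", "ATA", "ATG", "ATG", "ATG", "ATG", "ATG", "ATG",
                    "ATT", "ATG"),
    stop_codon = c("TAA", "AGA", "TAA", "TAG", "TAA", "TAA", "TAA", "AGG",
                   "TAA", "TAA"),
    stringsAsFactors = FALSE
  )
}
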
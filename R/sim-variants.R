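#' Simulate a population variant catalog with tunable start-codon conservation
#'
#' Emulates a homoplasmic mtDNA variant catalog: every possible single-
#' nucleotide substitution is observed independently with probability
#' \code{rate}, with Poisson-distributed carrier counts. At the designated
#' "conserved" target ATG, carriers are drawn directly: a fraction
#' \code{target_bias} of them carry a substitution that yields an alternative
#' start codon (ATA, ATT, or GTG); most of the remainder yield ACG.
#'
#' @param sim Output of \code{\link{make_toy_genome}}.
#' @param config A \code{\link{sim_config}}; settings under
#'   \code{config$variant_spec}: \code{rate} (per-substitution presence
#'   probability), \code{target_bias}, \code{target_carriers},
#'   \code{background_mean_carriers}, optional \code{target_acg_bias}
#'   (share of non-conservative carriers yielding ACG, default 35/36) and
#'   \code{target_position} (genomic position of the conserved ATG's first
#'   base; default: the first heavy-strand phase-matched ATG).
#' @param seed RNG seed (default \code{config$seed + 3}).
#' @return list(\code{variants} = data.table(position, ref, alt, count),
#'   \code{truth} = list(target site, bias, carrier breakdown)).
#' @export
simulate_variant_catalog <- function(sim, config, seed = NULL) {
  validate_sim_config(config)
  with_seed(seed %||% (config$seed + 3L), sim_variants_impl(sim, config))
}

sim_variants_impl <- function(sim, cfg) {
  vs <- cfg$variant_spec
  genome <- sim$genome
  L <- genome$length
  bases <- c("A", "C", "G", "T")

  sites <- find_phase_matched_atgs(genome, sim$annotation)
  target_pos <- vs$target_position %||% {
    if (!nrow(sites)) stopf("no phase-matched ATG to designate as target")
    plus <- sites[sites$strand == "+", ]
    if (nrow(plus)) plus$position[1L] else sites$position[1L]
  }
  target <- sites[sites$position == target_pos, ]
  if (!nrow(target)) stopf("target position %d is not a phase-matched ATG", target_pos)
  target_genomic <- c(target$pos1, target$pos2, target$pos3)

  # background: every possible substitution outside the target triplet
  if (vs$rate > 0) {
    ref <- rep(genome$bases, each = 3L)
    pos <- rep(seq_len(L) - 1L, each = 3L)
    alt <- unlist(lapply(genome$bases, function(b) setdiff(bases, b)),
                  use.names = FALSE)
    ok <- !(pos %in% target_genomic) & ref %in% bases
    hit <- ok & stats::runif(length(pos)) < vs$rate
    bg <- data.table::data.table(
      position = pos[hit], ref = ref[hit], alt = alt[hit],
      count = 1L + stats::rpois(sum(hit), max(vs$background_mean_carriers - 1, 0))
    )
  } else {
    bg <- data.table::data.table(position = integer(), ref = character(),
                                 alt = character(), count = integer())
  }

  # target ATG: carrier-level draw with conservative bias
  acg_bias <- vs$target_acg_bias %||% (35 / 36)
  n_car <- as.integer(vs$target_carriers)
  cons_mut <- c("ATA", "ATT", "GTG")   # the 3 single-nt alternative starts
  other_mut <- setdiff(setdiff(
    unlist(lapply(1:3, function(i) {
      vapply(setdiff(bases, substr("ATG", i, i)), function(b) {
        x <- "ATG"; substr(x, i, i) <- b; x
      }, character(1))
    })), "ATG"), cons_mut)
  is_cons <- stats::runif(n_car) < vs$target_bias
  mut <- character(n_car)
  mut[is_cons] <- sample(cons_mut, sum(is_cons), replace = TRUE)
  n_other <- sum(!is_cons)
  if (n_other > 0L) {
    to_acg <- stats::runif(n_other) < acg_bias
    mm <- character(n_other)
    mm[to_acg] <- "ACG"
    mm[!to_acg] <- sample(setdiff(other_mut, "ACG"), sum(!to_acg), replace = TRUE)
    mut[!is_cons] <- mm
  }
  tgt_tab <- table(mut)
  codon_pos <- vapply(names(tgt_tab), function(m) {
    which(strsplit(m, "")[[1]] != c("A", "T", "G"))[1]
  }, integer(1))
  alt_codon_base <- substr(names(tgt_tab), codon_pos, codon_pos)
  gpos <- target_genomic[codon_pos]
  if (target$strand[1] == "-") alt_base <- comp_base(alt_codon_base)
  else alt_base <- alt_codon_base
  tgt <- data.table::data.table(
    position = gpos, ref = genome$bases[gpos + 1L], alt = alt_base,
    count = as.integer(tgt_tab)
  )

  variants <- data.table::rbindlist(list(bg, tgt))
  data.table::setorder(variants, position, alt)
  truth <- list(
    target_position = target_pos,
    target_strand = target$strand[1],
    target_bias = vs$target_bias,
    target_carriers = n_car,
    target_conservative_carriers = sum(tgt_tab[names(tgt_tab) %in% cons_mut]),
    target_acg_carriers = sum(tgt_tab[names(tgt_tab) == "ACG"])
  )
  list(variants = variants, truth = truth)
}
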
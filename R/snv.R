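# Start-codon variant conservation: phase-matched antisense ATGs, SNV
# classification, and conservation ranking.

#' Find ATGs antisense to known ORF codons in the dORF-equivalent phase
#'
#' Returns every ATG triplet (either strand) whose footprint is antisense to
#' positions 2-3 of a sense-ORF codon and position 1 of the subsequent codon
#' -- the orientation the \emph{MT-ND5-dORF} start codon has relative to the
#' light-strand gene it overlaps. Restricting to this phase equalizes the
#' coding constraints acting on the compared sites.
#'
#' @param genome An \code{mt_genome}.
#' @param annotation An \code{mt_annotation} with CDS features.
#' @return data.table with columns \code{position} (first base of the ATG in
#'   its own translation order), \code{strand}, \code{pos1}, \code{pos2},
#'   \code{pos3} (genomic positions of the A, T, G bases), \code{sense_gene},
#'   \code{codon_index}.
#' @export
find_phase_matched_atgs <- function(genome, annotation) {
  out <- list()
  for (g in gene_ids(annotation, "CDS")) {
    pos <- feature_positions(annotation, g, "CDS")
    n <- length(pos) %/% 3L
    if (n < 2L) next
    strand <- gene_strand(annotation, g)
    anti <- if (strand == "+") "-" else "+"
    i <- seq_len(n - 1L)
    q2 <- pos[3L * i - 1L]; q3 <- pos[3L * i]; q4 <- pos[3L * i + 1L]
    trip <- vapply(q4, function(p) genome_triplet(genome, p, anti), character(1))
    hit <- trip == "ATG"
    if (!any(hit)) next
    out[[g]] <- data.table::data.table(
      position = q4[hit], strand = anti,
      pos1 = q4[hit], pos2 = q3[hit], pos3 = q2[hit],
      sense_gene = g, codon_index = i[hit]
    )
  }
  if (!length(out)) {
    return(data.table::data.table(
      position = integer(), strand = character(), pos1 = integer(),
      pos2 = integer(), pos3 = integer(), sense_gene = character(),
      codon_index = integer()
    ))
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, position)
  unique(res, by = c("position", "strand"))
}

#' Classify SNVs at an ATG site and fill its conservation statistics
#'
#' Each single-nucleotide variant falling in the ATG is applied to the codon;
#' mutants in \{ATT, ATA, GTG\} count as alternative (conservative) start
#' codons, ACG is tallied separately (initiation-capable in vitro only), and
#' everything else as non-conservative. Sites with fewer than 2 SNVs are
#' flagged excluded.
#'
#' @param atg One row of \code{\link{find_phase_matched_atgs}} output (or a
#'   data.frame with \code{position}, \code{strand}, \code{pos1..pos3}).
#' @param variants data.table/data.frame with \code{position}, \code{ref},
#'   \code{alt}, \code{count}.
#' @param genome An \code{mt_genome} (ref-allele check).
#' @param weight \code{"site"} (one SNV type = one observation, default) or
#'   \code{"carrier"} (weight by carrier count).
#' @return The input row with \code{n_snvs}, \code{n_alt_start}, \code{n_acg},
#'   \code{n_other}, \code{conservative_fraction}, \code{excluded} added.
#' @export
classify_snvs <- function(atg, variants, genome, weight = c("site", "carrier")) {
  weight <- match.arg(weight)
  atg <- as.data.frame(atg)[1L, , drop = FALSE]
  cod_pos <- c(atg$pos1, atg$pos2, atg$pos3)
  v <- data.table::as.data.table(variants)
  v <- v[v$position %in% cod_pos]
  if (is.null(v$count)) v$count <- 1L
  v <- as.data.frame(v[, list(count = sum(count)),
                       by = c("position", "ref", "alt")])
  n_alt_start <- n_acg <- n_other <- 0
  if (nrow(v)) {
    ref_gen <- genome$bases[v$position + 1L]
    if (any(v$ref != ref_gen))
      stopf("variant ref does not match genome at position(s) %s",
            paste(v$position[v$ref != ref_gen], collapse = ","))
    if (any(v$ref == v$alt)) stopf("ref == alt in variant record")
    idx <- match(v$position, cod_pos)
    alt_cod <- if (atg$strand == "-") comp_base(v$alt) else v$alt
    mut <- vapply(seq_len(nrow(v)), function(j) {
      x <- "ATG"; substr(x, idx[j], idx[j]) <- alt_cod[j]; x
    }, character(1))
    w <- if (weight == "carrier" && !is.null(v$count)) v$count else rep(1L, nrow(v))
    n_alt_start <- sum(w[mut %in% c("ATT", "ATA", "GTG")])
    n_acg <- sum(w[mut == "ACG"])
    n_other <- sum(w[!(mut %in% c("ATT", "ATA", "GTG", "ACG"))])
  }
  n_snvs <- n_alt_start + n_acg + n_other
  atg$n_snvs <- n_snvs
  atg$n_alt_start <- n_alt_start
  atg$n_acg <- n_acg
  atg$n_other <- n_other
  atg$conservative_fraction <- if (n_snvs > 0) n_alt_start / n_snvs else NA_real_
  atg$excluded <- n_snvs < 2
  atg
}

#' Classify SNVs at every ATG site
#'
#' @param sites Output of \code{\link{find_phase_matched_atgs}}.
#' @inheritParams classify_snvs
#' @return data.table of filled sites.
#' @export
classify_all_atgs <- function(sites, variants, genome,
                              weight = c("site", "carrier")) {
  weight <- match.arg(weight)
  data.table::rbindlist(lapply(seq_len(nrow(sites)), function(i) {
    classify_snvs(sites[i, ], variants, genome, weight)
  }))
}

#' Conservation rank of a target ATG against phase-matched background sites
#'
#' Fraction of background sites whose conservative-change fraction is smaller
#' than the target's (strictly, by default -- the conservative choice for a
#' "smaller fraction" claim). Sites failing the >= 2 SNV filter are dropped.
#'
#' @param target A filled site (from \code{\link{classify_snvs}}).
#' @param background data.frame of filled sites.
#' @param strict Use strict inequality (default TRUE).
#' @return Fraction in [0, 1].
#' @export
conservation_rank <- function(target, background, strict = TRUE) {
  target <- as.data.frame(target)[1L, ]
  if (isTRUE(target$excluded)) stopf("target site fails the >= 2 SNV filter")
  bg <- as.data.frame(background)
  bg <- bg[!bg$excluded & !(bg$position == target$position &
                            bg$strand == target$strand), , drop = FALSE]
  if (!nrow(bg)) stopf("no background sites pass the >= 2 SNV filter")
  if (strict) mean(bg$conservative_fraction < target$conservative_fraction)
  else mean(bg$conservative_fraction <= target$conservative_fraction)
}
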
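# Relative synthesis / RNA abundance quantification with CDS masking,
# per-complex aggregation, and mitonuclear balance statistics.

#' Counting specification for footprint / RNA-seq quantification
#'
#' Captures the end-anchored shift counting used for relative synthesis:
#' mitochondrial footprints are counted at their 3' end shifted 14 nt
#' upstream, cytosolic footprints at their 5' end shifted 17 nt downstream,
#' and RNA-seq fragments by CDS overlap of at least 22 nt.
#'
#' @param anchor \code{"3p"} or \code{"5p"}.
#' @param shift_dir \code{"upstream"} or \code{"downstream"}.
#' @param shift_size Shift in nt.
#' @param min_overlap Minimum read/CDS overlap (RNA mode).
#' @param mode \code{"footprint"} or \code{"rna"}.
#' @param stranded Require read strand to match the CDS strand.
#' @return list of class \code{counting_spec}.
#' @export
counting_spec <- function(anchor = "3p", shift_dir = "upstream",
                          shift_size = 14L, min_overlap = 22L,
                          mode = c("footprint", "rna"), stranded = TRUE) {
  mode <- match.arg(mode)
  if (shift_size < 0L) stopf("shift size must be >= 0")
  structure(list(anchor = match.arg(anchor, c("3p", "5p")),
                 shift_dir = match.arg(shift_dir, c("upstream", "downstream")),
                 shift_size = as.integer(shift_size),
                 min_overlap = as.integer(min_overlap),
                 mode = mode, stranded = stranded),
            class = "counting_spec")
}

#' @rdname counting_spec
#' @export
mito_footprint_spec <- function() {
  counting_spec("3p", "upstream", 14L, mode = "footprint", stranded = TRUE)
}

#' @rdname counting_spec
#' @export
cyto_footprint_spec <- function() {
  counting_spec("5p", "downstream", 17L, mode = "footprint", stranded = TRUE)
}

#' @rdname counting_spec
#' @export
rna_counting_spec <- function(min_overlap = 22L) {
  counting_spec(min_overlap = min_overlap, mode = "rna", stranded = FALSE)
}

#' Build the masked-region set for synthesis counting
#'
#' Mitochondrial footprint counting excludes the first 6 codons of every gene
#' (variable depending on the presence of a 5' UTR) and all regions where two
#' CDSs overlap; RNA counting excludes only the overlaps; the nuclear mask is
#' empty by default.
#'
#' @param annotation An \code{mt_annotation}.
#' @param mode \code{"footprint"} or \code{"rna"}.
#' @param compartment \code{"mito"} or \code{"nuclear"}.
#' @param genes Genes considered (default: all CDS genes).
#' @param n_codons Codons masked at each CDS start (default 6).
#' @return data.frame(start, end): 0-based half-open excluded intervals.
#' @export
build_mask <- function(annotation, mode = c("footprint", "rna"),
                       compartment = c("mito", "nuclear"), genes = NULL,
                       n_codons = 6L) {
  mode <- match.arg(mode)
  compartment <- match.arg(compartment)
  genes <- genes %||% gene_ids(annotation, "CDS")
  empty <- data.frame(start = integer(), end = integer())
  if (compartment == "nuclear") return(empty)
  out <- list()
  if (mode == "footprint") {
    for (g in genes) {
      pos <- feature_positions(annotation, g, "CDS")
      head_pos <- pos[seq_len(min(3L * n_codons, length(pos)))]
      out[[paste0(g, ".head")]] <-
        data.frame(start = min(head_pos), end = max(head_pos) + 1L)
    }
  }
  cds <- ann_features(annotation, "CDS")
  cds <- cds[cds$gene_id %in% genes, , drop = FALSE]
  if (nrow(cds) > 1L) {
    for (i in seq_len(nrow(cds) - 1L)) {
      for (j in seq((i + 1L), nrow(cds))) {
        a <- max(cds$start[i], cds$start[j])
        b <- min(cds$end[i], cds$end[j])
        if (cds$gene_id[i] != cds$gene_id[j] && a < b)
          out[[paste0("ovl.", i, ".", j)]] <- data.frame(start = a, end = b)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

mask_flags <- function(mask, L) {
  m <- rep(FALSE, L)
  for (i in seq_len(nrow(mask))) m[(mask$start[i] + 1L):mask$end[i]] <- TRUE
  m
}

#' Count reads per gene under a counting specification
#'
#' Footprint mode assigns each read to the gene whose unmasked CDS contains
#' its single shifted counting position (strand-matched); RNA mode counts a
#' read for every gene whose unmasked CDS it overlaps by at least
#' \code{min_overlap} nt.
#'
#' @param reads Read table.
#' @param annotation,genome Annotation and genome.
#' @param spec A \code{\link{counting_spec}}.
#' @param mask Excluded intervals from \code{\link{build_mask}} (default:
#'   built to match \code{spec$mode} for the mito compartment).
#' @param genes Genes to count (default: all CDS genes).
#' @return data.table(gene_id, counts, eff_length, complex_id,
#'   stoichiometry).
#' @export
count_gene <- function(reads, annotation, genome, spec, mask = NULL,
                       genes = NULL) {
  genes <- genes %||% gene_ids(annotation, "CDS")
  mask <- mask %||% build_mask(annotation, mode = spec$mode, genes = genes)
  L <- genome$length
  masked <- mask_flags(mask, L)
  reads <- data.table::as.data.table(reads)
  reads <- reads[reads$genome_id == genome$id]
  cds <- ann_features(annotation, "CDS")
  meta <- cds[match(genes, cds$gene_id), c("complex_id", "stoichiometry")]

  eff_len <- vapply(genes, function(g) {
    pos <- feature_positions(annotation, g, "CDS")
    sum(!masked[pos + 1L])
  }, integer(1))

  # unmasked CDS intervals per gene (runs of retained positions)
  unmasked_ivs <- lapply(genes, function(g) {
    pos <- sort(feature_positions(annotation, g, "CDS"))
    pos <- pos[!masked[pos + 1L]]
    if (!length(pos)) return(data.frame(start = integer(), end = integer()))
    brk <- c(0L, which(diff(pos) != 1L), length(pos))
    data.frame(start = pos[brk[-length(brk)] + 1L],
               end = pos[brk[-1L]] + 1L)
  })

  if (spec$mode == "footprint") {
    sgn <- if (spec$shift_dir == "upstream") -1L else 1L
    anchor_bio <- if (spec$anchor == "3p") {
      bio_pos(genome, read_end3_genomic(reads), reads$strand)
    } else {
      bio_pos(genome, read_end5_genomic(reads), reads$strand)
    }
    cp <- genomic_pos(genome, anchor_bio + sgn * spec$shift_size, reads$strand)
    cp <- wrap_pos(cp, L, genome$circular)
    counts <- vapply(seq_along(genes), function(k) {
      iv <- unmasked_ivs[[k]]
      strand <- gene_strand(annotation, genes[k])
      sel <- rep(FALSE, nrow(reads))
      for (i in seq_len(nrow(iv)))
        sel <- sel | (cp >= iv$start[i] & cp < iv$end[i])
      if (spec$stranded) sel <- sel & reads$strand == strand
      sum(sel)
    }, numeric(1))
  } else {
    counts <- vapply(seq_along(genes), function(k) {
      iv <- unmasked_ivs[[k]]
      ov <- rep(0L, nrow(reads))
      for (i in seq_len(nrow(iv)))
        ov <- ov + pmax(0L, pmin(reads$end, iv$end[i]) -
                          pmax(reads$start, iv$start[i]))
      sel <- ov >= spec$min_overlap
      if (spec$stranded)
        sel <- sel & reads$strand == gene_strand(annotation, genes[k])
      sum(sel)
    }, numeric(1))
  }
  data.table::data.table(
    gene_id = genes, counts = counts, eff_length = eff_len,
    complex_id = meta$complex_id, stoichiometry = meta$stoichiometry
  )
}

#' Length- and library-size-normalized relative values
#'
#' RPK = counts per kilobase of unmasked CDS. Mitochondrial relative
#' synthesis is expressed per ten thousand over the mitochondrial
#' protein-coding genes (tpm/100; values sum to 10,000); nuclear values are
#' transcripts per million over the supplied gene universe (tpm; values sum
#' to 1,000,000). The two compartments carry distinct unit tags and are never
#' directly comparable in absolute terms.
#'
#' @param counts Output of \code{\link{count_gene}}.
#' @param compartment \code{"mito"} or \code{"nuclear"}.
#' @return A \code{synthesis_table}: the input with \code{rpk} and
#'   \code{value} columns, \code{compartment} and \code{unit} attributes.
#' @export
relative_values <- function(counts, compartment = c("mito", "nuclear")) {
  compartment <- match.arg(compartment)
  counts <- data.table::as.data.table(counts)
  if (any(counts$eff_length <= 0)) stopf("effective lengths must be > 0")
  rpk <- counts$counts / (counts$eff_length / 1000)
  tot <- sum(rpk)
  if (tot == 0) stopf("zero total RPK; relative values undefined")
  scale <- if (compartment == "mito") 1e4 else 1e6
  out <- data.table::copy(counts)
  out[, "rpk" := rpk]
  out[, "value" := rpk / tot * scale]
  out[, "compartment" := compartment]
  data.table::setattr(out, "unit",
                      if (compartment == "mito") "tpm/100" else "tpm")
  data.table::setattr(out, "class",
                      c("synthesis_table", class(out)))
  out
}

#' Sum paralog families into single rows
#'
#' Alternative-isoform paralogs (COX4I1/COX4I2-style families) are summed
#' into one family row; rows outside any family pass through unchanged.
#'
#' @param table A \code{synthesis_table} (or count table).
#' @param families Named list: family id -> member gene ids.
#' @return Table with family rows replacing member rows.
#' @export
sum_paralogs <- function(table, families) {
  if (!length(families)) return(table)
  all_members <- unlist(families, use.names = FALSE)
  if (anyDuplicated(all_members)) stopf("overlapping paralog families")
  tab <- data.table::as.data.table(table)
  keep <- tab[!tab$gene_id %in% all_members]
  fam_rows <- lapply(names(families), function(f) {
    mem <- tab[tab$gene_id %in% families[[f]]]
    if (nrow(mem) < length(families[[f]]))
      warnf("family %s: %d of %d members present; summing present members",
            f, nrow(mem), length(families[[f]]))
    if (!nrow(mem)) return(NULL)
    row <- mem[1L]
    row$gene_id <- f
    for (col in intersect(c("counts", "rpk", "value"), names(mem)))
      row[[col]] <- sum(mem[[col]])
    row$eff_length <- sum(mem$eff_length)
    row
  })
  out <- data.table::rbindlist(c(list(keep), fam_rows))
  for (a in c("unit", "compartment")) {
    at <- attr(table, a, exact = TRUE)
    if (!is.null(at)) data.table::setattr(out, a, at)
  }
  out
}

#' Per-complex average synthesis (with replicate ranges)
#'
#' Arithmetic mean of relative values over the subunits of each complex;
#' replicates (a list of tables) are aggregated by the mean of per-replicate
#' averages with the min-max range. The nuclear side may be restricted to a
#' configured core-subunit set.
#'
#' @param x A \code{synthesis_table} or a list of replicate tables.
#' @param core_genes Optional subunit filter (gene ids) applied before
#'   averaging.
#' @return data.table(complex_id, average, min, max, n_subunits).
#' @export
complex_averages <- function(x, core_genes = NULL) {
  if (data.table::is.data.table(x) || is.data.frame(x)) x <- list(x)
  per_rep <- lapply(x, function(tab) {
    tab <- data.table::as.data.table(tab)
    if (!is.null(core_genes)) tab <- tab[tab$gene_id %in% core_genes]
    tab <- tab[!is.na(tab$complex_id)]
    if (!nrow(tab)) stopf("no subunits left after filtering")
    tab[, list(avg = mean(value), n = .N), by = "complex_id"]
  })
  cx <- sort(unique(unlist(lapply(per_rep, `[[`, "complex_id"))))
  m <- sapply(per_rep, function(r) r$avg[match(cx, r$complex_id)])
  m <- matrix(m, nrow = length(cx))
  dropped <- rowSums(!is.na(m)) == 0L
  if (any(dropped)) warnf("empty complex dropped: %s",
                          paste(cx[dropped], collapse = ","))
  data.table::data.table(
    complex_id = cx,
    average = rowMeans(m, na.rm = TRUE),
    min = apply(m, 1L, min, na.rm = TRUE),
    max = apply(m, 1L, max, na.rm = TRUE),
    n_subunits = per_rep[[1]]$n[match(cx, per_rep[[1]]$complex_id)]
  )[!dropped]
}

#' Mitonuclear balance correlation
#'
#' Pearson correlation of per-complex average synthesis between the
#' mitochondrial and cytosolic compartments; at least 3 complexes must be
#' present in both. Averages may be compared on the linear (default) or
#' log10 scale.
#'
#' @param mito_avg,nuc_avg Outputs of \code{\link{complex_averages}}.
#' @param scale \code{"linear"} or \code{"log10"}.
#' @return Pearson r (single numeric).
#' @export
balance_correlation <- function(mito_avg, nuc_avg,
                                scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  m <- merge(data.table::as.data.table(mito_avg)[, c("complex_id", "average")],
             data.table::as.data.table(nuc_avg)[, c("complex_id", "average")],
             by = "complex_id", suffixes = c(".mito", ".nuc"))
  if (nrow(m) < 3L) stopf("need >= 3 complexes present in both compartments")
  a <- m$average.mito; b <- m$average.nuc
  if (scale == "log10") { a <- log10(a); b <- log10(b) }
  stats::cor(a, b)
}

#' Synthesis stoichiometry relative to a reference complex
#'
#' Rescales per-complex average synthesis so the reference complex takes the
#' conventional value (Complex III = 3 in the published convention).
#'
#' @param averages Output of \code{\link{complex_averages}}.
#' @param reference Reference complex id.
#' @param reference_value Value assigned to the reference (default 3).
#' @return Named numeric vector of rescaled averages.
#' @export
stoichiometry_of_averages <- function(averages, reference = "CIII",
                                      reference_value = 3) {
  avg <- data.table::as.data.table(averages)
  ref <- avg$average[avg$complex_id == reference]
  if (!length(ref) || ref == 0) stopf("reference complex missing or zero")
  stats::setNames(avg$average / ref * reference_value, avg$complex_id)
}

#' Within-complex synthesis spread
#'
#' Log2-fold difference of each subunit's synthesis from its complex median,
#' and the fraction of subunits within a 2-fold band. Complexes need at least
#' 2 nonzero subunits; zero-valued subunits are excluded with a flag.
#'
#' @param table A \code{synthesis_table}.
#' @return list(per_gene = data.table(gene_id, complex_id, log2_diff),
#'   within_2fold_share, n_excluded_zero).
#' @export
fold_spread <- function(table) {
  tab <- data.table::as.data.table(table)
  tab <- tab[!is.na(tab$complex_id)]
  n_zero <- sum(tab$value == 0)
  tab <- tab[tab$value > 0]
  sizes <- tab[, list(n = .N), by = "complex_id"]
  tab <- tab[tab$complex_id %in% sizes$complex_id[sizes$n >= 2L]]
  if (!nrow(tab)) stopf("no complex with >= 2 nonzero subunits")
  tab[, "log2_diff" := log2(.SD$value / stats::median(.SD$value)),
      by = "complex_id", .SDcols = "value"]
  per_gene <- tab[, c("gene_id", "complex_id", "value", "log2_diff")]
  list(per_gene = per_gene,
       within_2fold_share = mean(abs(per_gene$log2_diff) <= 1),
       n_excluded_zero = n_zero)
}
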
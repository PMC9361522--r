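#' Annotation container: features, processing junctions, paralog families
#'
#' Features are stored as one row per interval part with 0-based, half-open
#' \code{start}/\code{end} coordinates. A CDS that wraps the circular origin
#' is represented as two parts (\code{part} 1, 2, ...) listed in translation
#' order. The light strand is first-class: features carry their own strand and
#' all downstream tracks are kept per strand.
#'
#' @param features data.frame with columns \code{gene_id}, \code{kind} (one of
#'   mRNA, CDS, tRNA, rRNA, UTR5, UTR3), \code{strand}, \code{start},
#'   \code{end}; optional \code{part}, \code{leader_len}, \code{complex_id},
#'   \code{stoichiometry}, \code{family}.
#' @param junctions data.frame with columns \code{name}, \code{position}:
#'   processing sites joining two mRNAs (position = 0-based first base of the
#'   downstream message).
#' @param families named list mapping family id to member gene ids.
#' @return An object of class \code{mt_annotation}.
#' @export
mt_annotation <- function(features, junctions = NULL, families = list()) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("gene_id", "kind", "strand", "start", "end")
  if (!all(need %in% names(features)))
    stopf("features must have columns: %s", paste(need, collapse = ", "))
  for (col in c("part", "leader_len", "complex_id", "stoichiometry", "family")) {
    if (is.null(features[[col]])) {
      features[[col]] <- rep(if (col == "part") 1L else NA, nrow(features))
    }
  }
  if (!all(features$kind %in% c("mRNA", "CDS", "tRNA", "rRNA", "UTR5", "UTR3")))
    stopf("unknown feature kind")
  if (!all(features$strand %in% c("+", "-"))) stopf("strand must be + or -")
  if (any(features$end <= features$start))
    stopf("each interval part must satisfy end > start")
  # gene ids unique per kind (one row per part is allowed)
  for (k in unique(features$kind)) {
    f <- features[features$kind == k, ]
    if (anyDuplicated(paste(f$gene_id, f$part)))
      stopf("duplicate gene_id/part for kind %s", k)
  }
  cds <- features[features$kind == "CDS", ]
  if (nrow(cds)) {
    len <- tapply(cds$end - cds$start, cds$gene_id, sum)
    if (any(len %% 3L != 0L))
      stopf("CDS length not divisible by 3 for: %s",
            paste(names(len)[len %% 3L != 0L], collapse = ", "))
  }
  if (!is.null(junctions)) {
    junctions <- as.data.frame(junctions, stringsAsFactors = FALSE)
    if (!all(c("name", "position") %in% names(junctions)))
      stopf("junctions need columns name, position")
  } else {
    junctions <- data.frame(name = character(), position = integer())
  }
  structure(
    list(features = features, junctions = junctions, families = families),
    class = "mt_annotation"
  )
}

#' @export
print.mt_annotation <- function(x, ...) {
  tab <- table(x$features$kind[x$features$part == 1L])
  cat("<mt_annotation>", paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
      sprintf("| %d junction(s), %d paralog familie(s)\n",
              nrow(x$junctions), length(x$families)))
  invisible(x)
}

ann_features <- function(annotation, kind = NULL, gene_id = NULL) {
  f <- annotation$features
  if (!is.null(kind)) f <- f[f$kind %in% kind, , drop = FALSE]
  if (!is.null(gene_id)) f <- f[f$gene_id %in% gene_id, , drop = FALSE]
  f
}

gene_ids <- function(annotation, kind = "CDS") {
  unique(ann_features(annotation, kind)$gene_id)
}

gene_strand <- function(annotation, gene_id) {
  f <- ann_features(annotation, gene_id = gene_id)
  if (!nrow(f)) stopf("unknown gene %s", gene_id)
  f$strand[1]
}

# Genomic positions of a feature in translation (5'->3' on the coding strand)
# order: ascending within a part on "+", descending on "-"; parts concatenated
# in listed order.
feature_positions <- function(annotation, gene_id, kind = "CDS") {
  f <- ann_features(annotation, kind = kind, gene_id = gene_id)
  if (!nrow(f)) stopf("gene %s has no %s feature", gene_id, kind)
  f <- f[order(f$part), , drop = FALSE]
  unlist(lapply(seq_len(nrow(f)), function(i) {
    if (f$strand[i] == "+") seq.int(f$start[i], f$end[i] - 1L)
    else seq.int(f$end[i] - 1L, f$start[i])
  }), use.names = FALSE)
}

#' Codon coordinates of a CDS
#'
#' Lists every codon of a CDS with the three genome positions it occupies, in
#' translation order. Codon 1 is the first three CDS nucleotides 5'->3' on the
#' coding strand; light-strand codons have descending genome coordinates, and
#' CDSs wrapping the circular origin are supported through multi-part
#' intervals.
#'
#' @param annotation An \code{mt_annotation}.
#' @param gene_id Gene whose CDS to enumerate.
#' @return data.frame with columns \code{codon_index}, \code{p1}, \code{p2},
#'   \code{p3} (0-based genome positions in translation order).
#' @export
codon_coords <- function(annotation, gene_id) {
  pos <- feature_positions(annotation, gene_id, "CDS")
  n <- length(pos) %/% 3L
  data.frame(
    codon_index = seq_len(n),
    p1 = pos[seq(1L, by = 3L, length.out = n)],
    p2 = pos[seq(2L, by = 3L, length.out = n)],
    p3 = pos[seq(3L, by = 3L, length.out = n)]
  )
}

cds_length <- function(annotation, gene_id) {
  f <- ann_features(annotation, "CDS", gene_id)
  sum(f$end - f$start)
}

leader_length <- function(annotation, gene_id) {
  f <- ann_features(annotation, "mRNA", gene_id)
  if (!nrow(f) || is.na(f$leader_len[1])) 0L else as.integer(f$leader_len[1])
}

# Biological-coordinate conversion: position along the strand 5'->3'.
# `strand` is recycled to the length of the position vector.
bio_pos <- function(genome, genomic, strand) {
  minus <- rep_len(strand == "-", length(genomic))
  out <- as.integer(genomic)
  out[minus] <- genome$length - 1L - as.integer(genomic)[minus]
  out
}
genomic_pos <- function(genome, bio, strand) {
  bio <- as.integer(wrap_pos(bio, genome$length, genome$circular))
  minus <- rep_len(strand == "-", length(bio))
  bio[minus] <- genome$length - 1L - bio[minus]
  bio
}

# First base of the CDS (start codon) in biological coordinates.
cds_start_bio <- function(annotation, genome, gene_id) {
  bio_pos(genome, feature_positions(annotation, gene_id, "CDS")[1L],
          gene_strand(annotation, gene_id))
}

# First base of the message (mRNA 5' end) in biological coordinates.
message_start_bio <- function(annotation, genome, gene_id) {
  f <- ann_features(annotation, "mRNA", gene_id)
  if (nrow(f)) {
    f <- f[order(f$part), , drop = FALSE]
    if (f$strand[1] == "+") f$start[1] else genome$length - f$end[nrow(f)]
  } else {
    cds_start_bio(annotation, genome, gene_id)
  }
}

# Per-strand arrays (length L) giving the subcodon class (0 = first, 1 =
# middle, 2 = third base of a codon in translation order) for positions inside
# exactly one CDS; NA elsewhere and where CDSs overlap on the same strand.
cds_frame_classes <- function(annotation, genome) {
  L <- genome$length
  out <- list()
  for (s in c("+", "-")) {
    cls <- rep(NA_integer_, L)
    hits <- integer(L)
    f <- ann_features(annotation, "CDS")
    for (g in unique(f$gene_id[f$strand == s])) {
      pos <- feature_positions(annotation, g, "CDS")
      cls[pos + 1L] <- (seq_along(pos) - 1L) %% 3L
      hits[pos + 1L] <- hits[pos + 1L] + 1L
    }
    cls[hits > 1L] <- NA_integer_
    out[[s]] <- cls
  }
  names(out) <- c("plus", "minus")
  out
}
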
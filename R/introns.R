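# Intron extraction and summaries: tRNA introns sit at the canonical
# position one base 3' of the anticodon; here they are pulled out of the
# genome strand-aware and summarized per isotype and lineage, with a
# catalog of the rare carriers outside eMet/Tyr.

#' Extract intron sequences from annotated tDNAs
#'
#' @param records a [tdna_records] table; genes without intron bounds are
#'   skipped.
#' @param genome the [tdna_genome] carrying sequence.
#' @return data.frame: gene_id, isotype, anticodon, contig,
#'   intron_start/intron_end (0-based half-open), strand, length, sequence
#'   (sense strand).
#' @export
extract_introns <- function(records, genome) {
  has <- !is.na(records$intron_start)
  r <- records[has, , drop = FALSE]
  bad <- r$intron_start < r$start | r$intron_end > r$end
  if (any(bad)) stop("intron locus outside gene locus for: ",
                     paste(r$gene_id[bad], collapse = ", "))
  seqs <- vapply(seq_len(nrow(r)), function(i)
    genome_slice(genome, r$contig[i], r$intron_start[i], r$intron_end[i],
                 r$strand[i]), character(1))
  data.frame(gene_id = r$gene_id, isotype = r$isotype,
             anticodon = r$anticodon, contig = r$contig,
             intron_start = r$intron_start, intron_end = r$intron_end,
             strand = r$strand,
             length = r$intron_end - r$intron_start,
             sequence = if (nrow(r)) seqs else character(0),
             stringsAsFactors = FALSE)
}

#' Summarize an intron catalog
#'
#' @param introns output of [extract_introns()]; may carry `genome_id`
#'   and/or `lineage` columns for grouped summaries.
#' @param outlier_bp lengths above this are flagged as outliers
#'   (default 50).
#' @return list with `by_isotype` (count/mean/min/max length per isotype,
#'   per lineage when available), `noncanonical` (intron-bearing genes
#'   outside eMet/Tyr), and `outliers`.
#' @export
intron_summary <- function(introns, outlier_bp = 50L) {
  if (nrow(introns) == 0L)
    return(list(by_isotype = data.frame(), noncanonical = data.frame(),
                outliers = data.frame()))
  grp <- introns$isotype
  if ("lineage" %in% names(introns))
    grp <- paste(introns$lineage, introns$isotype, sep = "|")
  agg <- do.call(rbind, lapply(split(introns, grp), function(d) {
    data.frame(lineage = if ("lineage" %in% names(d)) d$lineage[1]
                         else NA_character_,
               isotype = d$isotype[1], n = nrow(d),
               mean_length = mean(d$length),
               min_length = min(d$length), max_length = max(d$length),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  noncan <- introns[!introns$isotype %in% c("eMet", "iMet", "Met", "Tyr"), ,
                    drop = FALSE]
  noncan_tab <- if (nrow(noncan)) {
    key <- if ("genome_id" %in% names(noncan))
      paste(noncan$isotype, noncan$genome_id, sep = "|") else noncan$isotype
    do.call(rbind, lapply(split(noncan, key), function(d)
      data.frame(isotype = d$isotype[1],
                 genome_id = if ("genome_id" %in% names(d)) d$genome_id[1]
                             else NA_character_,
                 n = nrow(d), stringsAsFactors = FALSE)))
  } else data.frame(isotype = character(), genome_id = character(),
                    n = integer())
  rownames(noncan_tab) <- NULL
  list(by_isotype = agg,
       noncanonical = noncan_tab,
       outliers = introns[introns$length > outlier_bp, , drop = FALSE])
}

#' Per-column conservation of an alignment
#'
#' For each column the majority non-gap base and its gap-inclusive
#' frequency are reported, plus information content in bits (2 - Shannon
#' entropy over the non-gap base distribution; gaps reduce the effective
#' support but are excluded from the entropy). Maximal runs of conserved
#' columns (majority frequency >= `threshold`) are reported as motif spans
#' with their consensus strings.
#'
#' @param alignment character matrix (rows = sequences) as returned by
#'   [read_alignment()], or a character vector of equal-length sequences.
#' @param threshold conservation threshold on the majority frequency
#'   (default 0.8).
#' @return list with `columns` (data.frame: column, majority_base,
#'   frequency, ic_bits, support) and `spans` (data.frame: start, end,
#'   consensus; 1-based inclusive columns).
#' @export
column_conservation <- function(alignment, threshold = 0.8) {
  if (!is.matrix(alignment)) alignment <- alignment_matrix(alignment)
  if (nrow(alignment) == 0L) stop("empty alignment")
  L <- ncol(alignment)
  nr <- nrow(alignment)
  cols <- lapply(seq_len(L), function(c) {
    x <- alignment[, c]
    bases <- x[x != "-"]
    if (length(bases) == 0L)
      return(data.frame(column = c, majority_base = "-", frequency = 0,
                        ic_bits = 0, support = 0L))
    tab <- sort(table(bases), decreasing = TRUE)
    p <- as.numeric(tab) / sum(tab)
    data.frame(column = c, majority_base = names(tab)[1],
               frequency = as.numeric(tab[1]) / nr,   # gap-inclusive
               ic_bits = 2 + sum(p * log2(p)),
               support = length(bases), stringsAsFactors = FALSE)
  })
  cols <- do.call(rbind, cols)
  conserved <- cols$frequency >= threshold
  spans <- if (any(conserved)) {
    r <- rle(conserved)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start = starts[keep], end = ends[keep],
               consensus = vapply(keep, function(k)
                 paste(cols$majority_base[starts[k]:ends[k]], collapse = ""),
                 character(1)),
               stringsAsFactors = FALSE)
  } else data.frame(start = integer(), end = integer(),
                    consensus = character())
  list(columns = cols, spans = spans)
}

#' Write an intron catalog as FASTA
#'
#' One record per intron, header `gene_id|isotype|anticodon`.
#'
#' @param introns output of [extract_introns()].
#' @param path output path.
#' @export
write_intron_fasta <- function(introns, path) {
  seqs <- introns$sequence
  names(seqs) <- paste(introns$gene_id, introns$isotype, introns$anticodon,
                       sep = "|")
  write_fasta(seqs, path)
}
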
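#' @keywords internal
"_PACKAGE"

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet A/C/G/T/N (case
#' preserved as upper case; inputs are uppercased first).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Run code with a locally seeded RNG, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a normalized tDNA annotation table
#'
#' The internal annotation convention used throughout the package:
#' 0-based half-open coordinates with an explicit strand column. Intron
#' bounds, when present, use the same convention and must lie strictly
#' inside the gene locus.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param contig contig identifier per gene.
#' @param start,end 0-based half-open genomic coordinates, `start < end`.
#' @param strand `"+"` or `"-"` per gene.
#' @param isotype three-letter amino-acid code, or one of `eMet`, `iMet`,
#'   `Sup`, `Undet`.
#' @param anticodon 3-mer over A/C/G/T, or `NA` when unknown.
#' @param intron_start,intron_end optional intron locus (same convention),
#'   `NA` for intron-less genes.
#' @param score Infernal bit score (numeric).
#' @param note free-text annotation column (e.g. a pseudogene flag).
#' @param gene_seq sense-strand gene sequence (introns included), or `NA`.
#' @return a `data.frame` of class `tdna_records`.
#' @export
tdna_records <- function(gene_id, contig, start, end, strand,
                         isotype, anticodon = NA_character_,
                         intron_start = NA_integer_, intron_end = NA_integer_,
                         score = NA_real_, note = "", gene_seq = NA_character_) {
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    contig = rep_len(as.character(contig), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    isotype = rep_len(as.character(isotype), n),
    anticodon = rep_len(as.character(anticodon), n),
    intron_start = rep_len(as.integer(intron_start), n),
    intron_end = rep_len(as.integer(intron_end), n),
    score = rep_len(as.numeric(score), n),
    note = rep_len(as.character(note), n),
    gene_seq = rep_len(as.character(gene_seq), n),
    stringsAsFactors = FALSE
  )
  validate_tdna_records(df)
  class(df) <- c("tdna_records", "data.frame")
  df
}

validate_tdna_records <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(df$start < 0L)) stop("negative start coordinate")
  if (any(df$start >= df$end)) stop("start must be < end (0-based half-open)")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  has_intron <- !is.na(df$intron_start)
  if (any(has_intron != !is.na(df$intron_end)))
    stop("intron_start and intron_end must be NA together")
  if (any(has_intron & (df$intron_start <= df$start |
                        df$intron_end >= df$end |
                        df$intron_start >= df$intron_end)))
    stop("intron locus must lie strictly inside the gene locus")
  ok_seq <- is.na(df$gene_seq) | nchar(df$gene_seq) == (df$end - df$start)
  if (!all(ok_seq))
    stop("gene_seq length must equal end - start for: ",
         paste(df$gene_id[!ok_seq], collapse = ", "))
  invisible(df)
}

#' Construct a genome record
#'
#' @param genome_id genome identifier.
#' @param contigs named character vector of contig sequences (A/C/G/T).
#'   May be `NULL` for metadata-only genomes (e.g. large simulated cohorts
#'   where only gene counts and declared sizes enter a regression).
#' @param lineage lineage label used for grouping (`ANA`, `eudicot`,
#'   `monocot`, `Ceratophyllum`, or `other`); metadata only, never inferred.
#' @param size_bp genome size in bp; defaults to the summed contig lengths
#'   and must equal them when contigs are present.
#' @return a list of class `tdna_genome`.
#' @export
tdna_genome <- function(genome_id, contigs, lineage = "other", size_bp = NULL) {
  if (!is.null(contigs)) {
    if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
      stop("contigs must be uniquely named")
    contigs <- toupper(contigs)
    csum <- sum(nchar(contigs))
    if (is.null(size_bp)) size_bp <- csum
    if (size_bp != csum)
      stop("size_bp (", size_bp, ") != total contig length (", csum, ")")
  } else if (is.null(size_bp)) {
    stop("size_bp required when contigs are absent")
  }
  structure(list(genome_id = as.character(genome_id),
                 lineage = as.character(lineage),
                 contigs = contigs,
                 size_bp = as.numeric(size_bp)),
            class = "tdna_genome")
}

#' @export
print.tdna_genome <- function(x, ...) {
  cat("<tdna_genome> ", x$genome_id, " (", x$lineage, "): ",
      if (is.null(x$contigs)) 0L else length(x$contigs), " contig(s), ",
      format(x$size_bp, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

# Slice [start, end) from a genome contig, reverse-complemented for "-".
genome_slice <- function(genome, contig, start, end, strand = "+") {
  seqs <- genome$contigs
  if (is.null(seqs)) stop("genome '", genome$genome_id, "' has no sequence")
  if (!contig %in% names(seqs)) stop("unknown contig: ", contig)
  L <- nchar(seqs[[contig]])
  if (start < 0 || end > L) stop("slice [", start, ",", end,
                                 ") outside contig ", contig, " (length ", L, ")")
  s <- substr(seqs[[contig]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Extract sense-strand gene sequences from a genome
#'
#' Fills (or refreshes) the `gene_seq` column of an annotation table from
#' the attached genome, reverse-complementing minus-strand genes.
#'
#' @param records a [tdna_records] table.
#' @param genome a [tdna_genome] with sequence.
#' @return the records with `gene_seq` populated.
#' @export
attach_gene_sequences <- function(records, genome) {
  records$gene_seq <- vapply(seq_len(nrow(records)), function(i) {
    genome_slice(genome, records$contig[i], records$start[i],
                 records$end[i], records$strand[i])
  }, character(1))
  records
}

#' Reverse-complement a genome and mirror its annotations
#'
#' Every contig is reverse-complemented and every annotated interval is
#' mapped to the mirrored coordinates with its strand flipped. All
#' strand-aware analyses must be invariant under this transformation.
#'
#' @param genome a [tdna_genome] with sequence.
#' @param records a [tdna_records] table on that genome.
#' @return list with elements `genome` and `records`.
#' @export
mirror_genome <- function(genome, records) {
  lens <- vapply(genome$contigs, nchar, integer(1))
  g2 <- genome
  g2$contigs <- vapply(genome$contigs, revcomp, character(1))
  r2 <- records
  L <- lens[records$contig]
  r2$start <- as.integer(L - records$end)
  r2$end <- as.integer(L - records$start)
  has_i <- !is.na(records$intron_start)
  r2$intron_start[has_i] <- as.integer(L[has_i] - records$intron_end[has_i])
  r2$intron_end[has_i] <- as.integer(L[has_i] - records$intron_start[has_i])
  r2$strand <- ifelse(records$strand == "+", "-", "+")
  list(genome = g2, records = r2)
}
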
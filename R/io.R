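# Readers and writers for the formats the pipeline touches. All coordinates
# are normalized here to the internal 0-based half-open + explicit-strand
# convention; tRNAscan-SE's 1-based, strand-by-column-order encoding never
# leaves this file.

#' Read a (multi-)FASTA file
#'
#' @param path path to a FASTA file.
#' @param dna if `TRUE` (default) sequences are treated as genomic DNA:
#'   uppercased and with U mapped to T.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, dna = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for: ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  if (dna) seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a tRNAscan-SE tabular output file
#'
#' Parses the `.out` dialect (three header lines, then one row per gene).
#' Both the plain and the extended (`-H`) column layouts are accepted;
#' trailing columns beyond the nine mandatory ones are preserved verbatim
#' in `note`. tRNAscan-SE encodes the minus strand by begin > end; rows are
#' converted to 0-based half-open coordinates with an explicit strand.
#'
#' @param path path to a tRNAscan-SE `.out` file.
#' @param header number of header lines to skip (default 3).
#' @return a [tdna_records] table.
#' @export
read_trnascan_table <- function(path, header = 3L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) > header) lines <- lines[-seq_len(header)] else lines <- character()
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(tdna_records(character(), character(),
                                               integer(), integer(), character(),
                                               character())[0, ])
  rows <- lapply(seq_along(lines), function(k) {
    f <- strsplit(trimws(lines[[k]]), "[ \t]+")[[1]]
    if (length(f) < 9L)
      stop("line ", k + header, ": expected >= 9 columns, got ", length(f))
    ints <- suppressWarnings(as.integer(f[c(2, 3, 4, 7, 8)]))
    if (anyNA(ints))
      stop("line ", k + header, ": non-integer coordinate field")
    sc <- suppressWarnings(as.numeric(f[9]))
    if (is.na(sc)) stop("line ", k + header, ": non-numeric score")
    b <- ints[2]; e <- ints[3]
    if (b == e) stop("line ", k + header, ": begin == end")
    strand <- if (b > e) "-" else "+"
    ib <- ints[4]; ie <- ints[5]
    note <- if (length(f) > 9L) paste(f[10:length(f)], collapse = " ") else ""
    list(contig = f[1], num = ints[1],
         start = min(b, e) - 1L, end = max(b, e), strand = strand,
         isotype = f[5], anticodon = f[6],
         intron_start = if (ib == 0L && ie == 0L) NA_integer_ else min(ib, ie) - 1L,
         intron_end = if (ib == 0L && ie == 0L) NA_integer_ else max(ib, ie),
         score = sc, note = note)
  })
  g <- function(x) sapply(rows, `[[`, x)
  tdna_records(
    gene_id = paste0(g("contig"), ".trna", g("num")),
    contig = g("contig"), start = g("start"), end = g("end"),
    strand = g("strand"), isotype = g("isotype"),
    anticodon = ifelse(g("anticodon") %in% c("???", "NNN"), NA, g("anticodon")),
    intron_start = g("intron_start"), intron_end = g("intron_end"),
    score = g("score"), note = g("note"))
}

#' Write annotations in the tRNAscan-SE tabular dialect
#'
#' Inverse of [read_trnascan_table()]: minus-strand genes are written with
#' begin > end in 1-based inclusive coordinates, so reading the file back
#' reproduces the records exactly.
#'
#' @param records a [tdna_records] table.
#' @param path output path.
#' @export
write_trnascan_table <- function(records, path) {
  hdr <- c(
    "Sequence\t\ttRNA\tBounds\t\ttRNA\tAnti\tIntron Bounds\t\tInf",
    "Name    \ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
    "--------\t------\t-----\t---\t----\t-----\t-----\t---\t-----")
  n <- nrow(records)
  num <- stats::ave(seq_len(n), records$contig, FUN = seq_along)
  body <- vapply(seq_len(n), function(i) {
    r <- records[i, ]
    minus <- r$strand == "-"
    b <- if (minus) r$end else r$start + 1L
    e <- if (minus) r$start + 1L else r$end
    if (is.na(r$intron_start)) { ib <- 0L; ie <- 0L } else {
      ib <- if (minus) r$intron_end else r$intron_start + 1L
      ie <- if (minus) r$intron_start + 1L else r$intron_end
    }
    paste(r$contig, num[i], b, e, r$isotype,
          if (is.na(r$anticodon)) "???" else r$anticodon,
          ib, ie, format(r$score, nsmall = 1),
          if (nzchar(r$note)) r$note else NULL, sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a tRNAscan-SE secondary-structure (.ss) file
#'
#' Blocks are separated by blank lines; each block's first token names the
#' gene and its `Seq:`/`Str:` lines carry the predicted tRNA sequence and
#' structure over the alphabet `> < .`, with `>` pairing a downstream `<`.
#'
#' @param path path to a `.ss` file.
#' @return list of records, each `list(gene_id, sequence, pairing)` where
#'   `pairing` is a 2-column matrix of 0-based paired positions (i < j).
#' @export
read_trnascan_ss <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  breaks <- cumsum(!nzchar(trimws(lines)))
  blocks <- split(lines[nzchar(trimws(lines))], breaks[nzchar(trimws(lines))])
  out <- lapply(blocks, function(bl) {
    gid <- strsplit(trimws(bl[[1]]), "[ \t]+")[[1]][1]
    seq_line <- grep("^\\s*Seq:", bl, value = TRUE)
    str_line <- grep("^\\s*Str:", bl, value = TRUE)
    if (length(seq_line) != 1L || length(str_line) != 1L)
      stop("block '", gid, "': need exactly one Seq: and one Str: line")
    sq <- toupper(gsub("^\\s*Seq:\\s*", "", seq_line))
    st <- gsub("^\\s*Str:\\s*", "", str_line)
    list(gene_id = gid, sequence = chartr("U", "T", sq),
         pairing = parse_pairing(st, gid))
  })
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  unname(out)
}

# Stack-match a structure string over {>, <, .} (or dot-bracket "( )").
parse_pairing <- function(str, label = "structure") {
  ch <- strsplit(str, "", fixed = TRUE)[[1]]
  open <- ch %in% c(">", "(")
  close <- ch %in% c("<", ")")
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (open[i]) stack <- c(stack, i - 1L)
    else if (close[i]) {
      if (length(stack) == 0L) stop("unbalanced structure in ", label)
      pairs <- rbind(pairs, c(stack[length(stack)], i - 1L))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) stop("unbalanced structure in ", label)
  colnames(pairs) <- c("i", "j")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

records_to_granges <- function(records) {
  gr <- GenomicRanges::GRanges(
    seqnames = records$contig,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = records$strand)
  S4Vectors::mcols(gr)$name <- paste0(records$isotype, "-",
                                      ifelse(is.na(records$anticodon), "NNN",
                                             records$anticodon))
  S4Vectors::mcols(gr)$score <- records$score
  gr
}

#' Export annotations to BED6 or GFF3
#'
#' BED6 is 0-based half-open with `name = isotype-anticodon` and the bit
#' score in the score column. GFF3 is 1-based inclusive, type `tRNA`, with
#' `ID`, `isotype`, `anticodon` and (1-based inclusive) intron-bound
#' attributes, so a GFF3 round trip is the identity on records.
#'
#' @param records a [tdna_records] table.
#' @param path output path.
#' @param format `"BED6"` or `"GFF3"`.
#' @export
export_annotations <- function(records, path, format = c("BED6", "GFF3")) {
  format <- match.arg(format)
  gr <- records_to_granges(records)
  if (format == "BED6") {
    rtracklayer::export(gr, path, format = "bed")
  } else {
    S4Vectors::mcols(gr)$name <- NULL
    S4Vectors::mcols(gr) <- cbind(S4Vectors::mcols(gr), S4Vectors::DataFrame(
      source = "tdnascape", type = "tRNA",
      ID = records$gene_id, isotype = records$isotype,
      anticodon = ifelse(is.na(records$anticodon), "NNN", records$anticodon),
      intron_begin = ifelse(is.na(records$intron_start), "0",
                            as.character(records$intron_start + 1L)),
      intron_end = ifelse(is.na(records$intron_end), "0",
                          as.character(records$intron_end)),
      tsnote = ifelse(nzchar(records$note), records$note, ".")))
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Import annotations from BED6 or GFF3
#'
#' Inverse of [export_annotations()]. BED6 carries no intron bounds or
#' note; those fields come back `NA`/empty.
#'
#' @param path input path.
#' @param format `"BED6"` or `"GFF3"` (guessed from the extension when
#'   missing).
#' @return a [tdna_records] table.
#' @export
import_annotations <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "GFF3" else "BED6"
  }
  format <- match.arg(format, c("BED6", "GFF3"))
  gr <- rtracklayer::import(path, format = if (format == "BED6") "bed" else "gff3")
  st <- as.integer(GenomicRanges::start(gr)) - 1L
  en <- as.integer(GenomicRanges::end(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  mc <- S4Vectors::mcols(gr)
  if (format == "BED6") {
    iso_ac <- strsplit(mc$name, "-", fixed = TRUE)
    tdna_records(
      gene_id = paste0(as.character(GenomicRanges::seqnames(gr)), ".trna",
                       seq_along(gr)),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = st, end = en, strand = strand,
      isotype = vapply(iso_ac, `[`, character(1), 1),
      anticodon = ifelse(vapply(iso_ac, `[`, character(1), 2) == "NNN", NA,
                         vapply(iso_ac, `[`, character(1), 2)),
      score = as.numeric(mc$score))
  } else {
    ib <- as.integer(mc$intron_begin)
    ie <- as.integer(mc$intron_end)
    tdna_records(
      gene_id = mc$ID, contig = as.character(GenomicRanges::seqnames(gr)),
      start = st, end = en, strand = strand,
      isotype = mc$isotype,
      anticodon = ifelse(mc$anticodon == "NNN", NA, mc$anticodon),
      intron_start = ifelse(ib == 0L, NA_integer_, ib - 1L),
      intron_end = ifelse(ie == 0L, NA_integer_, ie),
      score = as.numeric(mc$score),
      note = ifelse(is.na(mc$tsnote) | mc$tsnote == ".", "", mc$tsnote))
  }
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned FASTA (all rows equal length; `-` gaps).
#' @return character matrix, one row per sequence (rownames = identifiers),
#'   one column per alignment position.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    warning("empty alignment file: ", path)
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  w <- nchar(seqs)
  if (length(unique(w)) > 1L)
    stop("ragged alignment; offending rows: ",
         paste(ids[w != w[1]], collapse = ", "))
  alignment_matrix(seqs, ids)
}

#' Build an alignment matrix from in-memory sequences
#'
#' @param seqs character vector of equal-length (gapped) sequences.
#' @param ids row identifiers.
#' @return character matrix (rows = sequences).
#' @export
alignment_matrix <- function(seqs, ids = names(seqs)) {
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) stop("sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- ids %||% paste0("seq", seq_along(seqs))
  m
}

#' Read a rooted newick tree
#'
#' Thin wrapper over [ape::read.tree()] adding the checks downstream
#' reconciliation relies on: a single tree, labelled leaves and (optionally)
#' unique leaf labels. Branch lengths are retained but ignored downstream.
#'
#' @param path path to a newick file (or use `text =`).
#' @param text newick string, alternative to `path`.
#' @param require_unique_labels error on duplicate leaf labels (used for
#'   species trees).
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL, require_unique_labels = FALSE) {
  tr <- if (is.null(text)) {
    if (!file.exists(path)) stop("no such file: ", path)
    ape::read.tree(path)
  } else ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1]]
  }
  if (any(!nzchar(tr$tip.label))) stop("tree has unlabelled leaves")
  if (require_unique_labels && anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}
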
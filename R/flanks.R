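# Strand-aware flanking windows and RNA polymerase III regulatory-element
# scans: upstream TATA-box and CAA motifs, downstream poly(T) terminator
# runs, and positional base-composition profiles of the windows.

# 0-based start positions of (possibly overlapping) motif occurrences
motif_start_positions <- function(window, motif) {
  if (!nzchar(window) || nchar(window) < nchar(motif)) return(integer(0))
  hits <- gregexpr(paste0("(?=", motif, ")"), window, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# maximal T-runs of length >= min_run: data.frame(offset 0-based, length,
# truncated = touches a window edge)
find_t_runs <- function(window, min_run = 4L) {
  empty <- data.frame(offset = integer(), length = integer(),
                      truncated = logical())
  if (!nzchar(window)) return(empty)
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  r <- rle(ch == "T")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(empty)
  data.frame(offset = starts[keep] - 1L, length = r$lengths[keep],
             truncated = starts[keep] == 1L | ends[keep] == length(ch))
}

#' Extract strand-aware flanking windows
#'
#' Windows are reported 5'-to-3' on each gene's sense strand and abut the
#' gene boundary: for a plus-strand gene the upstream window is the top
#' strand just before the start; for a minus-strand gene it is the reverse
#' complement of the top strand just after the end. Windows running off a
#' contig edge are truncated and flagged.
#'
#' @param records a [tdna_records] table.
#' @param genome the [tdna_genome] carrying the sequence.
#' @param upstream integer vector of upstream window sizes (default
#'   `c(50, 300)`).
#' @param downstream downstream window size (default 50).
#' @return data.frame with one row per gene: `gene_id`, one column per
#'   window (`upstream50`, `upstream300`, `downstream50`, ...), and
#'   matching `*_trunc` logical flags.
#' @export
extract_flanks <- function(records, genome, upstream = c(50L, 300L),
                           downstream = 50L) {
  lens <- vapply(genome$contigs, nchar, integer(1))
  n <- nrow(records)
  out <- data.frame(gene_id = records$gene_id, stringsAsFactors = FALSE)
  grab <- function(i, w, side) {
    L <- lens[[records$contig[i]]]
    s <- records$start[i]; e <- records$end[i]
    if (s < 0 || e > L) stop("locus of ", records$gene_id[i],
                             " outside contig")
    plus <- records$strand[i] == "+"
    if ((side == "up") == plus) {   # top-strand region before the gene
      a <- max(0L, s - w); b <- s
    } else {
      a <- e; b <- min(L, e + w)
    }
    seq <- genome_slice(genome, records$contig[i], a, b,
                        records$strand[i])
    list(seq = seq, trunc = (b - a) < w)
  }
  for (w in upstream) {
    res <- lapply(seq_len(n), grab, w = w, side = "up")
    out[[paste0("upstream", w)]] <- vapply(res, `[[`, character(1), "seq")
    out[[paste0("upstream", w, "_trunc")]] <- vapply(res, `[[`, logical(1),
                                                     "trunc")
  }
  for (w in downstream) {
    res <- lapply(seq_len(n), grab, w = w, side = "down")
    out[[paste0("downstream", w)]] <- vapply(res, `[[`, character(1), "seq")
    out[[paste0("downstream", w, "_trunc")]] <- vapply(res, `[[`, logical(1),
                                                       "trunc")
  }
  out
}

#' Count TATA-box motifs in a window
#'
#' Occurrences of any motif in the set are counted at distinct start
#' positions (overlaps count separately). The category bins the count as
#' `0`, `1`, `2` or `>2`.
#'
#' @param window nucleotide string (a sense-strand upstream window).
#' @param motifs motif set (default the literal `"TATA"`; see
#'   [tata_motifs()] for the documented extended variant list).
#' @return list with `count` and `category`.
#' @export
scan_tata <- function(window, motifs = "TATA") {
  if (length(motifs) == 0L) stop("motif set must be nonempty")
  pos <- unique(unlist(lapply(toupper(motifs), motif_start_positions,
                              window = toupper(window))))
  n <- length(pos)
  list(count = n,
       category = if (n == 0L) "0" else if (n == 1L) "1"
                  else if (n == 2L) "2" else ">2")
}

#' Extended TATA-box motif set
#'
#' A documented approximation of plant cis-regulatory TATA-box variants
#' (the canonical 4-mer plus common A/T extensions); the default scan uses
#' only the literal `TATA`.
#'
#' @return character vector of motifs.
#' @export
tata_motifs <- function() c("TATA", "TATAA", "TATATA", "TTATA", "ATATA")

#' Count upstream CAA motifs
#'
#' @param upstream50 the 50-base (nominal) upstream window, sense strand,
#'   ending at the gene start.
#' @return list with `count_50` (whole window) and `count_10` (occurrences
#'   starting within the 10 bases adjacent to the gene start).
#' @export
scan_caa <- function(upstream50) {
  w <- toupper(upstream50)
  n10 <- substr(w, max(1L, nchar(w) - 9L), nchar(w))
  list(count_50 = length(motif_start_positions(w, "CAA")),
       count_10 = length(motif_start_positions(n10, "CAA")))
}

#' Find downstream poly(T) terminator runs
#'
#' Maximal runs of T of length >= `min_run`, reported 5'-to-3'; the first is
#' the terminator, any later ones are backup signals. Runs touching a window
#' edge are flagged truncated.
#'
#' @param downstream50 the downstream window, sense strand.
#' @param min_run minimum run length (default 4).
#' @return list with `runs` (data.frame offset/length/truncated),
#'   `terminator` (first row or NULL), `n_backup`.
#' @export
scan_polyt <- function(downstream50, min_run = 4L) {
  runs <- find_t_runs(toupper(downstream50), min_run)
  list(runs = runs,
       terminator = if (nrow(runs)) runs[1, , drop = FALSE] else NULL,
       n_backup = max(0L, nrow(runs) - 1L))
}

#' Per-gene regulatory-element report
#'
#' Runs the TATA, CAA and poly(T) scans over a flank table.
#'
#' @param flanks output of [extract_flanks()] (must include `upstream50`
#'   and `downstream50`).
#' @param motifs TATA motif set.
#' @param min_run minimum poly(T) run length.
#' @return data.frame with one row per gene: `tata_count`, `tata_category`,
#'   `caa_count_50`, `caa_count_10`, `term_offset`, `term_length`,
#'   `term_truncated`, `n_backup`, and a `t_runs` list-column of full run
#'   tables.
#' @export
flank_report <- function(flanks, motifs = "TATA", min_run = 4L) {
  n <- nrow(flanks)
  rep1 <- lapply(seq_len(n), function(i) {
    tata <- scan_tata(flanks$upstream50[i], motifs)
    caa <- scan_caa(flanks$upstream50[i])
    pt <- scan_polyt(flanks$downstream50[i], min_run)
    data.frame(gene_id = flanks$gene_id[i],
               tata_count = tata$count, tata_category = tata$category,
               caa_count_50 = caa$count_50, caa_count_10 = caa$count_10,
               term_offset = if (is.null(pt$terminator)) NA_integer_
                             else pt$terminator$offset,
               term_length = if (is.null(pt$terminator)) NA_integer_
                             else pt$terminator$length,
               term_truncated = if (is.null(pt$terminator)) NA
                                else pt$terminator$truncated,
               n_backup = pt$n_backup,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rep1)
  out$t_runs <- lapply(seq_len(n), function(i)
    scan_polyt(flanks$downstream50[i], min_run)$runs)
  out
}

#' Aggregate flank reports into cohort-level percentages
#'
#' The shape of the classical summary tables: percentage of genes with at
#' least one upstream TATA (split by count category), with upstream CAA
#' motifs in the 50- and 10-base windows, and with downstream terminator
#' and backup poly(T) signals, plus terminator-length statistics.
#'
#' @param report output of [flank_report()].
#' @return list of named aggregates.
#' @export
aggregate_flank_reports <- function(report) {
  n <- nrow(report)
  if (n == 0L) stop("empty report")
  has_term <- !is.na(report$term_length)
  list(n_genes = n,
       pct_tata_1 = 100 * mean(report$tata_category == "1"),
       pct_tata_2 = 100 * mean(report$tata_category == "2"),
       pct_tata_gt2 = 100 * mean(report$tata_category == ">2"),
       pct_tata_ge1 = 100 * mean(report$tata_count >= 1),
       pct_caa_50 = 100 * mean(report$caa_count_50 >= 1),
       pct_caa_10 = 100 * mean(report$caa_count_10 >= 1),
       pct_polyt = 100 * mean(has_term),
       pct_backup = 100 * mean(report$n_backup >= 1),
       mean_term_length = if (any(has_term))
         mean(report$term_length[has_term]) else NA_real_,
       term_length_range = if (any(has_term))
         range(report$term_length[has_term]) else c(NA_real_, NA_real_))
}

#' Positional base-composition profile of flank windows
#'
#' @param flanks output of [extract_flanks()].
#' @param window window column name (default `"upstream50"`); truncated
#'   windows are excluded.
#' @param genome optional [tdna_genome] used to add a genome-wide A/T
#'   baseline.
#' @return list with `freq` (4 x L base-frequency matrix), `at_fraction`
#'   (per position), `ic_bits` (2 - Shannon entropy per position, no
#'   small-sample correction), `n_windows`, and `baseline_at` when a genome
#'   is supplied.
#' @export
composition_profile <- function(flanks, window = "upstream50",
                                genome = NULL) {
  trunc_col <- paste0(window, "_trunc")
  keep <- !flanks[[trunc_col]]
  if (!any(keep)) stop("all windows are truncated")
  seqs <- flanks[[window]][keep]
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  L <- ncol(m)
  freq <- vapply(seq_len(L), function(c)
    as.numeric(table(factor(m[, c], levels = c("A", "C", "G", "T"))) /
               nrow(m)),
    numeric(4))
  rownames(freq) <- c("A", "C", "G", "T")
  ent <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  res <- list(freq = freq,
              at_fraction = freq["A", ] + freq["T", ],
              ic_bits = 2 - ent,
              n_windows = nrow(m))
  if (!is.null(genome)) {
    bases <- table(factor(strsplit(paste(genome$contigs, collapse = ""),
                                   "")[[1]],
                          levels = c("A", "C", "G", "T")))
    res$baseline_at <- as.numeric((bases["A"] + bases["T"]) / sum(bases))
  }
  res
}
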
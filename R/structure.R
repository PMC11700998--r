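# Cloverleaf partitioning, internal-promoter (A/B box) extraction by
# structural landmarks, and base-pair covariation scoring over structural
# alignments.

#' Partition a tRNA secondary structure into cloverleaf elements
#'
#' Helices are maximal runs of stacked pairs (pair (i, j) followed by
#' (i+1, j-1); bulges are not allowed — tRNA stems are canonically
#' contiguous and anything else fails loudly). Exactly four helices are
#' required and are assigned in 5' order: acceptor, D, anticodon, T. Loops
#' are the unpaired stretches the helices enclose; the variable loop lies
#' between the anticodon-stem 3' strand and the T-stem 5' strand.
#'
#' @param ss a secondary-structure record as returned by
#'   [read_trnascan_ss()] (list with `sequence` and `pairing`), or a bare
#'   pairing matrix.
#' @return list of class `cloverleaf`: per-stem pair matrices
#'   (`acceptor_stem`, `d_stem`, `anticodon_stem`, `t_stem`), loop position
#'   vectors (0-based: `d_loop`, `anticodon_loop`, `variable_loop`,
#'   `t_loop`) and `lengths` (stems in bp, loops in nt).
#' @export
partition_cloverleaf <- function(ss) {
  pairing <- if (is.list(ss) && !is.null(ss$pairing)) ss$pairing else ss
  if (nrow(pairing) == 0L) stop("empty pairing")
  p <- pairing[order(pairing[, 1]), , drop = FALSE]
  helix_id <- cumsum(c(1L, as.integer(
    !(diff(p[, 1]) == 1L & diff(p[, 2]) == -1L))))
  helices <- split(seq_len(nrow(p)), helix_id)
  if (length(helices) != 4L)
    stop("non-canonical structure: ", length(helices),
         " helices found (expected 4)")
  stems <- lapply(helices, function(idx) p[idx, , drop = FALSE])
  names(stems) <- c("acceptor_stem", "d_stem", "anticodon_stem", "t_stem")
  inner_loop <- function(stem) {
    k <- nrow(stem)
    lo <- stem[k, 1] + 1L; hi <- stem[k, 2] - 1L
    if (lo > hi) integer(0) else lo:hi
  }
  d_loop <- inner_loop(stems$d_stem)
  ac_loop <- inner_loop(stems$anticodon_stem)
  t_loop <- inner_loop(stems$t_stem)
  v_lo <- stems$anticodon_stem[1, 2] + 1L
  v_hi <- stems$t_stem[1, 1] - 1L
  variable_loop <- if (v_lo > v_hi) integer(0) else v_lo:v_hi
  structure(c(stems, list(
    d_loop = d_loop, anticodon_loop = ac_loop, t_loop = t_loop,
    variable_loop = variable_loop,
    lengths = c(acceptor_stem = nrow(stems$acceptor_stem),
                d_stem = nrow(stems$d_stem),
                anticodon_stem = nrow(stems$anticodon_stem),
                t_stem = nrow(stems$t_stem),
                d_loop = length(d_loop),
                anticodon_loop = length(ac_loop),
                t_loop = length(t_loop),
                variable_loop = length(variable_loop)))),
    class = "cloverleaf")
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat("<cloverleaf> stems (bp): ",
      paste(names(x$lengths[1:4]), x$lengths[1:4], sep = "=",
            collapse = " "),
      "\n  loops (nt): ",
      paste(names(x$lengths[5:8]), x$lengths[5:8], sep = "=",
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Extract internal promoter boxes by structural landmarks
#'
#' The A box is the 12-nt window of the mature (intron-spliced) sequence
#' starting at position 8 (1-based); the B box is the 11-nt window starting
#' one base after the first position of the T-stem 5' strand. The conserved
#' residues checked are T...GG for the A box and GG...CC for the B box.
#' Window anchors and lengths are configurable.
#'
#' @param sequence gene sequence (sense strand, intron included if
#'   `intron_start` is given).
#' @param partition a [partition_cloverleaf()] result for the mature
#'   structure.
#' @param intron_start,intron_end optional 0-based half-open intron bounds
#'   relative to the gene sequence; the intron is spliced out first.
#' @param a_box_start 1-based mature start of the A box (default 8).
#' @param a_box_len,b_box_len window lengths (defaults 12 and 11).
#' @param b_box_offset offset from the T-stem 5' first position (default 1).
#' @return list: `a_box`, `b_box`, `a_box_ok`, `b_box_ok`.
#' @export
extract_boxes <- function(sequence, partition,
                          intron_start = NA, intron_end = NA,
                          a_box_start = 8L, a_box_len = 12L,
                          b_box_len = 11L, b_box_offset = 1L) {
  mature <- toupper(sequence)
  if (!is.na(intron_start))
    mature <- paste0(substr(mature, 1L, intron_start),
                     substr(mature, intron_end + 1L, nchar(mature)))
  a_end <- a_box_start + a_box_len - 1L
  t5_first <- partition$t_stem[1, 1] + 1L          # 1-based
  b_start <- t5_first + b_box_offset
  b_end <- b_start + b_box_len - 1L
  if (nchar(mature) < max(a_end, b_end))
    stop("mature sequence too short for the requested box windows")
  a_box <- substr(mature, a_box_start, a_end)
  b_box <- substr(mature, b_start, b_end)
  list(a_box = a_box, b_box = b_box,
       a_box_ok = startsWith(a_box, "T") && endsWith(a_box, "GG"),
       b_box_ok = startsWith(b_box, "GG") && endsWith(b_box, "CC"))
}

PAIRABLE <- c("AT", "TA", "GC", "CG", "GT", "TG")

#' Base-pair covariation scores over a structural alignment
#'
#' For each base pair (i, j) of the reference structure, with N aligned
#' sequences: a sequence is pairable at (i, j) if its two bases form a
#' Watson-Crick or GT wobble pair (gaps are non-pairable); q is the
#' non-pairable fraction; B is the mean Hamming distance between the
#' two-base tuples of all unordered sequence pairs in which both sequences
#' are pairable, normalised by C(N, 2); the score is `B - phi * q`, in
#' `[-phi, 2]`. Positive scores indicate compensatory (covarying) pairs,
#' negative scores pairing-disrupting variation.
#'
#' @param alignment character matrix (rows = gapped sequences) or character
#'   vector of equal-length sequences.
#' @param structure reference structure: dot-bracket string over alignment
#'   columns, or a 2-column 0-based pairing matrix.
#' @param phi penalty weight on the non-pairable fraction (default 1).
#' @return data.frame: i, j (0-based alignment columns), n_pairable,
#'   n_nonpairable, B, q, score, classification
#'   (`positive`/`negative`/`zero`, zero at |score| < 1e-12).
#' @export
covariation_scores <- function(alignment, structure, phi = 1) {
  if (!is.matrix(alignment)) alignment <- alignment_matrix(alignment)
  N <- nrow(alignment)
  if (N == 0L) stop("empty alignment")
  pairs <- if (is.character(structure)) parse_pairing(structure)
           else structure
  if (nrow(pairs) > 0L && max(pairs) >= ncol(alignment))
    stop("structure column index outside alignment (width ",
         ncol(alignment), ")")
  denom <- choose(N, 2)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    bi <- alignment[, i + 1L]; bj <- alignment[, j + 1L]
    pairable <- paste0(bi, bj) %in% PAIRABLE
    q <- mean(!pairable)
    m <- sum(pairable)
    B <- 0
    if (m >= 2L && denom > 0) {
      diff_at <- function(x) {
        tab <- table(x[pairable])
        choose(m, 2) - sum(choose(tab, 2))
      }
      B <- (diff_at(bi) + diff_at(bj)) / denom
    }
    s <- B - phi * q
    data.frame(i = i, j = j, n_pairable = m, n_nonpairable = N - m,
               B = B, q = q, score = s,
               classification = if (abs(s) < 1e-12) "zero"
                                else if (s > 0) "positive" else "negative",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(i = integer(), j = integer(), n_pairable = integer(),
               n_nonpairable = integer(), B = numeric(), q = numeric(),
               score = numeric(), classification = character())
  out
}
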
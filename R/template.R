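# Canonical 72-nt cloverleaf template used by the synthetic-genome
# generator. Stems are 7/4/5/5 bp (acceptor/D/anticodon/T) with a 4-nt
# variable loop; the anticodon sits at mature positions 34-36 (1-based) and
# introns are inserted at the canonical 37/38 position. The backbone carries
# the conserved internal-promoter residues: the A box (mature 8-19) starts
# with T and ends with GG, the B box (T-stem anchored, 11 nt) starts with GG
# and ends with CC.

# Backbone blocks, 0-based layout:
#   0-6 acceptor 5' | 7-8 spacer | 9-12 D 5' | 13-20 D loop | 21-24 D 3'
#   25 spacer | 26-30 AC 5' | 31-37 AC loop (anticodon 33-35) | 38-42 AC 3'
#   43-46 variable loop | 47-51 T 5' | 52-58 T loop | 59-63 T 3'
#   64-70 acceptor 3' | 71 discriminator
TEMPLATE_BACKBONE <- paste0(
  "GGGCGTG", "TA", "GCTC", "AGTTGGTA", "GAGC", "A",
  "CTGGC", "CT", "NNN", "AA", "GCCAG", "ATTC",
  "TGGAG", "TTCGACC", "CTCCA", "CACGCCC", "A")

# Base-pair table of the canonical template (0-based mature positions).
template_pairing <- function() {
  acc <- cbind(0:6, 70:64)
  d <- cbind(9:12, 24:21)
  ac <- cbind(26:30, 42:38)
  t <- cbind(47:51, 63:59)
  m <- rbind(acc, d, ac, t)
  colnames(m) <- c("i", "j")
  m
}

# Loop/spacer positions free to vary between isotype backbones; excludes the
# anticodon, all stem bases and the checked A/B box boundary residues.
TEMPLATE_FREE_POS <- c(13:16, 19, 20, 25, 31, 32, 36, 37, 43:46, 52:56, 71)

# Representative anticodon per isotype (used by the cohort generator).
ISO_ANTICODONS <- c(
  Ala = "AGC", Arg = "ACG", Asn = "GTT", Asp = "GTC", Cys = "GCA",
  Gln = "TTG", Glu = "TTC", Gly = "GCC", His = "GTG", Ile = "AAT",
  Leu = "AAG", Lys = "CTT", eMet = "CAT", iMet = "CAT", Phe = "GAA",
  Pro = "TGG", Ser = "AGA", Thr = "AGT", Trp = "CCA", Tyr = "GTA",
  Val = "AAC")

#' Build a synthetic tRNA gene from the canonical cloverleaf template
#'
#' Produces a 72-nt gene with stems of 7/4/5/5 base pairs, the requested
#' anticodon at mature positions 34-36 (1-based) and, optionally, an intron
#' inserted after mature position 37. Each isotype gets a fixed backbone
#' (deterministic loop-position variants of the canonical template) so that
#' different isotypes yield distinct but reproducible sequences.
#'
#' Intron sequences start with GCT and end with GAGT — the residues
#' conserved across plant tRNA-eMet introns — with a seeded random interior.
#'
#' @param isotype isotype label (any string; determines the backbone).
#' @param anticodon 3-mer over A/C/G/T.
#' @param intron_length 0 (no intron) or a length in `[8, 200]`.
#' @param seed integer seed for the intron interior.
#' @return list with `sequence` (the gene, intron included), `mature`
#'   (intron-spliced sequence), `pairing` (0-based pairs on the mature
#'   sequence), `intron_start`/`intron_end` (0-based half-open, relative to
#'   the gene; `NA` when intron-less) and `anticodon`.
#' @export
build_trna_template <- function(isotype, anticodon, intron_length = 0L,
                                seed = 1L) {
  if (!grepl("^[ACGT]{3}$", anticodon))
    stop("anticodon must be a 3-mer over A/C/G/T: ", anticodon)
  if (intron_length != 0L && (intron_length < 8L || intron_length > 200L))
    stop("intron_length must be 0 or in [8, 200], got ", intron_length)
  s <- strsplit(TEMPLATE_BACKBONE, "", fixed = TRUE)[[1]]
  # deterministic isotype variation at free loop positions
  h <- sum(utf8ToInt(isotype)) + seq_along(TEMPLATE_FREE_POS) * 7L
  n_var <- 6L
  vary <- TEMPLATE_FREE_POS[order(h %% 31L)[seq_len(n_var)]]
  s[vary + 1L] <- c("A", "C", "G", "T")[(h[order(h %% 31L)[seq_len(n_var)]] %% 4L) + 1L]
  s[34:36] <- strsplit(anticodon, "", fixed = TRUE)[[1]]
  mature <- paste(s, collapse = "")
  if (intron_length == 0L) {
    return(list(sequence = mature, mature = mature,
                pairing = template_pairing(),
                intron_start = NA_integer_, intron_end = NA_integer_,
                anticodon = anticodon))
  }
  interior <- with_seed(seed, {
    n_mid <- intron_length - 7L
    if (n_mid > 0L) paste(sample(c("A", "C", "G", "T"), n_mid,
                                 replace = TRUE, prob = c(.35, .15, .15, .35)),
                          collapse = "") else ""
  })
  intron <- paste0("GCT", interior, "GAGT")
  intron <- substr(intron, 1L, intron_length)  # length 8 exactly -> GCT.GAGT
  gene <- paste0(substr(mature, 1, 37), intron,
                 substr(mature, 38, nchar(mature)))
  list(sequence = gene, mature = mature, pairing = template_pairing(),
       intron_start = 37L, intron_end = 37L + intron_length,
       anticodon = anticodon)
}
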
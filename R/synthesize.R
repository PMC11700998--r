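# Synthetic genomes with planted tDNA features and machine-readable ground
# truth. The generator is the package's study-condition stand-in for real
# assemblies: genes are canonical cloverleaf templates, regulatory elements
# (upstream TATA/CAA, downstream poly(T) terminators with optional backups)
# are written into the flanking windows at known offsets, tandem/alternating
# layouts realize the cluster criterion, and background sequence inside the
# declared windows is sanitized so no accidental motif or T-run inflates the
# expected counts.

#' Describe one planted tRNA gene specification
#'
#' @param isotype isotype label (e.g. `"Pro"`, `"eMet"`).
#' @param anticodon 3-mer; default looked up from the representative table.
#' @param strand `"+"` or `"-"` (applies to the whole group).
#' @param copy_number number of copies (for `alternating`, number of pairs).
#' @param layout `"scattered"` (each copy placed independently), `"tandem"`
#'   (copies in a run separated by `spacer_bp`) or `"alternating"` (copies
#'   interleaved with `partner`).
#' @param spacer_bp end-to-start gap between neighbouring copies in a
#'   tandem/alternating group.
#' @param partner a second `gene_spec` for `alternating` layouts.
#' @param intron_length 0 or a length in `[8, 200]`; introns go in at the
#'   canonical position after the 37th mature base.
#' @param upstream_motifs `data.frame(motif, offset)`: each motif is planted
#'   so that it ends `offset - nchar(motif)` bases before the gene start
#'   (i.e. `offset` counts bases upstream from the gene start to the motif
#'   start).
#' @param downstream_t_runs `data.frame(length, offset)`: T-runs planted
#'   `offset` bases after the gene end; the first is the terminator,
#'   subsequent ones are backups.
#' @param mutate_copies number of random substitutions applied per copy.
#' @return list of class `gene_spec`.
#' @export
gene_spec <- function(isotype, anticodon = NULL, strand = "+",
                      copy_number = 1L,
                      layout = c("scattered", "tandem", "alternating"),
                      spacer_bp = 100L, partner = NULL,
                      intron_length = 0L,
                      upstream_motifs = NULL, downstream_t_runs = NULL,
                      mutate_copies = 0L) {
  layout <- match.arg(layout)
  if (is.null(anticodon)) {
    if (!isotype %in% names(ISO_ANTICODONS))
      stop("no default anticodon for isotype ", isotype)
    anticodon <- ISO_ANTICODONS[[isotype]]
  }
  if (layout == "alternating" && is.null(partner))
    stop("alternating layout requires a partner gene_spec")
  if (!is.null(upstream_motifs))
    stopifnot(all(c("motif", "offset") %in% names(upstream_motifs)))
  if (!is.null(downstream_t_runs))
    stopifnot(all(c("length", "offset") %in% names(downstream_t_runs)))
  structure(list(isotype = isotype, anticodon = anticodon, strand = strand,
                 copy_number = as.integer(copy_number), layout = layout,
                 spacer_bp = as.integer(spacer_bp), partner = partner,
                 intron_length = as.integer(intron_length),
                 upstream_motifs = upstream_motifs,
                 downstream_t_runs = downstream_t_runs,
                 mutate_copies = as.integer(mutate_copies)),
            class = "gene_spec")
}

# n random substitutions, never replacing a base with itself
mutate_seq <- function(seq, n) {
  if (n <= 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), min(n, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Expand gene_specs into placement groups (lists of per-gene spec rows).
expand_groups <- function(specs) {
  groups <- list()
  for (sp in specs) {
    if (sp$layout == "scattered") {
      for (k in seq_len(sp$copy_number))
        groups[[length(groups) + 1L]] <-
          list(members = list(sp), spacer = sp$spacer_bp,
               strand = sp$strand, layout = "scattered")
    } else if (sp$layout == "tandem") {
      groups[[length(groups) + 1L]] <-
        list(members = rep(list(sp), sp$copy_number), spacer = sp$spacer_bp,
             strand = sp$strand, layout = "tandem")
    } else {
      mem <- list()
      for (k in seq_len(sp$copy_number)) {
        mem[[length(mem) + 1L]] <- sp
        mem[[length(mem) + 1L]] <- sp$partner
      }
      groups[[length(groups) + 1L]] <-
        list(members = mem, spacer = sp$spacer_bp,
             strand = sp$strand, layout = "alternating")
    }
  }
  groups
}

# Build one sense-strand cassette for a group: background + genes + planted
# elements, sanitized windows, expected per-gene truth. Returns the cassette
# character vector plus relative gene metadata.
build_cassette <- function(group, base_freq, w_up, w_down, min_t_run,
                           motif_set) {
  members <- group$members
  n <- length(members)
  tmpl <- vector("list", n)
  lens <- integer(n)
  for (k in seq_len(n)) {
    m <- members[[k]]
    tm <- build_trna_template(m$isotype, m$anticodon, m$intron_length,
                              seed = sample.int(2^30, 1))
    seq <- mutate_seq(tm$sequence, m$mutate_copies)
    tmpl[[k]] <- list(seq = seq, intron_start = tm$intron_start,
                      intron_end = tm$intron_end, spec = m)
    lens[k] <- nchar(seq)
  }
  spacer <- group$spacer
  starts <- w_up + cumsum(c(0L, head(lens, -1) + spacer))
  ends <- starts + lens
  clen <- w_up + sum(lens) + (n - 1L) * spacer + w_down
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, clen, replace = TRUE, prob = base_freq)
  mask <- logical(clen)
  for (k in seq_len(n)) {
    idx <- (starts[k] + 1L):ends[k]
    chars[idx] <- strsplit(tmpl[[k]]$seq, "", fixed = TRUE)[[1]]
    mask[idx] <- TRUE
  }
  # plant upstream motifs and downstream T-runs
  for (k in seq_len(n)) {
    m <- members[[k]]
    if (!is.null(m$upstream_motifs)) {
      for (r in seq_len(nrow(m$upstream_motifs))) {
        mo <- toupper(m$upstream_motifs$motif[r])
        off <- m$upstream_motifs$offset[r]
        if (off < nchar(mo) || off > w_up)
          stop("upstream motif offset ", off, " does not fit window of ", w_up)
        p0 <- starts[k] - off          # 0-based motif start
        if (p0 < 0L) stop("motif extends beyond cassette start")
        idx <- (p0 + 1L):(p0 + nchar(mo))
        if (any(mask[idx])) stop("planted motif overlaps another feature")
        chars[idx] <- strsplit(mo, "", fixed = TRUE)[[1]]
        mask[idx] <- TRUE
      }
    }
    if (!is.null(m$downstream_t_runs)) {
      for (r in seq_len(nrow(m$downstream_t_runs))) {
        len <- m$downstream_t_runs$length[r]
        off <- m$downstream_t_runs$offset[r]
        if (off + len > w_down)
          stop("T-run (offset ", off, ", length ", len,
               ") does not fit window of ", w_down)
        p0 <- ends[k] + off
        idx <- (p0 + 1L):(p0 + len)
        if (any(mask[idx])) stop("planted T-run overlaps another feature")
        chars[idx] <- "T"
        mask[idx] <- TRUE
        for (b in c(p0, p0 + len + 1L)) {  # non-T boundaries keep runs maximal
          if (b >= 1L && b <= clen && !mask[b] && chars[b] == "T")
            chars[b] <- sample(c("A", "C", "G"), 1)
        }
      }
    }
  }
  # sanitize: no accidental TATA/CAA upstream, no accidental T-runs downstream
  scrub <- c(motif_set, "CAA")
  for (k in seq_len(n)) {
    up <- (starts[k] - w_up + 1L):starts[k]       # 1-based window indices
    dn <- (ends[k] + 1L):(ends[k] + w_down)
    for (iter in 1:100) {
      changed <- FALSE
      w <- paste(chars[up], collapse = "")
      for (mo in scrub) {
        for (p in motif_start_positions(w, mo)) {   # 0-based in window
          idx <- up[(p + 1L):(p + nchar(mo))]
          free <- idx[!mask[idx]]
          planted <- all(mask[idx])
          if (!planted && length(free) > 0L) {
            chars[free[1]] <- "G"
            changed <- TRUE
          }
        }
      }
      d <- paste(chars[dn], collapse = "")
      runs <- find_t_runs(d, min_t_run)
      if (nrow(runs) > 0L) {
        for (r in seq_len(nrow(runs))) {
          idx <- dn[(runs$offset[r] + 1L):(runs$offset[r] + runs$length[r])]
          free <- idx[!mask[idx]]
          if (length(free) > 0L && !all(mask[idx])) {
            chars[free[1]] <- "G"
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  # expected truth from the final sense-strand windows
  truth <- lapply(seq_len(n), function(k) {
    up <- paste(chars[(starts[k] - w_up + 1L):starts[k]], collapse = "")
    dn <- paste(chars[(ends[k] + 1L):(ends[k] + w_down)], collapse = "")
    runs <- find_t_runs(dn, min_t_run)
    tata <- length(unique(unlist(lapply(motif_set, function(m)
      motif_start_positions(up, m)))))
    list(tata_count = tata,
         caa_count_50 = length(motif_start_positions(up, "CAA")),
         caa_count_10 = length(motif_start_positions(
           substr(up, nchar(up) - 9L, nchar(up)), "CAA")),
         t_runs = runs,
         term_length = if (nrow(runs)) runs$length[1] else NA_integer_,
         n_backup = max(0L, nrow(runs) - 1L),
         intron_seq = if (!is.na(tmpl[[k]]$intron_start))
           substr(paste(chars[(starts[k] + 1L):ends[k]], collapse = ""),
                  tmpl[[k]]$intron_start + 1L, tmpl[[k]]$intron_end)
           else NA_character_)
  })
  # orient the cassette
  strand <- group$strand
  if (strand == "-") {
    chars <- rev(chartr("ACGT", "TGCA", chars))
    new_starts <- clen - ends
    ends <- clen - starts
    starts <- new_starts
    ord <- order(starts)
  } else ord <- seq_len(n)
  gene_rel <- data.frame(
    start = starts, end = ends, strand = strand,
    isotype = vapply(members, `[[`, character(1), "isotype"),
    anticodon = vapply(members, `[[`, character(1), "anticodon"),
    intron_rel_start = vapply(tmpl, function(t)
      if (is.na(t$intron_start)) NA_integer_ else t$intron_start, integer(1)),
    intron_rel_end = vapply(tmpl, function(t)
      if (is.na(t$intron_end)) NA_integer_ else t$intron_end, integer(1)),
    stringsAsFactors = FALSE)
  list(chars = chars, len = clen, genes = gene_rel, truth = truth,
       order = ord, layout = group$layout, spacer = group$spacer)
}

#' Synthesize a genome with planted tDNA features and ground truth
#'
#' Background sequence is drawn i.i.d. from `base_freq`; gene cassettes
#' (gene + flanking windows with planted motifs) are placed without overlap
#' and with enough separation (`> gap_bp`) that the only clusters present
#' are the planted tandem/alternating groups. Minus-strand groups are
#' reverse-complemented into the contig. All randomness flows through
#' `seed`; two calls with the same arguments are identical.
#'
#' @param specs list of [gene_spec()] objects.
#' @param contig_lengths named integer vector of contig lengths.
#' @param seed integer seed (mandatory).
#' @param base_freq background base probabilities, named A/C/G/T.
#' @param genome_id,lineage genome metadata.
#' @param gap_bp cluster merge distance the layout is guarded against.
#' @param upstream_window,downstream_window flank window sizes within which
#'   motif truth is maintained.
#' @param min_t_run minimum poly(T) run length treated as a signal.
#' @param motif_set TATA motif set used for expected counts.
#' @param score_range range of simulated bit scores.
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `annotation.out` (tRNAscan dialect) and `truth.json`.
#' @return list with `genome` ([tdna_genome]), `records` ([tdna_records],
#'   `gene_seq` populated) and `manifest` (ground truth: per-gene loci,
#'   motif counts, T-runs, intron sequences; expected clusters; expected
#'   unique-sequence percentage).
#' @export
synthesize_genome <- function(specs, contig_lengths = c(chr1 = 200000L),
                              seed,
                              base_freq = c(A = .3, C = .2, G = .2, T = .3),
                              genome_id = "syn1", lineage = "other",
                              gap_bp = 1000L,
                              upstream_window = 50L, downstream_window = 50L,
                              min_t_run = 4L, motif_set = "TATA",
                              score_range = c(96, 120), dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (inherits(specs, "gene_spec")) specs <- list(specs)
  base_freq <- base_freq[c("A", "C", "G", "T")]
  with_seed(seed, {
    groups <- expand_groups(specs)
    cassettes <- lapply(groups, build_cassette, base_freq = base_freq,
                        w_up = upstream_window, w_down = downstream_window,
                        min_t_run = min_t_run, motif_set = motif_set)
    # background contigs
    contigs <- lapply(contig_lengths, function(L)
      sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = base_freq))
    names(contigs) <- names(contig_lengths)
    guard <- gap_bp + 100L
    occupied <- lapply(contig_lengths, function(L) matrix(numeric(0), ncol = 2))
    placements <- vector("list", length(cassettes))
    for (ci in sample(seq_along(cassettes))) {
      cs <- cassettes[[ci]]
      placed <- FALSE
      for (att in 1:1000) {
        tc <- sample(names(contig_lengths), 1,
                     prob = as.numeric(contig_lengths))
        L <- contig_lengths[[tc]]
        if (L <= cs$len) next
        pos <- sample.int(L - cs$len, 1) - 1L   # 0-based cassette start
        occ <- occupied[[tc]]
        if (nrow(occ) == 0L ||
            all(pos >= occ[, 2] + guard | pos + cs$len <= occ[, 1] - guard)) {
          occupied[[tc]] <- rbind(occ, c(pos, pos + cs$len))
          contigs[[tc]][(pos + 1L):(pos + cs$len)] <- cs$chars
          placements[[ci]] <- list(contig = tc, pos = pos)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place cassette ", ci,
                        " without overlap after 1000 attempts")
    }
    # assemble records and truth
    rows <- list(); truths <- list(); cluster_rows <- list()
    gk <- 0L
    for (ci in seq_along(cassettes)) {
      cs <- cassettes[[ci]]
      pl <- placements[[ci]]
      n <- nrow(cs$genes)
      ids <- character(n)
      for (k in seq_len(n)) {
        gk <- gk + 1L
        ids[k] <- sprintf("%s_g%03d", genome_id, gk)
        g <- cs$genes[k, ]
        abs_start <- pl$pos + g$start
        abs_end <- pl$pos + g$end
        intron <- if (is.na(g$intron_rel_start)) c(NA_integer_, NA_integer_)
          else if (g$strand == "+")
            c(abs_start + g$intron_rel_start, abs_start + g$intron_rel_end)
          else c(abs_end - g$intron_rel_end, abs_end - g$intron_rel_start)
        rows[[gk]] <- data.frame(
          gene_id = ids[k], contig = pl$contig,
          start = abs_start, end = abs_end, strand = g$strand,
          isotype = g$isotype, anticodon = g$anticodon,
          intron_start = intron[1], intron_end = intron[2],
          score = round(stats::runif(1, score_range[1], score_range[2]), 1),
          note = "", stringsAsFactors = FALSE)
        truths[[gk]] <- c(list(gene_id = ids[k]), cs$truth[[k]])
      }
      if (n >= 3L && cs$spacer <= gap_bp && cs$layout != "scattered") {
        iso <- cs$genes$isotype[cs$order]
        cluster_rows[[length(cluster_rows) + 1L]] <- list(
          contig = pl$contig,
          start = pl$pos + min(cs$genes$start),
          end = pl$pos + max(cs$genes$end),
          size = n, members = ids[cs$order],
          pattern = classify_pattern(iso))
      }
    }
    rec <- do.call(rbind, rows)
    rec <- tdna_records(rec$gene_id, rec$contig, rec$start, rec$end,
                        rec$strand, rec$isotype, rec$anticodon,
                        rec$intron_start, rec$intron_end, rec$score, rec$note)
    genome <- tdna_genome(genome_id,
                          vapply(contigs, paste, character(1), collapse = ""),
                          lineage = lineage)
    rec <- attach_gene_sequences(rec, genome)
    manifest <- list(
      genome_id = genome_id, seed = seed, lineage = lineage,
      params = list(gap_bp = gap_bp, upstream_window = upstream_window,
                    downstream_window = downstream_window,
                    min_t_run = min_t_run, motif_set = motif_set),
      genes = truths,
      expected_clusters = cluster_rows,
      expected_unique_pct = 100 * length(unique(rec$gene_seq)) / nrow(rec))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(genome$contigs, file.path(dir, "genome.fa"))
      write_trnascan_table(rec, file.path(dir, "annotation.out"))
      jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(genome = genome, records = rec, manifest = manifest)
  })
}

#' Synthesize a cohort with a controlled gene-count/genome-size relationship
#'
#' Gene count per genome is `round(intercept + slope * size_Mb + N(0, sd))`,
#' floored at 1, with genes scattered along a single contig. Intended to
#' exercise the count-vs-size regression: by default only gene placements,
#' sequences and metadata are generated; set `realize = TRUE` (with small
#' sizes) to also realize contig background so sequence-level analyses can
#' run on the cohort.
#'
#' @param n_genomes number of genomes (>= 3).
#' @param size_range genome size range in Mb; sizes are evenly spaced.
#' @param slope,intercept,noise_sd generating regression parameters
#'   (genes per Mb / genes / genes).
#' @param lineages lineage labels recycled across genomes.
#' @param seed integer seed.
#' @param copy_mutations substitutions per gene relative to its isotype
#'   template (controls sequence uniqueness).
#' @param shared_sequence optional sequence planted verbatim (as one extra
#'   plus-strand gene) in every genome, for cross-genome identity analyses.
#' @param realize realize contig background sequence (memory scales with
#'   genome size; keep sizes small).
#' @param annotate generate per-gene records and sequences (default TRUE).
#'   With `annotate = FALSE` only genome metadata and realized gene counts
#'   are produced — enough for the count-vs-size regression and cheap at
#'   any scale. Counts are drawn before annotation, so they are identical
#'   either way for a given seed.
#' @return list with `genomes`, `records` (parallel lists; `NULL` when
#'   `annotate = FALSE`) and `manifest` (generating parameters, sizes in
#'   Mb, realized counts).
#' @export
synthesize_cohort <- function(n_genomes = 69L, size_range = c(120, 4800),
                              slope = 0.28, intercept = 150, noise_sd = 160,
                              lineages = c("eudicot", "monocot", "ANA"),
                              seed, copy_mutations = 1L,
                              shared_sequence = NULL, realize = FALSE,
                              annotate = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_genomes < 3L) stop("n_genomes must be >= 3")
  if (size_range[1] == size_range[2] && noise_sd == 0)
    stop("degenerate size range with zero noise: regression undefined")
  with_seed(seed, {
    sizes_mb <- seq(size_range[1], size_range[2], length.out = n_genomes)
    counts <- pmax(1L, as.integer(round(
      intercept + slope * sizes_mb + stats::rnorm(n_genomes, 0, noise_sd))))
    lin <- rep_len(lineages, n_genomes)
    iso_pool <- names(ISO_ANTICODONS)
    genomes <- vector("list", n_genomes)
    records <- vector("list", n_genomes)
    for (g in seq_len(n_genomes)) {
      gid <- sprintf("cg%03d", g)
      size_bp <- round(sizes_mb[g] * 1e6)
      if (!annotate) {
        genomes[[g]] <- tdna_genome(gid, NULL, lineage = lin[g],
                                    size_bp = size_bp)
        next
      }
      n <- counts[g]
      extra <- !is.null(shared_sequence)
      ntot <- n + extra
      isos <- sample(iso_pool, n, replace = TRUE)
      seqs <- vapply(isos, function(it) {
        mutate_seq(build_trna_template(it, ISO_ANTICODONS[[it]], 0L,
                                       seed = sample.int(2^30, 1))$sequence,
                   copy_mutations)
      }, character(1))
      if (extra) {
        isos <- c(isos, "Ala")
        seqs <- c(seqs, toupper(shared_sequence))
      }
      lens <- nchar(seqs)
      pitch <- max(2500, floor(size_bp / (ntot + 1)))
      starts <- (seq_len(ntot)) * pitch
      if (starts[ntot] + max(lens) > size_bp)
        stop("genome too small for ", ntot, " scattered genes")
      strands <- c(sample(c("+", "-"), n, replace = TRUE),
                   if (extra) "+")
      rec <- tdna_records(
        gene_id = sprintf("%s_g%04d", gid, seq_len(ntot)),
        contig = "chr1", start = starts, end = starts + lens,
        strand = strands, isotype = isos,
        anticodon = ISO_ANTICODONS[isos],
        score = round(stats::runif(ntot, 96, 120), 1),
        gene_seq = seqs)
      if (realize) {
        bg <- sample(c("A", "C", "G", "T"), size_bp, replace = TRUE,
                     prob = c(.3, .2, .2, .3))
        for (k in seq_len(ntot)) {
          s <- if (strands[k] == "+") seqs[k] else revcomp(seqs[k])
          bg[(starts[k] + 1L):(starts[k] + lens[k])] <-
            strsplit(s, "", fixed = TRUE)[[1]]
        }
        genomes[[g]] <- tdna_genome(gid, c(chr1 = paste(bg, collapse = "")),
                                    lineage = lin[g])
      } else {
        genomes[[g]] <- tdna_genome(gid, NULL, lineage = lin[g],
                                    size_bp = size_bp)
      }
      records[[g]] <- rec
    }
    ids <- vapply(genomes, `[[`, character(1), "genome_id")
    names(genomes) <- ids
    if (annotate) names(records) <- ids else records <- NULL
    list(genomes = genomes, records = records,
         manifest = list(slope = slope, intercept = intercept,
                         noise_sd = noise_sd, sizes_mb = sizes_mb,
                         counts = counts, lineages = lin, seed = seed))
  })
}
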
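# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (quadratic closures, exhaustive enumeration, per-char
# loops): they must stay independent of the implementation they check.

# ---- cluster oracle: transitive closure over pairwise gap <= threshold ----

# membership sets of all >= min_size components under pairwise linkage
cluster_oracle <- function(starts, ends, ids, gap_bp, min_size = 3L) {
  n <- length(starts)
  if (n == 0L) return(list())
  gap <- outer(starts, ends, function(s, e) s - e)     # gap[i,j] = s_i - e_j
  link <- (pmax(gap, t(gap)) <= gap_bp)
  diag(link) <- TRUE
  comp <- integer(n)
  cid <- 0L
  for (seed_node in seq_len(n)) {
    if (comp[seed_node] != 0L) next
    cid <- cid + 1L
    queue <- seed_node
    comp[seed_node] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(link[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  groups <- split(seq_len(n), comp)
  groups <- Filter(function(g) length(g) >= min_size, groups)
  lapply(groups, function(g) sort(ids[g]))
}

random_layout <- function(n, contig_len = 50000L) {
  starts <- sort(sample.int(contig_len, n))
  lens <- sample(60:90, n, replace = TRUE)
  # avoid containment weirdness: keep intervals disjoint-ish but allow overlap
  tdna_records(gene_id = paste0("g", seq_len(n)), contig = "c1",
               start = starts, end = starts + lens,
               strand = sample(c("+", "-"), n, replace = TRUE),
               isotype = sample(c("Ala", "Pro", "Ser"), n, replace = TRUE),
               anticodon = "AGC", score = 100)
}

cluster_sets <- function(clusters) {
  if (nrow(clusters) == 0L) return(list())
  unname(lapply(clusters$members, sort))
}

same_set_of_sets <- function(a, b) {
  key <- function(l) unname(sort(vapply(l, paste, character(1),
                                        collapse = ",")))
  identical(key(a), key(b))
}

# ---- naive per-character scan oracles ----

naive_motif_count <- function(window, motif) {
  n <- 0L
  lw <- nchar(window); lm <- nchar(motif)
  if (lw < lm) return(0L)
  for (p in 1:(lw - lm + 1L))
    if (substr(window, p, p + lm - 1L) == motif) n <- n + 1L
  n
}

naive_t_runs <- function(window, min_run) {
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  runs <- list()
  p <- 1L
  while (p <= length(ch)) {
    if (ch[p] == "T") {
      q <- p
      while (q < length(ch) && ch[q + 1L] == "T") q <- q + 1L
      if (q - p + 1L >= min_run)
        runs[[length(runs) + 1L]] <- c(offset = p - 1L, length = q - p + 1L)
      p <- q + 1L
    } else p <- p + 1L
  }
  if (length(runs) == 0L)
    return(data.frame(offset = integer(), length = integer()))
  as.data.frame(do.call(rbind, runs))
}

random_window <- function(len = 50L)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

# ---- reconciliation oracles ----

# all node pairs LCA by explicit ancestor chains
naive_lca <- function(tree, a, b) {
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  chain <- function(v) {
    out <- v
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  }
  ca <- chain(a)
  for (v in chain(b)) if (v %in% ca) return(v)
  stop("no common ancestor")
}

# Exhaustive minimum-duplication count over all consistent mappings with
# event assignments: a gene node can be a speciation mapped to species node
# s only if s is a strict ancestor of both child mappings and the children
# descend through two *different* child subtrees of s; otherwise the node
# is a duplication (s ancestor-or-equal of both child mappings).
min_dup_enum <- function(gene_tree, species_tree, leaf_map) {
  ntip_g <- ape::Ntip(gene_tree)
  ntip_s <- ape::Ntip(species_tree)
  n_s <- ntip_s + species_tree$Nnode
  parent_s <- integer(n_s)
  parent_s[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  anc <- matrix(FALSE, n_s, n_s)   # anc[a, b]: a ancestor-or-equal of b
  for (b in seq_len(n_s)) {
    v <- b
    repeat {
      anc[v, b] <- TRUE
      if (parent_s[v] == 0L) break
      v <- parent_s[v]
    }
  }
  sp_ch <- vector("list", n_s)
  for (r in seq_len(nrow(species_tree$edge)))
    sp_ch[[species_tree$edge[r, 1]]] <- c(sp_ch[[species_tree$edge[r, 1]]],
                                          species_tree$edge[r, 2])
  ch <- list()
  for (r in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[r, 1]
    ch[[as.character(u)]] <- c(ch[[as.character(u)]], gene_tree$edge[r, 2])
  }
  sp_tip_id <- stats::setNames(seq_len(ntip_s), species_tree$tip.label)
  M <- integer(ntip_g + gene_tree$Nnode)
  M[seq_len(ntip_g)] <- sp_tip_id[leaf_map[gene_tree$tip.label]]
  po <- ape::reorder.phylo(gene_tree, "postorder")$edge
  root <- setdiff(po[, 1], po[, 2])
  internal_po <- unique(c(po[po[, 2] > ntip_g, 2], root))
  best <- Inf
  recurse <- function(k, M, dups) {
    if (dups >= best) return()
    if (k > length(internal_po)) { best <<- min(best, dups); return() }
    v <- internal_po[k]
    kids <- ch[[as.character(v)]]
    m1 <- M[kids[1]]; m2 <- M[kids[2]]
    for (s in seq_len(n_s)) {
      if (anc[s, m1] && anc[s, m2]) {
        spec_ok <- FALSE
        if (s != m1 && s != m2) {
          k1 <- sp_ch[[s]][anc[sp_ch[[s]], m1]]
          k2 <- sp_ch[[s]][anc[sp_ch[[s]], m2]]
          spec_ok <- length(k1) == 1L && length(k2) == 1L && k1 != k2
        }
        M[v] <- s
        recurse(k + 1L, M, dups + as.integer(!spec_ok))
      }
    }
  }
  recurse(1L, M, 0L)
  as.integer(best)
}

# all rooted binary topologies over distinct leaf names, as newick strings
all_topologies <- function(leaves) {
  if (length(leaves) == 1L) return(leaves)
  out <- character(0)
  n <- length(leaves)
  # unordered splits: fix leaves[1] in the left part
  for (sz in 1:(n - 1L)) {
    rest <- leaves[-1]
    combs <- utils::combn(rest, sz - 1L, simplify = FALSE)
    if (sz == 1L) combs <- list(character(0))
    for (cmb in combs) {
      left <- c(leaves[1], cmb)
      right <- setdiff(leaves, left)
      if (length(right) == 0L) next
      for (lt in all_topologies(left))
        for (rt in all_topologies(right))
          out <- c(out, paste0("(", lt, ",", rt, ")"))
    }
  }
  out
}

random_gene_species_pair <- function(n_gene, n_species) {
  species <- LETTERS[seq_len(n_species)]
  st <- ape::rtree(n_species, rooted = TRUE, tip.label = species)
  st$edge.length <- NULL
  gt <- ape::rtree(n_gene, rooted = TRUE)
  gt$edge.length <- NULL
  sp <- sample(species, n_gene, replace = TRUE)
  gt$tip.label <- paste0(sp, "_", seq_len(n_gene))
  list(gene = gt, species = st,
       leaf_map = stats::setNames(sp, gt$tip.label))
}

# ---- covariation alignment simulators ----

PAIR_SET <- c("AT", "TA", "GC", "CG", "GT", "TG")

# n sequences over n_pair structural pairs: columns 2k-1/2k are a pair
compensatory_alignment <- function(n, n_pair) {
  rows <- replicate(n, {
    pairs <- sample(PAIR_SET, n_pair, replace = TRUE)
    paste(vapply(pairs, function(p)
      paste(strsplit(p, "")[[1]], collapse = ""), character(1)),
      collapse = "")
  })
  alignment_matrix(rows)
}

independent_alignment <- function(n, n_pair) {
  rows <- replicate(n, paste(sample(c("A", "C", "G", "T"), 2 * n_pair,
                                    replace = TRUE), collapse = ""))
  alignment_matrix(rows)
}

pair_matrix <- function(n_pair)
  cbind(i = seq(0L, by = 2L, length.out = n_pair),
        j = seq(1L, by = 2L, length.out = n_pair))

# ---- study-condition synthetic genome ----

# one ~200 kb genome with 30-80 genes: tandem Pro and alternating Tyr/Ser
# clusters, intron-bearing eMet/Tyr, planted TATA/CAA motifs and poly(T)
# terminators (with backups), both strands, plus scattered background genes
make_study_genome <- function(seed, contig_len = 200000L) {
  set.seed(seed)
  n_scatter <- sample(20:55, 1)   # totals land in the 30-80 gene band
  iso_pool <- c("Ala", "Arg", "Gly", "Leu", "Lys", "Val", "Thr", "Phe")
  scatter <- lapply(seq_len(n_scatter), function(k) {
    gene_spec(sample(iso_pool, 1),
              strand = sample(c("+", "-"), 1),
              upstream_motifs = if (k %% 2L == 0L)
                data.frame(motif = c("TATA", "CAA"),
                           offset = c(sample(15:45, 1), sample(4:10, 1)))
                else NULL,
              downstream_t_runs = if (k %% 3L == 0L)
                data.frame(length = c(sample(4:7, 1), 4L),
                           offset = c(sample(2:6, 1), sample(25:40, 1)))
                else NULL)
  })
  specs <- c(scatter, list(
    gene_spec("Pro", copy_number = sample(3:6, 1), layout = "tandem",
              spacer_bp = sample(80:200, 1),
              strand = sample(c("+", "-"), 1)),
    gene_spec("Tyr", copy_number = sample(2:4, 1), layout = "alternating",
              partner = gene_spec("Ser"), spacer_bp = sample(60:120, 1),
              strand = sample(c("+", "-"), 1)),
    gene_spec("eMet", copy_number = 2L, intron_length = sample(11:13, 1),
              upstream_motifs = data.frame(motif = "CAA", offset = 3L),
              downstream_t_runs = data.frame(length = c(5L, 4L),
                                             offset = c(3L, 20L)),
              strand = sample(c("+", "-"), 1)),
    gene_spec("Tyr", copy_number = 1L, intron_length = sample(13:20, 1))))
  synthesize_genome(specs, c(chr1 = contig_len), seed = seed + 1L,
                    genome_id = sprintf("syn%03d", seed))
}

expect_manifest_recovered <- function(syn, profile) {
  man <- syn$manifest
  # clusters: member lists and envelopes
  called <- profile$clusters
  expect_equal(nrow(called), length(man$expected_clusters))
  for (ec in man$expected_clusters) {
    hit <- which(called$start == ec$start & called$end == ec$end &
                 called$contig == ec$contig)
    expect_length(hit, 1L)
    expect_identical(called$members[[hit]], ec$members)
    expect_identical(called$size[hit], as.integer(ec$size))
    expect_identical(called$pattern[hit], ec$pattern)
  }
  # per-gene motif counts, terminators and introns
  fr <- profile$flank_report
  ir <- profile$introns
  for (g in man$genes) {
    row <- fr[fr$gene_id == g$gene_id, ]
    expect_identical(row$tata_count, g$tata_count)
    expect_identical(row$caa_count_50, g$caa_count_50)
    expect_identical(row$caa_count_10, g$caa_count_10)
    expect_identical(row$n_backup, g$n_backup)
    expect_equal(row$t_runs[[1]][, c("offset", "length")],
                 g$t_runs[, c("offset", "length")], ignore_attr = TRUE)
    if (!is.na(g$term_length))
      expect_identical(row$term_length, g$term_length)
    if (!is.na(g$intron_seq))
      expect_identical(ir$sequence[ir$gene_id == g$gene_id], g$intron_seq)
  }
  expect_equal(profile$unique$pct, man$expected_unique_pct)
}
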
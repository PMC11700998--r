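# Flank extraction and regulatory-element scans.

test_that("flank windows follow the strand-aware definitions", {
  set.seed(77)
  top <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  g <- tdna_genome("t", c(c1 = top))
  rec <- tdna_records(c("plus", "minus"), "c1", c(100L, 100L), c(172L, 172L),
                      c("+", "-"), "Ala", "AGC", score = 100)
  fl <- extract_flanks(rec, g, upstream = 50L, downstream = 50L)
  expect_identical(fl$upstream50[1], substr(top, 51, 100))
  expect_identical(fl$downstream50[1], substr(top, 173, 222))
  expect_identical(fl$upstream50[2], revcomp(substr(top, 173, 222)))
  expect_identical(fl$downstream50[2], revcomp(substr(top, 51, 100)))
  expect_false(any(fl$upstream50_trunc))
})

test_that("windows truncate (flagged) at contig edges", {
  g <- tdna_genome("t", c(c1 = strrep("ACGT", 50)))
  rec <- tdna_records("edge", "c1", 10L, 82L, "+", "Ala", "AGC", score = 100)
  fl <- extract_flanks(rec, g, upstream = 50L, downstream = 50L)
  expect_identical(nchar(fl$upstream50), 10L)
  expect_true(fl$upstream50_trunc)
  expect_false(fl$downstream50_trunc)
})

test_that("TATA scan counts overlapping occurrences and bins categories", {
  w <- paste0(strrep("C", 10), "TATATA", strrep("C", 10))
  s <- scan_tata(w)
  expect_identical(s$count, 2L)
  expect_identical(s$category, "2")
  expect_identical(scan_tata("CCCCGGGG")$category, "0")
  expect_identical(scan_tata("CCTATACC")$category, "1")
  expect_identical(scan_tata("TATACCTATACCTATA")$count, 3L)
  expect_identical(scan_tata("TATACCTATACCTATA")$category, ">2")
  expect_error(scan_tata("ACGT", motifs = character(0)), "nonempty")
})

test_that("CAA scan distinguishes the 50- and 10-base windows", {
  w <- paste0(strrep("G", 44), "CAACAA")
  s <- scan_caa(w)
  expect_identical(s$count_50, 2L)
  expect_identical(s$count_10, 2L)
  expect_identical(scan_caa(paste0(strrep("G", 46), "CAAA"))$count_50, 1L)
  expect_identical(scan_caa(strrep("CA", 25))$count_50, 0L)
  # CAA outside the last 10 bases counts only in the 50-window
  w2 <- paste0("CAA", strrep("G", 47))
  s2 <- scan_caa(w2)
  expect_identical(s2$count_50, 1L)
  expect_identical(s2$count_10, 0L)
})

test_that("poly(T) scan reports maximal runs with terminator/backup roles", {
  s <- scan_polyt(paste0("AATTTTTAA", strrep("C", 41)))
  expect_identical(s$terminator$offset, 2L)
  expect_identical(s$terminator$length, 5L)
  expect_identical(s$n_backup, 0L)

  s2 <- scan_polyt(paste0("TTTTAATTTTA", strrep("C", 39)))
  expect_identical(s2$terminator$length, 4L)
  expect_identical(s2$n_backup, 1L)
  expect_true(s2$terminator$truncated)   # run starts at the window edge

  s3 <- scan_polyt(paste0("TTTAAA", strrep("C", 44)))
  expect_null(s3$terminator)
})

test_that("scans agree with the naive per-character oracle on random windows", {
  set.seed(303)
  for (k in 1:500) {
    w <- random_window(sample(10:60, 1))
    expect_identical(scan_tata(w)$count, naive_motif_count(w, "TATA"))
    expect_identical(scan_caa(w)$count_50, naive_motif_count(w, "CAA"))
    runs <- scan_polyt(w, 4)$runs
    want <- naive_t_runs(w, 4)
    expect_equal(runs[, c("offset", "length")], want,
                 ignore_attr = TRUE)
  }
})

test_that("composition profile: uniform, planted-rich and degenerate cases", {
  fl <- data.frame(gene_id = c("a", "b"),
                   upstream50 = c(strrep("A", 20), strrep("A", 20)),
                   upstream50_trunc = c(FALSE, FALSE))
  p <- composition_profile(fl)
  expect_true(all(p$freq["A", ] == 1))
  expect_true(all(abs(p$ic_bits - 2) < 1e-12))

  # uniform random windows: per-position A/T fraction near 0.5 within 3 sigma
  set.seed(99)
  n <- 400
  flr <- data.frame(gene_id = paste0("g", 1:n),
                    upstream50 = replicate(n, random_window(30)),
                    upstream50_trunc = FALSE)
  pr <- composition_profile(flr)
  sigma <- sqrt(0.25 / n)
  expect_true(all(abs(pr$at_fraction - 0.5) < 5 * sigma))

  # planted AT-rich upstream exceeds a balanced genome baseline everywhere
  set.seed(100)
  rich <- replicate(200, paste(sample(c("A", "T", "G", "C"), 30,
                                      replace = TRUE,
                                      prob = c(.4, .4, .1, .1)),
                               collapse = ""))
  fl_rich <- data.frame(gene_id = paste0("r", 1:200), upstream50 = rich,
                        upstream50_trunc = FALSE)
  g <- tdna_genome("t", c(c1 = strrep("ACGT", 1000)))
  pp <- composition_profile(fl_rich, genome = g)
  expect_equal(pp$baseline_at, 0.5)
  expect_true(all(pp$at_fraction > pp$baseline_at))

  flt <- data.frame(gene_id = "x", upstream50 = "ACG",
                    upstream50_trunc = TRUE)
  expect_error(composition_profile(flt), "truncated")
})

test_that("per-gene reports are invariant under the strand mirror", {
  syn <- make_study_genome(7, contig_len = 150000L)
  prof <- run_genome_profile(syn$genome, syn$records)
  mir <- mirror_genome(syn$genome, syn$records)
  prof_m <- run_genome_profile(mir$genome, mir$records)
  ord <- order(prof$flank_report$gene_id)
  ord_m <- order(prof_m$flank_report$gene_id)
  expect_identical(prof$flank_report[ord, ], prof_m$flank_report[ord_m, ])
  expect_identical(prof$introns[order(prof$introns$gene_id), "sequence"],
                   prof_m$introns[order(prof_m$introns$gene_id), "sequence"])
  expect_true(same_set_of_sets(cluster_sets(prof$clusters),
                               cluster_sets(prof_m$clusters)))
})
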
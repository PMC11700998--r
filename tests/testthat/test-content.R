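# Content profiling: filtering, tallies, uniqueness, identity, regression.

mk_rec <- function(n, isotype = "Ala", anticodon = "AGC", score = 100,
                   note = "", seqs = NA_character_, prefix = "g") {
  starts <- seq(0L, by = 5000L, length.out = n)
  lens <- if (all(is.na(seqs))) 72L else nchar(seqs)
  tdna_records(sprintf("%s%d", prefix, seq_len(n)), "c1", starts, starts + lens,
               "+", isotype, anticodon, score = score, note = note,
               gene_seq = seqs)
}

test_that("high-confidence filter is boundary-inclusive and pseudo-aware", {
  r <- mk_rec(3, score = c(94.5, 95.0, 96.1))
  kept <- filter_high_confidence(r, 95)
  expect_identical(nrow(kept), 2L)
  expect_identical(attr(kept, "n_dropped"), 1L)

  rp <- mk_rec(3, score = 100, note = "pseudo")
  expect_warning(k2 <- filter_high_confidence(rp, 95, drop_pseudo = TRUE))
  expect_identical(nrow(k2), 0L)
  expect_identical(nrow(filter_high_confidence(rp, 95, drop_pseudo = FALSE)),
                   3L)

  expect_identical(nrow(filter_high_confidence(r, -Inf)), 3L)
})

test_that("tallies split by isotype and isoacceptor and report missing", {
  r <- rbind(mk_rec(3, "Ala", "AGC"), mk_rec(2, "Pro", "TGG", prefix = "p"))
  r <- tdna_records(r$gene_id, r$contig, r$start, r$end, r$strand,
                    r$isotype, r$anticodon, score = r$score)
  empty <- mk_rec(0)
  tc <- tally_counts(list(g1 = r, g2 = empty))
  expect_identical(tc$isotype["g1", ], c(Ala = 3L, Pro = 2L))
  expect_identical(tc$isoacceptor["g1", ], c(`Ala-AGC` = 3L, `Pro-TGG` = 2L))
  expect_identical(unname(tc$isotype["g2", ]), c(0L, 0L))
  miss <- tc$missing
  expect_setequal(miss$isoacceptor[miss$genome_id == "g2"],
                  c("Ala-AGC", "Pro-TGG"))
  expect_true(all(miss$isotype_absent[miss$genome_id == "g2"]))

  # order permutation invariance
  perm <- r[sample(nrow(r)), ]
  tc2 <- tally_counts(list(g1 = perm, g2 = empty))
  expect_identical(tc$isoacceptor, tc2$isoacceptor)
})

test_that("unique fraction follows its definition exactly", {
  seqs10 <- c(rep("AAAA", 4), rep("CCCC", 3), "GGGG", "TTTT", "ACGT")
  r <- tdna_records(paste0("g", 1:10), "c1",
                    seq(0L, by = 5000L, length.out = 10),
                    seq(0L, by = 5000L, length.out = 10) + 4L,
                    "+", "Ala", "AGC", score = 100, gene_seq = seqs10)
  u <- unique_fraction(r)
  expect_identical(u$distinct, 5L)
  expect_equal(u$pct, 50)

  # 4 distinct of 10 -> 40%
  seqs <- c(rep("AAAA", 7), "CCCC", "GGGG", "TTTT")
  r2 <- tdna_records(paste0("g", 1:10), "c1",
                     seq(0L, by = 5000L, length.out = 10),
                     seq(0L, by = 5000L, length.out = 10) + 4L,
                     "+", "Ala", "AGC", score = 100, gene_seq = seqs)
  expect_equal(unique_fraction(r2)$pct, 40)

  all_same <- mk_rec(8, seqs = rep(strrep("A", 72), 8))
  expect_equal(unique_fraction(all_same)$pct, 100 / 8)

  expect_identical(unique_fraction(mk_rec(0))$pct, NA_real_)
})

test_that("five identical copies plus five distinct genes give 60%", {
  syn <- synthesize_genome(
    list(gene_spec("Pro", copy_number = 5, mutate_copies = 0),
         gene_spec("Ala"), gene_spec("Gly"), gene_spec("Leu"),
         gene_spec("Val"), gene_spec("Thr")),
    c(chr1 = 80000L), seed = 31)
  u <- unique_fraction(syn$records)
  expect_identical(u$total, 10L)
  expect_equal(u$pct, 60)
  # enumeration oracle on the raw strings
  expect_identical(u$distinct, length(unique(syn$records$gene_seq)))
})

test_that("duplicating every gene halves the unique percentage", {
  syn <- synthesize_genome(
    list(gene_spec("Ala"), gene_spec("Pro"), gene_spec("Gly")),
    c(chr1 = 40000L), seed = 33)
  r <- syn$records
  dup <- r
  dup$gene_id <- paste0(dup$gene_id, "_copy")
  both <- rbind(as.data.frame(r), as.data.frame(dup))
  both <- tdna_records(both$gene_id, both$contig, both$start, both$end,
                       both$strand, both$isotype, both$anticodon,
                       score = both$score, gene_seq = both$gene_seq)
  expect_equal(unique_fraction(both)$pct, unique_fraction(r)$pct / 2)
})

test_that("shared identical sequences are found across genomes and strands", {
  shared <- build_trna_template("Ala", "AGC")$sequence
  mk <- function(gid, strand) {
    tdna_records(paste0(gid, "_1"), "c1", 1000L, 1000L + nchar(shared),
                 strand, "Ala", "AGC", score = 100, gene_seq = shared)
  }
  tab <- shared_identical_sequences(
    list(a = mk("a", "+"), b = mk("b", "+"), c = mk("c", "-")))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$n_genomes, 3L)
  expect_identical(tab$genomes, "a,b,c")

  none <- shared_identical_sequences(
    list(a = mk_rec(1, seqs = "AAAA"), b = mk_rec(1, seqs = "CCCC")))
  expect_identical(nrow(none), 0L)
  expect_error(shared_identical_sequences(list(a = mk_rec(1, seqs = "AAAA"))),
               ">= 2")
})

test_that("regression matches the closed form and handles edge cases", {
  x <- seq(1, 10)
  fit <- regress_counts_vs_size(x, 2 * x + 5)
  expect_equal(fit$slope[1], 2, tolerance = 1e-12)
  expect_equal(fit$intercept[1], 5, tolerance = 1e-12)
  expect_equal(fit$r_squared[1], 1, tolerance = 1e-12)

  flat <- regress_counts_vs_size(x, rep(7, 10))
  expect_identical(flat$slope[1], 0)
  expect_identical(flat$r_squared[1], 0)

  # closed-form hand computation on an arbitrary 3-point input
  x3 <- c(1.5, 4.2, 9.1); y3 <- c(3.0, 7.7, 12.4)
  b <- sum((x3 - mean(x3)) * (y3 - mean(y3))) / sum((x3 - mean(x3))^2)
  a <- mean(y3) - b * mean(x3)
  r2 <- stats::cor(x3, y3)^2
  f3 <- regress_counts_vs_size(x3, y3)
  expect_equal(f3$slope[1], b, tolerance = 1e-10)
  expect_equal(f3$intercept[1], a, tolerance = 1e-10)
  expect_equal(f3$r_squared[1], r2, tolerance = 1e-10)

  expect_error(regress_counts_vs_size(rep(5, 4), 1:4), "zero variance")
  expect_warning(
    fits <- regress_counts_vs_size(c(x, 1, 2), c(2 * x + 5, 9, 9),
                                   groups = c(rep("big", 10), "tiny", "tiny")),
    "tiny")
  expect_false("tiny" %in% fits$group)

  # p-value is the slope t-test with n - 2 df
  set.seed(2)
  xn <- 1:20; yn <- 3 * xn + rnorm(20, 0, 4)
  f <- regress_counts_vs_size(xn, yn)
  expect_equal(f$p_value[1], summary(lm(yn ~ xn))$coefficients[2, 4],
               tolerance = 1e-12)
})
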
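# The synthetic generator: template geometry, planted layouts, determinism.

test_that("template builds a canonical cloverleaf with the requested anticodon", {
  tm <- build_trna_template("Ala", "AGC", 0L, seed = 1)
  expect_identical(nchar(tm$sequence), 72L)
  expect_identical(substr(tm$mature, 34, 36), "AGC")
  p <- partition_cloverleaf(tm)
  expect_identical(unname(p$lengths[c("acceptor_stem", "d_stem",
                                      "anticodon_stem", "t_stem")]),
                   c(7L, 4L, 5L, 5L))
  expect_identical(unname(p$lengths["variable_loop"]), 4L)
  # stems are genuinely complementary in the generated sequence
  ch <- strsplit(tm$mature, "")[[1]]
  for (r in seq_len(nrow(tm$pairing))) {
    b1 <- ch[tm$pairing[r, 1] + 1L]
    b2 <- ch[tm$pairing[r, 2] + 1L]
    expect_true(paste0(b1, b2) %in% c("AT", "TA", "GC", "CG", "GT", "TG"))
  }
})

test_that("introns go in after mature position 37 and are recoverable", {
  tm <- build_trna_template("eMet", "CAT", 12L, seed = 5)
  expect_identical(nchar(tm$sequence), 84L)
  intron <- substr(tm$sequence, 38, 49)   # 0-based [37, 49)
  expect_identical(nchar(intron), 12L)
  expect_match(intron, "^GCT")
  expect_match(intron, "GAGT$")
  # splicing the intron back out recovers the mature sequence
  spliced <- paste0(substr(tm$sequence, 1, 37),
                    substr(tm$sequence, 50, nchar(tm$sequence)))
  expect_identical(spliced, tm$mature)
  expect_error(build_trna_template("Ala", "AGC", 5L), "intron_length")
  expect_error(build_trna_template("Ala", "AGX", 0L), "anticodon")
})

test_that("different isotypes get distinct deterministic backbones", {
  a1 <- build_trna_template("Ala", "AGC")$mature
  a2 <- build_trna_template("Ala", "AGC")$mature
  p1 <- build_trna_template("Pro", "AGC")$mature
  expect_identical(a1, a2)
  expect_false(identical(a1, p1))
})

test_that("tandem and alternating layouts produce the expected clusters", {
  syn <- synthesize_genome(
    list(gene_spec("Pro", copy_number = 3, layout = "tandem",
                   spacer_bp = 100)),
    c(chr1 = 50000L), seed = 3)
  expect_length(syn$manifest$expected_clusters, 1L)
  ec <- syn$manifest$expected_clusters[[1]]
  expect_identical(ec$size, 3L)
  expect_identical(ec$pattern, "homogeneous:Pro")

  syn2 <- synthesize_genome(
    list(gene_spec("Tyr", copy_number = 4, layout = "alternating",
                   partner = gene_spec("Ser"), spacer_bp = 80)),
    c(chr1 = 50000L), seed = 4)
  ec2 <- syn2$manifest$expected_clusters[[1]]
  expect_identical(ec2$size, 8L)
  expect_identical(ec2$pattern, "alternating:Tyr/Ser")
})

test_that("planted terminator and backup T-runs are recorded in the truth", {
  syn <- synthesize_genome(
    list(gene_spec("Ala", downstream_t_runs =
                     data.frame(length = c(5, 4), offset = c(3, 20)))),
    c(chr1 = 20000L), seed = 9)
  g <- syn$manifest$genes[[1]]
  expect_identical(g$term_length, 5L)
  expect_identical(g$n_backup, 1L)
  expect_identical(g$t_runs$offset, c(3L, 20L))
})

test_that("generation is deterministic in the seed", {
  specs <- list(gene_spec("Ala", copy_number = 3),
                gene_spec("Pro", copy_number = 3, layout = "tandem"))
  a <- synthesize_genome(specs, c(chr1 = 60000L), seed = 21)
  b <- synthesize_genome(specs, c(chr1 = 60000L), seed = 21)
  d <- synthesize_genome(specs, c(chr1 = 60000L), seed = 22)
  expect_identical(a$genome$contigs, b$genome$contigs)
  expect_identical(a$records, b$records)
  expect_false(identical(a$genome$contigs, d$genome$contigs))
})

test_that("generator refuses layouts that cannot be placed", {
  expect_error(
    synthesize_genome(list(gene_spec("Ala", copy_number = 30)),
                      c(chr1 = 3000L), seed = 1),
    "place")
})

test_that("cohort counts follow the generating line and are reproducible", {
  co <- synthesize_cohort(10, c(100, 1000), slope = 2, intercept = 5,
                          noise_sd = 0, seed = 8, annotate = FALSE)
  m <- co$manifest
  fit <- regress_counts_vs_size(m$sizes_mb, m$counts)
  expect_equal(fit$slope[1], 2, tolerance = 1e-9)
  expect_equal(fit$intercept[1], 5, tolerance = 1e-6)
  expect_equal(fit$r_squared[1], 1, tolerance = 1e-12)

  a <- synthesize_cohort(50, c(100, 1000), slope = 1, intercept = 10,
                         noise_sd = 20, seed = 5, annotate = FALSE)
  b <- synthesize_cohort(50, c(100, 1000), slope = 1, intercept = 10,
                         noise_sd = 20, seed = 5, annotate = FALSE)
  expect_identical(a$manifest$counts, b$manifest$counts)

  expect_error(synthesize_cohort(5, c(100, 100), slope = 1, intercept = 10,
                                 noise_sd = 0, seed = 1),
               "degenerate")
})

test_that("cohort annotation does not change the realized counts", {
  light <- synthesize_cohort(6, c(1, 3), slope = 5, intercept = 10,
                             noise_sd = 2, seed = 13, annotate = FALSE)
  full <- synthesize_cohort(6, c(1, 3), slope = 5, intercept = 10,
                            noise_sd = 2, seed = 13)
  expect_identical(light$manifest$counts, full$manifest$counts)
  expect_identical(vapply(full$records, nrow, integer(1)),
                   stats::setNames(full$manifest$counts,
                                   names(full$records)))
})

test_that("a zero-slope cohort yields a statistically null fitted slope", {
  # OLS sampling theory: fitted slope ~ N(0, sd^2 / Sxx)
  co <- synthesize_cohort(100, c(100, 2000), slope = 0, intercept = 300,
                          noise_sd = 30, seed = 17, annotate = FALSE)
  m <- co$manifest
  fit <- regress_counts_vs_size(m$sizes_mb, m$counts)
  sxx <- sum((m$sizes_mb - mean(m$sizes_mb))^2)
  se <- 30 / sqrt(sxx)
  expect_lt(abs(fit$slope[1]), 3 * se + 0.5 / sqrt(sxx))  # + rounding slack
})
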
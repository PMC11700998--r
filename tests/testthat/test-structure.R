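# Cloverleaf partitioning, A/B boxes, covariation scoring.

# hand-built nested cloverleaf pairing with a configurable variable loop
make_cloverleaf_pairing <- function(var_len = 4L) {
  acc5 <- 0:6
  d5 <- 9:12
  ac5 <- 26:30
  t5 <- 42 + var_len + (1:5)
  t3_start <- max(t5) + 8L
  cbind(i = c(acc5, d5, ac5, t5),
        j = c(seq(t3_start + 12L, t3_start + 6L), 24:21, 42:38,
              seq(t3_start + 4L, t3_start)))
}

test_that("canonical templates partition into the constructed elements", {
  for (iso in c("Ala", "Pro", "eMet", "Tyr")) {
    tm <- build_trna_template(iso, "AGC")
    p <- partition_cloverleaf(tm)
    expect_identical(unname(p$lengths[1:4]), c(7L, 4L, 5L, 5L))
    expect_identical(unname(p$lengths["variable_loop"]), 4L)
    # the anticodon loop straddles the anticodon positions (0-based 33-35)
    expect_true(all(33:35 %in% p$anticodon_loop))
  }
})

template_pairing_drop_d <- function() {
  full <- build_trna_template("Ala", "AGC")$pairing
  full[full[, 1] < 9 | full[, 1] > 12, ]   # melt the D stem
}

test_that("non-canonical helix counts fail loudly", {
  p <- template_pairing_drop_d()
  expect_error(partition_cloverleaf(p), "3 helices")
})

test_that("partitions of different variable-loop lengths differ only there", {
  p4 <- partition_cloverleaf(make_cloverleaf_pairing(4L))
  p6 <- partition_cloverleaf(make_cloverleaf_pairing(6L))
  expect_identical(p4$lengths[1:4], p6$lengths[1:4])
  expect_identical(unname(p4$lengths["variable_loop"]), 4L)
  expect_identical(unname(p6$lengths["variable_loop"]), 6L)
  expect_identical(length(p4$d_loop), length(p6$d_loop))
})

test_that("A and B boxes carry the conserved residues on clean templates", {
  tm <- build_trna_template("Ala", "AGC")
  p <- partition_cloverleaf(tm)
  bx <- extract_boxes(tm$sequence, p)
  expect_true(bx$a_box_ok)
  expect_true(bx$b_box_ok)
  expect_identical(nchar(bx$a_box), 12L)
  expect_identical(nchar(bx$b_box), 11L)

  # targeted mutation at mature position 8 (T -> C) breaks the A box check
  mut <- tm$sequence
  substr(mut, 8, 8) <- "C"
  bx2 <- extract_boxes(mut, p)
  expect_false(bx2$a_box_ok)
  expect_true(nzchar(bx2$a_box))
  expect_true(bx2$b_box_ok)

  # intron-bearing gene: boxes are extracted from the spliced sequence
  tmi <- build_trna_template("Tyr", "GTA", 13L, seed = 3)
  bxi <- extract_boxes(tmi$sequence, p, intron_start = 37L, intron_end = 50L)
  expect_true(bxi$a_box_ok)
  expect_true(bxi$b_box_ok)
  expect_identical(bxi$b_box, extract_boxes(tmi$mature, p)$b_box)

  expect_error(extract_boxes("ACGT", p), "too short")
})

test_that("covariation scores match hand computations", {
  pm <- matrix(c(0L, 1L), 1, dimnames = list(NULL, c("i", "j")))
  conserved <- covariation_scores(alignment_matrix(c("GC", "GC", "GC")), pm)
  expect_equal(conserved$score, 0)
  expect_identical(conserved$classification, "zero")

  compensatory <- covariation_scores(alignment_matrix(c("GC", "AT")), pm)
  expect_equal(compensatory$B, 2)
  expect_equal(compensatory$q, 0)
  expect_equal(compensatory$score, 2)
  expect_identical(compensatory$classification, "positive")

  halfbroken <- covariation_scores(alignment_matrix(c("GC", "AA")), pm)
  expect_equal(halfbroken$score, -0.5)
  expect_identical(halfbroken$classification, "negative")

  # GT wobble counts as pairable; gaps never do
  wob <- covariation_scores(alignment_matrix(c("GT", "G-")), pm)
  expect_identical(wob$n_pairable, 1L)
  expect_equal(wob$q, 0.5)

  expect_error(covariation_scores(alignment_matrix(c("GC", "AT")),
                                  matrix(c(0L, 5L), 1)),
               "outside alignment")
})

test_that("scores respect bounds and are invariant to row order and (i,j) swap", {
  set.seed(42)
  for (k in 1:300) {
    al <- independent_alignment(sample(2:6, 1), 3)
    sc <- covariation_scores(al, pair_matrix(3))
    expect_true(all(sc$score >= -1 - 1e-12 & sc$score <= 2 + 1e-12))
    perm <- al[sample(nrow(al)), , drop = FALSE]
    expect_equal(covariation_scores(perm, pair_matrix(3))$score, sc$score)
    swapped <- pair_matrix(3)[, c(2, 1)]   # relabel (i, j) as (j, i)
    colnames(swapped) <- c("i", "j")
    expect_equal(covariation_scores(al, swapped)$score, sc$score)
  }
})

test_that("compensatory evolution scores positive, independent drift does not", {
  set.seed(2024)
  comp_means <- replicate(20, {
    al <- compensatory_alignment(12, 5)
    mean(covariation_scores(al, pair_matrix(5))$score)
  })
  indep_means <- replicate(20, {
    al <- independent_alignment(12, 5)
    mean(covariation_scores(al, pair_matrix(5))$score)
  })
  expect_true(all(comp_means > 0))
  expect_lt(mean(indep_means), 0)
})

test_that("partitioned templates reproduce the generator's box windows", {
  for (iso in names(tdnascape:::ISO_ANTICODONS)) {
    tm <- build_trna_template(iso, tdnascape:::ISO_ANTICODONS[[iso]])
    p <- partition_cloverleaf(tm)
    bx <- extract_boxes(tm$sequence, p)
    # the generator plants T...GG / GG...CC at the box boundaries
    expect_true(bx$a_box_ok, info = iso)
    expect_true(bx$b_box_ok, info = iso)
    # and the B box is anchored one base into the T stem
    expect_identical(substr(tm$mature, p$t_stem[1, 1] + 2L,
                            p$t_stem[1, 1] + 12L), bx$b_box)
  }
})
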
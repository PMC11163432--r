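make_pockets <- function(n = 5L, tm = 0.9, cov = 0.95, seqid = 0.5,
                         residues = "ACDEFGHIK") {
  tibble::tibble(
    template_id = sprintf("t%02d", seq_len(n)),
    tm_score = rep_len(tm, n),
    aligned_fraction = rep_len(cov, n),
    seq_identity = rep_len(seqid, n),
    rank_score = seq(1, 0.1, length.out = n),
    pocket_residues = rep_len(residues, n),
    template_ligands = rep(list("c1ccccc1CC"), n)
  )
}

test_that("pocket filtering enforces all three thresholds and the cap", {
  p <- dplyr::bind_rows(
    make_pockets(1, tm = 0.5),          # TM too low
    make_pockets(1, tm = 0.6),          # boundary: strict >
    make_pockets(1, cov = 0.7),         # coverage too low
    make_pockets(1, seqid = 0.95),      # excluded only in benchmark mode
    make_pockets(1)
  )
  kept <- filter_template_pockets(p)
  expect_equal(nrow(kept), 2L)
  kept_bench <- filter_template_pockets(p, seqid_cutoff = 0.8)
  expect_equal(nrow(kept_bench), 1L)

  many <- make_pockets(80)
  expect_equal(nrow(filter_template_pockets(many)), 75L)

  withr::local_seed(3)
  for (i in 1:30) {
    cand <- make_pockets(40, tm = runif(40, 0.3, 1),
                         cov = runif(40, 0.5, 1),
                         seqid = runif(40, 0, 1))
    out <- filter_template_pockets(cand, seqid_cutoff = 0.8,
                                   max_pockets = 10L)
    expect_lte(nrow(out), 10L)
    expect_true(all(out$tm_score > 0.6 & out$aligned_fraction >= 0.8 &
                      out$seq_identity <= 0.8))
  }
})

test_that("pocket composition averages per-pocket compositions", {
  one <- make_pockets(1, residues = "AAG")
  comp <- pocket_composition(one)
  expect_equal(comp[["A"]], 2 / 3)
  expect_equal(comp[["G"]], 1 / 3)
  expect_equal(sum(comp), 1, tolerance = 1e-9)

  two <- make_pockets(2)
  two$pocket_residues <- c("AA", "GG")
  comp2 <- pocket_composition(two)
  expect_equal(comp2[["A"]], 0.5)
  expect_equal(comp2[["G"]], 0.5)

  # equal pocket weight vs pooled counts differ under size imbalance
  imb <- make_pockets(2)
  imb$pocket_residues <- c("A", "GGGG")
  expect_equal(pocket_composition(imb)[["A"]], 0.5)
  expect_equal(pocket_composition(imb, method = "pooled")[["A"]], 0.2)

  # permutation invariance
  withr::local_seed(11)
  p <- make_pockets(6)
  p$pocket_residues <- replicate(6, paste(sample(ligscreen:::AA_ALPHABET,
                                                 15, TRUE), collapse = ""))
  expect_equal(pocket_composition(p), pocket_composition(p[sample(6), ]))
})

test_that("non-standard residues are dropped; empty pocket sets error", {
  p <- make_pockets(2)
  p$pocket_residues <- c("AXG", "XXX")
  expect_warning(comp <- pocket_composition(p), "non-standard")
  expect_equal(comp[["A"]], 0.5)
  expect_error(pocket_composition(make_pockets(0)), "no usable")
})

test_that("sequence identity is a symmetric global-alignment fraction", {
  expect_equal(sequence_identity("ACDEFG", "ACDEFG"), 1)
  expect_equal(sequence_identity("AAAA", "TTTT"), 0)
  expect_equal(sequence_identity("AAAA", "AATT"), 0.5)
  withr::local_seed(13)
  for (i in 1:25) {
    a <- paste(sample(ligscreen:::AA_ALPHABET, 30, TRUE), collapse = "")
    b <- paste(sample(ligscreen:::AA_ALPHABET, 35, TRUE), collapse = "")
    expect_identical(sequence_identity(a, b), sequence_identity(b, a))
  }
})

test_that("target profiles carry filtered pockets and a unit-sum composition", {
  prof <- target_profile("T1", "ACDEFGHIKLMNPQRSTVWY", make_pockets(5))
  expect_s3_class(prof, "target_profile")
  expect_equal(nrow(prof$accepted_pockets), 5L)
  expect_equal(sum(prof$composition), 1, tolerance = 1e-9)
  bad <- make_pockets(2, tm = 0.3)
  expect_error(target_profile("T2", "ACDE", bad), "no template pockets")
})
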
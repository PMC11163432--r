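test_that("folding reduces hash values modulo the fingerprint length", {
  expect_equal(fold_identifier(0, 2048), 0L)
  expect_equal(fold_identifier(2049, 2048), 1L)
  expect_equal(fold_identifier(3000, 1024), 952L)
  h <- ligscreen:::fnv1a32(as.character(1:500))
  for (len in c(881L, 1024L, 2048L)) {
    idx <- fold_identifier(h, len)
    expect_true(all(idx >= 0L & idx < len))
  }
})

test_that("a single-atom molecule yields exactly one Morgan bit at any radius", {
  for (r in 0:3) {
    fp <- morgan_fingerprint(test_mols$methane, radius = r)
    expect_length(fp$bits, 1L)
  }
})

test_that("Morgan bits are invariant under random atom-order permutations", {
  withr::local_seed(41)
  for (nm in c("ethanamine", "benzene", "acetamide", "mek")) {
    mol <- test_mols[[nm]]
    ref <- morgan_fingerprint(mol)$bits
    for (i in seq_len(25)) {
      perm <- sample(nrow(mol$atoms))
      expect_identical(morgan_fingerprint(permute_mol(mol, perm))$bits, ref)
    }
  }
})

test_that("Morgan set-bit counts match the canonical-environment oracle", {
  for (nm in names(test_mols)) {
    mol <- test_mols[[nm]]
    expect_equal(length(morgan_fingerprint(mol)$bits),
                 oracle_morgan_env_count(mol), info = nm)
  }
})

test_that("FP2 indexes exactly the distinct 2..7-atom linear paths", {
  # ethanamine: C-C, C-N, C-C-N
  expect_length(fp2_fingerprint(test_mols$ethanamine)$bits, 3L)
  # single atoms contribute nothing
  expect_length(fp2_fingerprint(test_mols$methane)$bits, 0L)
  # brute-force path-enumeration oracle on every fixture molecule
  for (nm in names(test_mols)) {
    expect_identical(fp2_fingerprint(test_mols[[nm]])$bits,
                     oracle_fp2_bits(test_mols[[nm]]), info = nm)
  }
})

test_that("tanimoto satisfies identity, disjointness and symmetry", {
  a <- make_fp(c(1L, 2L, 3L))
  b <- make_fp(c(2L, 3L, 4L))
  d <- make_fp(c(10L, 11L))
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, d), 0)
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(make_fp(integer()), make_fp(integer())), 0)
  withr::local_seed(7)
  for (i in 1:20) {
    x <- make_fp(sample(0:2047, 20))
    y <- make_fp(sample(0:2047, 30))
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    expect_lte(tanimoto(x, y), 1)
  }
  expect_error(tanimoto(a, make_fp(1L, scheme = "fp2", length = 1024L)),
               "mismatch")
})

test_that("combined fingerprints concatenate blocks with correct offsets", {
  mol <- test_mols$benzene
  pub <- pubchem_fingerprint(mol)
  fp2 <- fp2_fingerprint(mol)
  mf <- morgan_fingerprint(mol)
  full <- combine_fingerprints(pub, fp2, mf)
  expect_equal(full$length, 3953L)
  expect_equal(combine_fingerprints(pub, NULL, mf, "noFP2")$length, 2929L)
  expect_equal(combine_fingerprints(mf = mf, ablation = "onlyMF")$length,
               2048L)
  # round-trip: offsets recover each block exactly
  back <- split_combined(full)
  expect_identical(back$pubchem$bits, pub$bits)
  expect_identical(back$fp2$bits, fp2$bits)
  expect_identical(back$morgan$bits, mf$bits)
  expect_error(combine_fingerprints(NULL, NULL, NULL, "onlyMF"), "needs")
  expect_error(combine_fingerprints(pub, fp2,
                                    make_fp(1L, length = 1024L), "full"),
               "length")
})

test_that("fingerprint dumps round-trip with 1-based indices", {
  mol <- test_mols$ethanamine
  fps <- tibble::tibble(id = "eth", fp = list(morgan_fingerprint(mol)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fps, tf)
  raw <- readr::read_tsv(tf, show_col_types = FALSE,
                         col_types = readr::cols(bits = readr::col_character()))
  expect_equal(min(as.integer(strsplit(raw$bits, ",")[[1]])),
               min(fps$fp[[1]]$bits) + 1L)
  back <- read_fingerprints(tf)
  expect_identical(back$bits[[1]], fps$fp[[1]]$bits)
})
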
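test_that("generated molecules are valid, sized, and seed-deterministic", {
  expect_identical(generate_molecule(7), generate_molecule(7))
  smis <- vapply(1:300, function(i) generate_molecule(i, c(3, 30)), "")
  parsed <- parse_smiles(smis)
  expect_true(all(parsed$ok))
  sizes <- vapply(parsed$mol, n_atoms, 1L)
  expect_true(all(sizes >= 3L & sizes <= 30L))
  tiny <- vapply(1:40, function(i) generate_molecule(i, c(3, 3)), "")
  expect_true(all(vapply(parse_smiles(tiny)$mol, n_atoms, 1L) == 3L))
})

test_that("generated targets have the specified counts and filterable pockets", {
  spec <- benchmark_spec(actives_per_target = 5L, decoy_ratio = 60L,
                         seed = 3L)
  tg <- generate_target(19, spec, "T01")
  expect_equal(nrow(tg$actives), 5L)
  expect_equal(nrow(tg$decoys), 300L)
  expect_equal(nrow(tg$pockets), spec$n_pockets + spec$n_reject)
  kept <- filter_template_pockets(tg$pockets)
  expect_equal(nrow(kept), spec$n_pockets)
  # ids carry no label information: actives not clustered at the id extremes
  ids <- sort(c(tg$actives$id, tg$decoys$id))
  expect_false(all(match(tg$actives$id, ids) <= 5L))
})

test_that("a planted signal separates actives from decoys in template similarity", {
  spec <- benchmark_spec(n_targets = 2L, actives_per_target = 5L,
                         decoy_ratio = 20L, signal_strength = 1,
                         seed = 23L)
  bench <- generate_benchmark(spec)
  tg <- bench$targets[[1]]
  prof <- benchmark_profiles(bench)[[1]]
  tls <- build_template_ligand_set(prof)
  sim_of <- function(smiles) {
    parsed <- parse_smiles(smiles)
    vapply(parsed$mol[parsed$ok], function(m) {
      as.numeric(similarity_score(morgan_fingerprint(m), tls))
    }, numeric(1))
  }
  gap <- mean(sim_of(tg$actives$smiles)) - mean(sim_of(tg$decoys$smiles))
  expect_gt(gap, 0.2)

  # at signal 0 the same gap sits inside the null band around zero
  bench0 <- generate_benchmark(
    benchmark_spec(n_targets = 2L, actives_per_target = 5L,
                   decoy_ratio = 20L, signal_strength = 0, seed = 23L))
  tg0 <- bench0$targets[[1]]
  prof0 <- benchmark_profiles(bench0)[[1]]
  tls0 <- build_template_ligand_set(prof0)
  sim0 <- function(smiles) {
    parsed <- parse_smiles(smiles)
    vapply(parsed$mol[parsed$ok], function(m) {
      as.numeric(similarity_score(morgan_fingerprint(m), tls0))
    }, numeric(1))
  }
  act0 <- sim0(tg0$actives$smiles)
  dec0 <- sim0(tg0$decoys$smiles)
  gap0 <- mean(act0) - mean(dec0)
  # permutation band from the generator's own null
  withr::local_seed(91)
  pooled <- c(act0, dec0)
  perm <- replicate(2000, {
    idx <- sample(length(pooled), length(act0))
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  band <- stats::quantile(perm, c(0.025, 0.975))
  expect_gte(gap0, band[[1]])
  expect_lte(gap0, band[[2]])
})

test_that("benchmark trees are byte-identical across runs of the same seed", {
  spec <- benchmark_spec(n_targets = 3L, actives_per_target = 3L,
                         decoy_ratio = 5L, seed = 31L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_benchmark(spec, dir = d1)
  generate_benchmark(spec, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_equal(length(f1), 3L * 3L + 3L)  # 3 files per target + 3 global
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("benchmark trees round-trip through the package readers", {
  spec <- benchmark_spec(n_targets = 3L, actives_per_target = 3L,
                         decoy_ratio = 5L, seed = 37L)
  d <- withr::local_tempdir()
  bench <- generate_benchmark(spec, dir = d)
  back <- read_benchmark(d)
  expect_equal(names(back$targets), names(bench$targets))
  for (tid in names(bench$targets)) {
    expect_equal(back$targets[[tid]]$actives, bench$targets[[tid]]$actives)
    expect_equal(back$targets[[tid]]$decoys, bench$targets[[tid]]$decoys)
    expect_equal(back$targets[[tid]]$pockets$template_ligands,
                 bench$targets[[tid]]$pockets$template_ligands)
    expect_equal(back$targets[[tid]]$sequence,
                 bench$targets[[tid]]$sequence)
  }
  expect_equal(back$identity, bench$identity)
  expect_equal(back$spec$decoy_ratio, spec$decoy_ratio)
})

test_that("clone pairs plant high-identity sequences for exclusion tests", {
  spec <- benchmark_spec(n_targets = 4L, actives_per_target = 3L,
                         decoy_ratio = 5L, n_clone_pairs = 1L, seed = 41L)
  bench <- generate_benchmark(spec)
  expect_gt(bench$identity["T01", "T02"], 0.8)
  expect_lt(bench$identity["T01", "T03"], 0.8)
  kept <- loocv_exclusion("T01", bench$identity)
  expect_false("T02" %in% kept)
  expect_true("T03" %in% kept)
})
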
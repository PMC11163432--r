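# A tiny deterministic benchmark shared by the scoring tests.
tiny_bench <- local({
  ligscreen::generate_benchmark(
    ligscreen::benchmark_spec(n_targets = 4L, actives_per_target = 4L,
                              decoy_ratio = 10L, seed = 7L)
  )
})
tiny_profiles <- ligscreen::benchmark_profiles(tiny_bench)

test_that("feature vectors are composition plus fingerprint blocks", {
  prof <- tiny_profiles[[1]]
  lib <- head(benchmark_library(tiny_bench, "T01"), 4)
  parsed <- parse_smiles(lib)
  full <- fingerprint_library(parsed, ablation = "full")
  x <- assemble_features(prof, full)
  expect_equal(ncol(x), 3973L)
  expect_equal(sum(x[1, 1:20]), 1, tolerance = 1e-9)
  expect_equal(unname(as.vector(x[1, 1:20])), unname(prof$composition))
  # each block is recoverable from the recorded offsets
  layout <- attr(x, "layout")
  mfrow <- layout[layout$block == "morgan", ]
  mf_bits <- which(x[2, (mfrow$offset + 1):(mfrow$offset + mfrow$length)]
                   == 1) - 1L
  expect_identical(as.integer(mf_bits),
                   split_combined(full$fp[[2]])$morgan$bits)

  only <- fingerprint_library(parsed, ablation = "onlyMF")
  expect_equal(ncol(assemble_features(prof, only)), 2068L)
  pubonly <- fingerprint_library(parsed, ablation = "onlyPubChem")
  expect_equal(ncol(assemble_features(prof, pubonly)), 901L)
})

test_that("training sets label actives 1 and subsample decoys per target", {
  pairs <- build_training_set(tiny_bench, decoy_fraction = 0.1, seed = 5)
  per <- dplyr::count(pairs, target_id, label)
  expect_true(all(per$n[per$label == 1] == 4L))
  expect_true(all(per$n[per$label == 0] == 4L))  # round(0.1 * 40)
  all_in <- build_training_set(tiny_bench, decoy_fraction = 1, seed = 5)
  expect_equal(sum(all_in$label == 0), 4L * 40L)
  expect_identical(pairs,
                   build_training_set(tiny_bench, decoy_fraction = 0.1,
                                      seed = 5))
  expect_false(identical(pairs,
                         build_training_set(tiny_bench,
                                            decoy_fraction = 0.1,
                                            seed = 6)))
  expect_error(build_training_set(tiny_bench, decoy_fraction = 0), "0, 1")
})

test_that("cross-validation exclusion drops targets above the identity cutoff", {
  ids <- c("A", "B", "C")
  m <- diag(1, 3); dimnames(m) <- list(ids, ids)
  expect_equal(loocv_exclusion("A", m), c("B", "C"))
  m["B", "A"] <- m["A", "B"] <- 0.95
  m["C", "A"] <- m["A", "C"] <- 0.05
  expect_equal(loocv_exclusion("A", m), "C")
  expect_equal(loocv_exclusion("A", m, cutoff = 0), character())
  expect_error(loocv_exclusion("Z", m), "absent")
})

test_that("the boosted scorer separates a planted signal and is deterministic", {
  pairs <- build_training_set(tiny_bench, decoy_fraction = 0.5, seed = 5)
  parsed <- parse_smiles(unique(pairs$smiles), id = unique(pairs$smiles))
  fps <- fingerprint_library(parsed, ablation = "onlyMF")
  feats <- lapply(split(pairs, pairs$target_id), function(p) {
    x <- assemble_features(
      tiny_profiles[[p$target_id[1]]],
      tibble::tibble(id = paste(p$target_id, p$ligand_id),
                     fp = fps$fp[match(p$smiles, fps$smiles)]))
    list(x = x, y = p$label)
  })
  x <- do.call(rbind, lapply(feats, `[[`, "x"))
  attr(x, "layout") <- attr(feats[[1]]$x, "layout")
  y <- unlist(lapply(feats, `[[`, "y"), use.names = FALSE)

  model <- train_scoring_model(x, y, score_model_spec("fast"), seed = 2)
  scores <- predict(model, x)
  # training-set separation: every binder above every non-binder
  expect_gt(min(scores[y == 1]), max(scores[y == 0]))

  # determinism under the same seed
  model2 <- train_scoring_model(x, y, score_model_spec("fast"), seed = 2)
  expect_identical(predict(model2, x), scores)

  # invariance to input pair order (canonical reordering before the fit)
  perm <- sample(nrow(x))
  xp <- x[perm, , drop = FALSE]
  attr(xp, "layout") <- attr(x, "layout")
  model3 <- train_scoring_model(xp, y[perm], score_model_spec("fast"),
                                seed = 2)
  expect_equal(predict(model3, x), scores, tolerance = 1e-12)

  expect_error(train_scoring_model(x, rep(1, nrow(x))), "both")
  expect_error(predict(model, x[, 1:100]), "layout mismatch")
})

test_that("scoring a library yields a ranked screen with per-SMILES determinism", {
  pairs <- build_training_set(tiny_bench, decoy_fraction = 0.5, seed = 5)
  parsed <- parse_smiles(unique(pairs$smiles), id = unique(pairs$smiles))
  fps <- fingerprint_library(parsed, ablation = "onlyMF")
  p1 <- pairs[pairs$target_id != "T01", ]
  parts <- lapply(split(p1, p1$target_id), function(p) {
    list(x = assemble_features(
      tiny_profiles[[p$target_id[1]]],
      tibble::tibble(id = paste(p$target_id, p$ligand_id),
                     fp = fps$fp[match(p$smiles, fps$smiles)])),
      y = p$label)
  })
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  attr(x, "layout") <- attr(parts[[1]]$x, "layout")
  y <- unlist(lapply(parts, `[[`, "y"), use.names = FALSE)
  model <- train_scoring_model(x, y, score_model_spec("fast"), seed = 2)

  lib <- benchmark_library(tiny_bench, "T01")
  # duplicate record: identical SMILES must get identical scores
  dup <- dplyr::bind_rows(lib, dplyr::mutate(head(lib, 1),
                                             id = "dup0001"))
  screen <- score_library(model, tiny_profiles[["T01"]], dup,
                          ablation = "onlyMF")
  expect_s3_class(screen, "ranked_screen")
  expect_equal(nrow(screen), nrow(dup))
  s_orig <- screen$score[screen$ligand_id == lib$id[1]]
  s_dup <- screen$score[screen$ligand_id == "dup0001"]
  expect_identical(s_orig, s_dup)

  one <- score_library(model, tiny_profiles[["T01"]], head(lib, 1),
                       ablation = "onlyMF")
  expect_equal(nrow(one), 1L)
})

test_that("model archives round-trip and refuse mismatched layouts", {
  x <- Matrix::rsparsematrix(60, 50, 0.2, rand.x = function(n) 1)
  rownames(x) <- sprintf("r%03d", 1:60)
  y <- rep(c(1, 0), 30)
  model <- train_scoring_model(x, y, score_model_spec("custom",
                                                      n_estimators = 20L),
                               seed = 9)
  td <- withr::local_tempdir()
  write_score_model(model, td)
  back <- read_score_model(td)
  expect_equal(predict(back, x), predict(model, x))
  expect_equal(back$spec$n_estimators, 20L)
  expect_error(predict(back, x[, 1:10]), "layout mismatch")
})
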
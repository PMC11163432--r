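test_that("a two-block pool recovers its block precisions exactly", {
  # scores >= 1 are 90% positive; scores < 1 are 10% positive
  pool <- tibble::tibble(
    score = rep(c(0, 1), each = 200),
    label = c(rep(c(0, 1), c(180, 20)), rep(c(0, 1), c(20, 180)))
  )
  cal <- fit_precision_calibration(pool)
  expect_equal(predict_precision(cal, 0), 0.1)
  expect_equal(predict_precision(cal, 1), 0.9)
  expect_equal(predict_precision(cal, -5), 0.1)  # below range: boundary
  expect_equal(predict_precision(cal, 10), 0.9)  # above range: boundary
})

test_that("the fitted mapping is monotone non-decreasing everywhere", {
  withr::local_seed(17)
  pool <- tibble::tibble(score = runif(500),
                         label = as.numeric(runif(500) < runif(500)^0.5))
  cal <- fit_precision_calibration(pool)
  probes <- predict_precision(cal, seq(-0.2, 1.2, length.out = 1000))
  expect_true(all(diff(probes) >= -1e-12))
  expect_true(all(probes >= 0 & probes <= 1))
})

test_that("degenerate pools give constant mappings", {
  all_pos <- tibble::tibble(score = runif(10), label = 1)
  cal <- fit_precision_calibration(all_pos)
  expect_equal(predict_precision(cal, c(-1, 0.5, 2)), rep(1, 3))
})

test_that("calibration is invariant to duplicating the pool", {
  withr::local_seed(23)
  pool <- tibble::tibble(score = runif(300),
                         label = rbinom(300, 1, 0.3))
  c1 <- fit_precision_calibration(pool)
  c2 <- fit_precision_calibration(dplyr::bind_rows(pool, pool))
  probes <- seq(0, 1, length.out = 200)
  expect_equal(predict_precision(c1, probes), predict_precision(c2, probes))
})

test_that("a pool whose scores already equal precision calibrates to identity", {
  withr::local_seed(29)
  score <- rep(seq(0.05, 0.95, by = 0.1), each = 400)
  label <- rbinom(length(score), 1, score)
  cal <- fit_precision_calibration(tibble::tibble(score = score,
                                                  label = label))
  probes <- seq(0.1, 0.9, length.out = 50)
  expect_equal(predict_precision(cal, probes), probes, tolerance = 0.06)
})

test_that("calibration archives round-trip through JSON", {
  pool <- tibble::tibble(score = c(0, 0, 1, 1), label = c(0, 1, 0, 1),
                         method = "sim")
  cal <- fit_precision_calibration(pool, method = "sim")
  tf <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, tf)
  back <- read_calibration(tf)
  expect_equal(back$method, "sim")
  probes <- seq(-1, 2, length.out = 50)
  expect_equal(predict_precision(back, probes),
               predict_precision(cal, probes))
})

test_that("meta-combination takes the best predicted precision per ligand", {
  per <- tibble::tibble(
    method = rep(c("m1", "m2", "m3"), each = 1),
    ligand_id = "lig1",
    precision = c(0.2, 0.9, 0.5)
  )
  combined <- meta_combine(per)
  expect_equal(combined$score, 0.9)
  expect_equal(combined$winner, "m2")

  # single method: identical ranking to its input
  one <- tibble::tibble(method = "m1",
                        ligand_id = sprintf("L%02d", 1:10),
                        precision = seq(1, 0.1, length.out = 10))
  expect_equal(meta_combine(one)$ligand_id, one$ligand_id)
  expect_equal(meta_combine(one)$score, one$precision)

  # asymmetric coverage: max over the methods that scored the ligand
  asym <- tibble::tibble(
    method = c("m1", "m1", "m2"),
    ligand_id = c("a", "b", "a"),
    precision = c(0.3, 0.6, 0.8)
  )
  comb <- meta_combine(asym)
  expect_equal(comb$score[comb$ligand_id == "a"], 0.8)
  expect_equal(comb$score[comb$ligand_id == "b"], 0.6)

  # max dominance over every component method
  withr::local_seed(37)
  big <- tibble::tibble(
    method = rep(c("m1", "m2"), each = 50),
    ligand_id = rep(sprintf("L%02d", 1:50), 2),
    precision = runif(100)
  )
  comb2 <- meta_combine(big)
  for (m in c("m1", "m2")) {
    sub <- big[big$method == m, ]
    expect_true(all(comb2$score[match(sub$ligand_id, comb2$ligand_id)] >=
                      sub$precision))
  }
  expect_error(meta_combine(big[0, ]), "no method predictions")
})
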
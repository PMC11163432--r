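test_that("ranked screens sort by score with identifier tie-breaks", {
  s <- ranked_screen(tibble::tibble(
    ligand_id = c("b", "a", "c"), score = c(1, 2, 1), label = c(0, 1, 0)
  ))
  expect_equal(s$ligand_id, c("a", "b", "c"))
  expect_equal(s$rank, 1:3)
})

test_that("enrichment factor counts actives in the ceiling-cut top fraction", {
  # 100 entries, 10 actives, the single top-1% entry active
  s <- make_screen(100, c(1, seq(50, 58)))
  expect_equal(enrichment_factor(s, 0.01), 10)
  # all actives ranked last
  worst <- make_screen(200, 191:200)
  expect_equal(enrichment_factor(worst, 0.01), 0)
  # perfect ranking at a 60:1 decoy:active ratio, large N
  perfect <- make_screen(6100, 1:100)
  expect_equal(enrichment_factor(perfect, 0.01), 61)
  expect_error(enrichment_factor(make_screen(50, integer())), "no actives")
})

test_that("EF and AUPR match the brute-force counting oracle exactly", {
  withr::local_seed(99)
  for (i in seq_len(1000)) {
    n <- sample(10:500, 1)
    n_act <- sample(seq_len(max(1, n %/% 5)), 1)
    s <- make_screen(n, sample(n, n_act))
    x <- runif(1, 0.005, 0.5)
    ef <- enrichment_factor(s, x)
    expect_identical(ef, oracle_ef(s$label, x))
    expect_equal(precision_recall_aupr(s), oracle_aupr(s$label),
                 tolerance = 1e-12)
    # analytic cap under the ceiling top-fraction cutoff: at most
    # min(ceiling(xN), N_act) actives fit in the selection
    expect_lte(ef, min(1 / x, ceiling(x * n) / (x * n_act)) + 1e-12)
  }
})

test_that("ROC enrichment is 100 for a perfect ranking at 1% FPR", {
  perfect <- make_screen(1010, 1:10)
  expect_equal(roc_enrichment(perfect, 0.01), 100)
  # all actives after the first 1% of decoys
  late <- make_screen(1010, 1001:1010)
  expect_equal(roc_enrichment(late, 0.01), 0)
  # a uniformly random large screen has expectation about 1
  withr::local_seed(21)
  vals <- replicate(40, {
    roc_enrichment(make_screen(2000, sample(2000, 100)), 0.01)
  })
  expect_gt(mean(vals), 0.5)
  expect_lt(mean(vals), 2)
  expect_error(roc_enrichment(make_screen(10, 1:10)), "no decoys")
})

test_that("AUPR is step-curve average precision", {
  expect_equal(precision_recall_aupr(make_screen(4, c(1, 3))),
               (1 + 2 / 3) / 2)
  expect_equal(precision_recall_aupr(make_screen(50, 1:5)), 1)
  # reversing a perfect ranking collapses the area toward its minimum
  rev_aupr <- precision_recall_aupr(make_screen(50, 46:50))
  expect_lt(rev_aupr, 0.2)
  # shuffled screens concentrate around the active prevalence
  withr::local_seed(31)
  n <- 200; n_act <- 20
  sims <- replicate(10000, oracle_aupr(sample(rep(c(1, 0),
                                                  c(n_act, n - n_act)))))
  band <- stats::quantile(sims, c(0.025, 0.975))
  obs <- precision_recall_aupr(make_screen(n, sample(n, n_act)))
  expect_gte(obs, band[[1]] * 0.99)
  expect_lte(obs, band[[2]] * 1.01)
})

test_that("per-target metrics aggregate with means, sds and NA exclusion", {
  per <- dplyr::bind_rows(
    screen_metrics(make_screen(100, 1:5, target = "A")),
    screen_metrics(make_screen(100, 96:100, target = "B"))
  )
  agg <- aggregate_metrics(per)
  expect_equal(agg$mean[agg$metric == "ef"],
               mean(per$ef))
  same <- dplyr::bind_rows(per[1, ], per[1, ])
  agg2 <- aggregate_metrics(same)
  expect_equal(agg2$sd, rep(0, 3))
  per$rocef[2] <- NA
  expect_message(agg3 <- aggregate_metrics(per), "excluded")
  expect_equal(agg3$n[agg3$metric == "rocef"], 1L)
})

test_that("curves and screen TSVs round-trip", {
  s <- make_screen(50, c(1, 10, 30), target = "T9")
  pr <- pr_curve(s)
  expect_equal(nrow(pr), 50L)
  expect_equal(pr$recall[50], 1)
  roc <- roc_curve(s)
  expect_equal(roc$fpr[50], 1)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_screen(s, tf)
  back <- read_ranked_screen(tf)
  expect_equal(back$ligand_id, s$ligand_id)
  expect_equal(back$score, s$score)
  expect_equal(back$target_id[1], "T9")
})
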
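# Screening evaluation: enrichment factor at a top fraction, ROC
# enrichment at a false-positive rate, and the area under the
# precision-recall curve (average-precision form).

#' Construct a ranked screen
#'
#' Orders entries by score descending with ties broken by ligand
#' identifier ascending, and assigns ranks. The resulting tibble is the
#' unit all screening metrics operate on.
#'
#' @param entries Data frame with columns `ligand_id`, `score` and
#'   (optionally) `label` (0/1). Extra columns are kept.
#' @param target Optional target identifier, stored as an attribute and as
#'   a `target_id` column.
#' @return A tibble of class `ranked_screen` with a leading `rank` column.
#' @export
ranked_screen <- function(entries, target = NULL) {
  stopifnot(all(c("ligand_id", "score") %in% names(entries)))
  if ("label" %in% names(entries)) {
    stopifnot(all(entries$label %in% c(0, 1)))
  }
  out <- as_tibble(entries)
  out <- out[order(-out$score, out$ligand_id, method = "radix"), ]
  out$rank <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "rank")
  if (!is.null(target)) out$target_id <- target
  class(out) <- c("ranked_screen", class(out))
  out
}

.check_screen <- function(screen, need_active = TRUE, need_decoy = FALSE) {
  stopifnot(is.data.frame(screen), "label" %in% names(screen))
  if (need_active && sum(screen$label == 1) == 0L) {
    abort("screen has no actives")
  }
  if (need_decoy && sum(screen$label == 0) == 0L) {
    abort("screen has no decoys")
  }
  invisible(screen)
}

#' Enrichment factor at the top fraction of a ranked screen
#'
#' `EF_x` = (fraction of all actives found in the top `ceiling(x * N)`
#' entries) / `x`. A random ranking gives roughly 1; the maximum is
#' `min(1/x, N / N_actives)`. The top-fraction cutoff uses the ceiling so
#' the selection is non-empty for any `x > 0`.
#'
#' @param screen A `ranked_screen` (or ordered data frame) with binary
#'   `label`.
#' @param x Top fraction (default 0.01, i.e. EF at 1%).
#' @return Non-negative enrichment factor.
#' @export
enrichment_factor <- function(screen, x = 0.01) {
  stopifnot(x > 0, x <= 1)
  .check_screen(screen)
  n <- nrow(screen)
  top <- ceiling(x * n)
  hits <- sum(screen$label[seq_len(top)] == 1)
  (hits / sum(screen$label == 1)) / x
}

#' ROC enrichment at a false-positive rate
#'
#' True-positive rate at the first rank where the false-positive fraction
#' reaches `fpr`, divided by `fpr`. Unlike the enrichment factor its
#' maximum does not depend on the decoy:active ratio: a perfect ranking
#' scores `1/fpr` (100 at the default 1% FPR).
#'
#' @inheritParams enrichment_factor
#' @param fpr False-positive rate threshold (default 0.01).
#' @return Non-negative ROC enrichment.
#' @export
roc_enrichment <- function(screen, fpr = 0.01) {
  stopifnot(fpr > 0, fpr <= 1)
  .check_screen(screen, need_active = TRUE, need_decoy = TRUE)
  lab <- screen$label
  n_act <- sum(lab == 1)
  n_dec <- sum(lab == 0)
  fp_frac <- cumsum(lab == 0) / n_dec
  k <- which(fp_frac >= fpr)[1]
  if (is.na(k)) k <- length(lab)
  tpr <- sum(lab[seq_len(k)] == 1) / n_act
  tpr / fpr
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-curve average precision: the mean, over actives, of the precision
#' at each active's rank. No linear interpolation is applied (interpolating
#' the PR curve overestimates the area).
#'
#' @inheritParams enrichment_factor
#' @return AUPR in `[0, 1]`.
#' @export
precision_recall_aupr <- function(screen) {
  .check_screen(screen)
  lab <- screen$label
  ranks <- seq_along(lab)
  prec_at <- cumsum(lab == 1) / ranks
  mean(prec_at[lab == 1])
}

#' Per-screen metric row
#'
#' @inheritParams enrichment_factor
#' @param ef_x Top fraction for the enrichment factor.
#' @param fpr FPR threshold for the ROC enrichment.
#' @return One-row tibble: `target_id`, `n`, `n_actives`, `ef`, `rocef`,
#'   `aupr`.
#' @export
screen_metrics <- function(screen, ef_x = 0.01, fpr = 0.01) {
  tid <- if ("target_id" %in% names(screen)) screen$target_id[1] else NA_character_
  tibble(
    target_id = tid,
    n = nrow(screen),
    n_actives = sum(screen$label == 1),
    ef = enrichment_factor(screen, ef_x),
    rocef = if (sum(screen$label == 0) > 0L) roc_enrichment(screen, fpr)
            else NA_real_,
    aupr = precision_recall_aupr(screen)
  )
}

#' Aggregate per-target metrics
#'
#' Unweighted arithmetic means and standard deviations across targets.
#' Targets with a missing value for some metric are excluded from that
#' metric's mean, with a message.
#'
#' @param per_target Tibble of per-target metric rows ([screen_metrics()]).
#' @return Tibble with one row per metric: `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_metrics <- function(per_target) {
  stopifnot(nrow(per_target) >= 1L)
  metrics <- intersect(c("ef", "rocef", "aupr"), names(per_target))
  rows <- lapply(metrics, function(m) {
    v <- per_target[[m]]
    miss <- sum(is.na(v))
    if (miss > 0L) {
      inform(paste0(miss, " target(s) missing metric '", m,
                    "' excluded from its mean"))
    }
    v <- v[!is.na(v)]
    tibble(metric = m, mean = mean(v),
           sd = if (length(v) > 1L) sd(v) else 0, n = length(v))
  })
  bind_rows(rows)
}

#' Precision-recall curve points
#' @inheritParams enrichment_factor
#' @return Tibble with `rank`, `recall`, `precision`.
#' @export
pr_curve <- function(screen) {
  .check_screen(screen)
  lab <- screen$label
  tp <- cumsum(lab == 1)
  tibble(rank = seq_along(lab),
         recall = tp / sum(lab == 1),
         precision = tp / seq_along(lab))
}

#' ROC curve points
#' @inheritParams enrichment_factor
#' @return Tibble with `rank`, `fpr`, `tpr`.
#' @export
roc_curve <- function(screen) {
  .check_screen(screen, need_decoy = TRUE)
  lab <- screen$label
  tibble(rank = seq_along(lab),
         fpr = cumsum(lab == 0) / sum(lab == 0),
         tpr = cumsum(lab == 1) / sum(lab == 1))
}

#' Write a ranked screen as TSV
#' @param screen A `ranked_screen`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_screen <- function(screen, path) {
  readr::write_tsv(as_tibble(screen), path)
  invisible(path)
}

#' Read a ranked screen TSV
#' @param path Path written by [write_ranked_screen()].
#' @return A `ranked_screen` tibble.
#' @export
read_ranked_screen <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  tid <- if ("target_id" %in% names(x)) x$target_id[1] else NULL
  x$rank <- NULL
  ranked_screen(x, target = tid)
}
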
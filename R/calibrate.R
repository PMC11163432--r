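# Score-to-precision calibration and best-precision meta-combination.
#
# Each method's raw scores live on their own scale (a Tanimoto similarity
# is not comparable to a boosted-regression output), so every method is
# calibrated separately: the pooled cross-validation predictions for all
# targets are fit by isotonic regression of the binary label on the score,
# which is exactly the empirical precision of the pool as a monotone
# non-decreasing function of the score, and is parameter-free. Methods are
# then combined by taking, per ligand, the best predicted precision.

#' Fit a score-to-precision calibration
#'
#' Isotonic (monotone non-decreasing) regression of the 0/1 label on the
#' raw score over pooled cross-validation predictions. The fitted step
#' blocks are stored as breakpoints; [predict_precision()] interpolates
#' between them and clamps to `[0, 1]`.
#'
#' @param pooled Data frame of pooled predictions with columns `score` and
#'   `label` (0/1); typically the merged leave-one-out predictions for
#'   actives and decoys of all targets. A `method` column, if present, is
#'   filtered by `method`.
#' @param method Optional method name (used to filter `pooled` and stored
#'   on the result).
#' @param family `"isotonic"` (default) or `"logistic"` (parametric
#'   alternative: a logistic regression of label on score).
#' @return A `precision_calibration` object.
#' @export
fit_precision_calibration <- function(pooled, method = NULL,
                                      family = c("isotonic", "logistic")) {
  family <- match.arg(family)
  if (!is.null(method) && "method" %in% names(pooled)) {
    pooled <- pooled[pooled$method == method, , drop = FALSE]
  }
  stopifnot(all(c("score", "label") %in% names(pooled)),
            all(pooled$label %in% c(0, 1)))
  if (length(unique(pooled$label)) < 2L) {
    if (nrow(pooled) == 0L) abort("empty prediction pool")
    # degenerate single-class pool: constant mapping at the class rate
    const <- mean(pooled$label)
    return(structure(
      list(method = method, family = "constant",
           breakpoints = tibble(score = range(pooled$score),
                                precision = const),
           n = nrow(pooled), n_pos = sum(pooled$label)),
      class = "precision_calibration"
    ))
  }
  ord <- order(pooled$score)
  s <- pooled$score[ord]
  y <- pooled$label[ord]
  if (family == "isotonic") {
    fit <- isoreg(s, y)
    bp <- tibble(score = s, precision = pmin(pmax(fit$yf, 0), 1))
    # collapse to unique (score, precision) breakpoints
    bp <- bp %>%
      group_by(.data$score) %>%
      summarise(precision = max(.data$precision), .groups = "drop")
  } else {
    gfit <- stats::glm(y ~ s, family = stats::binomial())
    grid <- seq(min(s), max(s), length.out = 512L)
    bp <- tibble(score = grid,
                 precision = stats::predict(
                   gfit, newdata = data.frame(s = grid), type = "response"))
  }
  structure(
    list(method = method, family = family, breakpoints = bp,
         n = nrow(pooled), n_pos = sum(pooled$label)),
    class = "precision_calibration"
  )
}

#' Predicted precision for raw scores
#'
#' Interpolates the fitted monotone mapping; scores beyond the fitted
#' range take the boundary value, and outputs are clamped to `[0, 1]`.
#'
#' @param cal A `precision_calibration`.
#' @param score Numeric vector of raw scores.
#' @return Predicted precisions in `[0, 1]`.
#' @export
predict_precision <- function(cal, score) {
  stopifnot(inherits(cal, "precision_calibration"))
  bp <- cal$breakpoints
  if (nrow(bp) == 1L) return(rep(bp$precision, length(score)))
  out <- approx(bp$score, bp$precision, xout = score, rule = 2,
                ties = max)$y
  pmin(pmax(out, 0), 1)
}

#' @export
print.precision_calibration <- function(x, ...) {
  cat("<precision_calibration", if (!is.null(x$method)) paste0(" [", x$method, "]"),
      "> ", x$family, ", ", nrow(x$breakpoints), " breakpoints, fit on ",
      x$n, " predictions (", x$n_pos, " positives)\n", sep = "")
  invisible(x)
}

#' Tidy a precision calibration (its breakpoint table)
#' @param x A `precision_calibration`.
#' @param ... Unused.
#' @return A tibble of breakpoints.
#' @method tidy precision_calibration
#' @export
tidy.precision_calibration <- function(x, ...) {
  x$breakpoints
}

#' Glance at a precision calibration
#' @inheritParams tidy.precision_calibration
#' @return A one-row tibble.
#' @method glance precision_calibration
#' @export
glance.precision_calibration <- function(x, ...) {
  tibble(method = x$method %||% NA_character_, family = x$family,
         n = x$n, n_pos = x$n_pos, n_breakpoints = nrow(x$breakpoints))
}

#' Save / load a calibration archive
#'
#' JSON with the method name, calibration family, breakpoints, and
#' fitted-pool summary counts.
#'
#' @param cal A `precision_calibration`.
#' @param path JSON path.
#' @return `path` invisibly (write); a `precision_calibration` (read).
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(
    list(method = cal$method, family = cal$family,
         breakpoints = cal$breakpoints, n = cal$n, n_pos = cal$n_pos),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(method = x$method, family = x$family,
         breakpoints = as_tibble(x$breakpoints), n = x$n, n_pos = x$n_pos),
    class = "precision_calibration"
  )
}

#' Combine methods by best predicted precision
#'
#' The meta-screen's score for a ligand is the maximum predicted precision
#' over the component methods that scored it; the winning method is
#' recorded as provenance. Ranking descends by combined score with
#' identifier-ascending tie-break.
#'
#' @param per_method Data frame of per-ligand predicted precisions in long
#'   form: columns `method`, `ligand_id`, `precision`, optionally `label`
#'   and `target_id`.
#' @return A `ranked_screen` with columns `ligand_id`, `score` (the best
#'   precision), `winner`, and per-method precision columns.
#' @export
meta_combine <- function(per_method) {
  stopifnot(all(c("method", "ligand_id", "precision") %in% names(per_method)))
  if (nrow(per_method) == 0L) abort("no method predictions to combine")
  per_method <- per_method[order(per_method$method, method = "radix"), ]
  best <- per_method %>%
    group_by(.data$ligand_id) %>%
    slice(which.max(.data$precision)) %>%
    ungroup()
  wide <- tidyr::pivot_wider(
    per_method[, c("method", "ligand_id", "precision")],
    names_from = "method", values_from = "precision",
    names_prefix = "prec_"
  )
  entries <- tibble(ligand_id = best$ligand_id,
                    score = best$precision,
                    winner = best$method) %>%
    left_join(wide, by = "ligand_id")
  if ("label" %in% names(per_method)) {
    lab <- distinct(per_method[, c("ligand_id", "label")])
    entries <- left_join(entries, lab, by = "ligand_id")
  }
  target <- if ("target_id" %in% names(per_method)) {
    per_method$target_id[1]
  } else NULL
  ranked_screen(entries, target = target)
}
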
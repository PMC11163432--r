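# Pocket-aware boosted binder scoring: 20-dim pocket composition + up to
# 3953 fingerprint bits -> gradient-boosted regression against 0/1 binder
# labels. The learner is xgboost configured with fixed hyperparameter
# presets; tree induction itself is a commodity here, the features and the
# training protocol are the substance.

#' Scoring-model hyperparameter presets
#'
#' `"deep"` is the full-depth configuration (3000 trees, depth 6, learning
#' rate 0.05); `"fast"` is the lighter one (300 trees, same depth and
#' rate). Both fit squared error against the 0/1 binder label.
#'
#' @param preset `"deep"`, `"fast"`, or `"custom"`.
#' @param n_estimators,max_depth,learning_rate Used when
#'   `preset = "custom"`.
#' @return A `score_model_spec` list.
#' @export
score_model_spec <- function(preset = c("deep", "fast", "custom"),
                             n_estimators = NULL, max_depth = 6L,
                             learning_rate = 0.05) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    deep = list(n_estimators = 3000L, max_depth = 6L, learning_rate = 0.05),
    fast = list(n_estimators = 300L, max_depth = 6L, learning_rate = 0.05),
    custom = list(n_estimators = as.integer(n_estimators),
                  max_depth = as.integer(max_depth),
                  learning_rate = learning_rate)
  )
  spec$preset <- preset
  structure(spec, class = "score_model_spec")
}

#' Assemble a target-ligand feature matrix
#'
#' Prepends the 20-dimensional pocket composition of the target to each
#' ligand's combined fingerprint bits (as 0/1 values). The full
#' configuration gives 20 + 3953 = 3973 features; ablations shrink the
#' fingerprint part accordingly. The block layout is recorded so each
#' block can be recovered from the matrix by offset.
#'
#' @param profile A `target_profile` (source of the composition block).
#' @param fps List of `combined_fp` objects (or a tibble with an `fp`
#'   list-column and `id` column), all with identical block layout.
#' @return A sparse matrix (`dgCMatrix`), one row per ligand, with
#'   attribute `layout`: a tibble of blocks (`block`, `length`, `offset`).
#' @export
assemble_features <- function(profile, fps) {
  stopifnot(inherits(profile, "target_profile"))
  comp <- profile$composition
  if (is.null(comp) || length(comp) != 20L) {
    abort("profile is missing its 20-dimensional composition")
  }
  ids <- NULL
  if (is.data.frame(fps)) {
    ids <- fps$id
    fps <- fps$fp
  }
  stopifnot(length(fps) >= 1L)
  layouts <- unique(vapply(fps, function(f) {
    paste(f$blocks$scheme, f$blocks$length, collapse = "|")
  }, character(1)))
  if (length(layouts) != 1L) abort("inconsistent fingerprint layouts")
  fp_len <- fps[[1]]$length
  n <- length(fps)
  # composition block entries
  ci <- rep(seq_len(n), each = 20L)
  cj <- rep(seq_len(20L), times = n)
  cx <- rep(unname(comp), times = n)
  # fingerprint bits
  nb <- vapply(fps, function(f) length(f$bits), integer(1))
  fi <- rep(seq_len(n), times = nb)
  fj <- unlist(lapply(fps, function(f) f$bits)) + 21L
  m <- Matrix::sparseMatrix(
    i = c(ci, fi), j = c(cj, fj), x = c(cx, rep(1, sum(nb))),
    dims = c(n, 20L + fp_len)
  )
  rownames(m) <- ids
  layout <- bind_rows(
    tibble(block = "composition", length = 20L, offset = 0L),
    tibble(block = fps[[1]]$blocks$scheme,
           length = fps[[1]]$blocks$length,
           offset = fps[[1]]$blocks$offset + 20L)
  )
  attr(m, "layout") <- layout
  m
}

#' Build a labeled training set with per-target decoy subsampling
#'
#' All actives of every target are labeled 1; a seeded uniform sample of
#' `round(decoy_fraction * n_decoys)` decoys per target is labeled 0.
#' Subsampling is per-target so every target contributes negatives.
#'
#' @param benchmark A benchmark object ([read_benchmark()] /
#'   [generate_benchmark()]): list of per-target entries with `actives`
#'   and `decoys` SMILES tibbles.
#' @param decoy_fraction Fraction of decoys sampled per target (default
#'   0.1, in `(0, 1]`).
#' @param seed Integer seed making the sample reproducible.
#' @param targets Optional subset of target ids to include.
#' @return Tibble of labeled pairs: `target_id`, `ligand_id`, `smiles`,
#'   `label`.
#' @export
build_training_set <- function(benchmark, decoy_fraction = 0.1, seed = 1L,
                               targets = NULL) {
  if (decoy_fraction <= 0 || decoy_fraction > 1) {
    abort("decoy_fraction must be in (0, 1]")
  }
  entries <- benchmark$targets
  if (!is.null(targets)) entries <- entries[names(entries) %in% targets]
  withr::with_seed(seed, {
    rows <- lapply(entries, function(tg) {
      stopifnot(nrow(tg$actives) >= 1L)
      k <- round(decoy_fraction * nrow(tg$decoys))
      dec <- tg$decoys[sort(sample.int(nrow(tg$decoys), k)), , drop = FALSE]
      bind_rows(
        tibble(target_id = tg$target_id, ligand_id = tg$actives$id,
               smiles = tg$actives$smiles, label = 1),
        tibble(target_id = tg$target_id, ligand_id = dec$id,
               smiles = dec$smiles, label = 0)
      )
    })
  })
  bind_rows(rows)
}

#' Training targets surviving the cross-validation identity exclusion
#'
#' For leave-one-out evaluation, all targets with sequence identity above
#' the cutoff to the test target are excluded from training.
#'
#' @param test_target Test target id.
#' @param seqid Symmetric pairwise identity matrix with unit diagonal and
#'   target ids as dimnames.
#' @param cutoff Identity cutoff (default 0.80; targets with identity
#'   strictly above it are excluded).
#' @return Character vector of training target ids.
#' @export
loocv_exclusion <- function(test_target, seqid, cutoff = 0.80) {
  if (!(test_target %in% rownames(seqid))) {
    abort(paste0("test target ", test_target, " absent from identity matrix"))
  }
  ids <- rownames(seqid)
  keep <- ids != test_target & seqid[, test_target] <= cutoff
  ids[keep]
}

#' Train the boosted binder-scoring model
#'
#' Gradient-boosted regression trees (xgboost, exact tree method, single
#' thread) fit to squared error against the 0/1 labels, with exactly the
#' preset's hyperparameters. Rows are put into a canonical order before
#' fitting, so training is invariant to the input pair order.
#'
#' @param x Feature matrix from [assemble_features()] (rows may be named).
#' @param y Numeric 0/1 labels.
#' @param spec A `score_model_spec`.
#' @param seed Integer seed recorded with the model.
#' @return A `score_model`: the fitted ensemble plus metadata (spec, seed,
#'   feature layout, training size).
#' @export
train_scoring_model <- function(x, y, spec = score_model_spec("fast"),
                                seed = 1L) {
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    abort("training set must contain both binder and non-binder labels")
  }
  layout <- attr(x, "layout")
  if (is.null(layout)) {
    layout <- tibble(block = "features", length = ncol(x), offset = 0L)
  }
  ord <- order(rownames(x) %||% seq_len(nrow(x)), method = "radix")
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  booster <- withr::with_seed(seed, {
    xgboost::xgb.train(
      params = list(max_depth = spec$max_depth, eta = spec$learning_rate,
                    objective = "reg:squarederror", nthread = 1,
                    tree_method = "exact", seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = spec$n_estimators, verbose = 0
    )
  })
  structure(
    list(booster = booster, spec = spec, seed = seed,
         layout = layout, n_train = nrow(x),
         n_pos = sum(y == 1)),
    class = "score_model"
  )
}

#' @export
print.score_model <- function(x, ...) {
  cat("<score_model> ", x$spec$preset, " (", x$spec$n_estimators, " trees, depth ",
      x$spec$max_depth, ", eta ", x$spec$learning_rate, "), ",
      x$n_train, " training pairs (", x$n_pos, " binders), ",
      sum(x$layout$length), " features\n", sep = "")
  invisible(x)
}

#' Predict raw binder scores
#' @param object A `score_model`.
#' @param newdata Feature matrix with the model's layout.
#' @param ... Unused.
#' @return Numeric scores.
#' @export
predict.score_model <- function(object, newdata, ...) {
  if (ncol(newdata) != sum(object$layout$length)) {
    abort("feature layout mismatch between model and data")
  }
  stats::predict(object$booster,
                 xgboost::xgb.DMatrix(newdata, nthread = 1))
}

#' Tidy a fitted scoring model or calibration
#'
#' For a `score_model`, per-feature gain importances with the block each
#' feature belongs to; for a `precision_calibration`, the breakpoint
#' table.
#'
#' @param x A `score_model` or `precision_calibration`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy score_model
#' @export
tidy.score_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  idx <- as.integer(sub("^f", "", imp$Feature))
  block <- vapply(idx, function(j) {
    b <- x$layout
    b$block[max(which(b$offset <= j))]
  }, character(1))
  tibble(feature = imp$Feature, block = block,
         gain = imp$Gain, cover = imp$Cover, frequency = imp$Frequency)
}

#' Glance at a fitted scoring model or calibration
#'
#' One-row summary of the fit.
#'
#' @inheritParams tidy.score_model
#' @return A one-row tibble.
#' @method glance score_model
#' @export
glance.score_model <- function(x, ...) {
  tibble(preset = x$spec$preset, n_estimators = x$spec$n_estimators,
         max_depth = x$spec$max_depth, learning_rate = x$spec$learning_rate,
         n_train = x$n_train, n_pos = x$n_pos,
         n_features = sum(x$layout$length), seed = x$seed)
}

#' Score a ligand library against a target
#'
#' Fingerprints the library under the model's ablation setting, assembles
#' features with the target's pocket composition, predicts raw scores and
#' returns the ranked screen. Unparsable ligands are skipped with a
#' message.
#'
#' @param model A `score_model`.
#' @param profile A `target_profile`.
#' @param ligands SMILES library tibble (`smiles`, `id`, optional `label`).
#' @param ablation Fingerprint ablation; must reproduce the model's
#'   feature layout.
#' @param keys Key table for the PubChem block.
#' @param fps Optional precomputed fingerprint tibble (`id`, `fp`) to
#'   reuse across targets; must match the layout.
#' @return A `ranked_screen`.
#' @export
score_library <- function(model, profile, ligands, ablation = "full",
                          keys = NULL, fps = NULL) {
  if (is.null(fps)) {
    parsed <- parse_smiles(ligands)
    n_skip <- sum(!parsed$ok)
    if (n_skip > 0L) inform(paste0(n_skip, " unparsable ligand(s) skipped"))
    fps <- fingerprint_library(parsed[parsed$ok, ], ablation = ablation,
                               keys = keys %||% pubchem_keys())
  }
  x <- assemble_features(profile, fps)
  entries <- tibble(ligand_id = fps$id, score = predict(model, x))
  if ("label" %in% names(ligands)) {
    entries$label <- ligands$label[match(entries$ligand_id, ligands$id)]
  }
  ranked_screen(entries, target = profile$target_id)
}

#' Save / load a scoring-model archive
#'
#' A directory with the serialized ensemble (xgboost's own UBJ format) and
#' a JSON metadata manifest (spec, seed, feature layout, training size).
#' Loading refuses to proceed when the manifest and ensemble disagree.
#'
#' @param model A `score_model`.
#' @param path Archive directory.
#' @return `path` invisibly (write); a `score_model` (read).
#' @export
write_score_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(path, "ensemble.ubj"))
  jsonlite::write_json(
    list(spec = unclass(model$spec), seed = model$seed,
         layout = model$layout, n_train = model$n_train,
         n_pos = model$n_pos),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "manifest.json"),
                              simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(path, "ensemble.ubj"))
  spec <- structure(as.list(meta$spec), class = "score_model_spec")
  structure(
    list(booster = booster, spec = spec, seed = meta$seed,
         layout = as_tibble(meta$layout), n_train = meta$n_train,
         n_pos = meta$n_pos),
    class = "score_model"
  )
}
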
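# End-to-end drivers over a benchmark: similarity screening of every
# target, leave-one-out boosted-model screening, and the best-precision
# meta-combination. These are what the command-line surface and the
# reproduction script call.

#' Similarity-screen every benchmark target
#'
#' @param bench A `vls_benchmark`.
#' @param scheme Fingerprint scheme (default `"morgan"`).
#' @param aggregate Similarity aggregate; see [similarity_score()].
#' @param seqid_cutoff Optional template sequence-identity ceiling applied
#'   when building profiles (benchmarking mode).
#' @return List with `screens` (named list of `ranked_screen`s),
#'   `metrics` (per-target tibble), `summary` ([aggregate_metrics()]) and
#'   `pooled` (pooled predictions tibble for calibration).
#' @export
run_similarity_screens <- function(bench, scheme = "morgan",
                                   aggregate = "max",
                                   seqid_cutoff = NULL) {
  profiles <- benchmark_profiles(bench, seqid_cutoff = seqid_cutoff)
  screens <- lapply(names(bench$targets), function(tid) {
    similarity_screen_library(profiles[[tid]],
                              benchmark_library(bench, tid),
                              scheme = scheme, aggregate = aggregate)
  })
  names(screens) <- names(bench$targets)
  .collect_screen_results(screens, method = "similarity")
}

#' Leave-one-out boosted-model screening of a benchmark
#'
#' For every target: excludes training targets above the sequence-identity
#' cutoff, builds the labeled training set (all actives + a seeded decoy
#' subsample per training target), trains the boosted scorer, and screens
#' the held-out target's library. Fingerprints are computed once per
#' unique molecule and reused across folds.
#'
#' @param bench A `vls_benchmark`.
#' @param spec A `score_model_spec` (default the fast preset).
#' @param ablation Fingerprint ablation setting.
#' @param decoy_fraction Per-target decoy subsample fraction (default 0.1).
#' @param seqid_cutoff Training-target identity cutoff (default 0.8).
#' @param seed Master seed for decoy subsampling and training.
#' @param keys Substructure key table (when the PubChem block is in play).
#' @return As [run_similarity_screens()], plus `models = NULL` (models are
#'   not retained across folds).
#' @export
run_ml_loocv <- function(bench, spec = score_model_spec("fast"),
                         ablation = "full", decoy_fraction = 0.1,
                         seqid_cutoff = 0.8, seed = 1L, keys = NULL) {
  if (length(bench$targets) < 2L) {
    abort("leave-one-out screening needs at least two targets")
  }
  keys <- keys %||% if ("pubchem" %in% ablation_schemes(ablation)) {
    pubchem_keys()
  }
  profiles <- benchmark_profiles(bench)
  # fingerprint every unique molecule once
  all_smiles <- unique(unlist(lapply(bench$targets, function(tg) {
    c(tg$actives$smiles, tg$decoys$smiles)
  })))
  parsed <- parse_smiles(all_smiles, id = all_smiles)
  fp_index <- fingerprint_library(parsed[parsed$ok, ], ablation = ablation,
                                  keys = keys)
  fp_of <- function(smiles) fp_index$fp[match(smiles, fp_index$smiles)]
  screens <- vector("list", length(bench$targets))
  names(screens) <- names(bench$targets)
  for (tid in names(bench$targets)) {
    train_ids <- loocv_exclusion(tid, bench$identity, cutoff = seqid_cutoff)
    if (length(train_ids) == 0L) {
      abort(paste0("no training targets left for ", tid,
                   " at identity cutoff ", seqid_cutoff))
    }
    pairs <- build_training_set(bench, decoy_fraction = decoy_fraction,
                                seed = seed, targets = train_ids)
    xs <- lapply(train_ids, function(tr) {
      p <- pairs[pairs$target_id == tr, ]
      x <- assemble_features(
        profiles[[tr]],
        tibble(id = paste(tr, p$ligand_id), fp = fp_of(p$smiles))
      )
      list(x = x, y = p$label)
    })
    x <- do.call(rbind, lapply(xs, `[[`, "x"))
    attr(x, "layout") <- attr(xs[[1]]$x, "layout")
    y <- unlist(lapply(xs, `[[`, "y"))
    model <- train_scoring_model(x, y, spec = spec, seed = seed)
    lib <- benchmark_library(bench, tid)
    lib_p <- parsed[match(lib$smiles, parsed$smiles), ]
    keep <- lib_p$ok
    screens[[tid]] <- score_library(
      model, profiles[[tid]], lib,
      fps = tibble(id = lib$id[keep], fp = fp_of(lib$smiles[keep]))
    )
  }
  .collect_screen_results(screens, method = "ml")
}

.collect_screen_results <- function(screens, method) {
  metrics <- bind_rows(lapply(screens, screen_metrics))
  pooled <- bind_rows(lapply(screens, function(s) {
    tibble(method = method, target_id = s$target_id,
           ligand_id = s$ligand_id, score = s$score, label = s$label)
  }))
  list(method = method, screens = screens, metrics = metrics,
       summary = aggregate_metrics(metrics), pooled = pooled)
}

#' Best-precision meta-combination of screening methods
#'
#' Calibrates each method's raw scores to predicted precision on its own
#' pooled predictions, then combines the per-target screens by taking each
#' ligand's best predicted precision.
#'
#' @param results List of results from [run_similarity_screens()] /
#'   [run_ml_loocv()] (two or more, with distinct `method` names).
#' @param family Calibration family; see [fit_precision_calibration()].
#' @return As [run_similarity_screens()], plus `calibrations` (named
#'   list).
#' @export
run_meta_combination <- function(results, family = "isotonic") {
  stopifnot(length(results) >= 2L)
  methods <- vapply(results, `[[`, "", "method")
  stopifnot(!anyDuplicated(methods))
  cals <- lapply(results, function(r) {
    fit_precision_calibration(r$pooled, method = r$method, family = family)
  })
  names(cals) <- methods
  target_ids <- names(results[[1]]$screens)
  screens <- lapply(target_ids, function(tid) {
    per_method <- bind_rows(lapply(results, function(r) {
      s <- r$screens[[tid]]
      tibble(method = r$method, target_id = tid,
             ligand_id = s$ligand_id,
             precision = predict_precision(cals[[r$method]], s$score),
             label = s$label)
    }))
    meta_combine(per_method)
  })
  names(screens) <- target_ids
  out <- .collect_screen_results(screens, method = "combined")
  out$calibrations <- cals
  out
}
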
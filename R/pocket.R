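# Template-pocket handling: threshold filtering of precomputed pocket
# metadata and the 20-dimensional pocket-composition target feature.
# Structural pocket detection itself (threading, structure alignment,
# pocket ranking) happens upstream; its scores are consumed as given.

#' Read per-target template-pocket metadata
#'
#' TSV with columns `template_id`, `tm_score`, `aligned_fraction`,
#' `seq_identity`, `rank_score`, `pocket_residues` (one-letter codes) and
#' `template_ligand_smiles` (semicolon-separated SMILES records).
#'
#' @param path TSV path.
#' @return A tibble with `template_ligands` as a character list-column.
#' @export
read_template_pockets <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         template_id = readr::col_character(),
                         tm_score = readr::col_double(),
                         aligned_fraction = readr::col_double(),
                         seq_identity = readr::col_double(),
                         rank_score = readr::col_double(),
                         pocket_residues = readr::col_character(),
                         template_ligand_smiles = readr::col_character()
                       ))
  x$template_ligands <- lapply(x$template_ligand_smiles, function(s) {
    if (is.na(s) || !nzchar(s)) character() else
      strsplit(s, ";", fixed = TRUE)[[1]]
  })
  x$template_ligand_smiles <- NULL
  x
}

#' Write template-pocket metadata
#' @param pockets Pocket tibble (as from [read_template_pockets()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_template_pockets <- function(pockets, path) {
  out <- pockets
  out$template_ligand_smiles <-
    vapply(out$template_ligands, paste, "", collapse = ";")
  out$template_ligands <- NULL
  readr::write_tsv(out, path)
  invisible(path)
}

#' Filter template pockets by structural-match thresholds
#'
#' Keeps pockets whose template matches the target with TM-score strictly
#' above `tm_min` and at least `cov_min` of the template sequence aligned;
#' in benchmarking mode additionally excludes templates above the sequence
#' identity cutoff. Survivors are sorted by the upstream pocket-ranking
#' score and truncated to the top `max_pockets`.
#'
#' @param pockets Pocket tibble.
#' @param tm_min TM-score threshold (default 0.6; kept pockets have
#'   `tm_score > tm_min`).
#' @param cov_min Minimum aligned fraction of the template (default 0.8).
#' @param seqid_cutoff Optional sequence-identity ceiling (e.g. 0.8 in
#'   benchmarking mode); `NULL` disables the exclusion.
#' @param max_pockets Maximum pockets retained (default 75).
#' @return Filtered, sorted tibble (possibly empty).
#' @export
filter_template_pockets <- function(pockets, tm_min = 0.6, cov_min = 0.8,
                                    seqid_cutoff = NULL, max_pockets = 75L) {
  keep <- pockets$tm_score > tm_min & pockets$aligned_fraction >= cov_min
  if (!is.null(seqid_cutoff)) {
    keep <- keep & pockets$seq_identity <= seqid_cutoff
  }
  out <- pockets[keep, , drop = FALSE]
  out <- out[order(-out$rank_score, out$template_id), , drop = FALSE]
  head(out, max_pockets)
}

#' Pocket amino-acid composition feature
#'
#' The 20-dimensional target feature: the mean amino-acid composition of
#' the accepted template pockets, over the standard amino acids in
#' alphabetical one-letter order (A, C, D, ..., Y). By default each pocket
#' contributes its own composition with equal weight (robust to pocket-size
#' imbalance); `method = "pooled"` instead pools residue counts across
#' pockets. Non-standard residue codes are dropped before normalization;
#' pockets left empty by that are dropped with a warning.
#'
#' @param pockets Pocket tibble with a `pocket_residues` column.
#' @param method `"pocket"` (equal pocket weight, default) or `"pooled"`.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
pocket_composition <- function(pockets, method = c("pocket", "pooled")) {
  method <- match.arg(method)
  if (nrow(pockets) == 0L) {
    abort("no usable template pockets: cannot derive a composition")
  }
  res <- lapply(pockets$pocket_residues, function(s) {
    r <- strsplit(toupper(s), "")[[1]]
    r[r %in% AA_ALPHABET]
  })
  empty <- lengths(res) == 0L
  if (any(empty)) {
    warn(paste0(sum(empty), " pocket(s) with only non-standard residues dropped"))
    res <- res[!empty]
  }
  if (length(res) == 0L) {
    abort("no usable template pockets: cannot derive a composition")
  }
  counts <- vapply(res, function(r) {
    tabulate(match(r, AA_ALPHABET), nbins = 20L)
  }, numeric(20))
  comp <- if (method == "pocket") {
    rowMeans(sweep(counts, 2, colSums(counts), "/"))
  } else {
    rowSums(counts) / sum(counts)
  }
  setNames(comp, AA_ALPHABET)
}

#' Global-alignment sequence identity
#'
#' Fraction of identical positions in a global (Needleman-Wunsch)
#' alignment, divided by the alignment length. Scoring is fixed: BLOSUM62,
#' gap opening 10, gap extension 0.5 (via \pkg{Biostrings}); the two
#' sequences are ordered canonically before aligning, so the result is
#' exactly symmetric.
#'
#' @param seq_a,seq_b Amino-acid sequences (character scalars).
#' @return Identity in `[0, 1]`.
#' @export
sequence_identity <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            nzchar(seq_a), nzchar(seq_b))
  s <- sort(c(seq_a, seq_b), method = "radix")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s[1]), Biostrings::AAString(s[2]),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  unname(Biostrings::pid(pa, type = "PID1")) / 100
}

#' Pairwise sequence-identity matrix
#'
#' @param targets Tibble with columns `target_id` and `sequence`.
#' @return Symmetric matrix with unit diagonal, dimnames = target ids.
#' @export
sequence_identity_matrix <- function(targets) {
  ids <- targets$target_id
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <-
        sequence_identity(targets$sequence[i], targets$sequence[j])
    }
  }
  m
}

#' Build a target profile
#'
#' Applies the pocket filters and derives the composition feature,
#' yielding the per-target object consumed by feature assembly and by the
#' template-ligand similarity screen.
#'
#' @param target_id Target identifier.
#' @param sequence Target amino-acid sequence.
#' @param pockets Candidate pocket tibble (pre-filter).
#' @inheritParams filter_template_pockets
#' @param composition_method See [pocket_composition()].
#' @return A `target_profile`: list with `target_id`, `sequence`,
#'   `accepted_pockets` (tibble) and `composition` (named 20-vector).
#' @export
target_profile <- function(target_id, sequence, pockets,
                           tm_min = 0.6, cov_min = 0.8,
                           seqid_cutoff = NULL, max_pockets = 75L,
                           composition_method = "pocket") {
  accepted <- filter_template_pockets(pockets, tm_min, cov_min,
                                      seqid_cutoff, max_pockets)
  if (nrow(accepted) == 0L) {
    abort(paste0("target ", target_id,
                 ": no template pockets pass the filters"))
  }
  structure(
    list(target_id = target_id, sequence = sequence,
         accepted_pockets = accepted,
         composition = pocket_composition(accepted,
                                          method = composition_method)),
    class = "target_profile"
  )
}

#' @export
print.target_profile <- function(x, ...) {
  cat("<target_profile> ", x$target_id, ": ",
      nrow(x$accepted_pockets), " accepted pockets\n", sep = "")
  invisible(x)
}
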
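# Bit fingerprints: extended-connectivity (Morgan/ECFP), linear-path (FP2
# style) and substructure keys, plus folding, Tanimoto and concatenation.
#
# Identifier hashing is pinned to 32-bit FNV-1a (src/fnv.cpp) so bit
# positions are reproducible across platforms. Bit indices are 0-based
# internally; text dumps render them 1-based (the folding rule "remainder
# plus one" is treated as a display convention).

new_bit_fp <- function(scheme, length, bits) {
  bits <- sort(unique(as.integer(bits)))
  stopifnot(length >= 1L, all(bits >= 0L), all(bits < length))
  structure(list(scheme = scheme, length = as.integer(length), bits = bits),
            class = "bit_fp")
}

#' @export
print.bit_fp <- function(x, ...) {
  cat("<bit_fp ", x$scheme, "/", x$length, "> ", length(x$bits),
      " set bits\n", sep = "")
  invisible(x)
}

#' Fold a hashed identifier to a bit index
#'
#' Hash values are reduced modulo the fingerprint length; the remainder is
#' the (0-based) bit position. Dumps written by [write_fingerprints()]
#' render positions 1-based.
#'
#' @param hash_value Non-negative numeric vector of hash values.
#' @param length Fingerprint length (positive integer).
#' @return Integer bit indices in `[0, length)`.
#' @export
#' @examples
#' fold_identifier(c(0, 2049, 3000), 2048)
fold_identifier <- function(hash_value, length) {
  stopifnot(length >= 1, all(hash_value >= 0))
  as.integer(hash_value %% length)
}

# Neighbor list with bond symbols ("1","2","3" kekulized, "a" aromatic).
.mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  if (nrow(b) == 0L) {
    return(rep(list(list(nbr = integer(), sym = character(),
                         bond = integer())), n))
  }
  sym <- ifelse(b$aromatic, "a", as.character(b$order))
  at <- c(b$a1, b$a2)
  nbr <- c(b$a2, b$a1)
  sym2 <- c(sym, sym)
  bnd <- rep(seq_len(nrow(b)), 2L)
  f <- factor(at, levels = seq_len(n))
  nbr_s <- split(nbr, f)
  sym_s <- split(sym2, f)
  bnd_s <- split(bnd, f)
  lapply(seq_len(n), function(i) {
    list(nbr = nbr_s[[i]], sym = sym_s[[i]], bond = bnd_s[[i]])
  })
}

# Bond environment of radius r around atom a: bonds reachable along paths
# of length <= r, i.e. bonds whose nearer endpoint is within distance r-1.
.atom_environments <- function(mol, radius) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(b) > 0L) {
    for (i in seq_len(nrow(b))) d[b$a1[i], b$a2[i]] <- d[b$a2[i], b$a1[i]] <- 1
    for (k in seq_len(n)) {
      dk <- d[, k]
      d <- pmin(d, outer(dk, d[k, ], `+`))
    }
  }
  lapply(seq_len(n), function(a) {
    lapply(0:radius, function(r) {
      if (r == 0L || nrow(b) == 0L) return(integer())
      near <- pmin(d[a, b$a1], d[a, b$a2])
      which(near <= r - 1L)
    })
  })
}

#' Morgan (extended-connectivity) fingerprint
#'
#' Implements the ECFP procedure: each atom starts from an invariant hashed
#' from (element, degree, attached hydrogens, formal charge, ring flag,
#' aromatic flag); for `radius` rounds every atom's invariant is re-hashed
#' together with its neighbors' invariants and bond orders (neighbor list
#' sorted, so the result is independent of atom input order). All distinct
#' environment identifiers are folded modulo `length`. Environments that
#' stop growing, and duplicate environments covering the same bond set, are
#' dropped, following standard ECFP practice.
#'
#' @param mol A `mol_graph` from [parse_smiles()].
#' @param radius Neighborhood radius (default 2, the ECFP4 setting).
#' @param length Folded fingerprint length (default 2048).
#' @return A `bit_fp` with scheme `"morgan"`.
#' @export
#' @examples
#' m <- parse_smiles("CCN")$mol[[1]]
#' morgan_fingerprint(m)
morgan_fingerprint <- function(mol, radius = 2L, length = 2048L) {
  stopifnot(inherits(mol, "mol_graph"), radius >= 0L, length >= 1L)
  n <- nrow(mol$atoms)
  if (n == 0L) abort("molecule has no atoms")
  a <- mol$atoms
  inv <- fnv1a32(paste(a$element, a$degree, a$n_h, a$charge,
                       as.integer(a$in_ring), as.integer(a$aromatic),
                       sep = "|"))
  adj <- .mol_adjacency(mol)
  envs <- .atom_environments(mol, radius)
  feats <- tibble(round = 0L, atom = seq_len(n), id = inv,
                  key = "", keep = TRUE)
  seen <- character()
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      new_inv <- vapply(seq_len(n), function(i) {
        nb <- adj[[i]]
        parts <- sort(paste0(nb$sym, ":", sprintf("%.0f", inv[nb$nbr])),
                      method = "radix")
        fnv1a32(paste0(r, "|", sprintf("%.0f", inv[i]), "|",
                       paste(parts, collapse = ";")))
      }, numeric(1))
      grown <- vapply(seq_len(n), function(i) {
        length(envs[[i]][[r + 1L]]) > length(envs[[i]][[r]])
      }, logical(1))
      key <- vapply(seq_len(n), function(i) {
        paste(envs[[i]][[r + 1L]], collapse = ",")
      }, character(1))
      feats <- bind_rows(feats, tibble(round = r, atom = seq_len(n),
                                       id = new_inv, key = key,
                                       keep = grown))
      inv <- new_inv
    }
    # duplicate-environment removal: among grown features, the first by
    # (round, identifier) covering a given bond set wins.
    cand <- feats$round > 0L & feats$keep
    ord <- order(feats$round, feats$id)
    for (i in ord) {
      if (!cand[i]) next
      if (feats$key[i] %in% seen) {
        feats$keep[i] <- FALSE
      } else {
        seen <- c(seen, feats$key[i])
      }
    }
  }
  ids <- unique(feats$id[feats$keep])
  new_bit_fp("morgan", length, fold_identifier(ids, length))
}

# All simple linear paths of 2..max_atoms atoms, as canonical encodings
# "el sym el sym el ...": each path read in its lexicographically smaller
# direction. Returns the unique encoding set.
.linear_path_encodings <- function(mol, max_atoms = 7L) {
  n <- nrow(mol$atoms)
  adj <- .mol_adjacency(mol)
  el <- mol$atoms$element
  out <- character()
  encode <- function(path, syms) {
    fwd <- paste0(el[path], c(syms, ""), collapse = "")
    rev_ <- paste0(el[rev(path)], c(rev(syms), ""), collapse = "")
    sort(c(fwd, rev_), method = "radix")[1]
  }
  walk <- function(path, syms) {
    if (length(path) >= 2L) out[[length(out) + 1L]] <<- encode(path, syms)
    if (length(path) == max_atoms) return()
    last <- path[length(path)]
    nb <- adj[[last]]
    for (j in seq_along(nb$nbr)) {
      if (!(nb$nbr[j] %in% path)) {
        walk(c(path, nb$nbr[j]), c(syms, nb$sym[j]))
      }
    }
  }
  for (a in seq_len(n)) walk(a, character())
  unique(out)
}

#' Linear-path (FP2-style) fingerprint
#'
#' Indexes all simple linear fragments of 2 to 7 atoms. Each path is
#' encoded as its element/bond-order sequence read in the lexicographically
#' smaller direction, hashed, and folded modulo `length`. Single atoms and
#' ring closures as such contribute nothing (paths across ring atoms do).
#'
#' @inheritParams morgan_fingerprint
#' @param length Folded fingerprint length (default 1024).
#' @return A `bit_fp` with scheme `"fp2"`.
#' @export
#' @examples
#' m <- parse_smiles("CCN")$mol[[1]]
#' fp2_fingerprint(m)   # 3 paths: C-C, C-N, C-C-N
fp2_fingerprint <- function(mol, length = 1024L) {
  stopifnot(inherits(mol, "mol_graph"), length >= 1L)
  if (nrow(mol$atoms) == 0L) abort("molecule has no atoms")
  enc <- .linear_path_encodings(mol, 7L)
  if (length(enc) == 0L) return(new_bit_fp("fp2", length, integer()))
  new_bit_fp("fp2", length, fold_identifier(fnv1a32(enc), length))
}

#' Tanimoto similarity between two bit fingerprints
#'
#' @param a,b `bit_fp` objects with matching scheme and length.
#' @return Similarity in `[0, 1]`: set-bit intersection over union; 0 when
#'   both fingerprints are empty, by convention.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "bit_fp"), inherits(b, "bit_fp"))
  if (!identical(a$scheme, b$scheme) || a$length != b$length) {
    abort("fingerprint scheme/length mismatch")
  }
  u <- length(union(a$bits, b$bits))
  if (u == 0L) return(0)
  length(intersect(a$bits, b$bits)) / u
}

#' Concatenate fingerprint blocks into a combined fingerprint
#'
#' Blocks are laid out in the fixed order PubChem (881), FP2 (1024),
#' Morgan (2048); the full three-block vector has length 3953. Ablation
#' settings drop named blocks, mirroring the run-time configurations
#' `noFP2`, `noPubChem`, `noMF` and `onlyMF`.
#'
#' @param pub,fp2,mf `bit_fp` objects for the three schemes (those dropped
#'   by `ablation` may be `NULL`).
#' @param ablation One of `"full"`, `"noFP2"`, `"noPubChem"`, `"noMF"`,
#'   `"onlyMF"`, `"onlyPubChem"` (the last reproduces the original
#'   substructure-key-only configuration).
#' @return A `combined_fp`: set bits over the concatenated vector plus a
#'   block table recording scheme offsets.
#' @export
combine_fingerprints <- function(pub = NULL, fp2 = NULL, mf = NULL,
                                 ablation = c("full", "noFP2", "noPubChem",
                                              "noMF", "onlyMF",
                                              "onlyPubChem")) {
  ablation <- match.arg(ablation)
  schemes <- ablation_schemes(ablation)
  fps <- list(pubchem = pub, fp2 = fp2, morgan = mf)[schemes]
  missing <- names(fps)[vapply(fps, is.null, logical(1))]
  if (length(missing) > 0L) {
    abort(paste0("ablation '", ablation, "' needs block(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (s in schemes) {
    if (!identical(fps[[s]]$scheme, s)) abort("block scheme mismatch")
    if (fps[[s]]$length != SCHEME_LENGTHS[[s]]) {
      abort("block length differs from the standard scheme length")
    }
  }
  lens <- unname(SCHEME_LENGTHS[schemes])
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  bits <- unlist(lapply(seq_along(schemes), function(i) {
    fps[[i]]$bits + offsets[i]
  }))
  structure(
    list(bits = sort(as.integer(bits)),
         blocks = tibble(scheme = schemes, length = lens,
                         offset = as.integer(offsets)),
         length = sum(lens)),
    class = "combined_fp"
  )
}

#' Block schemes retained under an ablation setting
#' @param ablation Ablation name; see [combine_fingerprints()].
#' @return Character vector of scheme names in block order.
#' @export
ablation_schemes <- function(ablation = c("full", "noFP2", "noPubChem",
                                          "noMF", "onlyMF",
                                          "onlyPubChem")) {
  ablation <- match.arg(ablation)
  switch(ablation,
         full = c("pubchem", "fp2", "morgan"),
         noFP2 = c("pubchem", "morgan"),
         noPubChem = c("fp2", "morgan"),
         noMF = c("pubchem", "fp2"),
         onlyMF = "morgan",
         onlyPubChem = "pubchem")
}

#' @export
print.combined_fp <- function(x, ...) {
  cat("<combined_fp length ", x$length, "> blocks: ",
      paste(x$blocks$scheme, collapse = "|"), ", ", length(x$bits),
      " set bits\n", sep = "")
  invisible(x)
}

#' Split a combined fingerprint back into its blocks
#'
#' Inverse of [combine_fingerprints()]: recovers each scheme's `bit_fp`
#' from the recorded block offsets.
#'
#' @param cfp A `combined_fp`.
#' @return Named list of `bit_fp` objects.
#' @export
split_combined <- function(cfp) {
  stopifnot(inherits(cfp, "combined_fp"))
  out <- lapply(seq_len(nrow(cfp$blocks)), function(i) {
    off <- cfp$blocks$offset[i]
    len <- cfp$blocks$length[i]
    b <- cfp$bits[cfp$bits >= off & cfp$bits < off + len]
    new_bit_fp(cfp$blocks$scheme[i], len, b - off)
  })
  setNames(out, cfp$blocks$scheme)
}

#' Fingerprint a parsed ligand library
#'
#' Computes, for every parsed molecule, the fingerprint blocks retained by
#' the ablation setting and their concatenation. PubChem keys are evaluated
#' in batch (the SMARTS section goes through the OpenBabel engine once per
#' unique molecule).
#'
#' @param mols A tibble from [parse_smiles()] (rows with `ok == FALSE` are
#'   skipped).
#' @param ablation Block selection; see [combine_fingerprints()].
#' @param keys PubChem-style key table (defaults to the packaged synthetic
#'   table) — only consulted when the PubChem block is retained.
#' @param radius Morgan radius.
#' @return `mols` with a list-column `fp` of `combined_fp` objects.
#' @export
fingerprint_library <- function(mols, ablation = "full",
                                keys = pubchem_keys(), radius = 2L) {
  mols <- mols[mols$ok, , drop = FALSE]
  schemes <- ablation_schemes(ablation)
  n <- nrow(mols)
  pub <- fp2 <- mf <- vector("list", n)
  if ("pubchem" %in% schemes) {
    pub <- pubchem_fingerprint_batch(mols, keys)
  }
  if ("fp2" %in% schemes) {
    fp2 <- lapply(mols$mol, fp2_fingerprint)
  }
  if ("morgan" %in% schemes) {
    mf <- lapply(mols$mol, morgan_fingerprint, radius = radius)
  }
  mols$fp <- lapply(seq_len(n), function(i) {
    combine_fingerprints(pub[[i]], fp2[[i]], mf[[i]], ablation = ablation)
  })
  mols
}

#' Write a fingerprint dump
#'
#' TSV of identifier, scheme, length and comma-separated sorted set-bit
#' indices. Indices are written 1-based, matching the usual text-report
#' convention; [read_fingerprints()] converts them back.
#'
#' @param fps Tibble with columns `id` and `fp` (`bit_fp` or `combined_fp`
#'   list-column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  rows <- purrr::map2(fps$id, fps$fp, function(id, fp) {
    if (inherits(fp, "combined_fp")) {
      tibble(id = id, scheme = paste(fp$blocks$scheme, collapse = "|"),
             length = fp$length,
             bits = paste(fp$bits + 1L, collapse = ","))
    } else {
      tibble(id = id, scheme = fp$scheme, length = fp$length,
             bits = paste(fp$bits + 1L, collapse = ","))
    }
  })
  readr::write_tsv(bind_rows(rows), path)
  invisible(path)
}

#' Read a fingerprint dump written by [write_fingerprints()]
#' @param path Dump path.
#' @return Tibble with columns `id`, `scheme`, `length`, `bits` (integer
#'   list-column, 0-based).
#' @export
read_fingerprints <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         id = readr::col_character(),
                         scheme = readr::col_character(),
                         length = readr::col_integer(),
                         bits = readr::col_character()
                       ))
  x$bits <- lapply(x$bits, function(b) {
    if (is.na(b) || !nzchar(b)) return(integer())
    as.integer(strsplit(b, ",", fixed = TRUE)[[1]]) - 1L
  })
  x
}
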
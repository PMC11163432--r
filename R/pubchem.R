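# 881-bit substructure-key fingerprint.
#
# The packaged key table (inst/extdata/pubchem_keys_synthetic.tsv) is a
# synthetic table following the sectional structure of the published
# PubChem/CACTVS specification — hierarchic element counts, ring counts,
# bonded element pairs, atom neighborhoods with and without bond orders,
# and free SMARTS substructures — with exactly 881 keys, indices 0..880.
# It is NOT the verbatim CACTVS pattern list (which cannot be bundled);
# bit-level parity with external descriptor tools is not promised, and an
# ingestion path for precomputed 881-column descriptor tables is provided
# for parity studies.
#
# Count-style sections (element/ring/pair/nbr/env/henv) are evaluated
# natively from the molecular graph; type "smarts" goes through the
# OpenBabel SMARTS engine.

#' Load a substructure key table
#'
#' @param path Path to a key table TSV (defaults to the packaged synthetic
#'   881-key table). Columns: `bit` (0-based), `type`, `pattern`,
#'   `threshold`, `smarts`, `description`.
#' @return A tibble of 881 keys, validated for completeness.
#' @export
pubchem_keys <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pubchem_keys_synthetic.tsv",
                        package = "ligscreen")
  }
  keys <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            bit = readr::col_integer(),
                            type = readr::col_character(),
                            pattern = readr::col_character(),
                            threshold = readr::col_integer(),
                            smarts = readr::col_character(),
                            description = readr::col_character()
                          ))
  if (nrow(keys) != 881L || !identical(sort(keys$bit), 0:880)) {
    abort("key table must have exactly 881 keys with indices 0..880")
  }
  keys[order(keys$bit), ]
}

# --- native evaluation -----------------------------------------------------

# atoms x token count matrix from (atom index, token) pairs
.token_matrix <- function(at, tokens, n) {
  if (length(at) == 0L) {
    return(matrix(0L, n, 0L))
  }
  tab <- table(factor(at, levels = seq_len(n)), tokens)
  m <- matrix(as.integer(tab), nrow = n)
  colnames(m) <- colnames(tab)
  m
}

# Per-molecule profile consumed by the count-style keys.
.mol_key_profile <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  el_counts <- table(a$element)
  el_counts <- c(as.list(el_counts), H = sum(a$n_h) + sum(a$element == "H"))
  n <- nrow(a)
  if (nrow(b) > 0L) {
    e1 <- a$element[b$a1]; e2 <- a$element[b$a2]
    pair_counts <- table(paste(pmin(e1, e2), pmax(e1, e2), sep = "~"))
    sym_map <- c("1" = "-", "2" = "=", "3" = "#", "a" = ":")
    sym <- ifelse(b$aromatic, ":", sym_map[as.character(b$order)])
    at <- c(b$a1, b$a2)
    nb <- c(a$element[b$a2], a$element[b$a1])
    nb_el <- .token_matrix(at, nb, n)
    nb_bel <- .token_matrix(at, paste0(c(sym, sym), nb), n)
  } else {
    pair_counts <- table(character())
    nb_el <- nb_bel <- matrix(0L, n, 0L)
  }
  rings <- .ring_table(mol)
  list(atoms = a, el = el_counts, pairs = pair_counts,
       nb_el = nb_el, nb_bel = nb_bel, rings = rings)
}

# Count atoms whose neighbor token multiset contains `need` (a character
# vector of tokens, possibly with repeats), restricted to `center` element.
.count_with_neighbors <- function(profile, center, need, mat) {
  ok <- profile$atoms$element == center
  if (!any(ok)) return(0L)
  req <- table(need)
  for (tkn in names(req)) {
    if (!(tkn %in% colnames(mat))) return(0L)
    ok <- ok & (mat[, tkn] >= req[[tkn]])
  }
  sum(ok)
}

.count_rings <- function(profile, size, class) {
  r <- profile$rings
  if (nrow(r) == 0L) return(0L)
  if (!is.na(size)) r <- r[r$size == size, , drop = FALSE]
  sel <- switch(class,
                any = rep(TRUE, nrow(r)),
                arom = r$aromatic,
                carbon = r$carbon_only,
                sat = r$saturated,
                hetero = !r$carbon_only,
                hetN = r$has_n,
                hetO = r$has_o,
                hetS = r$has_s,
                aromN = r$aromatic & r$has_n,
                aromO = r$aromatic & r$has_o,
                aromS = r$aromatic & r$has_s,
                abort(paste0("unknown ring class '", class, "'")))
  sum(sel)
}

# "C(-N,=O)" / "C(N,O)" -> list(center, tokens)
.parse_env_pattern <- function(pattern) {
  m <- regmatches(pattern, regexec("^([A-Z][a-z]?)\\(([^)]*)\\)$", pattern))[[1]]
  if (length(m) != 3L) abort(paste0("bad environment pattern: ", pattern))
  list(center = m[2], tokens = strsplit(m[3], ",", fixed = TRUE)[[1]])
}

# Precompile the count-style keys so per-molecule evaluation is lookups.
.compile_native_keys <- function(native) {
  lapply(seq_len(nrow(native)), function(k) {
    type <- native$type[k]
    pattern <- native$pattern[k]
    ck <- list(type = type, bit = native$bit[k],
               threshold = native$threshold[k])
    if (type %in% c("element", "pair")) {
      ck$pattern <- pattern
    } else if (type == "ring") {
      f <- strsplit(pattern, ";", fixed = TRUE)[[1]]
      kv <- strsplit(f, "=", fixed = TRUE)
      vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      ck$size <- suppressWarnings(as.integer(vals[["size"]]))
      ck$class <- vals[["class"]]
    } else if (type %in% c("nbr", "env")) {
      p <- .parse_env_pattern(pattern)
      ck$center <- p$center
      ck$tokens <- p$tokens
    } else if (type == "henv") {
      f <- strsplit(pattern, ";H", fixed = TRUE)[[1]]
      ck$element <- f[1]
      ck$min_h <- as.integer(f[2])
    } else {
      abort(paste0("unknown key type '", type, "'"))
    }
    ck
  })
}

.eval_native_key <- function(profile, ck) {
  count <- switch(
    ck$type,
    element = profile$el[[ck$pattern]] %||% 0L,
    pair = {
      v <- profile$pairs[ck$pattern]
      if (is.na(v)) 0L else as.integer(v)
    },
    ring = .count_rings(profile, size = ck$size, class = ck$class),
    nbr = .count_with_neighbors(profile, ck$center, ck$tokens,
                                profile$nb_el),
    env = .count_with_neighbors(profile, ck$center, ck$tokens,
                                profile$nb_bel),
    henv = sum(profile$atoms$element == ck$element &
                 profile$atoms$n_h >= ck$min_h)
  )
  count >= ck$threshold
}

# --- SMARTS section --------------------------------------------------------

# Evaluate SMARTS key counts for a SMILES vector in one engine pass.
# Returns a matrix [molecule x pattern] of match counts. A malformed
# pattern raises a configuration error naming the key index.
.smarts_counts <- function(smiles, patterns, bits) {
  if (length(smiles) == 0L || length(patterns) == 0L) {
    return(matrix(0, length(smiles), length(patterns)))
  }
  records <- paste0(paste(smiles, paste0("s", seq_along(smiles))),
                    "\n", collapse = "")
  res <- ChemmineOB::forEachMol("SMILES", records, function(m) {
    vapply(seq_along(patterns), function(j) {
      tryCatch(
        ChemmineOB::smartsSearch_OB(list(m), patterns[j],
                                    uniqueMatches = TRUE),
        error = function(e) {
          abort(paste0("malformed SMARTS for key index ", bits[j], ": ",
                       patterns[j]))
        }
      )
    }, numeric(1))
  })
  do.call(rbind, res)
}

#' Substructure-key fingerprint
#'
#' Sets bit *k* when key *k*'s pattern matches the molecule at least its
#' threshold count. The result always has length 881.
#'
#' @param mol A `mol_graph`.
#' @param keys Key table from [pubchem_keys()].
#' @return A `bit_fp` with scheme `"pubchem"`.
#' @export
pubchem_fingerprint <- function(mol, keys = pubchem_keys()) {
  stopifnot(inherits(mol, "mol_graph"))
  lib <- tibble(id = mol$id %||% "mol", smiles = mol$smiles,
                mol = list(mol), ok = TRUE)
  pubchem_fingerprint_batch(lib, keys)[[1]]
}

#' Substructure-key fingerprints for a parsed library
#'
#' Batch form of [pubchem_fingerprint()]: the SMARTS section is evaluated
#' once per unique SMILES through the OpenBabel engine.
#'
#' @param mols Parsed library tibble ([parse_smiles()]), `ok` rows only.
#' @param keys Key table.
#' @return List of `bit_fp` objects, one per row of `mols`.
#' @export
pubchem_fingerprint_batch <- function(mols, keys = pubchem_keys()) {
  native <- keys[keys$type != "smarts", ]
  sm <- keys[keys$type == "smarts", ]
  uniq <- !duplicated(mols$smiles)
  usmiles <- mols$smiles[uniq]
  umols <- mols$mol[uniq]
  counts <- .smarts_counts(usmiles, sm$pattern, sm$bit)
  compiled <- .compile_native_keys(native)
  ubits <- lapply(seq_along(umols), function(i) {
    profile <- .mol_key_profile(umols[[i]])
    nat_on <- vapply(compiled, .eval_native_key, logical(1),
                     profile = profile)
    sm_on <- counts[i, ] >= sm$threshold
    sort(c(native$bit[nat_on], sm$bit[sm_on]))
  })
  idx <- match(mols$smiles, usmiles)
  lapply(idx, function(i) new_bit_fp("pubchem", 881L, ubits[[i]]))
}

#' Read a precomputed 881-column descriptor table
#'
#' Ingests externally computed substructure-key descriptors: a CSV whose
#' first column is the molecule identifier followed by 881 binary columns
#' in key order. Useful for parity studies against external descriptor
#' tools.
#'
#' @param path CSV path.
#' @return Tibble with columns `id` and `fp` (list of 881-bit `bit_fp`).
#' @export
read_descriptor_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(x) != 882L) {
    abort("descriptor table must have an id column plus 881 key columns")
  }
  vals <- as.matrix(x[, -1])
  if (!all(vals %in% c(0, 1))) abort("descriptor columns must be binary")
  tibble(
    id = as.character(x[[1]]),
    fp = lapply(seq_len(nrow(x)), function(i) {
      new_bit_fp("pubchem", 881L, which(vals[i, ] == 1) - 1L)
    })
  )
}
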
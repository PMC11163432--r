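#' Read a SMILES library file
#'
#' Reads the whitespace-delimited `.smi`/`.ism` dialect used by the common
#' screening benchmarks: one record per line, the SMILES string first,
#' followed by an identifier. Lines starting with `#` and blank lines are
#' skipped. Records missing an identifier get one derived from their line
#' number.
#'
#' @param path Path to a SMILES library file.
#' @return A tibble with columns `smiles` and `id`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".smi")
#' writeLines(c("CCN ethanamine", "c1ccccc1 benzene"), tf)
#' read_smiles(tf)
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(smiles = character(), id = character()))
  }
  smiles <- sub("\\s.*$", "", lines)
  id <- trimws(sub("^\\S+", "", lines))
  id[!nzchar(id)] <- paste0("mol", lineno[!nzchar(id)])
  tibble(smiles = smiles, id = id)
}

#' Write a SMILES library file
#'
#' @param lib A data frame with columns `smiles` and `id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(lib, path) {
  stopifnot(all(c("smiles", "id") %in% names(lib)))
  writeLines(paste(lib$smiles, lib$id), path)
  invisible(path)
}

# Old-style molfile charge codes (atom block column) -> formal charge.
.molfile_charge <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L,
                     "4" = 0L, "5" = -1L, "6" = -2L, "7" = -3L)

# Default valences used to infer implicit hydrogen counts from a kekulized
# connection table. Elements not listed get zero implicit hydrogens.
.default_valence <- function(element, charge) {
  base <- c(C = 4, N = 3, P = 3, O = 2, S = 2, B = 3,
            F = 1, Cl = 1, Br = 1, I = 1)
  v <- unname(base[element])
  v <- ifelse(is.na(v), 0,
              ifelse(element %in% c("N", "P", "O", "S", "F", "Cl", "Br", "I"),
                     v + charge, v - abs(charge)))
  pmax(v, 0)
}

# Parse one V2000 connection-table block (as emitted by OpenBabel) into
# atom/bond tibbles. `lines` spans from the title line to before "M  END".
.parse_v2000 <- function(lines) {
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1L) {
    abort("molecule has no atoms")
  }
  at <- lines[5:(4 + n_atoms)]
  element <- trimws(substr(at, 32, 34))
  charge <- unname(.molfile_charge[trimws(substr(at, 37, 39))])
  charge[is.na(charge)] <- 0L
  if (n_bonds > 0L) {
    bd <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    a1 <- as.integer(substr(bd, 1, 3))
    a2 <- as.integer(substr(bd, 4, 6))
    order <- as.integer(substr(bd, 7, 9))
  } else {
    a1 <- a2 <- order <- integer()
  }
  # "M  CHG" property lines override the legacy charge column.
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    f <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]])
    npair <- f[1]
    for (k in seq_len(npair)) {
      charge[f[2 * k]] <- f[2 * k + 1]
    }
  }
  list(element = element, charge = as.integer(charge),
       a1 = a1, a2 = a2, order = order)
}

.new_mol_graph <- function(ct, smiles, id = NA_character_) {
  n <- length(ct$element)
  bonds <- tibble(a1 = ct$a1, a2 = ct$a2, order = ct$order,
                  aromatic = FALSE)
  if (any(bonds$a1 == bonds$a2)) abort("self-bond in connection table")
  if (nrow(bonds) > 0 && (max(bonds$a1, bonds$a2) > n || min(bonds$a1, bonds$a2) < 1)) {
    abort("bond endpoint out of range")
  }
  # Bonds written as order 4 are aromatic already; otherwise perceive.
  bonds$aromatic <- bonds$order == 4L
  rings <- .chordless_cycles(n, bonds)
  arom <- .perceive_aromatic(ct, bonds, rings)
  bonds$aromatic <- bonds$aromatic | arom$bond
  # Kekulized orders retained; aromatic order-4 input normalized to 1.
  bonds$order[bonds$order == 4L] <- 1L
  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  bsum <- numeric(n)
  for (i in seq_len(nrow(bonds))) {
    bsum[bonds$a1[i]] <- bsum[bonds$a1[i]] + bonds$order[i]
    bsum[bonds$a2[i]] <- bsum[bonds$a2[i]] + bonds$order[i]
  }
  in_ring <- logical(n)
  for (r in rings) in_ring[r] <- TRUE
  n_h <- pmax(0, .default_valence(ct$element, ct$charge) - bsum)
  atoms <- tibble(
    element = ct$element, charge = ct$charge,
    aromatic = arom$atom, n_h = as.integer(round(n_h)),
    in_ring = in_ring, degree = deg
  )
  structure(
    list(atoms = atoms, bonds = bonds, rings = rings,
         smiles = smiles, id = id),
    class = "mol_graph"
  )
}

#' Parse SMILES records into molecular graphs
#'
#' Delegates SMILES interpretation to OpenBabel (via \pkg{ChemmineOB}) and
#' builds, for each record, a light molecular graph: a tibble of atoms
#' (element, formal charge, aromatic flag, implicit hydrogen count, ring
#' flag, degree) and a tibble of bonds (endpoints, kekulized order,
#' aromatic flag). Aromaticity is perceived on chordless rings of size 5-6
#' with a Hückel-style pi-electron count; ring membership comes from
#' chordless-cycle enumeration.
#'
#' @param smiles Character vector of SMILES strings, or a data frame with
#'   columns `smiles` and `id` as returned by [read_smiles()].
#' @param id Optional identifiers, recycled against `smiles`.
#' @return A tibble with columns `id`, `smiles`, `mol` (list of `mol_graph`
#'   objects; `NULL` where parsing failed) and `ok`. Unparsable records are
#'   reported with a warning naming the offending SMILES.
#' @export
#' @examples
#' parse_smiles("CCN")$mol[[1]]
parse_smiles <- function(smiles, id = NULL) {
  if (is.data.frame(smiles)) {
    id <- smiles$id
    smiles <- smiles$smiles
  }
  if (length(smiles) == 0L) {
    return(tibble(id = character(), smiles = character(),
                  mol = list(), ok = logical()))
  }
  stopifnot(is.character(smiles), all(nzchar(smiles)))
  if (is.null(id)) id <- paste0("mol", seq_along(smiles))
  # Internal tag keeps the output <-> input mapping robust when OpenBabel
  # silently drops records it cannot parse.
  tag <- paste0("q", seq_along(smiles))
  sdf <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(paste(smiles, tag), "\n", collapse = "")
    ),
    error = function(e) ""
  )
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  mols <- vector("list", length(smiles))
  for (b in blocks) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
    if (!nzchar(lines[1])) lines <- lines[-1]
    idx <- match(lines[1], tag)
    if (is.na(idx)) next
    ct <- tryCatch(.parse_v2000(lines), error = function(e) NULL)
    if (is.null(ct)) next
    mols[[idx]] <- tryCatch(
      .new_mol_graph(ct, smiles[idx], id[idx]),
      error = function(e) NULL
    )
  }
  ok <- !vapply(mols, is.null, logical(1))
  if (any(!ok)) {
    warn(paste0(
      sum(!ok), " SMILES record(s) could not be parsed: ",
      paste(utils::head(smiles[!ok], 5), collapse = ", ")
    ))
  }
  tibble(id = as.character(id), smiles = smiles, mol = mols, ok = ok)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), ", bonds: ", nrow(x$bonds),
      ", rings: ", length(x$rings), "\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param mol A `mol_graph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  nrow(mol$atoms)
}
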
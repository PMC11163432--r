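#!/usr/bin/env Rscript
# Generates inst/extdata/pubchem_keys_synthetic.tsv: a synthetic 881-entry
# substructure key table following the sectional structure of the
# published PubChem/CACTVS key specification (element counts, ring counts,
# bonded element pairs, neighbor environments with and without bond
# orders, free SMARTS substructures). Run from the repository root.
suppressPackageStartupMessages({
  library(tibble); library(dplyr); library(ChemmineOB)
})

elnum <- c(C = 6, N = 7, O = 8, S = 16, P = 15, F = 9, Cl = 17, Br = 35,
           I = 53, B = 5, Si = 14)
el_smarts <- function(e) paste0("[#", elnum[[e]], "]")

rows <- list()
add <- function(type, pattern, threshold, smarts, description) {
  rows[[length(rows) + 1L]] <<- tibble(
    type = type, pattern = pattern, threshold = as.integer(threshold),
    smarts = smarts, description = description)
}

## Section 1: hierarchic element counts (115 keys) -------------------------
ec <- list(H = c(1, 2, 4, 8, 16, 32), C = c(1, 2, 4, 8, 16, 24, 32),
           N = c(1, 2, 3, 4, 6, 8), O = c(1, 2, 3, 4, 6, 8, 12, 16),
           S = c(1, 2, 3, 4), F = c(1, 2, 3, 4), Cl = c(1, 2, 3, 4),
           Br = c(1, 2, 3), I = c(1, 2), P = c(1, 2), B = c(1, 2),
           Si = c(1, 2))
for (e in names(ec)) for (t in ec[[e]]) {
  add("element", e, t,
      if (e %in% names(elnum)) el_smarts(e) else NA_character_,
      sprintf(">=%d %s", t, e))
}
rare <- c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba", "Al",
          "Ga", "Ge", "As", "Se", "Te", "Sn", "Pb", "Fe", "Cu", "Zn", "Mn",
          "Co", "Ni", "Cr", "Ti", "V", "Mo", "W", "Pd", "Pt", "Ag", "Au",
          "Hg", "Cd", "Sb", "Bi", "Zr", "Nb", "Tc", "Ru", "Rh", "In", "Tl",
          "Sc", "Y", "La", "Ce", "Nd", "Sm", "Gd", "Dy", "Er", "Yb", "Hf",
          "Ta", "Re", "Os", "Ir", "Po", "At", "He", "Ne", "Ar", "Kr")
for (e in rare) add("element", e, 1, NA_character_, sprintf(">=1 %s", e))
n1 <- length(rows)
stopifnot(n1 == 115)

## Section 2: ring counts (148 keys) ---------------------------------------
ring_pat <- function(size, class) sprintf("size=%s;class=%s", size, class)
cand <- list()
radd <- function(size, class, thr, desc) {
  cand[[length(cand) + 1L]] <<- list(size = size, class = class, thr = thr,
                                     desc = desc)
}
for (size in 3:8) for (class in c("any", "carbon", "arom", "sat", "hetN",
                                  "hetO", "hetS")) for (thr in 1:2) {
  radd(size, class, thr, sprintf(">=%d %d-membered %s ring(s)", thr, size,
                                 class))
}
for (size in 5:6) for (class in c("any", "carbon", "arom", "sat")) {
  for (thr in 3:4) {
    radd(size, class, thr, sprintf(">=%d %d-membered %s ring(s)", thr,
                                   size, class))
  }
}
for (thr in c(1:8, 10, 12)) radd(NA, "any", thr,
                                 sprintf(">=%d ring(s) of any size", thr))
for (thr in 1:4) radd(NA, "arom", thr, sprintf(">=%d aromatic ring(s)", thr))
for (thr in 1:4) radd(NA, "sat", thr, sprintf(">=%d saturated ring(s)", thr))
for (size in 3:8) for (thr in 1:2) {
  radd(size, "hetero", thr,
       sprintf(">=%d %d-membered heteroatom ring(s)", thr, size))
}
for (size in 5:6) for (class in c("aromN", "aromO", "aromS")) {
  for (thr in 1:2) {
    radd(size, class, thr, sprintf(">=%d %d-membered %s ring(s)", thr,
                                   size, class))
  }
}
for (size in 3:8) radd(size, "any", 3,
                       sprintf(">=3 %d-membered rings", size))
stopifnot(length(cand) >= 148)
for (k in cand[seq_len(148)]) {
  add("ring", ring_pat(k$size, k$class), k$thr, NA_character_, k$desc)
}
stopifnot(length(rows) == 115 + 148)

## Section 3: bonded element pairs (65 keys) -------------------------------
pe <- names(elnum)
pairs <- list()
for (i in seq_along(pe)) for (j in i:length(pe)) {
  pairs[[length(pairs) + 1L]] <- c(pe[i], pe[j])
}
stopifnot(length(pairs) == 66)
for (p in pairs[seq_len(65)]) {
  add("pair", paste0(p[1], "~", p[2]), 1,
      paste0(el_smarts(p[1]), "~", el_smarts(p[2])),
      sprintf("%s bonded to %s", p[1], p[2]))
}
stopifnot(length(rows) == 115 + 148 + 65)

## Section 4: neighbor-pair environments (132 keys) ------------------------
centers <- c("C", "N", "O", "S", "P")
nbr_el <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
n4 <- 0L
for (ce in centers) {
  for (i in seq_along(nbr_el)) for (j in i:length(nbr_el)) {
    if (n4 >= 132L) break
    e1 <- nbr_el[i]; e2 <- nbr_el[j]
    add("nbr", sprintf("%s(%s,%s)", ce, e1, e2), 1,
        sprintf("%s(~%s)~%s", el_smarts(ce), el_smarts(e1), el_smarts(e2)),
        sprintf("%s with neighbors %s and %s", ce, e1, e2))
    n4 <- n4 + 1L
  }
  if (n4 >= 132L) break
}
stopifnot(length(rows) == 115 + 148 + 65 + 132)

## Section 5: bond-order environments + H-count keys (253 keys) ------------
hadd <- function(el, h, thr, desc) {
  # "at least h attached hydrogens": SMARTS Hn is an exact count, so the
  # minimum-count reading needs the negated lower counts
  sm <- sprintf("[#%d;%s]", elnum[[el]],
                paste0("!H", seq_len(h) - 1L, collapse = ";"))
  add("henv", sprintf("%s;H%d", el, h), thr, sm, desc)
}
hspec <- list(c("C", 1), c("C", 2), c("C", 3), c("N", 1), c("N", 2),
              c("O", 1), c("S", 1))
for (h in hspec) {
  hadd(h[1], as.integer(h[2]), 1,
       sprintf("%s with >=%s attached H", h[1], h[2]))
}
hcnt <- list(c("C", 3, 2), c("C", 3, 4), c("C", 2, 2), c("C", 2, 4),
             c("C", 2, 8), c("C", 1, 2), c("C", 1, 4), c("N", 1, 2),
             c("N", 2, 2), c("O", 1, 2))
for (h in hcnt) {
  hadd(h[1], as.integer(h[2]), as.integer(h[3]),
       sprintf(">=%s atoms %s with >=%s attached H", h[3], h[1], h[2]))
}
bond_syms <- c("-", "=", "#", ":")
bond_smarts <- c("-" = "-", "=" = "=", "#" = "#", ":" = ":")
env_centers <- c("C", "N", "S", "P", "O")
env_nbrs <- c("C", "N", "O", "S")
tok <- list()
for (b in bond_syms) for (e in env_nbrs) {
  if (b == ":" && !(e %in% c("C", "N", "O", "S"))) next
  tok[[length(tok) + 1L]] <- c(b, e)
}
n5 <- 17L
for (ce in env_centers) {
  for (i in seq_along(tok)) for (j in i:length(tok)) {
    if (n5 >= 253L) break
    t1 <- tok[[i]]; t2 <- tok[[j]]
    # skip impossible valences: O center with two multiple bonds etc.
    if (ce == "O" && (t1[1] %in% c("=", "#") || t2[1] %in% c("=", "#"))) next
    if (t1[1] == "#" && t2[1] == "#") next
    add("env", sprintf("%s(%s%s,%s%s)", ce, t1[1], t1[2], t2[1], t2[2]), 1,
        sprintf("%s(%s%s)%s%s", el_smarts(ce), bond_smarts[t1[1]],
                el_smarts(t1[2]), bond_smarts[t2[1]], el_smarts(t2[2])),
        sprintf("%s with %s%s and %s%s neighbors", ce, t1[1], t1[2],
                t2[1], t2[2]))
    n5 <- n5 + 1L
  }
  if (n5 >= 253L) break
}
stopifnot(n5 == 253L, length(rows) == 115 + 148 + 65 + 132 + 253)

## Sections 6-7: free SMARTS substructures (168 keys) ----------------------
curated <- c(
  "C(=O)[OX2H1]"        = "carboxylic acid",
  "C(=O)O[#6]"          = "ester",
  "C(=O)[NX3]"          = "amide",
  "[#6]C(=O)[#6]"       = "ketone",
  "[CX3H1]=O"           = "aldehyde",
  "N(~[OX1])~[OX1]"     = "nitro group",
  "C#N"                 = "nitrile",
  "S(=O)(=O)N"          = "sulfonamide",
  "S(=O)(=O)[#6]"       = "sulfonyl",
  "[SX2H]"              = "thiol",
  "[#6][SX2][#6]"       = "thioether",
  "[OX2H]"              = "hydroxyl",
  "[#6][OX2][#6]"       = "ether",
  "[NX3;H2]"            = "primary amine",
  "[NX3;H1]([#6])[#6]"  = "secondary amine",
  "[NX3]([#6])([#6])[#6]" = "tertiary amine",
  "c[OX2H]"             = "phenol",
  "c[NX3]"              = "aryl amine",
  "c[F,Cl,Br,I]"        = "aryl halide",
  "[CX4][F,Cl,Br,I]"    = "alkyl halide",
  "C(F)(F)F"            = "trifluoromethyl",
  "NC(=O)N"             = "urea",
  "NC(=O)O"             = "carbamate",
  "NC(=N)N"             = "guanidine",
  "C=C"                 = "alkene",
  "C#C"                 = "alkyne",
  "cC=O"                = "aryl carbonyl",
  "cC(=O)O"             = "aryl carboxyl",
  "cN(~[OX1])~[OX1]"    = "aryl nitro",
  "cc(c)c"              = "aromatic branch point",
  "[nH]"                = "pyrrole-type nitrogen",
  "n:c:n"               = "aromatic N-C-N",
  "o:c"                 = "aromatic O-C",
  "s:c"                 = "aromatic S-C",
  "OCC(O)C"             = "1,2-diol-like chain",
  "OCCO"                = "ethylene glycol unit",
  "NCCN"                = "ethylene diamine unit",
  "NCCO"                = "aminoethanol unit",
  "C=CC=O"              = "conjugated enone",
  "C=CC=C"              = "conjugated diene"
)
ring_sm <- c(
  "c1ccccc1"            = "benzene ring",
  "c1ccncc1"            = "pyridine ring",
  "c1ccoc1"             = "furan ring",
  "c1ccsc1"             = "thiophene ring",
  "c1cc[nH]c1"          = "pyrrole ring",
  "C1CCCCC1"            = "cyclohexane ring",
  "C1CCNCC1"            = "piperidine ring",
  "C1CCOCC1"            = "oxane ring",
  "c1ccc2ccccc2c1"      = "naphthalene system",
  "c1ccccc1[#6]"        = "substituted benzene (C)",
  "c1ccccc1[#8]"        = "substituted benzene (O)",
  "c1ccccc1[#7]"        = "substituted benzene (N)",
  "c1ccccc1c2ccccc2"    = "biphenyl",
  "c1ccccc1Cc2ccccc2"   = "diphenylmethane",
  "c1ccccc1Oc2ccccc2"   = "diphenyl ether"
)
for (p in names(curated)) add("smarts", p, 1, p, curated[[p]])
for (p in names(ring_sm)) add("smarts", p, 1, p, ring_sm[[p]])
# generated short element sequences with explicit bonds
seq_el <- c("C", "N", "O", "S")
seq_bonds <- c("-", "=")
gen <- character()
for (e1 in seq_el) for (b1 in seq_bonds) for (e2 in seq_el) {
  for (b2 in seq_bonds) for (e3 in seq_el) {
    if (b1 == "=" && b2 == "=" && e2 != "C") next
    gen <- c(gen, sprintf("[#%d]%s[#%d]%s[#%d]", elnum[e1], b1, elnum[e2],
                          b2, elnum[e3]))
  }
}
gen <- unique(gen)
# drop sequences equivalent to their reverse to avoid duplicate keys
canon <- vapply(strsplit(gen, ""), function(x) {
  s <- paste(x, collapse = "")
  r <- paste(rev(x), collapse = "")
  min(s, r)
}, "")
gen <- gen[!duplicated(canon)]
need <- 168 - (length(curated) + length(ring_sm))
quads <- c("CCCC", "CCCCCC", "CCOC", "CCNC", "OCCCO", "NCCCN", "CC(C)C",
           "CC(C)(C)C", "CC(C)N", "CC(C)O", "C(=O)CC(=O)", "cCC", "cCCc",
           "cCN", "cCO", "cOC", "cNC(=O)", "cS", "CSC", "COC(=O)")
pool <- unique(c(gen, quads))
stopifnot(length(pool) >= need)
for (p in pool[seq_len(need)]) {
  add("smarts", p, 1, p, paste0("substructure ", p))
}
keys <- bind_rows(rows)
stopifnot(nrow(keys) == 881)
keys <- mutate(keys, bit = dplyr::row_number() - 1L, .before = 1)

## validate every SMARTS pattern through the engine ------------------------
probe <- paste(
  "CCN p1", "c1ccccc1 p2", "CC(=O)NC1CCCCC1O p3", "ClC(F)(F)c1ccncc1 p4",
  "OC(=O)c1ccc(N)cc1 p5", "CCOC(=O)CC#N p6", "CS(=O)(=O)NCc1ccsc1 p7",
  sep = "\n")
sm <- keys$smarts[keys$type == "smarts"]
res <- ChemmineOB::forEachMol("SMILES", probe, function(mol) {
  vapply(sm, function(p) {
    tryCatch(ChemmineOB::smartsSearch_OB(list(mol), p),
             error = function(e) NA_real_)
  }, numeric(1))
})
counts <- do.call(rbind, res)
bad <- sm[apply(is.na(counts), 2, any)]
if (length(bad) > 0) stop("invalid SMARTS: ", paste(bad, collapse = " | "))
cat("SMARTS keys validated:", length(sm),
    "| matched by probes:", sum(colSums(counts) > 0), "\n")

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
readr::write_tsv(keys, "inst/extdata/pubchem_keys_synthetic.tsv")
cat("wrote", nrow(keys), "keys;",
    file.size("inst/extdata/pubchem_keys_synthetic.tsv"), "bytes\n")
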
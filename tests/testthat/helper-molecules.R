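# Shared molecule fixtures, parsed once per test run.

test_smiles <- c(
  methane = "C", ethanamine = "CCN", cyclopropane = "C1CC1",
  benzene = "c1ccccc1", pyridine = "c1ccncc1", furan = "c1ccoc1",
  thiophene = "c1ccsc1", ethanol = "CCO", acetamide = "CC(=O)N",
  isobutane = "CC(C)C", propyne = "CC#C", glycol = "OCCO",
  acetic = "CC(=O)O", mek = "CCC(C)=O"
)

test_mols <- local({
  p <- ligscreen::parse_smiles(unname(test_smiles), id = names(test_smiles))
  stats::setNames(p$mol, names(test_smiles))
})

# Build a bit fingerprint directly (for metric/similarity fixtures).
make_fp <- function(bits, scheme = "morgan", length = 2048L) {
  ligscreen:::new_bit_fp(scheme, length, bits)
}

# Permute the atom order of a mol_graph, remapping bonds and rings.
permute_mol <- function(mol, perm) {
  inv <- order(perm)
  out <- mol
  out$atoms <- mol$atoms[perm, ]
  out$bonds <- mol$bonds
  out$bonds$a1 <- inv[mol$bonds$a1]
  out$bonds$a2 <- inv[mol$bonds$a2]
  out$rings <- lapply(mol$rings, function(r) inv[r])
  out
}

# A small labeled screen: n entries, n_act actives placed at the given
# ranks (1-based) of a score-descending list.
make_screen <- function(n, active_ranks, target = "T") {
  label <- rep(0, n)
  label[active_ranks] <- 1
  ligscreen::ranked_screen(
    tibble::tibble(
      ligand_id = sprintf("L%04d", seq_len(n)),
      score = seq(n, 1), label = label
    ),
    target = target
  )
}
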
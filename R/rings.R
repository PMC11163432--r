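# Ring perception and aromaticity.
#
# Rings are taken to be chordless simple cycles of size 3..8 (induced
# cycles): fused systems decompose into their component rings because the
# perimeter cycle has the fusion bond as a chord. This is the ring set used
# for ring-membership flags, ring-count substructure keys, and aromaticity.

# Enumerate chordless cycles of length 3..max_size. Returns a list of
# integer vertex vectors (cycle order, smallest vertex first).
.chordless_cycles <- function(n, bonds, max_size = 8L) {
  if (nrow(bonds) == 0L || n < 3L) return(list())
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  amat <- matrix(FALSE, n, n)
  amat[cbind(bonds$a1, bonds$a2)] <- TRUE
  amat[cbind(bonds$a2, bonds$a1)] <- TRUE
  cycles <- list()
  # DFS from each start vertex v; only vertices > v may appear later, and
  # the cycle's second vertex must be smaller than its last to fix one
  # traversal direction.
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) < 2L) next
    stack <- list(c(v))
    while (length(stack) > 0L) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- path[length(path)]
      for (u in adj[[last]]) {
        if (u == v && length(path) >= 3L) {
          if (path[2] < path[length(path)]) {
            # chordless: no adjacency between non-consecutive members
            k <- length(path)
            chord <- FALSE
            for (i in seq_len(k - 2L)) {
              js <- (i + 2L):k
              if (i == 1L) js <- js[js != k]
              if (any(amat[path[i], path[js]])) { chord <- TRUE; break }
            }
            if (!chord) cycles[[length(cycles) + 1L]] <- path
          }
        } else if (u > v && !(u %in% path) && length(path) < max_size) {
          stack[[length(stack) + 1L]] <- c(path, u)
        }
      }
    }
  }
  cycles
}

# Hückel-style aromaticity over chordless rings of size 5-6.
# An atom contributes one pi electron if it carries any double/triple bond,
# two if it is an N/O/S donating a lone pair, and disqualifies the ring if
# it is a saturated carbon. A ring is aromatic when the pi count is 4n+2.
.perceive_aromatic <- function(ct, bonds, rings) {
  n <- length(ct$element)
  atom_arom <- logical(n)
  bond_arom <- logical(nrow(bonds))
  if (length(rings) == 0L) {
    return(list(atom = atom_arom, bond = bond_arom))
  }
  has_multi <- logical(n)
  if (nrow(bonds) > 0L) {
    mb <- bonds$order >= 2L | bonds$aromatic
    has_multi[unique(c(bonds$a1[mb], bonds$a2[mb]))] <- TRUE
  }
  bond_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bk <- bond_key(bonds$a1, bonds$a2)
  for (ring in rings) {
    k <- length(ring)
    if (k < 5L || k > 6L) next
    el <- ct$element[ring]
    if (!all(el %in% c("C", "N", "O", "S"))) next
    pi <- integer(k)
    bad <- FALSE
    for (i in seq_len(k)) {
      a <- ring[i]
      if (has_multi[a]) {
        pi[i] <- 1L
      } else if (el[i] %in% c("N", "O", "S")) {
        pi[i] <- 2L
      } else {
        bad <- TRUE
        break
      }
    }
    if (bad || sum(pi) %% 4L != 2L) next
    atom_arom[ring] <- TRUE
    edges <- bond_key(ring, c(ring[-1], ring[1]))
    bond_arom[bk %in% edges] <- TRUE
  }
  list(atom = atom_arom, bond = bond_arom)
}

# Ring summary used by ring-count substructure keys: one row per perceived
# ring with its size and element/aromaticity character.
.ring_table <- function(mol) {
  rings <- mol$rings
  if (length(rings) == 0L) {
    return(tibble(size = integer(), aromatic = logical(),
                  carbon_only = logical(), has_n = logical(),
                  has_o = logical(), has_s = logical(),
                  saturated = logical()))
  }
  el <- mol$atoms$element
  arom <- mol$atoms$aromatic
  tibble(
    size = vapply(rings, length, integer(1)),
    aromatic = vapply(rings, function(r) all(arom[r]), logical(1)),
    carbon_only = vapply(rings, function(r) all(el[r] == "C"), logical(1)),
    has_n = vapply(rings, function(r) any(el[r] == "N"), logical(1)),
    has_o = vapply(rings, function(r) any(el[r] == "O"), logical(1)),
    has_s = vapply(rings, function(r) any(el[r] == "S"), logical(1)),
    saturated = vapply(
      rings,
      function(r) {
        b <- mol$bonds
        on_ring <- (b$a1 %in% r) & (b$a2 %in% r)
        all(b$order[on_ring] == 1L & !b$aromatic[on_ring])
      },
      logical(1)
    )
  )
}
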
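# Synthetic multi-target actives/decoys benchmark with a planted scaffold
# signal.
#
# Molecules are assembled from a small validated grammar: a ring core, a
# linker, a second ring as substituent, and chain/heteroatom decorations.
# A target's actives and its template ligands share a target-specific
# scaffold (core, linker, second ring) and differ in decorations, so the
# signal lives exactly where the screening methods look: shared
# fingerprint bits. Pocket residue composition is coupled to the
# scaffold's ring types through a fixed ring->residue map, so the boosted
# scorer can, in principle, learn which pocket compositions pair with
# which ligand substructures across targets. At signal strength 0 actives
# are drawn from the decoy distribution and the benchmark is an exact
# null.

# ring vocabulary: core templates (attachment digit 1) with and without a
# decoration slot, substituent templates (digit 2) with and without a
# chain tail, heavy-atom counts, and the residues each ring type enriches
# in the pocket.
.RING_POOL <- list(
  BENZ = list(core = "c1ccccc1%A%", core_dec = "c1cc(%B%)ccc1%A%",
              sub = "c2ccccc2", sub_tail = "c2ccc(%T%)cc2",
              size = 6L, residues = c("F", "W", "Y")),
  PYRI = list(core = "c1ccncc1%A%", core_dec = "c1cc(%B%)ncc1%A%",
              sub = "c2ccncc2", sub_tail = "c2ccnc(%T%)c2",
              size = 6L, residues = c("H", "K", "R")),
  THIO = list(core = "c1ccsc1%A%", core_dec = "c1cc(%B%)sc1%A%",
              sub = "c2ccsc2", sub_tail = "c2cc(%T%)sc2",
              size = 5L, residues = c("C", "M", "S")),
  FURA = list(core = "c1ccoc1%A%", core_dec = "c1cc(%B%)oc1%A%",
              sub = "c2ccoc2", sub_tail = "c2cc(%T%)oc2",
              size = 5L, residues = c("D", "E", "N")),
  CHEX = list(core = "C1CCCCC1%A%", core_dec = "C1CC(%B%)CCC1%A%",
              sub = "C2CCCCC2", sub_tail = "C2CCC(%T%)CC2",
              size = 6L, residues = c("L", "I", "V")),
  PIPE = list(core = "C1CCNCC1%A%", core_dec = "C1CC(%B%)NCC1%A%",
              sub = "C2CCNCC2", sub_tail = "C2CC(%T%)NCC2",
              size = 6L, residues = c("T", "Q", "G"))
)

.LINKERS <- c("", "C", "CC", "O", "CO", "C(=O)")

.DECORATIONS <- c("C", "CC", "CCC", "O", "OC", "OCC", "N", "NC", "Cl",
                  "F", "Br", "C(=O)O", "C(=O)N", "C#N", "C(F)(F)F")

# sample one element of x (safe for length-1 x, unlike sample())
.sample1 <- function(x) x[sample.int(length(x), 1L)]

# heavy atoms in a SMILES fragment
.count_heavy <- function(s) {
  if (!nzchar(s)) return(0L)
  m <- gregexpr("Cl|Br|[BCNOSPFI]|c|n|o|s", s)[[1]]
  sum(m > 0)
}

.fill <- function(template, ...) {
  subs <- list(...)
  for (nm in names(subs)) {
    template <- sub(paste0("%", nm, "%"), subs[[nm]], template, fixed = TRUE)
  }
  template
}

# Assemble one molecule from scaffold (core/linker/sub ring names) and
# decorations dec1 (on the core) and dec2 (tail on the second ring).
.assemble_molecule <- function(core, linker, sub, dec1 = "", dec2 = "") {
  rc <- .RING_POOL[[core]]
  rs <- .RING_POOL[[sub]]
  sub_part <- if (nzchar(dec2)) .fill(rs$sub_tail, T = dec2) else rs$sub
  a <- paste0(linker, sub_part)
  if (nzchar(dec1)) .fill(rc$core_dec, B = dec1, A = a)
  else .fill(rc$core, A = a)
}

#' Benchmark specification
#'
#' The study conditions of the bundled synthetic screen: number of
#' targets, actives per target, decoy:active ratio (default 60, the
#' common benchmark regime; 30 mirrors the smaller-ratio collections),
#' planted signal strength in `[0, 1]`, and the master seed. Optionally a
#' number of near-duplicate target pairs (`n_clone_pairs`) plants
#' high-identity sequence pairs to exercise the cross-validation
#' exclusion.
#'
#' @param n_targets Number of targets (default 10).
#' @param actives_per_target Actives per target (default 5).
#' @param decoy_ratio Decoys per active (default 60).
#' @param signal_strength Probability that an active carries the target
#'   scaffold (default 1; 0 gives an exact null).
#' @param n_pockets Accepted-range template pockets per target.
#' @param n_reject Below-threshold template pockets per target.
#' @param pocket_size_range Pocket residue-count range.
#' @param n_clone_pairs Near-duplicate target sequence pairs (default 0).
#' @param seed Master seed.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_targets = 10L, actives_per_target = 5L,
                           decoy_ratio = 60L, signal_strength = 1,
                           n_pockets = 6L, n_reject = 3L,
                           pocket_size_range = c(10L, 25L),
                           n_clone_pairs = 0L, seed = 42L) {
  stopifnot(n_targets >= 1L, actives_per_target >= 1L, decoy_ratio >= 1L,
            signal_strength >= 0, signal_strength <= 1)
  structure(
    list(n_targets = as.integer(n_targets),
         actives_per_target = as.integer(actives_per_target),
         decoy_ratio = as.integer(decoy_ratio),
         signal_strength = signal_strength,
         n_pockets = as.integer(n_pockets),
         n_reject = as.integer(n_reject),
         pocket_size_range = as.integer(pocket_size_range),
         n_clone_pairs = as.integer(n_clone_pairs),
         seed = as.integer(seed)),
    class = "benchmark_spec"
  )
}

# A random scaffold triple (core, linker, sub).
.random_scaffold <- function() {
  list(core = .sample1(names(.RING_POOL)),
       linker = .sample1(.LINKERS),
       sub = .sample1(names(.RING_POOL)))
}

# A molecule with the given scaffold and random decorations.
.random_decorated <- function(scaffold) {
  dec1 <- .sample1(c("", .DECORATIONS))
  dec2 <- .sample1(c("", .DECORATIONS))
  .assemble_molecule(scaffold$core, scaffold$linker, scaffold$sub,
                     dec1, dec2)
}

#' Generate one random molecule
#'
#' Grammar-based assembly from the bundled fragment vocabulary (ring
#' cores, linkers, second rings, chain/heteroatom decorations; plain
#' heteroatom chains below 12 heavy atoms). The result is a valid SMILES
#' with a heavy-atom count drawn uniformly from `size_range`, exactly;
#' deterministic for a given seed.
#'
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param size_range Heavy-atom count range, within 3..30.
#' @return A single SMILES string.
#' @export
generate_molecule <- function(seed = NULL, size_range = c(10L, 24L)) {
  stopifnot(size_range[1] >= 3L, size_range[2] <= 30L,
            size_range[1] <= size_range[2])
  gen <- function() {
    n <- .sample1(size_range[1]:size_range[2])
    if (n < 12L) {
      # heteroatom chain of exactly n atoms
      inner <- sample(c("C", "C", "C", "N", "O"), max(0L, n - 2L),
                      replace = TRUE)
      ends <- sample(c("C", "C", "N", "O"), min(2L, n), replace = TRUE)
      return(paste(c(ends[1], inner, if (n > 1L) ends[2]), collapse = ""))
    }
    # ring assembly padded to exactly n atoms with a chain tail
    repeat {
      sc <- .random_scaffold()
      base <- .RING_POOL[[sc$core]]$size + .count_heavy(sc$linker) +
        .RING_POOL[[sc$sub]]$size
      if (base <= n) break
    }
    room <- n - base
    d1 <- .sample1(c("", .DECORATIONS[vapply(.DECORATIONS, .count_heavy,
                                             integer(1)) <= room]))
    room <- room - .count_heavy(d1)
    d2 <- if (room > 0L) strrep("C", room) else ""
    .assemble_molecule(sc$core, sc$linker, sc$sub, d1, d2)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# residue distribution for a target given its scaffold: 70% of the mass on
# the ring-associated residues, 30% spread over the rest.
.target_residue_probs <- function(scaffold) {
  enriched <- unique(c(.RING_POOL[[scaffold$core]]$residues,
                       .RING_POOL[[scaffold$sub]]$residues))
  p <- setNames(rep(0.3 / (20 - length(enriched)), 20L), AA_ALPHABET)
  p[enriched] <- 0.7 / length(enriched)
  p
}

# One target's data; assumes the caller controls the RNG state.
.generate_target_impl <- function(target_id, spec, scaffold,
                                  sequence = NULL) {
  n_act <- spec$actives_per_target
  n_dec <- n_act * spec$decoy_ratio
  probs <- .target_residue_probs(scaffold)
  if (is.null(sequence)) {
    sequence <- paste(sample(AA_ALPHABET, .sample1(150:250),
                             replace = TRUE, prob = probs), collapse = "")
  }
  actives <- vapply(seq_len(n_act), function(i) {
    if (runif(1) < spec$signal_strength) .random_decorated(scaffold)
    else .random_decorated(.random_scaffold())
  }, character(1))
  decoys <- vapply(seq_len(n_dec), function(i) {
    .random_decorated(.random_scaffold())
  }, character(1))
  # neutral ids over a random permutation so identifiers carry no label
  ids <- paste0("L", formatC(seq_len(n_act + n_dec), width = 4, flag = "0"))
  ids <- ids[order(sample.int(n_act + n_dec))]
  n_all <- spec$n_pockets + spec$n_reject
  szr <- spec$pocket_size_range
  pockets <- tibble(
    template_id = paste0(target_id, "_t",
                         formatC(seq_len(n_all), width = 2, flag = "0")),
    tm_score = c(runif(spec$n_pockets, 0.65, 0.95),
                 runif(spec$n_reject, 0.2, 0.58)),
    aligned_fraction = c(runif(spec$n_pockets, 0.85, 1),
                         runif(spec$n_reject, 0.3, 0.95)),
    seq_identity = runif(n_all, 0.2, 0.7),
    rank_score = sort(runif(n_all, 0, 1), decreasing = TRUE),
    pocket_residues = vapply(seq_len(n_all), function(i) {
      paste(sample(AA_ALPHABET, .sample1(szr[1]:szr[2]),
                   replace = TRUE, prob = probs), collapse = "")
    }, character(1)),
    template_ligands = lapply(seq_len(n_all), function(i) {
      vapply(seq_len(.sample1(1:2)), function(j) {
        .random_decorated(scaffold)
      }, character(1))
    })
  )
  list(target_id = target_id, sequence = sequence, scaffold = scaffold,
       actives = tibble(smiles = actives, id = ids[seq_len(n_act)]),
       decoys = tibble(smiles = decoys, id = ids[n_act + seq_len(n_dec)]),
       pockets = pockets)
}

#' Generate one synthetic target
#'
#' Draws a target scaffold and emits the target's actives (scaffold +
#' random decorations, with probability `signal_strength`), decoys
#' (unrelated grammar molecules), template-pocket metadata (a mix of
#' records passing and failing the structural filters) and scaffold-bearing
#' template ligands.
#'
#' @param seed Integer seed.
#' @param spec A `benchmark_spec`.
#' @param target_id Target identifier.
#' @return A list with `target_id`, `sequence`, `scaffold`, `actives`,
#'   `decoys` and `pockets`.
#' @export
generate_target <- function(seed, spec = benchmark_spec(),
                            target_id = "T01") {
  withr::with_seed(seed, {
    .generate_target_impl(target_id, spec, .random_scaffold())
  })
}

#' Generate a synthetic benchmark
#'
#' Builds the full multi-target benchmark from the master seed: distinct
#' scaffolds per target, per-target actives/decoys/template metadata, the
#' pairwise sequence-identity matrix, and (when `dir` is given) the
#' on-disk tree: one directory per target with `actives.smi`,
#' `decoys.smi` and `templates.tsv`, plus global `targets.tsv`,
#' `identity.tsv` and `manifest.json`. Reproducible byte-for-byte from the
#' seed.
#'
#' @param spec A `benchmark_spec`.
#' @param dir Optional output directory.
#' @return A `vls_benchmark` object (invisibly when writing to disk).
#' @export
generate_benchmark <- function(spec = benchmark_spec(), dir = NULL) {
  # Targets fall into chemotype families: scaffolds are drawn from a small
  # pool and shared round-robin, the way real benchmark collections contain
  # target families binding related chemotypes. This is what lets a scorer
  # trained on the other targets generalize to a held-out one.
  scaffolds <- withr::with_seed(spec$seed, {
    all_sc <- expand.grid(core = names(.RING_POOL), linker = .LINKERS,
                          sub = names(.RING_POOL),
                          stringsAsFactors = FALSE)
    pool_n <- max(2L, ceiling(spec$n_targets / 3))
    pool <- all_sc[sample.int(nrow(all_sc), pool_n), , drop = FALSE]
    pool[rep(seq_len(pool_n), length.out = spec$n_targets), , drop = FALSE]
  })
  ids <- paste0("T", formatC(seq_len(spec$n_targets), width = 2, flag = "0"))
  targets <- withr::with_seed(spec$seed + 1L, {
    out <- lapply(seq_len(spec$n_targets), function(i) {
      .generate_target_impl(ids[i], spec, as.list(scaffolds[i, ]))
    })
    # clone pairs: overwrite sequences to near-duplicates
    if (spec$n_clone_pairs > 0L) {
      for (k in seq_len(min(spec$n_clone_pairs,
                            floor(spec$n_targets / 2)))) {
        i <- 2L * k - 1L; j <- 2L * k
        s <- strsplit(out[[i]]$sequence, "")[[1]]
        flip <- sample(length(s), max(1L, round(0.05 * length(s))))
        s[flip] <- sample(AA_ALPHABET, length(flip), replace = TRUE)
        out[[j]]$sequence <- paste(s, collapse = "")
      }
    }
    out
  })
  names(targets) <- ids
  identity <- sequence_identity_matrix(
    tibble(target_id = ids,
           sequence = vapply(targets, `[[`, "", "sequence"))
  )
  bench <- structure(list(spec = spec, targets = targets,
                          identity = identity),
                     class = "vls_benchmark")
  if (!is.null(dir)) {
    write_benchmark(bench, dir)
    return(invisible(bench))
  }
  bench
}

#' @export
print.vls_benchmark <- function(x, ...) {
  s <- x$spec
  cat("<vls_benchmark> ", s$n_targets, " targets, ",
      s$actives_per_target, " actives + ",
      s$actives_per_target * s$decoy_ratio, " decoys each, signal ",
      s$signal_strength, ", seed ", s$seed, "\n", sep = "")
  invisible(x)
}

#' Write a benchmark tree to disk
#' @param bench A `vls_benchmark`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory ", dir))
  for (tg in bench$targets) {
    td <- file.path(dir, tg$target_id)
    dir.create(td, showWarnings = FALSE)
    write_smiles(tg$actives, file.path(td, "actives.smi"))
    write_smiles(tg$decoys, file.path(td, "decoys.smi"))
    write_template_pockets(tg$pockets, file.path(td, "templates.tsv"))
  }
  readr::write_tsv(
    tibble(target_id = names(bench$targets),
           sequence = vapply(bench$targets, `[[`, "", "sequence")),
    file.path(dir, "targets.tsv")
  )
  idm <- as.data.frame(bench$identity)
  idm <- cbind(target_id = rownames(bench$identity), idm)
  readr::write_tsv(as_tibble(idm), file.path(dir, "identity.tsv"))
  jsonlite::write_json(
    list(spec = unclass(bench$spec),
         scaffolds = lapply(bench$targets, `[[`, "scaffold")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a benchmark tree written by [write_benchmark()]
#' @param dir Benchmark directory.
#' @return A `vls_benchmark`.
#' @export
read_benchmark <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  spec <- do.call(benchmark_spec, manifest$spec)
  tg_tbl <- readr::read_tsv(file.path(dir, "targets.tsv"),
                            show_col_types = FALSE)
  idm <- readr::read_tsv(file.path(dir, "identity.tsv"),
                         show_col_types = FALSE)
  identity <- as.matrix(idm[, -1])
  rownames(identity) <- idm$target_id
  targets <- lapply(seq_len(nrow(tg_tbl)), function(i) {
    tid <- tg_tbl$target_id[i]
    td <- file.path(dir, tid)
    sc <- manifest$scaffolds[[tid]]
    list(target_id = tid, sequence = tg_tbl$sequence[i],
         scaffold = sc,
         actives = read_smiles(file.path(td, "actives.smi")),
         decoys = read_smiles(file.path(td, "decoys.smi")),
         pockets = read_template_pockets(file.path(td, "templates.tsv")))
  })
  names(targets) <- tg_tbl$target_id
  structure(list(spec = spec, targets = targets, identity = identity),
            class = "vls_benchmark")
}

#' Target profiles for every benchmark target
#'
#' Applies the pocket filters and composition derivation to each target's
#' template metadata.
#'
#' @param bench A `vls_benchmark`.
#' @inheritParams target_profile
#' @return Named list of `target_profile` objects.
#' @export
benchmark_profiles <- function(bench, tm_min = 0.6, cov_min = 0.8,
                               seqid_cutoff = NULL, max_pockets = 75L) {
  lapply(bench$targets, function(tg) {
    target_profile(tg$target_id, tg$sequence, tg$pockets,
                   tm_min = tm_min, cov_min = cov_min,
                   seqid_cutoff = seqid_cutoff, max_pockets = max_pockets)
  })
}

#' A target's labeled screening library
#'
#' @param bench A `vls_benchmark`.
#' @param target_id Target id.
#' @return Tibble `smiles`, `id`, `label` (actives 1, decoys 0).
#' @export
benchmark_library <- function(bench, target_id) {
  tg <- bench$targets[[target_id]]
  if (is.null(tg)) abort(paste0("unknown target ", target_id))
  bind_rows(
    mutate(tg$actives, label = 1),
    mutate(tg$decoys, label = 0)
  ) %>% arrange(.data$id)
}
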
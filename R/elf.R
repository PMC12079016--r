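#' Configuration for ELF-style conformer selection
#'
#' Parameters of the electrostatically-least-interacting conformer filter:
#' keep the `top_fraction` of conformers with the lowest intramolecular
#' repulsion score (computed with all charges made positive), then pick
#' `n_select` mutually diverse conformers and average their charges.
#'
#' @param top_fraction proportion of conformers forming the low-interaction
#'   pool (default 0.02, i.e. the top 2 percent).
#' @param n_select number of diverse conformers to average (default 10).
#' @param min_conformers recommended minimum ensemble size (default 500);
#'   smaller inputs trigger a warning, not an error, so small studies can run.
#' @param distance_floor Angstrom floor applied to interatomic distances in
#'   the repulsion score, capping the 1/r singularity (default 0.5).
#' @return list of class `elf_config`.
#' @export
elf_config <- function(top_fraction = 0.02, n_select = 10L,
                       min_conformers = 500L, distance_floor = 0.5) {
  stopifnot(top_fraction > 0, top_fraction <= 1, n_select >= 1,
            distance_floor > 0)
  structure(list(top_fraction = top_fraction, n_select = as.integer(n_select),
                 min_conformers = as.integer(min_conformers),
                 distance_floor = distance_floor),
            class = "elf_config")
}

# pairwise distance matrix of a conformer
coord_dist <- function(coords) as.matrix(stats::dist(coords))

# eligibility mask: atom pairs at topological distance >= 3 (1-2 and 1-3
# pairs are fixed by covalent geometry and carry no conformational signal)
eligible_pairs_mask <- function(mol) {
  topo_distances(mol) >= 3
}

#' Intramolecular electrostatic repulsion score of a conformer
#'
#' Sum over eligible atom pairs (topological distance >= 3) of
#' `|q_i| * |q_j| / max(r_ij, distance_floor)` -- all charges made positive,
#' so every close contact is penalized regardless of sign. Lower scores mean
#' fewer or weaker close intramolecular contacts; the ELF filter keeps the
#' lowest-scoring conformers.
#'
#' @param conf a `conformer`.
#' @param q a `charge_set` aligned to the conformer's molecule.
#' @param cfg an [elf_config()].
#' @return numeric scalar in e^2/Angstrom, >= 0 (0 when no pair is eligible).
#' @export
intramolecular_repulsion_score <- function(conf, q, cfg = elf_config()) {
  stopifnot(inherits(conf, "conformer"), inherits(q, "charge_set"))
  mol <- conf$molecule
  if (length(q$charges) != n_atoms(mol))
    stop("charge set is not aligned to the conformer's molecule")
  mask <- eligible_pairs_mask(mol)
  if (!any(mask)) return(0)
  r <- pmax(coord_dist(conf$coords), cfg$distance_floor)
  aq <- abs(q$charges)
  contrib <- outer(aq, aq) / r
  sum(contrib[mask & upper.tri(mask)])
}

#' Kabsch RMSD between two conformers
#'
#' Minimal root-mean-square deviation over rigid-body superposition
#' (translation plus proper rotation), computed by the Kabsch/SVD algorithm
#' with the determinant correction that excludes reflections.
#'
#' @param confA,confB `conformer` objects with equal atom counts.
#' @param atoms optional integer vector restricting the superposition to a
#'   subset of atoms (e.g. heavy atoms); default all.
#' @return numeric RMSD in Angstrom, >= 0; 0 for congruent geometries.
#' @export
kabsch_rmsd <- function(confA, confB, atoms = NULL) {
  A <- if (inherits(confA, "conformer")) confA$coords else as.matrix(confA)
  B <- if (inherits(confB, "conformer")) confB$coords else as.matrix(confB)
  if (!is.null(atoms)) {
    A <- A[atoms, , drop = FALSE]
    B <- B[atoms, , drop = FALSE]
  }
  if (nrow(A) != nrow(B)) stop("atom count mismatch between conformers")
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(max(0, mean(rowSums((A - B %*% R)^2))))
}

#' Greedy max-min diverse subset of conformers
#'
#' Starting from `seed_index`, repeatedly adds the conformer whose minimum
#' Kabsch RMSD to the already-chosen set is largest (farthest-point greedy),
#' breaking ties by lowest index. Deterministic.
#'
#' @param confs list of `conformer` objects of the same molecule.
#' @param k number of conformers to select (`k <= length(confs)`).
#' @param seed_index index of the first selected conformer.
#' @param atoms optional atom subset for the RMSD (e.g. heavy atoms).
#' @return integer vector of `k` indices into `confs`, in selection order
#'   (seed first).
#' @export
greedy_diverse_subset <- function(confs, k, seed_index = 1L, atoms = NULL) {
  n <- length(confs)
  k <- as.integer(k)
  if (k > n) stop("k exceeds the number of conformers")
  if (seed_index < 1L || seed_index > n) stop("seed_index out of range")
  if (k < 1L) stop("k must be >= 1")
  D <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <- kabsch_rmsd(confs[[i]], confs[[j]], atoms = atoms)
    }
  }
  chosen <- as.integer(seed_index)
  mind <- D[, seed_index]
  while (length(chosen) < k) {
    mind[chosen] <- -Inf
    nxt <- which.max(mind)  # first (lowest) index on ties
    chosen <- c(chosen, as.integer(nxt))
    mind <- pmin(mind, D[, nxt])
  }
  chosen
}

#' Select the electrostatically least-interacting diverse conformers
#'
#' The ELF selection rule: score every conformer with
#' [intramolecular_repulsion_score()], keep the `ceiling(top_fraction * n)`
#' lowest-scoring conformers (enlarged to `n_select` if the pool would be
#' smaller), and pick `n_select` mutually diverse members by greedy max-min
#' heavy-atom Kabsch RMSD, seeded at the lowest-scoring conformer. With the
#' defaults (2 percent of 500 conformers) the pool size equals the 10
#' conformers to be selected.
#'
#' @param confs list of `conformer` objects (one geometry each).
#' @param sets list of `charge_set` objects, one per conformer.
#' @param cfg an [elf_config()].
#' @return integer vector of `n_select` indices into `confs`, in selection
#'   order. A warning is issued when fewer than `cfg$min_conformers`
#'   conformers are supplied.
#' @export
elf_select <- function(confs, sets, cfg = elf_config()) {
  n <- length(confs)
  if (length(sets) != n) stop("need exactly one charge set per conformer")
  if (n < cfg$n_select)
    stop(sprintf("need at least %d conformers, got %d", cfg$n_select, n))
  if (n < cfg$min_conformers)
    warning(sprintf("only %d conformers supplied; %d are recommended for ELF selection",
                    n, cfg$min_conformers))
  scores <- mapply(intramolecular_repulsion_score, confs, sets,
                   MoreArgs = list(cfg = cfg))
  pool_size <- max(ceiling(cfg$top_fraction * n), cfg$n_select)
  ord <- order(scores, seq_len(n))  # stable: ties by lowest index
  pool <- ord[seq_len(pool_size)]
  mol <- confs[[1L]]$molecule
  ha <- heavy_atoms(mol)
  if (length(ha) < 3L) ha <- NULL  # too few heavy atoms to superpose alone
  sel <- greedy_diverse_subset(confs[pool], cfg$n_select, seed_index = 1L,
                               atoms = ha)
  pool[sel]
}

#' ELF consensus charges
#'
#' Averages, atom-wise, the charge sets of the conformers chosen by
#' [elf_select()]. The mean preserves the total molecular charge exactly,
#' and the result's provenance records the selected conformer ids.
#'
#' @inheritParams elf_select
#' @return a `charge_set` with method tag `"elf-consensus"`.
#' @export
elf_consensus_charges <- function(confs, sets, cfg = elf_config()) {
  idx <- elf_select(confs, sets, cfg)
  q <- rowMeans(vapply(sets[idx], function(s) s$charges,
                       numeric(length(sets[[1L]]$charges))))
  ids <- vapply(confs[idx], function(cf) cf$id, character(1))
  charge_set(q, confs[[1L]]$molecule, method = "elf-consensus",
             conformer_id = paste(ids, collapse = "+"),
             platform = sets[[idx[1L]]]$platform)
}
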
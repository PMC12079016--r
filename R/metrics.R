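#' Maximal per-atom charge difference between two charge sets
#'
#' The largest absolute difference in partial charge at any single atom
#' between two aligned charge sets: `max_u |q1(u) - q2(u)|`. Symmetric in its
#' arguments and zero iff the sets are identical.
#'
#' @param q1,q2 `charge_set` objects for the same molecule, same atom order.
#' @return numeric scalar (e), >= 0.
#' @export
pairwise_max_atom_diff <- function(q1, q2) {
  stopifnot(inherits(q1, "charge_set"), inherits(q2, "charge_set"))
  if (length(q1$charges) != length(q2$charges))
    stop("charge sets are not aligned (length mismatch)")
  max(abs(q1$charges - q2$charges))
}

#' Per-atom charge range across an ensemble
#'
#' For each atom, the range (max minus min) of its partial charge over all
#' charge sets in the ensemble -- the per-atom spread that the maximal
#' partial-charge-difference metric summarizes.
#'
#' @param ens a `charge_ensemble`.
#' @return numeric vector, one range (e) per atom.
#' @export
per_atom_range <- function(ens) {
  q <- ensemble_matrix(ens)
  apply(q, 1L, function(x) max(x) - min(x))
}

#' Maximal partial charge difference of an ensemble
#'
#' The molecule-level variability metric: the largest per-atom charge range
#' observed across all charge sets. Identically equal to the maximum over all
#' set pairs of [pairwise_max_atom_diff()].
#'
#' @param ens a `charge_ensemble`.
#' @return numeric scalar (e).
#' @export
max_charge_range <- function(ens) max(per_atom_range(ens))

#' Per-bond charge differences (bond polarity proxy)
#'
#' For one charge set, the charge seen across each bond:
#' `dq_bond = q(u) - q(v)` in the molecule's bond-storage order. The sign
#' convention (u first) is fixed by bond storage; all reported metrics use
#' absolute differences or ranges, so the convention never affects results.
#'
#' @param q a `charge_set`.
#' @param mol the `mol_graph` supplying the bond list (defaults to the
#'   charge set's own molecule).
#' @return An object of class `bond_delta_set`: numeric `values` (e), one per
#'   bond, plus the source set's provenance.
#' @export
bond_delta_q <- function(q, mol = q$molecule) {
  stopifnot(inherits(q, "charge_set"), inherits(mol, "mol_graph"))
  if (length(q$charges) != n_atoms(mol))
    stop("charge set is not aligned to the molecule")
  v <- if (nrow(mol$bonds) > 0L)
    q$charges[mol$bonds[, "u"]] - q$charges[mol$bonds[, "v"]]
  else numeric(0)
  structure(list(values = v, source = q$conformer_id, method = q$method),
            class = "bond_delta_set")
}

#' Maximal bond-charge-difference between two charge sets
#'
#' The largest absolute change, at any bond, of the bond charge difference
#' dq_bond between two sets: `max_(u,v) |(q1(u)-q1(v)) - (q2(u)-q2(v))|`.
#' Bounded above by twice [pairwise_max_atom_diff()] (triangle inequality).
#'
#' @param q1,q2 `charge_set` objects aligned to `mol`.
#' @param mol the `mol_graph` supplying the bond list.
#' @return numeric scalar (e), >= 0; 0 when the molecule has no bonds.
#' @export
pairwise_max_bond_diff <- function(q1, q2, mol = q1$molecule) {
  d1 <- bond_delta_q(q1, mol)$values
  d2 <- bond_delta_q(q2, mol)$values
  if (length(d1) == 0L) return(0)
  max(abs(d1 - d2))
}

#' Maximal dq_bond difference of an ensemble
#'
#' Per bond, the range (max minus min) of dq_bond across all charge sets;
#' the metric is the largest such range over bonds. Identically equal to the
#' maximum over all set pairs of [pairwise_max_bond_diff()].
#'
#' @param ens a `charge_ensemble`.
#' @return numeric scalar (e); 0 when the molecule has no bonds.
#' @export
max_bond_delta_range <- function(ens) {
  mol <- ens$molecule
  if (nrow(mol$bonds) == 0L) return(0)
  q <- ensemble_matrix(ens)
  d <- q[mol$bonds[, "u"], , drop = FALSE] - q[mol$bonds[, "v"], , drop = FALSE]
  max(apply(d, 1L, function(x) max(x) - min(x)))
}

#' Full variability report for a charge ensemble
#'
#' Computes both molecule-level variability metrics together with the
#' per-atom and per-bond profiles and the argmax locations.
#'
#' @param ens a `charge_ensemble`.
#' @return An object of class `variability_report` with fields
#'   `per_atom_range`, `per_bond_range`, `max_atom_range`, `max_bond_range`,
#'   `argmax_atom`, `argmax_bond` (1-based indices; first index on ties),
#'   and `n_sets`.
#' @export
variability_report <- function(ens) {
  mol <- ens$molecule
  par <- per_atom_range(ens)
  if (nrow(mol$bonds) > 0L) {
    q <- ensemble_matrix(ens)
    d <- q[mol$bonds[, "u"], , drop = FALSE] - q[mol$bonds[, "v"], , drop = FALSE]
    pbr <- apply(d, 1L, function(x) max(x) - min(x))
  } else pbr <- numeric(0)
  structure(list(
    molecule = mol$name,
    per_atom_range = par,
    per_bond_range = pbr,
    max_atom_range = max(par),
    max_bond_range = if (length(pbr)) max(pbr) else 0,
    argmax_atom = which.max(par),
    argmax_bond = if (length(pbr)) which.max(pbr) else NA_integer_,
    n_sets = length(ens$sets)), class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  cat(sprintf(paste0("<variability_report> %s (%d sets)\n",
                     "  max partial charge difference: %.4f e (atom %d)\n",
                     "  max dq_bond difference:        %.4f e (bond %s)\n"),
              x$molecule, x$n_sets, x$max_atom_range, x$argmax_atom,
              x$max_bond_range, as.character(x$argmax_bond)))
  invisible(x)
}

#' Matched-pair comparison of two ensembles (hardware study)
#'
#' Compares two ensembles of the same molecule set-by-set: set k of `ensA` is
#' paired with set k of `ensB`, which must derive from the same conformer --
#' the design used to compare charges produced from identical conformers on
#' different compute platforms. Returns the per-pair maximal atom charge
#' difference and its overall maximum.
#'
#' @param ensA,ensB `charge_ensemble` objects of the same molecule, with
#'   equally many sets and matching conformer ids pair by pair.
#' @return list with `per_pair` (numeric, e, named by conformer id) and
#'   `max` (numeric scalar, e).
#' @export
compare_matched_sets <- function(ensA, ensB) {
  stopifnot(inherits(ensA, "charge_ensemble"), inherits(ensB, "charge_ensemble"))
  if (!identical(ensA$molecule$elements, ensB$molecule$elements))
    stop("ensembles describe different molecules")
  if (length(ensA$sets) != length(ensB$sets))
    stop("ensembles have different numbers of charge sets")
  ida <- vapply(ensA$sets, function(s) s$conformer_id, character(1))
  idb <- vapply(ensB$sets, function(s) s$conformer_id, character(1))
  if (!identical(ida, idb))
    stop("paired charge sets derive from different conformers")
  per <- mapply(pairwise_max_atom_diff, ensA$sets, ensB$sets)
  names(per) <- ida
  list(per_pair = per, max = max(per))
}
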
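#' Molecular graph
#'
#' A minimal chemical data model: atoms carry an element symbol and an integer
#' formal charge; bonds are undirected edges with an integer order. Hydrogens
#' are explicit atoms -- valence checking and truncation depend on them. Atom
#' ordering is the single source of alignment across conformers and charge
#' sets; no atom mapping is ever inferred.
#'
#' @param elements character vector of element symbols (e.g. "C", "H", "O").
#' @param bonds integer matrix (or data.frame) with columns `u`, `v`, `order`;
#'   atom indices are 1-based, `order` is 1, 2 or 3. A molecule with a single
#'   atom may pass a zero-row matrix.
#' @param formal_charges integer vector of per-atom formal charges (e).
#'   Defaults to all zero.
#' @param name text identifier for the molecule.
#' @return An object of class `mol_graph`.
#' @seealso [validate_molecule()] for the full chemical invariant check.
#' @export
mol_graph <- function(elements, bonds, formal_charges = integer(length(elements)),
                      name = "mol") {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("molecule must have at least one atom")
  if (is.data.frame(bonds)) bonds <- as.matrix(bonds)
  if (is.null(bonds) || length(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 3L)
  }
  bonds <- matrix(as.integer(bonds), ncol = 3L,
                  dimnames = list(NULL, c("u", "v", "order")))
  if (nrow(bonds) > 0L) {
    if (any(bonds[, c("u", "v")] < 1L) || any(bonds[, c("u", "v")] > n))
      stop("bond atom index out of range")
    if (any(bonds[, "u"] == bonds[, "v"]))
      stop("self-bond (u == v) not allowed")
    if (!all(bonds[, "order"] %in% 1:3))
      stop("bond order must be 1, 2 or 3")
    key <- paste(pmin(bonds[, "u"], bonds[, "v"]),
                 pmax(bonds[, "u"], bonds[, "v"]))
    if (anyDuplicated(key))
      stop("duplicate bond between the same atom pair")
  }
  formal_charges <- as.integer(formal_charges)
  if (length(formal_charges) != n)
    stop("formal_charges length must equal atom count")
  structure(list(elements = elements, bonds = bonds,
                 formal_charges = formal_charges, name = as.character(name)),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds, total charge %+d e\n",
              x$name, n_atoms(x), nrow(x$bonds), total_formal_charge(x)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `mol_graph`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Total formal charge of a molecule
#' @param mol a `mol_graph`.
#' @return integer sum of per-atom formal charges (e).
#' @export
total_formal_charge <- function(mol) sum(mol$formal_charges)

#' Indices of heavy (non-hydrogen) atoms
#' @param mol a `mol_graph`.
#' @return integer vector of atom indices.
#' @export
heavy_atoms <- function(mol) which(mol$elements != "H")

# igraph view of the molecular graph (isolated atoms kept as vertices)
as_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    data.frame(from = mol$bonds[, "u"], to = mol$bonds[, "v"]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
}

# all-pairs topological (bond-count) distances
topo_distances <- function(mol) {
  d <- igraph::distances(as_igraph(mol))
  ord <- order(as.integer(rownames(d)))
  d[ord, ord, drop = FALSE]
}

# maximum valence by element; S is special-cased (divalent or hexavalent)
.max_valence <- c(H = 1, C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1)

atom_valences <- function(mol) {
  v <- numeric(n_atoms(mol))
  if (nrow(mol$bonds) > 0L) {
    for (b in seq_len(nrow(mol$bonds))) {
      v[mol$bonds[b, "u"]] <- v[mol$bonds[b, "u"]] + mol$bonds[b, "order"]
      v[mol$bonds[b, "v"]] <- v[mol$bonds[b, "v"]] + mol$bonds[b, "order"]
    }
  }
  v
}

#' Validate a molecular graph
#'
#' Checks the full set of structural invariants -- bond index sanity, no
#' duplicate bonds, connectivity, and per-atom valence limits (H 1, C 4, N 3,
#' O 2, halogens 1; S divalent or hexavalent) -- and reports violations rather
#' than erroring, so callers can decide how strict to be.
#'
#' @param mol a `mol_graph`.
#' @return character vector of human-readable violation descriptions, each
#'   naming the offending atom or bond index; empty when the molecule is valid.
#' @examples
#' methane <- mol_graph(c("C", "H", "H", "H", "H"),
#'                      cbind(u = 1, v = 2:5, order = 1), name = "methane")
#' validate_molecule(methane)  # character(0)
#' @export
validate_molecule <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  bad <- character(0)
  n <- n_atoms(mol)
  if (n > 1L) {
    if (nrow(mol$bonds) == 0L || !igraph::is_connected(as_igraph(mol))) {
      comp <- if (nrow(mol$bonds) > 0L)
        igraph::components(as_igraph(mol))$no else n
      bad <- c(bad, sprintf("graph is disconnected (%d components)", comp))
    }
  }
  val <- atom_valences(mol)
  for (i in seq_len(n)) {
    el <- mol$elements[i]
    ok <- if (el == "S") {
      val[i] <= 2 || val[i] == 6
    } else if (el %in% names(.max_valence)) {
      val[i] <= .max_valence[[el]]
    } else TRUE  # unknown elements: no valence rule
    if (!ok)
      bad <- c(bad, sprintf("atom %d (%s) has valence %g exceeding its allowed maximum",
                            i, el, val[i]))
  }
  bad
}

#' Conformer: one 3D geometry of a molecule
#'
#' @param coords numeric matrix, one row per atom, columns x, y, z in Angstrom.
#' @param molecule the `mol_graph` the geometry belongs to.
#' @param id text identifier (conformer ids key the matched-pair hardware
#'   comparison and ELF provenance).
#' @param check if `TRUE` (default), verify that every bonded atom pair lies
#'   within the physically sensible 0.7--2.5 Angstrom window.
#' @return An object of class `conformer`.
#' @export
conformer <- function(coords, molecule, id = "conf", check = TRUE) {
  stopifnot(inherits(molecule, "mol_graph"))
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) != n_atoms(molecule))
    stop("coordinate count must equal atom count")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  if (check && nrow(molecule$bonds) > 0L) {
    d <- sqrt(rowSums((coords[molecule$bonds[, "u"], , drop = FALSE] -
                       coords[molecule$bonds[, "v"], , drop = FALSE])^2))
    off <- which(d < 0.7 | d > 2.5)
    if (length(off) > 0L)
      stop(sprintf("bonded distance out of [0.7, 2.5] Angstrom at bond %d (%.3f A)",
                   off[1], d[off[1]]))
  }
  structure(list(coords = coords, molecule = molecule, id = as.character(id)),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %s of %s (%d atoms)\n",
              x$id, x$molecule$name, nrow(x$coords)))
  invisible(x)
}

#' Partial charge set
#'
#' One vector of per-atom partial charges for a molecule, with provenance
#' (charging method, source conformer, platform). The defining invariant is
#' charge conservation: the charges must sum to the molecule's total formal
#' charge to within 1e-6 e.
#'
#' @param charges numeric vector of per-atom charges (e), in atom order.
#' @param molecule the `mol_graph` the charges belong to.
#' @param method text tag for the charging method.
#' @param conformer_id id of the conformer the charges were derived from
#'   (`NA` for conformer-independent charges).
#' @param platform text tag for the compute platform.
#' @param tol tolerance (e) on the charge-sum invariant; the default 1e-6
#'   suits charges held at full precision, while readers of fixed-precision
#'   files may widen it to the format's quantization bound.
#' @return An object of class `charge_set`.
#' @export
charge_set <- function(charges, molecule, method = "unspecified",
                       conformer_id = NA_character_, platform = NA_character_,
                       tol = 1e-6) {
  stopifnot(inherits(molecule, "mol_graph"))
  charges <- as.numeric(charges)
  if (length(charges) != n_atoms(molecule))
    stop("charge count must equal atom count")
  dev <- abs(sum(charges) - total_formal_charge(molecule))
  if (dev > tol)
    stop(sprintf("charges sum to %.8f but total formal charge is %d (deviation %.2e e)",
                 sum(charges), total_formal_charge(molecule), dev))
  structure(list(charges = charges, molecule = molecule,
                 method = as.character(method),
                 conformer_id = as.character(conformer_id),
                 platform = as.character(platform)),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("<charge_set> %s / conf %s: %d charges, sum %+.6f e\n",
              x$method, x$conformer_id, length(x$charges), sum(x$charges)))
  invisible(x)
}

#' Charge ensemble: aligned charge sets for one molecule
#'
#' Bundles two or more atom-aligned [charge_set]s for the same molecule -- the
#' unit over which the variability metrics are computed (e.g. 50 charge sets,
#' one per conformer).
#'
#' @param molecule a `mol_graph`.
#' @param sets list of `charge_set` objects (at least 2), all aligned to the
#'   molecule's atom ordering.
#' @return An object of class `charge_ensemble`.
#' @export
charge_ensemble <- function(molecule, sets) {
  stopifnot(inherits(molecule, "mol_graph"))
  if (length(sets) < 2L)
    stop("an ensemble needs at least 2 charge sets")
  for (s in sets) {
    if (!inherits(s, "charge_set")) stop("sets must be charge_set objects")
    if (length(s$charges) != n_atoms(molecule))
      stop("charge set not aligned to molecule atom count")
    if (!identical(s$molecule$elements, molecule$elements))
      stop("charge set belongs to a different molecule")
  }
  structure(list(molecule = molecule, sets = sets), class = "charge_ensemble")
}

#' @export
print.charge_ensemble <- function(x, ...) {
  cat(sprintf("<charge_ensemble> %s: %d sets x %d atoms\n",
              x$molecule$name, length(x$sets), n_atoms(x$molecule)))
  invisible(x)
}

# charges as an n_atoms x n_sets matrix
ensemble_matrix <- function(ens) {
  stopifnot(inherits(ens, "charge_ensemble"))
  vapply(ens$sets, function(s) s$charges, numeric(n_atoms(ens$molecule)))
}
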
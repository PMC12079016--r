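#' Truncate a molecule at an acyclic single bond
#'
#' Cuts one single, non-ring bond, keeps the fragment containing `keep`, and
#' caps the open valence with a hydrogen -- the standard way to strip an
#' uninteresting substituent while leaving the retained scaffold chemically
#' complete. Atom ordering of the retained atoms is preserved and the capping
#' hydrogen is appended last, so charge sets and conformers of the result
#' remain trivially alignable.
#'
#' If a conformer is supplied, its retained coordinates are carried over and
#' the capping hydrogen is placed along the former bond vector at the
#' tabulated X-H bond length; callers who prefer fresh geometries can simply
#' regenerate them with [sample_conformers()].
#'
#' @param mol a `mol_graph`.
#' @param bond length-2 integer vector `(u, v)` naming the bond to cut
#'   (1-based atom indices, either order).
#' @param keep which endpoint's fragment to retain (must be `u` or `v`).
#' @param conf optional `conformer` of `mol` to carry through the cut.
#' @param params a [synth_params()] supplying the X-H bond length for
#'   geometric capping.
#' @return list with `molecule` (the truncated `mol_graph`), `conformer`
#'   (a `conformer` or `NULL`), and `map` (integer vector: for each retained
#'   original atom, its index in the new molecule).
#' @examples
#' # cutting propane's terminal C-C bond and keeping the methyl side
#' # yields methane
#' pro <- make_molecule("chain(3)")
#' truncate_at_bond(pro, c(1, 2), keep = 1)$molecule
#' @export
truncate_at_bond <- function(mol, bond, keep, conf = NULL,
                             params = synth_params()) {
  stopifnot(inherits(mol, "mol_graph"), length(bond) == 2L)
  u <- as.integer(bond[1]); v <- as.integer(bond[2])
  hit <- which((mol$bonds[, "u"] == u & mol$bonds[, "v"] == v) |
               (mol$bonds[, "u"] == v & mol$bonds[, "v"] == u))
  if (length(hit) == 0L) stop(sprintf("no bond between atoms %d and %d", u, v))
  if (mol$bonds[hit, "order"] != 1L)
    stop("only single bonds can be truncated")
  g <- as_igraph(mol)
  eid <- igraph::get_edge_ids(g, c(u, v))
  if (!eid %in% igraph::bridges(g))
    stop("bond lies in a cycle; only acyclic bonds can be truncated")
  keep <- as.integer(keep)
  if (!keep %in% c(u, v)) stop("keep must be one of the bond's endpoints")
  lost <- if (keep == u) v else u

  g_cut <- igraph::delete_edges(g, eid)
  comp <- igraph::components(g_cut)$membership
  retained <- sort(as.integer(names(comp)[comp == comp[as.character(keep)]]))

  map <- rep(NA_integer_, n_atoms(mol))
  map[retained] <- seq_along(retained)
  keep_bonds <- mol$bonds[mol$bonds[, "u"] %in% retained &
                          mol$bonds[, "v"] %in% retained, , drop = FALSE]
  new_elements <- c(mol$elements[retained], "H")
  new_fc <- c(mol$formal_charges[retained], 0L)
  h_idx <- length(new_elements)
  new_bonds <- rbind(cbind(u = map[keep_bonds[, "u"]],
                           v = map[keep_bonds[, "v"]],
                           order = keep_bonds[, "order"]),
                     c(map[keep], h_idx, 1L))
  out_mol <- mol_graph(new_elements, new_bonds, new_fc,
                       name = sprintf("%s|cut%d-%d|keep%d", mol$name, u, v, keep))
  bad <- validate_molecule(out_mol)
  if (length(bad)) stop(paste("truncation produced invalid molecule:",
                              paste(bad, collapse = "; ")))

  out_conf <- NULL
  if (!is.null(conf)) {
    stopifnot(inherits(conf, "conformer"))
    dir <- conf$coords[lost, ] - conf$coords[keep, ]
    dir <- dir / sqrt(sum(dir^2))
    hlen <- bond_length(mol$elements[keep], "H", params)
    coords <- rbind(conf$coords[retained, , drop = FALSE],
                    conf$coords[keep, ] + hlen * dir)
    out_conf <- conformer(coords, out_mol, id = paste0(conf$id, "-trunc"))
  }
  list(molecule = out_mol, conformer = out_conf, map = map)
}
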
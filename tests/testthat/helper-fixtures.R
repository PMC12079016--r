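# Shared fixtures and independent oracles, built in code at test time.

# toluene-like graph: benzene ring (alternating bond orders) with a methyl
# substituent; explicit hydrogens. Atoms: C1..C6 ring, C7 methyl, H8..H15.
toluene_graph <- function() {
  elements <- c(rep("C", 7), rep("H", 8))
  bonds <- rbind(
    c(1, 2, 2), c(2, 3, 1), c(3, 4, 2), c(4, 5, 1), c(5, 6, 2), c(6, 1, 1),
    c(1, 7, 1),                                   # ring-methyl bond
    c(2, 8, 1), c(3, 9, 1), c(4, 10, 1), c(5, 11, 1), c(6, 12, 1),
    c(7, 13, 1), c(7, 14, 1), c(7, 15, 1))
  mol_graph(elements, bonds, name = "toluene-like")
}

# random connected molecule (spanning tree plus optional extra edges) with
# centred random charges; used to exercise the metrics against brute force
random_ensemble <- function(n_atoms, n_sets, extra_edges = 0L) {
  bonds <- cbind(u = vapply(2:n_atoms, function(i) sample.int(i - 1L, 1L),
                            integer(1)),
                 v = 2:n_atoms, order = 1L)
  if (extra_edges > 0L && n_atoms > 3L) {
    for (k in seq_len(extra_edges)) {
      uv <- sort(sample.int(n_atoms, 2L))
      dup <- any(pmin(bonds[, "u"], bonds[, "v"]) == uv[1] &
                 pmax(bonds[, "u"], bonds[, "v"]) == uv[2])
      if (!dup) bonds <- rbind(bonds, c(uv[1], uv[2], 1L))
    }
  }
  mol <- mol_graph(rep("C", n_atoms), bonds, name = "random")
  sets <- lapply(seq_len(n_sets), function(k) {
    q <- stats::rnorm(n_atoms, 0, 0.2)
    charge_set(q - mean(q), mol, conformer_id = sprintf("c%03d", k))
  })
  charge_ensemble(mol, sets)
}

# brute-force oracles: plain loops over all set pairs, independent of the
# per-element range implementation they check
brute_max_atom_range <- function(ens) {
  q <- lapply(ens$sets, function(s) s$charges)
  best <- 0
  for (i in seq_along(q)) for (j in seq_along(q)) {
    if (i < j) best <- max(best, max(abs(q[[i]] - q[[j]])))
  }
  best
}

brute_max_bond_range <- function(ens) {
  b <- ens$molecule$bonds
  q <- lapply(ens$sets, function(s) s$charges)
  best <- 0
  for (i in seq_along(q)) for (j in seq_along(q)) {
    if (i >= j) next
    for (k in seq_len(nrow(b))) {
      d <- (q[[i]][b[k, "u"]] - q[[i]][b[k, "v"]]) -
           (q[[j]][b[k, "u"]] - q[[j]][b[k, "v"]])
      best <- max(best, abs(d))
    }
  }
  best
}

# independent labeled-path enumeration (recursive DFS) for the similarity
# oracle
brute_labeled_paths <- function(mol, max_len = 4L) {
  n <- n_atoms(mol)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (b in seq_len(nrow(mol$bonds))) {
    u <- mol$bonds[b, "u"]; v <- mol$bonds[b, "v"]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  out <- character(0)
  walk <- function(path) {
    if (length(path) > 1L) {
      lab <- paste(mol$elements[path], collapse = "-")
      rl <- paste(mol$elements[rev(path)], collapse = "-")
      out[[length(out) + 1L]] <<- if (lab <= rl) lab else rl
    }
    if (length(path) > max_len) return()
    for (nx in adj[[path[length(path)]]]) {
      if (!nx %in% path) walk(c(path, nx))
    }
  }
  for (v in seq_len(n)) walk(v)
  unique(out)
}

expect_conserved <- function(q, tol = 1e-6) {
  expect_s3_class(q, "charge_set")
  expect_lt(abs(sum(q$charges) - total_formal_charge(q$molecule)), tol)
}

# rigid-body transform of a conformer's coordinates
rotate_translate <- function(conf, angle = 0.7, axis = c(0, 0, 1),
                             shift = c(3, -2, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  conformer(sweep(conf$coords %*% t(R), 2L, -shift), conf$molecule,
            id = paste0(conf$id, "-moved"))
}
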
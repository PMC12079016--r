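#' Parameters of the synthetic charge-generation model
#'
#' The synthetic model is an explicit stand-in for geometry-dependent charge
#' engines, not an emulator of any particular one. Its contract is threefold:
#' (i) a conformer-independent base assignment from electronegativity
#' differences, (ii) a conformer-dependent perturbation driven by close
#' non-bonded contacts with a single amplitude knob `alpha`, and (iii) exact
#' charge conservation throughout. An optional Gaussian jitter of scale `eta`
#' emulates hardware/floating-point variation between platforms.
#'
#' @param kappa charge per unit electronegativity difference (e per Pauling
#'   unit) in the base assignment (default 0.08).
#' @param alpha dimensionless amplitude of the contact-driven conformer
#'   perturbation (default 0.05); 0 gives perfectly conformer-independent
#'   charges.
#' @param lambda_decay decay length (Angstrom) of the contact weight
#'   `exp(-r/lambda)` (default 1.5).
#' @param eta scale (e) of the hardware-style Gaussian jitter (default 0).
#' @param seed integer seed; all randomness in the generator flows through
#'   explicit seeds, never global state.
#' @param chi_table named numeric vector of Pauling electronegativities.
#' @param bond_length_table named numeric vector of equilibrium bond lengths
#'   (Angstrom), keyed by sorted element pair such as `"C-C"`, `"C-H"`.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(kappa = 0.08, alpha = 0.05, lambda_decay = 1.5,
                         eta = 0, seed = 1L,
                         chi_table = c(H = 2.20, C = 2.55, N = 3.04, O = 3.44,
                                       F = 3.98, S = 2.58, Cl = 3.16,
                                       Br = 2.96, I = 2.66),
                         bond_length_table = c(`C-C` = 1.54, `C-H` = 1.09,
                                               `C-O` = 1.43, `H-O` = 0.96,
                                               `C-N` = 1.47, `H-N` = 1.01,
                                               `C-S` = 1.82, `H-S` = 1.34,
                                               `C-F` = 1.35, `C-Cl` = 1.77,
                                               `Br-C` = 1.94, `C-I` = 2.14,
                                               `N-O` = 1.40, `O-O` = 1.48,
                                               `N-N` = 1.45)) {
  stopifnot(alpha >= 0, eta >= 0, lambda_decay > 0, kappa >= 0)
  structure(list(kappa = kappa, alpha = alpha, lambda_decay = lambda_decay,
                 eta = eta, seed = as.integer(seed), chi_table = chi_table,
                 bond_length_table = bond_length_table),
            class = "synth_params")
}

bond_length <- function(el_u, el_v, params) {
  key <- paste(sort(c(el_u, el_v)), collapse = "-")
  len <- params$bond_length_table[key]
  if (is.na(len)) stop(sprintf("no bond length tabulated for %s", key))
  unname(len)
}

# hydrogen-completion targets used by the template grammar
.completion_valence <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1,
                         I = 1)

#' Build a molecule from a chain template
#'
#' The template grammar is `chain(n)` or `chain(n, pos=El, ...)`: a chain of
#' `n` carbons with optional single-bonded heteroatom substituents attached
#' at 1-based chain positions (`pos:El` is also accepted). Hydrogens are
#' added explicitly to complete every valence (C to 4, N to 3, O and S to 2,
#' halogens to 1). Deterministic: the same template always yields the same
#' graph, with heavy atoms first (chain, then substituents in the order
#' written) and hydrogens appended in parent order.
#'
#' @param template template string, e.g. `"chain(3)"`, `"chain(4, 2=O)"`.
#' @param params a [synth_params()] (reserved for future grammar extensions).
#' @return a valid `mol_graph` with explicit hydrogens.
#' @examples
#' make_molecule("chain(3)")           # propane, C3H8
#' make_molecule("chain(2, 2=O)")      # ethanol-like C2H6O
#' @export
make_molecule <- function(template, params = synth_params()) {
  m <- regmatches(template,
                  regexec("^\\s*chain\\(\\s*(\\d+)\\s*(?:,(.*))?\\)\\s*$",
                          template))[[1]]
  if (length(m) == 0L) stop(sprintf("unparseable template: '%s'", template))
  n_chain <- as.integer(m[2])
  if (n_chain < 1L) stop("chain length must be >= 1")
  elements <- rep("C", n_chain)
  bonds <- if (n_chain > 1L)
    cbind(u = seq_len(n_chain - 1L), v = seq.int(2L, n_chain), order = 1L)
  else matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("u", "v", "order")))
  if (!is.na(m[3]) && nzchar(trimws(m[3]))) {
    for (tok in strsplit(m[3], ",")[[1]]) {
      parts <- strsplit(trimws(tok), "[=:]")[[1]]
      if (length(parts) != 2L)
        stop(sprintf("unparseable substituent token: '%s'", tok))
      pos <- as.integer(trimws(parts[1]))
      el <- trimws(gsub("['\"]", "", parts[2]))
      if (is.na(pos) || pos < 1L || pos > n_chain)
        stop(sprintf("substituent position %s outside chain", parts[1]))
      if (!el %in% names(.completion_valence))
        stop(sprintf("unsupported substituent element '%s'", el))
      elements <- c(elements, el)
      bonds <- rbind(bonds, c(pos, length(elements), 1L))
    }
  }
  # complete every heavy valence with explicit hydrogens, in parent order
  n_heavy <- length(elements)
  used <- numeric(n_heavy)
  for (b in seq_len(nrow(bonds))) {
    used[bonds[b, 1L]] <- used[bonds[b, 1L]] + 1
    used[bonds[b, 2L]] <- used[bonds[b, 2L]] + 1
  }
  for (i in seq_len(n_heavy)) {
    need <- .completion_valence[[elements[i]]] - used[i]
    if (need < 0)
      stop(sprintf("template over-saturates atom %d (%s)", i, elements[i]))
    for (h in seq_len(need)) {
      elements <- c(elements, "H")
      bonds <- rbind(bonds, c(i, length(elements), 1L))
    }
  }
  mol <- mol_graph(elements, bonds, name = template)
  bad <- validate_molecule(mol)
  if (length(bad)) stop(paste("template produced invalid molecule:",
                              paste(bad, collapse = "; ")))
  mol
}

.unit <- function(v) v / sqrt(sum(v^2))

# orthonormal vector pair perpendicular to unit axis a (deterministic)
.perp_frame <- function(a) {
  ref <- diag(3)[, which.min(abs(a))]
  b <- .unit(ref - sum(ref * a) * a)
  list(b = b, c = .unit(c(a[2] * b[3] - a[3] * b[2],
                          a[3] * b[1] - a[1] * b[3],
                          a[1] * b[2] - a[2] * b[1])))
}

# one geometry: ideal bond lengths, tetrahedral angles, random azimuths.
# Requires an acyclic, all-single-bond molecule (the template grammar's
# output). phis: one azimuth (radians) per atom, consumed per branching
# center.
build_geometry <- function(mol, phis, params) {
  n <- n_atoms(mol)
  if (nrow(mol$bonds) != n - 1L)
    stop("conformer generation requires an acyclic (tree) molecule")
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    u <- mol$bonds[b, "u"]; v <- mol$bonds[b, "v"]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj <- lapply(adj, sort)
  coords <- matrix(NA_real_, n, 3L)
  parent <- rep(NA_integer_, n)
  coords[1L, ] <- 0
  theta_t <- pi - acos(-1 / 3)        # 180 deg minus tetrahedral angle
  queue <- 1L
  while (length(queue) > 0L) {
    ctr <- queue[1L]; queue <- queue[-1L]
    kids <- setdiff(adj[[ctr]], parent[ctr])
    if (length(kids) == 0L) next
    phi0 <- phis[ctr]
    if (is.na(parent[ctr])) {  # root: first child defines the x axis
      lens <- vapply(kids, function(k)
        bond_length(mol$elements[ctr], mol$elements[k], params), numeric(1))
      coords[kids[1L], ] <- coords[ctr, ] + c(lens[1L], 0, 0)
      if (length(kids) > 1L) {
        fr <- .perp_frame(c(1, 0, 0))
        for (j in seq.int(2L, length(kids))) {
          phi <- phi0 + 2 * pi * (j - 2L) / 3
          dir <- cos(acos(-1 / 3)) * c(1, 0, 0) +
            sin(acos(-1 / 3)) * (cos(phi) * fr$b + sin(phi) * fr$c)
          coords[kids[j], ] <- coords[ctr, ] + lens[j] * dir
        }
      }
    } else {
      a <- .unit(coords[ctr, ] - coords[parent[ctr], ])
      fr <- .perp_frame(a)
      for (j in seq_along(kids)) {
        phi <- phi0 + 2 * pi * (j - 1L) / 3
        dir <- cos(theta_t) * a +
          sin(theta_t) * (cos(phi) * fr$b + sin(phi) * fr$c)
        len <- bond_length(mol$elements[ctr], mol$elements[kids[j]], params)
        coords[kids[j], ] <- coords[ctr, ] + len * dir
      }
    }
    parent[kids] <- ctr
    queue <- c(queue, kids)
  }
  coords
}

#' Sample conformers of a template-derived molecule
#'
#' Generates `n` geometries from idealized internal coordinates: bond lengths
#' from the parameter table, tetrahedral angles everywhere, and an
#' independent uniform random azimuth per branching center -- so every
#' rotatable-bond dihedral is uniform on [0, 2pi). Bonded distances match the
#' table exactly by construction. Deterministic for a given seed.
#'
#' @param mol an acyclic `mol_graph` (as produced by [make_molecule()]).
#' @param n number of conformers (>= 1).
#' @param params a [synth_params()] supplying the bond length table.
#' @param seed integer seed (defaults to `params$seed`).
#' @return list of `n` `conformer` objects with ids `"c001"`, `"c002"`, ...
#' @export
sample_conformers <- function(mol, n, params = synth_params(),
                              seed = params$seed) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  withr::with_seed(seed, {
    lapply(seq_len(n), function(k) {
      phis <- stats::runif(n_atoms(mol), 0, 2 * pi)
      conformer(build_geometry(mol, phis, params), mol,
                id = sprintf("c%03d", k))
    })
  })
}

#' Conformer-independent base charges
#'
#' The graph-only charge assignment
#' `q0(i) = kappa * sum_j (chi(j) - chi(i))` over bonded neighbours j, plus
#' the atom's integer formal charge. Pairwise antisymmetry makes the total
#' charge exactly the molecule's formal charge; the assignment never sees a
#' geometry, mirroring conformer-independent charge models.
#'
#' @param mol a `mol_graph`.
#' @param params a [synth_params()].
#' @return a `charge_set` with method tag `"base"`.
#' @export
base_charges <- function(mol, params = synth_params()) {
  chi <- params$chi_table[mol$elements]
  if (anyNA(chi))
    stop(sprintf("no electronegativity tabulated for element(s): %s",
                 paste(unique(mol$elements[is.na(chi)]), collapse = ", ")))
  q <- numeric(n_atoms(mol))
  for (b in seq_len(nrow(mol$bonds))) {
    u <- mol$bonds[b, "u"]; v <- mol$bonds[b, "v"]
    q[u] <- q[u] + params$kappa * (chi[v] - chi[u])
    q[v] <- q[v] + params$kappa * (chi[u] - chi[v])
  }
  charge_set(q + mol$formal_charges, mol, method = "base")
}

#' Conformer-dependent synthetic charges
#'
#' Perturbs the base charges by antisymmetric pairwise charge transfers
#' between atoms in close non-bonded contact:
#' `q(i) = q0(i) + alpha * sum_j (q0(j) - q0(i)) * exp(-r_ij / lambda)`,
#' the sum running over pairs at topological distance >= 3 (the pairs whose
#' separation actually varies with conformation). Transfers cancel pairwise,
#' so the total charge is conserved exactly; `alpha = 0` reduces to
#' [base_charges()] exactly.
#'
#' @param mol a `mol_graph`.
#' @param conf a `conformer` of `mol`.
#' @param params a [synth_params()].
#' @return a `charge_set` with method tag `"synthetic"` and the conformer's
#'   id in its provenance.
#' @export
conformer_charges <- function(mol, conf, params = synth_params()) {
  stopifnot(inherits(conf, "conformer"))
  if (nrow(conf$coords) != n_atoms(mol))
    stop("conformer is not aligned to the molecule")
  q0 <- base_charges(mol, params)$charges
  q <- q0
  if (params$alpha > 0) {
    mask <- eligible_pairs_mask(mol)
    if (any(mask)) {
      w <- exp(-coord_dist(conf$coords) / params$lambda_decay) * mask
      q <- q0 + params$alpha * (as.vector(w %*% q0) - q0 * rowSums(w))
    }
  }
  charge_set(q, mol, method = "synthetic", conformer_id = conf$id)
}

#' Hardware-style charge jitter
#'
#' Adds mean-centred i.i.d. Gaussian noise of scale `eta` to a charge set,
#' emulating platform/floating-point differences between runs on different
#' hardware. Centring makes the charge sum exactly invariant; `eta = 0`
#' returns the input charges unchanged.
#'
#' @param q a `charge_set`.
#' @param eta noise scale in e (>= 0).
#' @param seed integer seed.
#' @return a `charge_set` with platform tag `"jittered"`; provenance
#'   (method, conformer id) is preserved.
#' @export
hardware_jitter <- function(q, eta, seed) {
  stopifnot(inherits(q, "charge_set"), eta >= 0)
  if (eta == 0) return(q)
  noise <- withr::with_seed(seed, stats::rnorm(length(q$charges), 0, eta))
  noise <- noise - mean(noise)
  charge_set(q$charges + noise, q$molecule, method = q$method,
             conformer_id = q$conformer_id, platform = "jittered")
}

#' Generate a full benchmark ensemble
#'
#' Composes the generator end to end: template to molecule, `n_conformers`
#' random geometries, one conformer-dependent charge set per geometry (with
#' hardware jitter applied when `params$eta > 0`). Provenance (template,
#' alpha, eta, seed) is attached as an attribute of the ensemble.
#'
#' @param template chain template string (see [make_molecule()]).
#' @param n_conformers number of conformers / charge sets (default 50).
#' @param params a [synth_params()]; `params$seed` drives all randomness.
#' @return list with `molecule`, `conformers` (list of `conformer`), and
#'   `ensemble` (a `charge_ensemble`).
#' @export
make_benchmark_ensemble <- function(template, n_conformers = 50L,
                                    params = synth_params()) {
  mol <- make_molecule(template, params)
  confs <- sample_conformers(mol, n_conformers, params)
  sets <- lapply(confs, function(cf) conformer_charges(mol, cf, params))
  if (params$eta > 0) {
    sets <- lapply(seq_along(sets), function(k)
      hardware_jitter(sets[[k]], params$eta, seed = params$seed + 500000L + k))
  }
  ens <- charge_ensemble(mol, sets)
  attr(ens, "provenance") <- list(template = template, alpha = params$alpha,
                                  eta = params$eta, seed = params$seed,
                                  n_conformers = as.integer(n_conformers))
  list(molecule = mol, conformers = confs, ensemble = ens)
}
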
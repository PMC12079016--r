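test_that("chain templates build valid hydrogen-complete molecules", {
  propane <- make_molecule("chain(3)")
  expect_identical(n_atoms(propane), 11L)          # C3H8
  expect_identical(nrow(propane$bonds), 10L)
  expect_identical(validate_molecule(propane), character(0))

  ethanol <- make_molecule("chain(2, 2=O)")        # C2H6O
  expect_identical(n_atoms(ethanol), 9L)
  expect_identical(sum(ethanol$elements == "O"), 1L)
  expect_identical(validate_molecule(ethanol), character(0))

  # colon separator and multiple substituents
  m <- make_molecule("chain(4, 2:O, 3=N)")
  expect_identical(validate_molecule(m), character(0))

  # determinism
  expect_identical(make_molecule("chain(5, 3=O)"), make_molecule("chain(5, 3=O)"))

  expect_error(make_molecule("ring(6)"), "unparseable")
  expect_error(make_molecule("chain(2, 5=O)"), "outside chain")
  expect_error(make_molecule("chain(1, 1=F, 1=Cl, 1=Br, 1=O, 1=N)"),
               "over-saturates")
})

test_that("sampled conformers honor the bond length table and the seed", {
  mol <- make_molecule("chain(4, 2=O)")
  confs <- sample_conformers(mol, 50, seed = 41)
  expect_length(confs, 50L)
  p <- synth_params()
  for (cf in confs[c(1, 25, 50)]) {
    d <- sqrt(rowSums((cf$coords[mol$bonds[, "u"], ] -
                       cf$coords[mol$bonds[, "v"], ])^2))
    want <- vapply(seq_len(nrow(mol$bonds)), function(b)
      chargevar:::bond_length(mol$elements[mol$bonds[b, "u"]],
                              mol$elements[mol$bonds[b, "v"]], p), numeric(1))
    expect_equal(d, want, tolerance = 1e-6)
  }
  again <- sample_conformers(mol, 50, seed = 41)
  expect_identical(lapply(confs, `[[`, "coords"), lapply(again, `[[`, "coords"))
  other <- sample_conformers(mol, 50, seed = 42)
  expect_false(identical(confs[[1]]$coords, other[[1]]$coords))
  expect_error(sample_conformers(mol, 0, seed = 1), ">= 1")
})

test_that("base charges follow electronegativity differences and conserve charge", {
  h2 <- mol_graph(c("H", "H"), cbind(1, 2, 1))
  expect_identical(base_charges(h2)$charges, c(0, 0))

  # hetero diatomic, chi difference 0.5 at kappa 0.1: charges +/- 0.05
  p <- synth_params(kappa = 0.1, chi_table = c(C = 2.0, O = 2.5))
  co <- mol_graph(c("C", "O"), cbind(1, 2, 1))
  expect_equal(base_charges(co, p)$charges, c(0.05, -0.05))

  for (tmpl in c("chain(2)", "chain(4, 2=O)", "chain(6, 3=N, 5=O)")) {
    q0 <- base_charges(make_molecule(tmpl))
    expect_lt(abs(sum(q0$charges)), 1e-12)
  }
  bad <- mol_graph(c("C", "Xx"), cbind(1, 2, 1))
  expect_error(base_charges(bad), "electronegativity")
})

test_that("conformer perturbation is contact-driven, conservative, zero at alpha 0", {
  mol <- make_molecule("chain(4, 2=O)")
  confs <- sample_conformers(mol, 5, seed = 43)
  p0 <- synth_params(alpha = 0)
  q0 <- base_charges(mol, p0)
  for (cf in confs)
    expect_identical(conformer_charges(mol, cf, p0)$charges, q0$charges)

  p <- synth_params(alpha = 0.05)
  for (cf in confs) expect_conserved(conformer_charges(mol, cf, p), tol = 1e-12)

  # a close O...C contact perturbs the involved atoms more than a far one:
  # heavy-atom path C1-C2-C3-O4 bent so that d(C1,O4) is 2.0 vs 4.0 A
  path <- mol_graph(c("C", "C", "C", "O"), cbind(u = 1:3, v = 2:4, order = 1L))
  bend <- function(d14) {
    # place O4 on the circle of radius 1.43 around C3 = (3.08, 0, 0)
    ct <- (3.08^2 + 1.43^2 - d14^2) / (2 * 3.08 * 1.43)
    rbind(c(0, 0, 0), c(1.54, 0, 0), c(3.08, 0, 0),
          c(3.08, 0, 0) + 1.43 * c(-ct, sqrt(1 - ct^2), 0))
  }
  q_close <- conformer_charges(path, conformer(bend(2.0), path), p)
  q_far <- conformer_charges(path, conformer(bend(4.0), path), p)
  qb <- base_charges(path, p)$charges
  dev_close <- abs(q_close$charges - qb)[c(1, 4)]
  dev_far <- abs(q_far$charges - qb)[c(1, 4)]
  expect_true(all(dev_close > dev_far))
})

test_that("hardware jitter is seed-deterministic, centred, and identity at eta 0", {
  mol <- make_molecule("chain(3)")
  q <- base_charges(mol)
  expect_identical(hardware_jitter(q, 0, seed = 1), q)
  j1 <- hardware_jitter(q, 0.002, seed = 5)
  j2 <- hardware_jitter(q, 0.002, seed = 5)
  expect_identical(j1$charges, j2$charges)
  expect_false(identical(j1$charges, q$charges))
  expect_lt(abs(sum(j1$charges) - sum(q$charges)), 1e-12)
  expect_identical(j1$platform, "jittered")

  # matched-set comparison of jittered vs original is of order eta
  bench <- make_benchmark_ensemble("chain(3, 2=O)", 10, synth_params(seed = 44))
  jit <- charge_ensemble(bench$molecule,
                         lapply(seq_len(10), function(k)
                           hardware_jitter(bench$ensemble$sets[[k]], 0.002,
                                           seed = 200 + k)))
  cmp <- compare_matched_sets(bench$ensemble, jit)
  expect_gt(cmp$max, 0.002 * 0.1)
  expect_lt(cmp$max, 0.002 * 10)
})

test_that("benchmark ensembles are deterministic with alpha-monotone variability", {
  p <- synth_params(alpha = 0, eta = 0, seed = 45)
  for (tmpl in c("chain(3)", "chain(4, 2=O)", "chain(5, 3=N)")) {
    rep0 <- variability_report(make_benchmark_ensemble(tmpl, 10, p)$ensemble)
    expect_identical(rep0$max_atom_range, 0)
    expect_identical(rep0$max_bond_range, 0)
  }

  b1 <- make_benchmark_ensemble("chain(4, 2=O)", 8, synth_params(seed = 46))
  b2 <- make_benchmark_ensemble("chain(4, 2=O)", 8, synth_params(seed = 46))
  expect_identical(lapply(b1$ensemble$sets, `[[`, "charges"),
                   lapply(b2$ensemble$sets, `[[`, "charges"))
  expect_identical(attr(b1$ensemble, "provenance"),
                   attr(b2$ensemble, "provenance"))

  # shared-seed alpha grid: both metrics non-decreasing (Spearman rho 1)
  grid <- c(0, 0.01, 0.02, 0.05, 0.1)
  m <- vapply(grid, function(a) {
    ens <- make_benchmark_ensemble("chain(5, 2=O)", 15,
                                   synth_params(alpha = a, seed = 47))$ensemble
    c(max_charge_range(ens), max_bond_delta_range(ens))
  }, numeric(2))
  expect_true(all(diff(m[1, ]) >= 0) && all(diff(m[2, ]) >= 0))
  expect_identical(stats::cor(grid[-1], m[1, -1], method = "spearman"), 1)
})
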
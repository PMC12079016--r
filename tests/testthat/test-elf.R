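test_that("repulsion score sums |q_i||q_j|/r over topologically distant pairs", {
  # 3-atom chain: every pair is 1-2 or 1-3, so nothing is eligible
  chain3 <- mol_graph(rep("C", 3), cbind(u = 1:2, v = 2:3, order = 1L))
  conf3 <- conformer(cbind(c(0, 1.54, 3.08), 0, 0), chain3, check = FALSE)
  q3 <- charge_set(c(0.1, 0, -0.1), chain3)
  expect_identical(intramolecular_repulsion_score(conf3, q3), 0)

  # 4-atom chain: only the 1-4 pair is eligible; place it at exactly 2.0 A
  chain4 <- mol_graph(rep("C", 4), cbind(u = 1:3, v = 2:4, order = 1L))
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.5, 1, 0), c(2, 0, 0))
  conf4 <- conformer(coords, chain4)
  q4 <- charge_set(c(0.5, 0, 0, -0.5), chain4)
  expect_equal(intramolecular_repulsion_score(conf4, q4), 0.5 * 0.5 / 2.0)

  # 1/r homogeneity: doubling all coordinates halves the score
  conf4x2 <- conformer(2 * coords, chain4, check = FALSE)
  expect_equal(intramolecular_repulsion_score(conf4x2, q4),
               intramolecular_repulsion_score(conf4, q4) / 2)

  # the distance floor caps pathological close contacts
  near <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0.05, 0.05, 0))
  conf_near <- conformer(near, chain4, check = FALSE)
  expect_equal(intramolecular_repulsion_score(conf_near, q4), 0.25 / 0.5)
})

test_that("Kabsch RMSD is rigid-motion invariant with a collinear closed form", {
  bench <- make_benchmark_ensemble("chain(4, 2=O)", 2, synth_params(seed = 31))
  c1 <- bench$conformers[[1]]
  expect_lt(kabsch_rmsd(c1, c1), 1e-12)
  moved <- rotate_translate(c1, angle = 1.1, axis = c(1, 2, 3))
  expect_lt(kabsch_rmsd(c1, moved), 1e-9)
  expect_equal(kabsch_rmsd(c1, bench$conformers[[2]]),
               kabsch_rmsd(bench$conformers[[2]], c1))

  # centred collinear 2-point case: lengths 1 and 2 A give RMSD 0.5 A
  duo <- mol_graph(c("C", "C"), cbind(1, 2, 1))
  a <- conformer(rbind(c(0, 0, 0), c(1, 0, 0)), duo)
  b <- conformer(rbind(c(0, 0, 0), c(2, 0, 0)), duo)
  expect_equal(kabsch_rmsd(a, b), 0.5)
})

test_that("Kabsch RMSD matches an independent superposition implementation", {
  skip_if_not_installed("bio3d")
  bench <- make_benchmark_ensemble("chain(5, 3=O)", 4, synth_params(seed = 32))
  for (pair in list(c(1, 2), c(2, 3), c(1, 4))) {
    A <- bench$conformers[[pair[1]]]$coords
    B <- bench$conformers[[pair[2]]]$coords
    ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
    # bio3d reports the fitted RMSD rounded to three decimals
    expect_equal(kabsch_rmsd(bench$conformers[[pair[1]]],
                             bench$conformers[[pair[2]]]),
                 ref, tolerance = 1e-3)
  }
})

test_that("greedy max-min subset is deterministic with stated tie-breaks", {
  bench <- make_benchmark_ensemble("chain(4)", 6, synth_params(seed = 33))
  confs <- bench$conformers
  # k = count returns every index
  expect_setequal(greedy_diverse_subset(confs, 6, seed_index = 2), 1:6)
  expect_error(greedy_diverse_subset(confs, 7, 1), "exceeds")

  # all-identical conformers: seed first, then ascending indices
  same <- lapply(1:5, function(k) confs[[1]])
  expect_identical(greedy_diverse_subset(same, 4, seed_index = 3),
                   c(3L, 1L, 2L, 4L))

  # three geometries at increasing RMSD from the seed: picks the farthest
  duo <- mol_graph(c("C", "C"), cbind(1, 2, 1))
  g <- lapply(c(1.0, 1.5, 2.4), function(len)
    conformer(rbind(c(0, 0, 0), c(len, 0, 0)), duo, id = sprintf("%f", len)))
  expect_identical(greedy_diverse_subset(g, 2, seed_index = 1), c(1L, 3L))
})

test_that("ELF selection keeps the low-repulsion pool and shuns bad conformers", {
  p <- synth_params(seed = 34, alpha = 0.05)
  bench <- make_benchmark_ensemble("chain(5, 2=O)", 40, p)
  cfg <- elf_config(min_conformers = 40)  # desk-scale: no sub-500 warning
  sel <- elf_select(bench$conformers, bench$ensemble$sets, cfg)
  expect_length(sel, 10L)
  # pool of ceil(0.02*40)=1 is enlarged to n_select=10: selection must be
  # exactly the 10 lowest-scoring conformers
  scores <- mapply(intramolecular_repulsion_score, bench$conformers,
                   bench$ensemble$sets, MoreArgs = list(cfg = cfg))
  expect_setequal(sel, order(scores, seq_along(scores))[1:10])
  # seed of the greedy pass is the overall lowest-scoring conformer
  expect_identical(sel[1], which.min(scores))

  expect_warning(elf_select(bench$conformers, bench$ensemble$sets, elf_config()),
                 "recommended")
  expect_error(elf_select(bench$conformers[1:9], bench$ensemble$sets[1:9],
                          elf_config(min_conformers = 9)), "at least 10")

  # a conformer given an artificially strong close contact is never selected
  chain4 <- mol_graph(rep("C", 4), cbind(u = 1:3, v = 2:4, order = 1L))
  confs <- sample_conformers(chain4, 30, seed = 35)
  q <- charge_set(c(0.5, -0.1, -0.1, -0.3), chain4)
  sets <- rep(list(q), 30)
  bad_coords <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(1.4, 1.4, 0),
                      c(0.4, 0.3, 0))  # 1-4 contact at ~0.5 A
  confs[[17]] <- conformer(bad_coords, chain4, id = "bad")
  sel2 <- elf_select(confs, sets, elf_config(min_conformers = 30, n_select = 5))
  expect_false(17L %in% sel2)
})

test_that("ELF selection is invariant (up to relabeling) under input order", {
  p <- synth_params(seed = 36)
  bench <- make_benchmark_ensemble("chain(4, 2=O)", 25, p)
  cfg <- elf_config(min_conformers = 25, n_select = 5)
  sel <- elf_select(bench$conformers, bench$ensemble$sets, cfg)
  perm <- withr::with_seed(1, sample(25))
  sel_p <- elf_select(bench$conformers[perm], bench$ensemble$sets[perm], cfg)
  expect_setequal(vapply(bench$conformers[sel], function(cf) cf$id, ""),
                  vapply(bench$conformers[perm][sel_p], function(cf) cf$id, ""))
})

test_that("consensus charges are the atom-wise mean with exact conservation", {
  mol <- make_molecule("chain(2)")
  confs <- sample_conformers(mol, 2, seed = 37)
  n <- n_atoms(mol)
  qa <- charge_set(c(0.1, -0.1, rep(0, n - 2)), mol, conformer_id = "c001")
  qb <- charge_set(c(0.3, -0.3, rep(0, n - 2)), mol, conformer_id = "c002")
  cons <- elf_consensus_charges(confs, list(qa, qb),
                                elf_config(n_select = 2, min_conformers = 2))
  expect_equal(cons$charges[1:2], c(0.2, -0.2))
  expect_identical(cons$method, "elf-consensus")
  expect_match(cons$conformer_id, "c001")
  expect_conserved(cons, tol = 1e-9)

  # mean of identical sets is that set
  cons2 <- elf_consensus_charges(confs, list(qa, qa),
                                 elf_config(n_select = 2, min_conformers = 2))
  expect_identical(cons2$charges, qa$charges)
})
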
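---
title: "Quantifying conformer-dependent partial charge variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformer-dependent partial charge variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargevar)
```

## The problem

Fixed-charge force fields assign each atom of a small molecule a static
partial charge $q(u)$ (in units of the elementary charge e). Geometry-based
charge models -- semi-empirical population analyses with bond-charge
corrections being the canonical example -- derive those charges from one
input conformer. Conformers in which polar atoms sit close together (a
hydroxyl hydrogen folded back onto an ether oxygen, say) polarize the
electronic structure differently from extended conformers, so the *same
molecule* can receive meaningfully different charge sets depending on which
geometry was fed to the engine; numerical details of the implementation can
add a smaller platform-dependent component on top. Downstream quantities
computed from those charges -- hydration and binding free energies in
particular -- inherit this variability, which undermines reproducibility.

`chargevar` implements the analysis layer of this problem: given an
*ensemble* of atom-aligned charge sets $\{q_1, \dots, q_K\}$ for a molecule,
it quantifies the variability, mitigates it by multi-conformer consensus
charging, selects representative or extreme molecules for follow-up study,
and truncates molecules to cheaper analogues. A synthetic charge generator
with known ground truth stands in for the (heavy, partly proprietary)
quantum-chemical engines, so the entire pipeline is testable end to end.

## Data model

A `mol_graph` holds elements, integer formal charges and an explicit bond
list; hydrogens are explicit atoms because valence completion and
truncation need them. Atom ordering is the *only* alignment mechanism:
conformers (`conformer`, coordinates in Å) and charge sets (`charge_set`)
are valid only against the molecule's atom order, and no atom-mapping
inference is ever attempted. A `charge_set` must satisfy the conservation
invariant $|\sum_u q(u) - Q_{\mathrm{formal}}| \le 10^{-6}$ e at
construction time, so a violated invariant is caught at the operation that
introduced it, not three stages later. A `charge_ensemble` is two or more
aligned charge sets for one molecule.

## Variability metrics

Two molecule-level metrics summarize an ensemble.

**Maximal partial charge difference.** For each atom $u$, the range
$\max_k q_k(u) - \min_k q_k(u)$ across the ensemble; the metric is the
largest per-atom range. For two sets it reduces to
$\max_u |q_1(u) - q_2(u)|$, and for any ensemble it equals the maximum of
that pairwise quantity over all set pairs -- an identity the test suite
checks against an exhaustive all-pairs oracle.

**Maximal $\Delta q_\mathrm{bond}$ difference.** For a charge set, the bond
charge difference $\Delta q_\mathrm{bond}(u,v) = q(u) - q(v)$ is a proxy
for bond polarity. Across sets we take, per bond, the range of
$\Delta q_\mathrm{bond}$, and report the largest such range. We define the
two-set comparison as
$\max_{(u,v)} |(q_1(u)-q_1(v)) - (q_2(u)-q_2(v))|$ -- the difference *of*
the bond differences -- which is the only reading under which identical
sets give zero; it is bounded by twice the atom metric (triangle
inequality), a bound that is attainable and attained in the tests.

The sign convention for $\Delta q_\mathrm{bond}$ (first-stored atom minus
second) is fixed by bond storage order; every reported metric is a range or
absolute value, so the convention is observationally irrelevant.

`compare_matched_sets()` supports the platform-comparison design: two
ensembles whose $k$-th sets derive from the *same* conformer are compared
pair by pair, isolating hardware/numerics effects from conformer effects.

```{r metrics-example}
bench <- make_benchmark_ensemble("chain(5, 2=O)", n_conformers = 50,
                                 synth_params(seed = 1))
variability_report(bench$ensemble)
```

## ELF-style consensus charging

The consensus procedure follows the electrostatically-least-interacting
(ELF) recipe: score each conformer by the internal electrostatic repulsion
it would have if **all charges were made positive**,

$$S(\mathrm{conf}) = \sum_{(i,j)\ \mathrm{eligible}} \frac{|q_i|\,|q_j|}{\max(r_{ij}, r_\mathrm{floor})},$$

keep the top 2% least-interacting conformers (the pool is enlarged to 10
when 2% of the input is smaller), pick 10 mutually diverse conformers from
that pool, and average their charge sets atom-wise. Averaging preserves the
total charge exactly and damps the conformer-dependent component, because
the low-score pool is precisely the set of geometries without the close
contacts that drive charge perturbations. The recommended input is 500
conformers; smaller inputs warn rather than fail so that desk-scale
studies remain possible, and the pipeline records such warnings in its
manifest.

Three details of the published recipe are not public, so this package makes
deterministic, documented choices:

* **Diversity criterion** -- greedy max–min selection under heavy-atom
  Kabsch RMSD, seeded at the lowest-scoring conformer, ties broken by
  lowest index. Deterministic and standard.
* **Charge source for scoring** -- each conformer's own charge set,
  absolute-valued, which keeps the module agnostic to the charging engine.
* **Pair eligibility** -- pairs at topological distance $\ge 3$ (1-2 bonded
  and 1-3 angle pairs are excluded: their distances are fixed by covalent
  geometry and carry no conformational signal). Whether the reference
  implementation uses a distance-dependent dielectric or different
  exclusions is unknowable; this scoring is a stand-in with the same
  qualitative behaviour.

The `distance_floor` (0.5 Å) caps the $1/r$ singularity for pathological
geometries.

## The synthetic charge generator

The generator is *not* an emulator of any quantum-chemical method. Its
contract is exactly the statistical structure the analysis assumes:

1. a conformer-independent base assignment
   $q_0(i) = \kappa \sum_{j \sim i} (\chi_j - \chi_i)$ from Pauling
   electronegativities ($\kappa = 0.08$ e per Pauling unit), plus the
   atom's formal charge — pairwise antisymmetric, hence exactly
   charge-conserving, and the $\alpha = 0$ limit doubles as a model of
   graph-only (conformer-independent) charge methods;
2. a contact-driven conformer-dependent perturbation
   $q(i) = q_0(i) + \alpha \sum_j (q_0(j) - q_0(i))\,
   e^{-r_{ij}/\lambda}$ over pairs at topological distance $\ge 3$, with
   a single amplitude knob $\alpha$ (default 0.05, dimensionless) and decay
   length $\lambda = 1.5$ Å — antisymmetric transfers, so conservation is
   exact for every conformer;
3. an optional hardware-style jitter: mean-centred i.i.d. Gaussian noise of
   scale $\eta$ e (default 0), seed-deterministic, emulating
   platform/floating-point variation at fixed conformer.

Molecules come from a chain template grammar (`chain(n, pos=El, ...)`):
carbon chains with single-bonded N/O/S/halogen substituents and explicit
hydrogens completing every valence. Conformers are built from idealized
internal coordinates — tabulated bond lengths, tetrahedral angles, and an
independent uniform random azimuth at every branching centre, so all
rotatable-bond dihedrals are uniform. This deliberately ignores ring
systems, conjugation, sterics and energy minimization: only *relative
contact distances* matter downstream, and those the generator varies
exactly the way the analysis assumes real conformer ensembles do.

What passing tests on this generator do show: the metrics, consensus,
selection and truncation machinery are correct on data with known ground
truth, including the qualitative pattern that consensus charging reduces
across-run dispersion. What they do not show: anything about the magnitude
or chemistry of variability in real charge engines, which depends on
electronic-structure effects the stand-in does not model.

All randomness flows through explicit integer seeds (`withr::with_seed`);
there is no hidden global state, which is what makes the whole pipeline a
pure function of (config, seed).

## Molecule selection

**Stratified selection** mirrors the good/average/bad design: from the
sample mean $\bar x$ and standard deviation $\sigma$ (the $n-1$ estimator;
the choice is a documented convention) of the per-molecule metric values,
molecules are drawn from the closed windows
$[\bar x - 1.8\sigma,\ \bar x - 1.0\sigma]$ (good, little variability),
$[\bar x - 0.4\sigma,\ \bar x + 0.4\sigma]$ (average) and
$[\bar x + 1.0\sigma,\ \bar x + 1.8\sigma]$ (bad). Within a window we take
the $n$ values closest to the window midpoint (ties to the lower id) --
the published design does not say how eligible candidates were chosen, so
this package uses a deterministic rule. A value on a window edge belongs to
the window (closed intervals, overlap resolved toward the more extreme
stratum), and $\sigma = 0$ raises an explicit error rather than silently
declaring everything average.

**Ranked selection** orders molecules by maximal
$\Delta q_\mathrm{bond}$ difference, restricts to a top pool (default 25),
and greedily accepts candidates whose structural similarity to all
already-accepted molecules is below `tau` (default 0.6) -- a deterministic
stand-in for the manual "avoid near-duplicates" screen, returning up to
`k` (default 12) molecules. Similarity is a Tanimoto coefficient over
element-labeled simple paths of 1–4 bonds, canonicalized against reversal:
crude as chemical fingerprints go, but dependency-free, symmetric and
exactly reproducible.

## Truncation

`truncate_at_bond()` cuts one **single, acyclic** bond, keeps the fragment
containing the requested atom, and caps the open valence with a hydrogen;
ring bonds and multiple bonds error out. Retained atoms keep their order
(the capping H is appended), so downstream alignment survives the cut.
When a conformer is supplied the cap is placed along the former bond
vector at the tabulated X–H length; by default downstream geometries are
simply regenerated, which matches how truncation is used here (graphs are
truncated before conformer generation).

## Numerical choices and degenerate inputs

* Charge conservation is checked at 1e-6 e on construction, 1e-9 e for
  consensus and jitter outputs (pure means and centred noise), and at the
  quantization bound $n \cdot 5\times10^{-7}$ e when reading charges
  stored at 6 decimal places in SDF data fields.
* The ensemble metrics are computed per-element in $O(nK)$; the
  mathematically identical all-pairs form is retained in the tests as an
  oracle, not in the implementation.
* Kabsch superposition uses the SVD with the usual determinant correction,
  so reflections are never counted as rotations; ties in the greedy
  diversity pass and in every sort go to the lowest index, making all
  selections order-independent.
* SDF records are V2000 with charges in a `PARTIAL_CHARGES` data field
  (a per-atom-line `atom.dprop.PartialCharge` field is also read);
  malformed counts lines and charge-count mismatches are rejected, never
  repaired. Writers are byte-deterministic.
* Indices are 1-based in the R API and 0-based in all emitted files and
  CLI arguments; SDF bond blocks keep their native 1-based convention
  internally.
* Conformer construction requires acyclic molecules (the template
  grammar's output); bonded distances outside 0.7–2.5 Å are rejected at
  `conformer()` construction.

## Problem sizes

The shipped tests and the acceptance script run at desk scale on one CPU:
200 random ensembles up to 50 sets × 60 atoms for the metric/oracle
equivalence; a 10-template study population at 50 conformers per molecule;
20 independently seeded batches of 100 conformers per molecule for the
consensus-dispersion comparison (the sub-500 warning is recorded by
design); a 500-draw Gaussian sample for stratification. These sizes are the
package's choice of a thorough-but-quick default study and complete in a
few minutes.

## Known limitations

* The synthetic model's variability magnitudes are set by $\alpha$ and
  $\kappa$, not by chemistry; absolute numbers from it are not comparable
  to any real charge engine.
* The similarity fingerprint ignores bond orders and stereochemistry; two
  molecules differing only in a double-bond position can look identical.
* No aromaticity perception, tautomers, or protonation-state handling;
  formal charges are caller-supplied integers.
* Free-energy estimation is entirely out of scope: the package prepares
  and analyses charge ensembles, it does not simulate.
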
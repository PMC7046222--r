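---
title: "Geometric-constraint folding of sphere chains and protein residue networks"
author: "geofold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric-constraint folding of sphere chains and protein residue networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geofold)
```

## The model

`geofold` simulates a deliberately minimal picture of protein folding: a
protein is a chain of `N` near-identical units (one sphere per amino acid,
unit diameter and unit bond length) and the only physics retained is
geometry — units cannot overlap, and units that have come into contact stay
in contact. Folding proceeds by sequentially picking a random pair of
not-yet-linked spheres and attempting to join them; the attempt succeeds if
a configuration exists, reachable by continuous motion, in which the pair
touches while all previously formed links remain at contact distance and no
two spheres interpenetrate. The process stops when every remaining pair is
either linked or geometrically incapable of linking. The final adjacency
matrix (backbone plus formed links) is the model aggregate's contact
network.

The empirical counterpart is the protein residue network (PRN): one node
per residue at its Cα position and an edge whenever two Cα atoms lie within
a cutoff `d_c`. The package ships the conventional cutoff `d_c = 6.5` Å
(calibrated so that PRN mean degrees match large simulated aggregates;
sensible values span 4–8 Å) and the reference mean link length
`d_mean = 5.066` Å, which converts model units to Ångström when the two
ensembles are compared. Observables on both sides are identical: degree
statistics, graph diameter `D`, radius of gyration
`R_g = sqrt(mean(|x_i - x̄|²))`, and the spectrum of the combinatorial graph
Laplacian `L = diag(k) − A`.

Two scaling analyses connect them: the shifted power law `(D + 1) ~ N^ν`
(the `+1` keeps the two-sphere chain, with `D = 1`, on the law) and the
linear relation between `D + 1` and `R_g`. Reference exponents are shipped
for orientation: space-filling growth gives `ν_SF = 1/3`, a self-avoiding
random walk `ν_RW = 3/5`; compact model aggregates land slightly above
`1/3`, and the reference constants `nu_sim = 0.345` and
`slope_sim = 0.777 Å⁻¹` (together with their experimental PRN counterparts
`nu_exp = 0.374`, `slope_exp = 0.942 Å⁻¹`, which would require the external
1122-protein ensemble to recompute) are available from
`reference_constants()`.

## The joining dynamics

How spheres are "moved together" is not part of the model's contract — any
dynamics that keeps links at contact (within `tol_bond`, default 1e-2
relative), respects volume exclusion (within `tol_overlap`, default 1e-3
relative) and joins a pair only when its gap falls below `tol_contact`
(default 1e-2 relative) realizes the same process. The helper forces are
explicitly not physical. `geofold` implements the attempt as a small
soft-sphere relaxation:

* a constant helper pull acts on the selected pair;
* every formed link is a stiff harmonic spring at its contact length
  (stiffness 600 in model units), every overlapping non-bonded pair feels a
  one-sided harmonic repulsion (stiffness 300);
* the over-damped motion is integrated with FIRE (fast inertial
  relaxation), whose adaptive time step (cap 0.014) and inertia let the
  pulled spheres roll around obstacles instead of halting at the first
  dead end; per-bead speed is capped at 0.15 so collision transients stay
  an order of magnitude below the invariant tolerances.

Every 24 integrator iterations the run records one *accepted dynamics
step*: overlapping pairs are projected back to exact contact, link
lengths that a collision spike has pushed past half their tolerance are
projected back (the bulk of the load-bearing elastic strain sits well
inside that band and is left alone), the invariants are optionally
audited (`check_every_step = TRUE`), and the stall rule is applied. An
attempt fails when the pair distance has not decreased by `stall_eps`
(default 0.05) within `stall_window` accepted steps (default 5), when six
steps pass without any approach at all, or when the step budget
`max(6N, 150)` is exhausted. Failures are rolled back completely, so a
failed attempt leaves no trace in the configuration. After a success the
springs are quenched with the pull switched off and the new state is
projected onto the constraint set, so accepted aggregates carry no
elastic load.

Three refinements keep the process honest across chain lengths. First,
the collective drag of a long pull moves at a speed inversely
proportional to the number of dragged spheres; sustained coherent motion
is therefore renormalized to a fixed reference speed, without which
global folds stall on long chains and the aggregates grow elongated
instead of globular. Second, while fewer than five links have formed the
chain is still nearly straight and closes through slowly buckling hinge
modes; those early attempts get a much longer stall horizon and step
budget. Third, flat and collinear configurations are saddle points of the
pull — the closing mode carries no force at the saddle and the pair
distance changes only quadratically in the mode amplitude — so each
attempt starts with a tiny seeded positional kick of the pulled pair, and
the FIRE brake damps velocities only partially so the slowly amplifying
saddle-escape motion survives the in-plane force oscillations.

Because bonded pairs are actively held at contact by their bond
constraint, the excluded-volume audit applies the bond tolerance to them
and the (tighter) overlap tolerance to all other pairs; a transiently
compressed link is a bond-constraint matter, not an exclusion violation.

Two further details: the initial chain is exactly collinear, where every
helper force points along the chain axis and nothing can fold, so
`run_folding()` applies a tiny seeded jitter (amplitude 0.05, well below
any contact scale) and lets the springs settle it before starting; and a
finished aggregate is settled one-sidedly — every compressed pair is
pushed back to contact while links may keep a stretch within half their
tolerance, because over-braced contact networks are frustrated and
insisting on exact lengths everywhere would fight that frustration
forever without changing any topology.

## Termination and the rigidity certificate

"Until all pairs are either connected or geometrically incapable of
connecting" is operationalized with a retry set: failed pairs are marked,
any success clears all marks (geometry has changed, earlier failures may
now be feasible), and the run ends when every unlinked pair is marked. For
chains of a few hundred spheres the endgame would dominate the cost — the
last marks cover `O(N²)` pairs — so the run also maintains a first-order
rigidity certificate: when the rank of the rigidity matrix of the bond
framework reaches `3N − 6`, no continuous motion can change any pair
distance, so every unlinked pair whose gap exceeds its contact tolerance
is provably incapable of connecting. Near pairs (gap below 10% of the
contact distance) still get a dynamics attempt, because the certificate is
first-order and tolerance slack could in principle admit them. The
certificate is evaluated with a singular-value threshold that counts
near-flexes as flexes, i.e. it errs toward continuing the simulation.

## What the generator emulates — and what it does not

The simulator reproduces the study conditions of the reference analysis:
homogeneous unit spheres (heterogeneity `a` draws diameters uniformly from
`[1 − a, 1 + a]`; the scaling relations are insensitive to `a` apart from
increased variance), chains from `N = 3` to a few hundred, and ensembles
of independent seeded realizations. Real proteins differ in ways the model
deliberately ignores: no amino-acid identities, no secondary structure, no
solvent or thermodynamic fluctuations, and links never break. Model
aggregates therefore fold *maximally* — they trace the dense lower
envelope of real protein diameters rather than their mean, their mean
degree saturates near 6.8 where the PRN cutoff was calibrated, and
passing tests on synthetic aggregates says nothing about how real residue
networks deviate from that envelope.

Small aggregates have exact combinatorial answers which the test suite
pins down: `N = 3` always folds to the triangle, `N = 4` to the complete
contact network of the tetrahedron, and `N = 5` can never reach all ten
contacts (no five equal mutually tangent spheres exist in 3D); from about
`N = 5` on, final bond counts sit at the generic rigidity bound `3N − 6`
plus whatever zero-motion contacts the final sweep picks up.

## Numerical choices

* **Tolerances.** `tol_contact = 1e-2`, `tol_overlap = 1e-3`,
  `tol_bond = 1e-2` (all relative to the pair's contact distance); the
  interior projection works two orders below the tightest of these. They
  are small enough that no contact topology on the tested fixtures depends
  on them.
* **Stall rule.** The dynamics cannot decide "geometrically incapable";
  a progress budget is the standard surrogate. The defaults (0.05 model
  units of approach within 5 accepted steps) are calibrated to the cruise
  speed of an unobstructed pull (~0.1 per step) so that genuinely moving
  attempts never trip it, while blocked pairs fail within ~120 integrator
  iterations.
* **Determinism.** Each run consumes one Mersenne–Twister stream seeded
  from `folding_params(seed=)`: radii, the symmetry-breaking jitter and
  all pair picks. `run_ensemble()` derives per-run seeds from the base
  seed by a fixed linear-congruential step, so tables are reproducible
  row by row.
* **Degenerate inputs.** `N = 2` returns the single-bond chain without
  attempts; exactly coincident points in the projection are separated
  along a fixed axis; disconnected networks make `graph_diameter()` fail
  loudly with the component count rather than returning infinity.
* **Laplacian conventions.** `L = diag(k) − A`, all `N` eigenvalues enter
  pooled histograms, and the quantity tracked for saturation is literally
  the second-largest eigenvalue (descending rank 2). The smallest nonzero
  eigenvalue — the Fiedler value, which governs the slowest relaxation
  mode — is a different number for a Laplacian and is exposed separately;
  conflating the two is a common source of confusion, so both are
  reported.
* **Histogram peaks.** Fixed-width bins `[k·w, (k+1)·w)` with `w = 0.5`
  by default; ties go to the smaller eigenvalue; no de-duplication of
  degenerate eigenvalues.
* **Fits.** `fit_power_law()` is ordinary least squares on logs, with the
  exponent's standard error from the residuals. Diameters are averaged
  across realizations per chain length before fitting; fitting per-run
  values instead is available (`average_first = FALSE`) and changes the
  uncertainty, not the exponent. The diameter–extent relation fits
  `D + 1` against `R_g` for consistency with the shifted power law; using
  `D` instead shifts the intercept and leaves the slope within its
  standard error on the tested ensembles.

## Problem sizes

The package's own checks run on deliberately modest ensembles chosen to
exercise every code path at desk scale: the scaling ensemble uses 12
log-spaced chain lengths between 3 and 100 with 5 realizations each, and
the saturation and pooled-spectrum checks use six runs with lengths
between 110 and 160, where the mean-degree curve has essentially
flattened. These reproduce the
reference values within the wider tolerances quoted for reduced
ensembles; tightening toward the reference figures (30 realizations, 48
lengths up to 398) is a matter of compute, not of code.

## Known limitations

* The joining dynamics is one concrete realization of the model's
  contract. Final contact counts at small `N` are exact, but the
  approach to the mean-degree saturation, and with it the fitted scaling
  exponent, carries a mild dependence on the stall thresholds: a more
  patient dynamics packs slightly denser. The defaults were chosen for
  realism-per-compute, not as the unique correct setting.
* The rigidity certificate is numerical (SVD rank with a conservative
  threshold). A pathologically near-singular framework would only make
  the run slower, never terminate it early.
* PRN construction assumes standard PDB Cα records; exotic files
  (insertion-code-heavy, zero-occupancy alternates) follow
  `bio3d::read.pdb`'s interpretation.
* The experimental reference constants (`nu_exp`, `slope_exp`, `d_mean`)
  are documented values of the external 1122-protein ensemble, not
  quantities this package can recompute.

## A worked example

```{r example, eval = FALSE}
run <- run_folding(60, folding_params(seed = 1))
run
average_degree(run$network)
graph_diameter(run$network)

tab <- run_ensemble(log_spaced_lengths(3, 100, 8), reps = 3,
                    params = folding_params(seed = 1))
fit_diameter_scaling(tab)

pdb <- generate_toy_pdb("helix-like", n = 40, spacing = 3.8)
net <- build_prn(read_calpha(pdb))
degree_distribution(net)
```
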
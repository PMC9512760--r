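---
title: "Flexible-receptor covalent docking with covflex: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible-receptor covalent docking with covflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covflex)
```

## The problem

Covalent inhibitors of KRAS G12C bind in the switch-II pocket, a shallow
allosteric site whose walls — the switch-II loop, the alpha-2 helix and
several long side chains such as His95, Tyr64, Arg68 and Met72 — adopt
markedly different conformations depending on which ligand is bound.
Docking a new ligand into a crystal structure solved with a *different*
ligand (cross-docking) therefore often fails for a purely rigid receptor:
a side chain frozen in its cognate conformation physically occludes the
volume the new ligand needs.

covflex implements an open, desk-scale version of a flexible-receptor
covalent docking workflow built around two ideas:

1. **Blocking-residue masking.** Binding-site residues whose side chains
   can sterically occlude non-cognate ligands ("blocking residues") are
   temporarily mutated to alanine before pose enumeration, and restored
   to their true identities afterwards.
2. **Side-chain repacking.** After restoration, the side chains of all
   *flexible* binding-site residues are repacked from a rotamer library
   around each candidate pose and the pose is refined, so the receptor
   adapts to the ligand rather than vetoing it.

The package also provides the supporting protocol pieces: ensemble
chi-angle profiling to *derive* the flexible/blocking lists, a
cross-docking benchmark harness with symmetry-corrected RMSD, glycine
loop-mutant receptor preparation for downstream free-energy engines, and
a synthetic mini-pocket generator that makes the whole pipeline testable
without any external structures.

## Covalent pose enumeration

Docking is anchor-first. The reactive cysteine's chi1 is enumerated over
the three canonical staggered rotamers (-60, 180, +60 degrees), placing
SG from the backbone. The warhead carbon (the acrylamide beta-carbon
after Michael addition) is then positioned at the target adduct
geometry:

* S-C bond length 1.81 A (tolerance 0.3 A),
* CB-SG-C angle 100 degrees (tolerance 20 degrees),
* anti to CA about the CB-SG axis.

These thioether-geometry targets are configurable through
`warhead_spec()`; the same contract defines the hard geometry filter —
every emitted pose must satisfy it, and the supplied bond-order changes
(acrylamide C=C reduced to C-C) are applied before torsion analysis.
The remaining ligand degrees of freedom are enumerated on a grid:
rotation about the nascent S-C bond, rotation about the reactive
carbon's single bond when the warhead carbon carries no explicit
hydrogens (the "twist"), and every rotatable internal torsion. The
default grid step is 120 degrees, i.e. the staggered values; this keeps
the candidate count for a 3-torsion ligand below a thousand while
guaranteeing that staggered conformers are represented exactly. A
rotatable torsion is a single, acyclic bond with heavy-atom neighbours
on both sides.

Candidates clashing with the *non-flexible* part of the receptor (any
heavy-atom pair closer than 0.7 of the summed van der Waals radii) are
discarded. Flexible side chains are excluded from this hard filter in
flexible mode because repacking may move them; in rigid mode (the
conventional covalent-docking baseline) they are included and nothing is
repacked, which is exactly what makes blocked pockets fail there.

## The scoring surrogate

The commercial energy models used by the original workflow are not
reproducible, so covflex ships its own deliberately transparent pairwise
score (`score_params()`); lower is better:

* **repulsion** — squared overlap beyond the clash onset
  (`clash_onset_fraction` = 0.7 of summed vdW radii), weight 10;
* **attraction** — a capped linear well between the onset and 4.5 A,
  with a per-atom saturation cap (`attr_atom_cap` = 3): burying an atom
  against many wall atoms stops paying beyond the cap, which prevents
  promiscuous wall-hugging decoys from outranking specifically anchored
  poses, weight 0.25;
* **hydrogen bonds** — -1 per donor/acceptor pair within 2.5-3.5 A with
  an antecedent-donor-acceptor angle above 120 degrees, weight 1.5;
* **torsion strain** — squared deviation of each rotatable torsion from
  the nearest staggered value, weight 0.5.

All weights and geometric windows are config-exposed. The score is
purely pairwise and deterministic; `score_pose()` reports the term
breakdown, and the total is exactly the weighted sum of the terms.

## Repacking and refinement

`repack_site()` performs combinatorial rotamer optimization over the
flexible residues (the reactive cysteine is held fixed by the covalent
bond) against the energy above, evaluated among {flexible side chains,
ligand, rigid context}. Self and pairwise rotamer energies are
precomputed, after which the search runs multi-start greedy descent
followed by Metropolis sweeps at kT = 1 (defaults: 2 starts, 40 sweeps).
These defaults were chosen for the instance sizes this package targets —
at most a handful of flexible residues with at most nine rotamers each —
where they reliably reach the exhaustive global optimum (the test suite
verifies a >= 94% hit rate against full enumeration on 50 instances);
larger user systems can raise `n_starts`/`n_sweeps`.

Two departures from heavier production repackers are deliberate:

* a compact backbone-independent rotamer library (canonical staggered
  combinations, 3-9 rotamers per type, mildly non-uniform priors) ships
  with the package, with `load_rotamer_library()` as the hook for a
  richer user-supplied one;
* a flat **rotamer-shift prior** (`shift_penalty` = 1 energy unit) is
  charged for moving a residue off its input rotamer. It is negligible
  against a real steric clash (tens of units) but suppresses gratuitous
  induced fit, which otherwise lets every decoy buy itself a custom
  pocket.

Continuous refinement then runs a cyclic bounded line search
(golden-section via `optimize()`, +/-15 degree window, 2 cycles, 0.2
degree tolerance) over each flexible chi and each ligand rotatable
torsion plus the S-C spin, accepting only improvements, so the energy is
non-increasing and the covalent geometry is preserved exactly (only
branches not containing the anchor atom move). In the full pipeline the
continuous stage is applied to the best `n_continuous` (default 5)
repacked candidates; the rotamer stage is what recovers blocked poses,
and refining every candidate roughly doubles the cost for no measured
gain in ranking.

Backbone atoms are never moved. This is the package's known fidelity
gap relative to refinement engines that minimize backbone atoms too; it
is a declared restriction, not an approximation made silently.

## Classifying flexible and blocking residues

`profile_ensemble()` measures chi1/chi2 for each binding-site residue
across a superposed ensemble and classifies a residue *flexible* when
its chi1 circular standard deviation exceeds 30 degrees, OR its chi1
histogram (30-degree bins, modes = circular local maxima holding at
least 10% of observations) is multimodal, OR its CA moves more than
1.0 A across the ensemble — the last clause catches mobile-backbone
residues such as glycines that have no chi at all. The thresholds are
configurable; they are deliberately conservative relative to the jitter
scale of real (and synthetic) rigid residues.

`detect_blocking()` then flags a flexible residue as *blocking* when, in
at least one ensemble member, one of its side-chain heavy atoms overlaps
(closer than 0.7 of summed vdW radii) at least two heavy atoms of at
least one non-cognate ligand pose — blocking means hard-core overlap
here, not grazing contact. The classic switch-II lists
(flexible: Thr58-Thr74, Lys88, Asp92, His95, Tyr96, Gln99, Arg102,
Val103, Cys12, Glu37; blocking: Glu62, Tyr64, Arg68, Met72, His95) ship
as `inst/extdata/kras_g12c_site.yaml` for use with real structures.

## The synthetic mini-pocket generator

All tests and the acceptance script run on `make_minipocket()` systems:
a 40-60 residue single-chain receptor (an anchor strand carrying the
reactive cysteine, a helix, a loop and a far strand caged around the
ligand), plus a grammar-generated acrylamide-warhead ligand (6-20 heavy
atoms, 0-4 rotatable torsions) placed at exact covalent-anchor geometry
as the ground-truth pose. The generator guarantees, by construction and
bounded retries:

* the reference pose passes the adduct geometry check and has zero
  repulsion against the open-rotamer receptor;
* each planted blocking residue has a "closed" rotamer that hard-clashes
  the reference pose (one side-chain atom overlapping at least two
  ligand atoms) and an "open" rotamer that does not — the delivered
  receptor is in the closed state, which is what makes the fixture a
  receptor-flexibility test;
* the pose is *specifically anchored*: rigid serine/threonine hydroxyl
  probes are engineered complementary to the pose's polar atoms (or the
  pose picks up enough backbone hydrogen bonds), playing the role a real
  pocket's specific interactions play, so that pose ranking is a
  meaningful test rather than a lottery among wall-hugging decoys;
* every flexible residue has at least one alternative rotamer differing
  in chi1 by 60+ degrees, so ensembles generated by `make_ensemble()`
  have genuinely multimodal planted residues while rigid residues see
  only <= 0.05 A jitter.

What the fixtures deliberately do **not** emulate: real protein
sequences and packing density, solvent, crystallographic disorder, and
any physical energy beyond clash/contact/hydrogen-bond consistency.
Passing the fixture batteries therefore demonstrates that the
*algorithms* behave as specified (blocked pockets recover under masking
and repacking; profiling recovers planted flexibility; geometry
contracts hold), not that the scoring function is accurate on real
complexes.

`make_family()` builds cross-docking families on a shared scaffold: the
cage is built around a large base ligand, variants carry smaller tails
with the warhead amide pinned to the base orientation, and blocking
residues are closed wherever the closed rotamer tolerates the cognate
ligand — docking ligand j into receptor i then reproduces the
non-cognate blocking scenario.

## Benchmarking

`run_matrix()` docks every ligand into every receptor. Reference poses
are carried into the docking frame by superposing the reference
receptor on shared C-alpha atoms (whole-chain, not site-only — a
reproducible choice that is not biased by pocket motion; a site-only
selection can be passed explicitly). Pose accuracy is heavy-atom ligand
RMSD without re-superposition, minimized over graph automorphisms
(element- and bond-order-preserving, via VF2), so chemically equivalent
atoms such as a flipped para-phenyl never inflate the error; both the
corrected and identity-mapping values are reported. Per-job seeds derive
from the global seed and the system-id pair, making matrices
order-independent. Jobs that emit no poses count as failures at every
cutoff rather than being dropped. `success_curves()` reports success
fractions at 2.0/2.5 A for the top 1/5/20 poses by default.

## The glycine loop toy model

The loop-mutant receptor preparation (`prepare_loop_mutant()`) mutates
selected loop residues to glycine for downstream free-energy engines and
flags two caveats: runs of three or more consecutive glycines (extra
backbone mobility) and any mutated side chain within 4 A of ligand heavy
atoms (which would violate the assumption that the mutation leaves
relative binding unchanged). The kinetic rationale — lower per-residue
backbone barriers cross conformational transitions faster — is
demonstrated by `simulate_loop_transition()`: Metropolis Monte Carlo at
kT = 1 on torsion pairs moving on a cos-based periodic double well with
basins at 0 and +120 degrees, Gaussian proposals of 15 degrees, and
per-residue barrier heights (2 kT for glycine, 6 kT otherwise by
default). First-passage is the first step with every torsion inside the
target basin (+/-40 degrees around +120). This simulator is a
demonstration of barrier-limited kinetics, not a claim of molecular
dynamics equivalence.

## Numerical and scale choices

* Dihedrals follow the standard signed convention (verified against
  independent torsion implementations); the L-amino-acid CB improper is
  -122.5 degrees.
* Alternate locations: highest occupancy wins, ties alphabetically.
  Receptor hydrogens are dropped on read (heavy-atom model); ligand
  hydrogens are kept but excluded from scoring and RMSD.
* Clustering is greedy leader clustering on heavy-atom ligand RMSD in
  the shared receptor frame, visiting poses by ascending score; the
  representative is the lowest-score member. The default cutoff is
  1.0 A: the cutoff should not exceed the finest success resolution the
  results are judged at (fixture-scale success is judged at 1.0 A;
  paper-scale 2.0/2.5 A evaluations pair naturally with a 1.5 A
  cutoff, which `cluster_rmsd_cutoff` restores in one keystroke).
* Ties in ranking break by candidate construction index (stable).
* Scoring context is truncated 14 A beyond the anchor (the interaction
  terms all vanish beyond 4.5 A, so the truncation is exact with
  margin).
* Test batteries run at desk scale: 100-seed fixture batteries for the
  geometry filter, 50 ensembles for profiling, 50 small instances for
  the repacker oracle, 20 x 10 paired seeds for the flexible-vs-rigid
  comparison, 200 paired seeds for the loop toy. The vignette states
  these sizes as the package's own standard study conditions.

## Limitations

* Backbone conformational change is out of scope everywhere except the
  toy loop model; pockets gated by loop motion rather than side-chain
  motion will not open.
* The scoring surrogate is a ranking tool for the fixture scale and for
  method development; it is not calibrated against binding affinities,
  and no affinity prediction is attempted.
* Protonation/tautomer enumeration is not performed; a single input
  protomer is assumed.
* PDB v3.3 and SDF V2000 only; no mmCIF, no assembly expansion.
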
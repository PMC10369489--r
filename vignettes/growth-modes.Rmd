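---
title: "From dimer interfaces to growth modes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dimer interfaces to growth modes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Amyloid formation can begin with a single dimer: if the geometry of its
interface is compatible with adding a third monomer the same way the second
was added, and a fourth, and so on, the dimer seeds an open-ended polymer.
If instead the repeated geometry folds the chain back onto itself, growth
self-terminates in a closed oligomer. This vignette describes the models
implemented in `dimergrow`, the parameters that control them, and the
choices made where the underlying procedure leaves freedom.

## The two-angle reduction of an interface

A dimer of monomers A and B is summarized by four points: the geometric
centers of the two monomers, $GC_A$ and $GC_B$ (unweighted means over heavy
atoms), and the geometric centers of the interfacial residues of each
monomer, $GC_{IA}$ and $GC_{IB}$. From these the package computes

* the **polymerization angle** $\theta_{pol} \in [0, 180]^\circ$: the angle
  at $GC_{IA}$ between the directions to $GC_A$ and to $GC_B$. It measures
  how far the interface sits off the inter-center axis, i.e. how much the
  growing chain bends per added monomer ($180^\circ$ = no bend);
* the **polymerization dihedral** $\phi_{pol} \in [0, 180]^\circ$: the angle
  between the normals of the two planes spanned by the inter-center axis
  and each interface center,
  $P_A = (GC_B - GC_A) \times (GC_{IB} - GC_A)$ and
  $P_B = (GC_A - GC_B) \times (GC_{IA} - GC_B)$. It measures the relative
  twist of consecutive monomers. $\phi$ is reported unsigned: mirror-image
  dimers are equivalent for growth purposes, and coplanar interfaces give
  $180^\circ$ (interface centers on the same side of the axis) or $0^\circ$
  (opposite sides).

Projecting an interface center onto a monomer surface only rescales the
vector from that monomer's center without changing its direction, so angles
are computed directly from the centers; this invariance is part of the test
suite. Configurations with coincident or collinear centers raise errors
rather than returning a default, because a silently wrong angle would
corrupt every statistic downstream.

## Interface detection

Interfacial residues are found from solvent accessibility: the interfacial
area of a residue is the solvent-accessible surface area (SASA) it loses
when the partner is present,
$\Delta A = A_{\text{isolated}} - A_{\text{complex}}$, clamped at zero
against sampling noise. SASA uses the Shrake–Rupley algorithm with a
deterministic golden-spiral point lattice: **960 points per atom** (relative
accuracy well under the 3% tolerance the tests enforce against a dense
random-sampling oracle), **probe radius 1.4 Å** (a water molecule), and
Bondi-style van der Waals radii with user overrides. Unknown elements are
an error, not a guess.

$\Delta A$ is converted to a percentage of the residue type's maximal
exposure so a single threshold works for glycine and tryptophan alike. The
default reference is a fixed table of theoretical Gly-X-Gly maxima for the
20 standard amino acids. Residue types outside the table (such as the
generator's pseudo-residues) fall back to the residue's own
isolated-monomer SASA, i.e. relative burial of what is actually exposed.
An `ensemble-max` mode instead uses, for each residue, its maximum
isolated SASA across the models of a multi-model structure, for workflows
where an ensemble of conformations defines attainable exposure; it refuses
single-model input rather than silently degrading. Residues above
**10%** relative interfacial area (the conventional cutoff for this
analysis) form the interface sets; either set empty flags the descriptor
as "no interface", which all angle computations reject.

Interface conservation between two conformations of the same dimer is a
pure set overlap on residue identities (chain, residue number), ignoring
area magnitudes.

## Shape descriptors

Monomer shape is summarized by the gyration tensor of the (unweighted by
default, optionally mass-weighted) atom cloud. With eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ (the squared principal radii of
gyration) and $\bar\lambda$ their mean, the asphericity is the relative
shape anisotropy

$$A_s = \frac{3}{2}\,\frac{\sum_i (\lambda_i - \bar\lambda)^2}
        {\left(\sum_i \lambda_i\right)^2},$$

which is exactly 0 whenever the three principal radii are equal, exactly 1
for collinear configurations, and bounded by $[0,1]$ everywhere; sphericity
is $\psi = (1 - A_s) \times 100$. These limits are verified analytically in
the tests (octahedron, rod, planar hexagon with $A_s = 1/4$). This is the
standard gyration-tensor anisotropy satisfying every property the
two-angle analysis relies on; alternative normalizations of the same idea
exist, and any of them would order monomers identically.

## The sphere model and its propagation convention

The idealized dimer is two tangent unit spheres, monomer A centered at the
origin and B at $(-2, 0, 0)$, decorated with interface markers realizing a
requested $(\theta, \phi)$: the marker of A is placed on its surface in a
canonical half-plane at the polar position solving
$\cos\theta = (1 + 2\cos\alpha)/\sqrt{5 + 4\cos\alpha}$ (inverted in closed
form; the relation is monotone), and the marker of B at the mirrored
position rotated about the inter-center axis by $180^\circ - \phi$.
Measuring the construction recovers the requested angles to $10^{-6}$
degrees (a grid-wide test).

The two angles constrain only the interface, not the full relative pose of
the monomers, so propagating the dimer into a chain requires a convention
for the remaining rigid degrees of freedom. The package adopts the
**ideal-chain convention**: successive sphere centers form a chain with
bond length 2, bond angle $\theta$ and torsion $\phi$, generated by the
(unique) screw transform mapping one center triplet onto the next. Two
properties recommend it over the tempting alternative of aligning
interface-marker frames:

* aligning A's marker frame onto B's marker frame is an exchange map — an
  involution — so every chain folds straight back onto itself regardless
  of the angles; flipping the frame roll instead yields a
  limited/unlimited boundary far above the observed one. Neither
  reproduces the known behavior of real interfaces;
* the ideal-chain convention reproduces the full phenomenology: chains
  with $\theta$ below $\approx 57^\circ$ collide immediately (the
  third-neighbor distance is $4\sin(\theta/2)$), planar-curl chains
  ($\phi \approx 0$) close into rings, planar-zigzag chains
  ($\phi \approx 180$) extend indefinitely, and intermediate torsions give
  helices — exactly the limited/doughnut/linear/helical taxonomy observed
  for real dimers.

Degenerate angles get analytic transforms: $\theta = 180^\circ$ is a pure
translation (straight chain), $\theta = 0^\circ$ the half-turn fold-back.

**Overlap.** Two non-adjacent spheres (index gap at least 2; consecutive
spheres are tangent by construction) overlap when their centers come
closer than $2(1 - \delta)$ with $\delta = 0.05$. The tolerance exists so
that exact closures — a ring of tangent spheres — do not count as
collisions; any small positive value serves, and 5% of a diameter is well
below every geometric feature of the landscape.

**Horizon.** Chains are propagated to $n = 32$ monomers, the size at which
the distinct growth morphologies are visually and numerically unambiguous.
A chain that survives 32 additions without self-contact is called
unlimited; very slowly curling chains could in principle close beyond any
finite horizon, which is inherent to any finite criterion and is why a
boundary *band* exists (below).

**Subtypes.** Limited chains whose first overlap is between monomers 1 and
3 fold straight back: head-to-head (`h2h`). Other limited chains with
screw pitch below 0.1 radius units per step close flat: doughnut (`don`).
Unlimited chains are linear (`lin`) when the effective winding per step is
below $15^\circ$ and helical (`hel`) otherwise. The effective winding is
$\min(\omega(T), \omega(T^2))$: a planar zigzag has a one-step screw angle
of $180^\circ$ but its two-step transform is a pure translation, and a
one-step rule would mislabel every zigzag as helical. These thresholds
automate what is otherwise a visual call; they are exposed as arguments,
and only the limited/unlimited mode should be treated as the model's hard
output.

## The growth landscape

`scan_landscape()` classifies every cell of a $5^\circ$ grid over
$[0,180]^2$ (37 × 37 cells, 32-monomer chains; about two seconds of CPU).
For each dihedral column the largest $\theta$ still limited is a
transition point, and `fit_boundary()` fits the three-parameter
exponential $\theta^*(\phi) = a e^{b\phi} + c$ through the transition
points by Levenberg–Marquardt least squares (starting values from the
range of the transitions; a constant fit with a warning when they are
degenerate). On the default scan the boundary decays steeply from the
low-dihedral (planar-curl) side toward a plateau just below $60^\circ$,
and the fit tracks the transitions with an RMS residual below the grid
step — both properties are asserted in the tests. $\theta$ is the response
variable because the transitions are defined column-wise as the upper
limit of limited growth.

Points within **±10°** of the fitted curve are classified *uncertain*;
below, *limited*; above, *unlimited*. The band half-width is a parameter,
not a measurement: it absorbs both the finite grid step and the sphere
idealization itself, and conformations inside it should be resolved at
atomic resolution (`classify_structure_growth()` does exactly that).
Ensemble placement uses plain arithmetic means of the angles — observed
angle distributions sit well inside $(0, 180)$, so circular statistics
would change nothing while complicating the contract — and the
representative conformation is the ensemble member closest to that mean in
the angle plane, ties to the first.

## Atomic replication and the clash budget

For a real dimer, the A→B propagation transform comes from least-squares
superposition (SVD-based, proper rotations only) of the core Cα atoms of
the two chains; the fit RMSD doubles as a homodimer diagnostic. The
default core — residues 23–27, 36–39, 51–55, 62–66 and 78–82, author
numbering — is the β-sandwich core of β2-microglobulin, the system this
analysis was built around; any protein is analyzed by supplying its own
`core_selection()`. Heterodimers are rejected (the protocol's premise is
that monomer B is a copy of monomer A one step along the chain).

Iterating the transform over monomer A's full atom set yields an
n-monomer polymer with no conformational relaxation, by construction of
the protocol. Steric self-consistency is quantified by counting heavy-atom
pairs between monomers at index gap ≥ 2 closer than **2.0 Å** (spatial
grid, near-linear cost). The verdict for uncertain-region conformations is
*limited* when clashes exceed **0.5%** of the inter-monomer atom pairs
within twice the clash cutoff: a handful of contacts is relievable by
small rearrangements and should not veto growth, while widespread overlap
cannot be relieved. Both the cutoff and the budget are parameters; the
defaults encode "a few clashes are tolerable" without making the criterion
vacuous.

## The synthetic-structure generator

`make_monomer()` builds pseudo-monomers from carbon-like single-atom
residues: concentric golden-spiral shells fill a ball quasi-uniformly
(sphericity above 90%, asserted in tests), and the `with-termini` mode
adds two straight terminal strands that lower sphericity and, more
importantly, provide protruding contact features. This emulates the
morphology that matters for the analysis — a compact core with detached,
unstructured termini — at a scale (tens of atoms) where the whole
SASA→interface→angle→landscape→replication pipeline runs in seconds.

`make_dimer()` poses two copies of a monomer so that the *measured* angles
(through the full SASA pipeline, not the designed geometry) land within
5° of requested targets, by direct numerical refinement of the pose
parameters. A geometric fact shapes its contract: two convex,
quasi-spherical atom clouds always bury a patch centered on their
inter-center axis, so their measured polymerization angle is pinned near
180° no matter how they are posed — off-axis interfaces *require*
protruding features. Spherical monomers are therefore accepted only for
near-axial targets ($\theta \ge 165^\circ$), and very small angles
(roughly below 70°), which in real structures come from termini wrapping
around the partner, are outside what a rigid two-straight-tail fixture
can realize; the pose search reports achieved versus requested angles
when asked for an unreachable corner.

What the generator does **not** emulate: conformational flexibility,
side-chain chemistry, hydrogens, solvent structure, realistic residue
sizes, or wrap-around termini interfaces. Green tests on fixtures
therefore demonstrate that the geometry, the interface detection and the
classification machinery are correct and internally consistent — not that
any particular real protein polymerizes one way or the other.

## Numerical choices and degenerate inputs

* Angle computations clamp cosines into $[-1, 1]$ before `acos`;
  degenerate geometry raises errors naming the collapsed object.
* Superposition requires ≥ 3 non-collinear points (rank checked via
  singular values) and never returns a reflection.
* The screw decomposition handles the $\omega \to 0$ limit (axis taken
  along the translation) and $\omega \to 180^\circ$ (axis from the
  dominant column of $R + I$).
* PDB output keeps three decimals (format precision); the write/read
  round trip is tested at $10^{-3}$ Å. Alternate locations collapse to the
  highest-occupancy conformer on reading.
* Test problem sizes: 16–99-residue pseudo-monomers, ≤ 50-atom SASA oracle
  fixtures, 32-monomer chains, full 37 × 37 scans — sizes at which every
  oracle comparison is exact enough to be meaningful and the whole suite
  runs in well under a minute.

## Known limitations

The sphere model ignores monomer shape entirely; its verdict degrades
exactly where sphericity is low, which is why the uncertain band and the
atomic override exist. The finite 32-monomer horizon cannot distinguish
"unlimited" from "closes after more than 32 additions". The propagation
convention, while validated against every published anchor available to
us, is still a convention: other resolutions of the unconstrained degrees
of freedom would produce different landscapes away from the validated
regions. And the replication protocol deliberately excludes relaxation —
it answers "can this exact interface tile space?", not "what will this
dimer do in solution?".
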
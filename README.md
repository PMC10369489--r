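# dimergrow

Growth-mode analysis of protein dimer interfaces.

Amyloidogenic proteins such as the D76N variant of β2-microglobulin
aggregate through dimers, and whether a given dimer can seed an
ever-growing polymer is largely a question of interface geometry: adding
monomer after monomer with the same relative pose either extends an open
chain indefinitely or folds the chain back onto itself. `dimergrow`
implements that analysis for anyone with a dimer structure — from
simulation snapshots, docking, or structure prediction — and no patience
for building the polymers by hand.

## The model

A dimer of monomers A and B is reduced to four points: the geometric
centers of the monomers, GC_A and GC_B, and the geometric centers of
their interfacial residues, GC_IA and GC_IB (interface = residues losing
more than 10% of their maximal solvent-accessible surface area upon
complexation, from Shrake–Rupley SASA differences). Two angles summarize
the interface:

* the **polymerization angle** θ_pol — the angle at GC_IA between the
  directions to GC_A and GC_B; it sets how much the chain bends per added
  monomer (180° = straight growth);
* the **polymerization dihedral** φ_pol — the angle between the planes
  spanned by the inter-center axis and each interface center; it sets the
  twist between consecutive monomers.

An idealized dimer of two tangent unit spheres decorated with interface
markers realizes any (θ_pol, φ_pol); propagating it (bond length 2, bond
angle θ_pol, torsion φ_pol) produces a chain of spheres whose
self-collisions decide the growth mode: **limited** (head-to-head
fold-backs, closed doughnut rings) versus **unlimited** (linear or
helical protofilament-like chains). Scanning the whole angle plane on a
5° grid yields the *growth landscape*, whose limited/unlimited boundary
is fitted with an exponential θ\*(φ) = a·exp(bφ) + c and widened into an
uncertain band. Real structures in the uncertain band are resolved by the
replication protocol: superpose monomer A onto monomer B, iterate the
transform over the full atom set, and count steric clashes in the
resulting 32-monomer polymer.

The package also provides gyration-tensor shape descriptors (asphericity
A_s, sphericity ψ = (1 − A_s)·100 — the sphere model is trustworthy
exactly when ψ is high), rigid superposition with screw-axis
decomposition, PDB input/output, and a synthetic-structure generator so
the entire pipeline is testable without any external data.

## Worked example

Classify the interface geometry θ_pol = 81°, φ_pol = 160° and place it on
the landscape:

```r
library(dimergrow)

classify_sphere_growth(81, 160)
#> Growth mode: unlimited (hel)
#>   theta = 81.0 deg, phi = 160.0 deg
#>   min non-adjacent distance = 2.598, omega = 167.0 deg, pitch = -1.287

landscape <- fit_boundary(scan_landscape())
landscape
#> Growth landscape: 37 x 37 grid (step 5 deg, 32 monomers)
#>   limited: 552 cells, unlimited: 817 cells
#>   boundary fit: theta*(phi) = 104.969 * exp(-0.04057 * phi) + 54.151 (RMS 2.86 deg)
#>   uncertain band: +/- 10 deg

classify_region(landscape, 81, 160)
#> [1] "unlimited"
```

The 32-sphere chain at (81°, 160°) never brings two non-adjacent spheres
closer than 2.598 radii (tangency is 2, collision below 1.9), so the
interface supports unlimited growth; the per-step screw — 167° of
rotation with small pitch — makes it a (tightly wound) helical chain.
The fitted boundary decays from the planar-curl side of the dihedral axis
to a plateau just below 60°: interfaces bending more than ~120° per
monomer never grow, whatever their twist.

The same verdict for an atomic structure, end to end from a generated
fixture dimer posed at a 123°/16° interface:

```r
m <- make_monomer(16, shape = "with-termini", termini_length = 4, seed = 3)
d <- make_dimer(m, 123, 16)
angles_from_dimer(d)
#> Polymerization angles: theta = 123.04 deg, phi = 16.04 deg
```

`classify_structure_growth(d, core = core_selection(list(c(1, 16))))`
measures those angles, finds the landscape region, and (for uncertain
conformations) overrides it with the clash count of the replicated
32-monomer polymer. `polymerize_structure()` + `write_polymer()` export
the polymer as a multi-model PDB for visual inspection.

A command-line interface wraps the same functions
(`exec/dimergrow`, installed under the package's `exec/` directory):

```sh
dimergrow sphere --theta 81 --phi 160
dimergrow landscape --step 5 --out grid.tsv --json fit.json
dimergrow classify --pdb dimer.pdb --chains A,B
```

## Scope

The sphere model answers "can this exact interface tile space?" — no
conformational relaxation, no energetics, no kinetics. Shape deviations
(low sphericity, wrapping termini) degrade it, which is what the
uncertain band and the atomic-clash override are for; see the
`growth-modes` vignette for the full methods discussion.
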
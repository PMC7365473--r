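---
title: "Staggering, splaying and contact times of myosin II rod pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staggering, splaying and contact times of myosin II rod pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minifil)
```

## The model

Nonmuscle myosin II (NM2) assembles into minifilaments through electrostatic
contacts between the ~160 nm coiled-coil rods of its heavy-chain dimers.
`minifil` implements a coarse-grained model of how two such rods find and
keep their axial registration ("stagger"):

1. **Charge chain.** The rod is a linear chain of point charges on the
   coiled-coil lattice (0.1456 nm axial rise per residue). Arginine and
   lysine contribute +2 e, aspartate and glutamate −2 e (the factor 2
   because the rod is a two-chain dimer). Residues at heptad positions *a*
   and *d* face the hydrophobic seam and their charges are cancelled; skip
   residues are kept as charge sites, which breaks the otherwise
   unrealistically high symmetry of the rod. The heptad register is an
   *input* (an annotation file, or a fallback that cycles a–g from a fixed
   phase around a configured skip list); the package deliberately does not
   predict coiled-coil registers itself.

2. **Screened electrostatics.** Charges interact by the Debye–Hückel
   potential, so a pair at distance $r$ contributes
   $E = q_i q_j \, (l_B / r)\, e^{-r/l_{DH}}$ (in $k_BT$, charges in e),
   with the Bjerrum length $l_B \approx 0.7$ nm derived from the dielectric
   constant (80) and temperature (298 K, $k_BT = 0.593$ kcal/mol). The
   screening length defaults to the commonly quoted physiological value
   $l_{DH} = 1.3$ nm; `debye_length()` exposes the electrolyte formula,
   which at 100 mM monovalent salt gives ≈0.96 nm instead, and either value
   can be set in `electro_params()`. Two straight rods are placed 2 nm
   apart (twice the 1 nm rod radius), parallel or antiparallel, and the
   total energy is the double sum over all cross-rod pairs.

3. **Bending ("splaying").** The rod that arrived second may peel away from
   its partner: it is straight along an overlap $L_o$, follows a circular
   arc of radius $R$ and length $L_a$ curving away from the partner, and
   continues straight along the final tangent. The arc costs the worm-like
   chain energy $E_{bend} = l_p L_a / (2R^2)$ with persistence length
   $l_p = 130$ nm. At every (stagger, overlap) cell the total energy is
   minimized over a grid $R \in [75, 300]$ nm, $L_a \in [15, 40]$ nm.

4. **Contact times.** Once the tips have met at stagger $s$ (an initial
   contact of 25 residues, $x_0 = 3.6$ nm), the overlap fluctuates
   ("rolling and zipping") as overdamped diffusion in the one-dimensional
   potential $V(L_o)$ taken from the landscape column at $s$, with a
   reflecting boundary at full overlap and an absorbing boundary at
   $L_o = 0$ (detachment). The mean contact time is the standard
   mean-first-passage-time double integral
   $T_1(x_0) = D^{-1}\int_0^{x_0} e^{V(z)} \int_z^{L_{max}} e^{-V(y)}\,dy\,dz$.
   No microscopic model for the effective diffusion constant $D$ is
   attempted: profiles report $D\,T_1$ in nm² and only relative
   comparisons between staggers and rod pairs are meaningful.

## Geometry conventions

The fixed rod lies on the z axis with its N-terminus at the origin and its
C-terminal, positively charged assembly domain at the top. The mobile rod
is shifted by the stagger $s \ge 0$; antiparallel partners are reversed so
their C-tip sits at $z = s$, giving equal-length rods the maximum overlap
$L_{max} = L_{rod} - s$. Negative antiparallel staggers (tips pointing away
from each other) are strongly repulsive and are rejected outright.

The contact region of the mobile rod is anchored at its C-terminal side, so
the bend always releases the N-terminal, head-bearing part — this is the
"splaying" of heads away from the filament backbone in both orientations.
For parallel pairs the mobile rod overhangs its partner by $s$; the
overhang is collinear with the straight contact segment.

The unbent rod is admitted as a minimization candidate only at full
overlap. A straight rod *realizes* $L_o = L_{max}$ by construction, so
admitting it at smaller overlaps would silently collapse every strongly
attractive column of the landscape to a constant, destroying the very
overlap dependence (steadily decreasing antiparallel branches, parallel
branches that turn unfavorable at large overlap) that drives the passage
times. Near full overlap, candidate arcs that exceed the remaining contour
are clamped; the clamped arc length enters the bending energy.

## Numerical choices

* **Lattice resolution.** Stagger scans default to one lattice site
  (0.1456 nm). Landscape staggers and the overlap step (default 7 sites
  ≈ 1.02 nm) are snapped to the lattice; this keeps every bent-tail
  template reusable across cells and makes the straight part of each cell
  an exact prefix sum, so the grid minimization is fast without any change
  in the summed energies. Each landscape column always contains the exact
  $L_o = L_{max}$ cell.
* **Pair cutoff.** Pairs beyond $12\,l_{DH}$ (15.6 nm) are dropped. At that
  range the kernel has decayed by $e^{-12}$, and on rod-sized chains the
  scan energies agree with the uncut sum to well below $10^{-3}\,k_BT$
  (tested); `cutoff_nm = Inf` restores the literal double sum.
* **Tie-breaks.** Among bend candidates of equal total energy the least
  bent wins (largest radius, then shortest arc), so neutral inputs give
  clean straight or gentlest-arc answers.
* **Quadrature.** The passage-time integrals use the trapezoidal rule on a
  0.05 nm grid with the potential interpolated linearly between landscape
  cells; the flat-potential closed form $(2Lx_0 - x_0^2)/(2D)$ is
  reproduced essentially exactly, a linear potential to ~$10^{-5}$
  relative, and halving the step moves rod-pair results by well under
  0.5% (all tested). Potentials beyond ±500 $k_BT$ are refused rather than
  silently overflowed; rod-pair potentials stay two orders of magnitude
  below that.
* **Local minima / peaks.** A stagger is a minimum (peak) when strictly
  lower (higher) than both neighbours after an optional centered moving
  average; the default is no smoothing.

## The synthetic rod

Real heavy-chain sequences are inputs the package reads from FASTA; no
downloads are attempted. So that the whole pipeline is testable without
them, `synthetic_rod()` builds a chain that emulates the coarse charge
architecture the model actually exploits:

* 1078 sites (156.8 nm, close to the ~158 nm NM2 rod);
* the 196-residue charge repeat: five regions of increased negativity in
  the odd 98-site half-periods counted from the C-tip, one −2 e charge per
  heptad;
* a solid +2 e tip of 25 sites (the size of the initial contact, standing
  in for the positively charged assembly-critical domain);
* net charge ≈ −0.084 e per residue, matching the ~0.085 e per residue
  effective charge of an NM2 rod, hence a surface charge density of
  ≈0.09 e/nm² on a 1 nm cylinder — comfortably in the weak-coupling regime
  that justifies the linearized (Debye–Hückel) electrostatics.

A parallel self-scan of this rod has minima near, but a few sites above,
the odd multiples of 98 sites (15.1, 43.8, 72.7 nm), drifting upward with
order — the same behaviour as the experimentally observed staggers, whose
residue conversions (98.2, 296.7, 494.5) also sit increasingly above
98, 294 and 490. The drift comes from finite-rod edge effects under the
screened kernel. A stricter point-repeat variant
(`synthetic_rod(tip_sites = 1, block_stride = 98)`) isolates the
periodicity itself and scans to minima at exactly 98/294/490 sites.

What the fixture does **not** emulate: isoform-specific charge patterns
(so no NM2A/NM2B/NM2C ordering can be derived from it), the diffuse mix of
positive and negative residues along real rods (its blocks are purely
negative, its tip purely positive, which exaggerates antiparallel binding
energies and hence antiparallel/parallel contact-time ratios), and the
non-helical tailpiece. Passing tests on the fixture therefore validate the
machinery — energies, geometry, minimization, passage times — not
isoform-level biology.

## Problem sizes

The test suite works on toy chains of 150–600 sites with reduced bend
grids (3–4 radii × 3–4 arcs), which keeps the whole suite under a minute
while still covering every code path, and cross-checks the optimized paths
against brute-force double loops and exhaustive enumerations.
`scripts/acceptance.R` runs the full-size synthetic rod with the default
16 × 11 bend grid: lattice-resolution straight scans, and landscapes plus
contact-time profiles over ~50 staggers per orientation at the ~1 nm
overlap step (a few minutes on one CPU).

## Limitations

Beyond the synthetic-fixture caveats above: electrostatics is linearized
(no nonlinear Poisson–Boltzmann, counterion condensation, or dielectric
boundaries); bending is a single planar circular arc of one rod (no
thermal ensemble of shapes, no out-of-plane splay); the effective
diffusion constant is overlap-independent, so contact times are relative;
and skip-residue structural perturbations (local over/underwinding) are
not modelled — skips only enter as charge sites and register
interruptions.
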
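# minifil

Coarse-grained electrostatics, bending and contact times for myosin II
minifilament assembly.

Nonmuscle myosin II (NM2) motors assemble into ~300 nm minifilaments held
together by electrostatic contacts between their ~160 nm coiled-coil rods.
Electron microscopy shows parallel rods registered at characteristic axial
staggers (14.3, 43.2 and 72 nm — odd multiples of 98 residues of the
196-residue charge repeat) and antiparallel rods overlapping by 43–45 nm.
`minifil` is for biophysicists who want to compute, from sequence-level
charge information, *why* those registrations are selected and how long a
given rod pair stays engaged.

## The model

A rod is a linear chain of point charges on the coiled-coil lattice
(0.1456 nm per residue): R/K → +2e, D/E → −2e (two heavy chains per rod),
heptad *a*/*d* charges cancelled, skip residues kept. Two rods at lateral
distance 2 nm interact by the screened Coulomb (Debye–Hückel) energy

    E = Σᵢ Σⱼ qᵢ qⱼ (l_B / r_ij) exp(−r_ij / l_DH)   [k_B T]

with Bjerrum length l_B ≈ 0.7 nm and screening length l_DH = 1.3 nm. The
mobile rod may splay: straight along an overlap L_o, then a circular arc
(radius R, length L_a) curving away, costing the worm-like-chain energy
E_bend = l_p·L_a/(2R²) with l_p = 130 nm; at each (stagger s, overlap L_o)
the total energy is minimized over R ∈ [75, 300] nm, L_a ∈ [15, 40] nm.
The resulting one-dimensional potential V(L_o) at fixed s feeds a
mean-first-passage-time calculation (reflecting at full overlap, absorbing
at detachment, initial contact x₀ = 3.6 nm):

    T₁(x₀) = D⁻¹ ∫₀^{x₀} e^{V(z)} [ ∫_z^{L_max} e^{−V(y)} dy ] dz

Profiles of D·T₁ (nm²) versus stagger show which registrations keep two
rods engaged the longest — for homo- *and* hetero-dimers (the first rod of
a pair stays straight, the second shifts and bends).

## Worked example

```r
library(minifil)

rod <- synthetic_rod()       # 1078 sites, 196-site charge repeat
rod
#> # charge chain 'synthetic-rod': 1078 sites, 156.8 nm, net -90 e

scan <- stagger_scan(rod, rod, "parallel", s_min = 0, s_max = 80)
tidy(scan)                   # local energy minima
#> # A tibble: 3 × 2
#>   stagger_nm energy_kbt
#>        <dbl>      <dbl>
#> 1       15.1      -19.2
#> 2       43.8      -20.9
#> 3       72.7      -22.7
```

The three minima sit a few residues above the odd multiples of 98 sites
(14.3, 42.8, 71.3 nm) — the charge-repeat registrations, shifted slightly
by finite-rod edge effects, exactly as the experimentally observed staggers
(98.2, 296.7, 494.5 residues) sit above 98, 294 and 490.

```r
flat <- test_potential("flat", l_max_nm = 100)
mean_first_passage_time(flat, x0_nm = 3.6)
#> [1] 353.52                 # = (2·100·3.6 − 3.6²)/2, the closed form

prof <- contact_time_profile(rod, rod, "antiparallel",
                             staggers_nm = seq(125, 145, by = 1.456))
glance(prof)[c("peak_stagger_nm", "peak_dt1_nm2")]
#> # A tibble: 1 × 2
#>   peak_stagger_nm peak_dt1_nm2
#>             <dbl>        <dbl>
#> 1            131.    27253422.
```

The antiparallel contact-time peak (D·T₁ ≈ 2.7·10⁷ nm², against ~10² nm²
for parallel staggers of this rod) marks the registration where the
positive C-tips of both rods engage the partner's first negative region —
the configuration that nucleates a minifilament. `autoplot()` methods draw
charge profiles, scans, landscapes, overlap potentials and contact-time
profiles; `tidy()`/`glance()` summarize them.

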
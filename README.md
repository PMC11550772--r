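# nanoroll

Digital construction, relaxation and atomistic description of nanotubes
rolled from two-dimensional single-layer materials.

Nanotubes of materials beyond graphene — buckled silicene and germanene,
three-plane MoS2 and WS2, silica bilayers, graphyne networks — cannot be
built by the zero-thickness, hexagonal-only generators that serve carbon
nanotubes.  `nanoroll` is for computational materials and nanosafety
researchers who need (a) geometrically exact tubes from *any* 2-D lattice,
including non-zero-thickness layers and negative chiral indices, (b) the
tube's translational primitive cell for infinite-tube simulations, (c)
energy-minimized, physically relaxed structures rather than purely
geometric ones, and (d) a reproducible 30-descriptor feature table
(energies, coordination statistics, radii, surfaces, thicknesses) to feed
machine-learning models of nanomaterial properties such as toxicity.

## Method in brief

For a unit cell with lattice vectors **a**₁, **a**₂ and chiral indices
(n₁, n₂), the rolling vector is **C**ₕ = n₁**a**₁ + n₂**a**₂.  The
half-open strip [0, |**C**ₕ|) × [0, L) in the frame aligned with **C**ₕ is
rolled with mid-plane arc-length preservation:

    (x, y, z) → ((R+z) cos(2πx/|Cₕ|), (R+z) sin(2πx/|Cₕ|), y),  R = |Cₕ|/2π

so layer heights become radial shell offsets.  The translational period is
the smallest lattice vector **T** = t₁**a**₁ + t₂**a**₂ with
**T**·**C**ₕ = 0, found by exact integer reduction of the lattice metric
(with a 0.0001 Å seam-mismatch search fallback for irrational metrics).
MoS2 and WS2 structures are relaxed with an embedded Stillinger–Weber MX2
parameterization (original calibration documented in the package
vignette) using a FIRE minimizer with both an energy and a force stopping
tolerance.  Descriptors D1–D30 compare the nanosheet with its nanotube;
D3 = E(sheet) − E(tube) > 0 means the tube is the more stable form.

## Worked example

Build the MoS2 (30,10) nanotube primitive cell, relax sheet and tube, and
compile descriptors — as a library call:

```r
library(nanoroll)
cfg <- run_config(material = "MoS2", n1 = 30, n2 = 10,
                  mode = "primitive", outdir = "mos2-30-10")
summary <- cli_build(cfg)
```

or from a shell via the bundled front end:

```sh
Rscript inst/cli/nanoroll build --material MoS2 --n1 30 --n2 10 --primitive --out mos2-30-10
```

which logs each stage and prints:

```
[nanoroll] material     MoS2 (3 basis atoms)
[nanoroll] sheet        3x3 reps, 27 atoms
[nanoroll] tube         (30,10) primitive: 420 atoms, R=13.31 A, wrap=19.11 deg, period=14.4809 A
[nanoroll] energy       geometric: sheet -5.1102, tube -5.0102 eV/atom
[nanoroll] minimize     sheet -5.1102 (conv=TRUE), tube -5.0555 eV/atom (conv=FALSE)
wrap angle 19.11 deg, nominal radius 13.31 A, period 14.48 A
```

Reading the numbers: the (30,10) rolling vector wraps at 19.11° with a
13.31 Å mid-plane radius; the translational cell repeats every 14.48 Å
along the axis and holds 420 atoms.  The flat monolayer relaxes to
−5.110 eV/atom.  The geometric tube starts 0.10 eV/atom above the sheet
(curvature strain), relaxation recovers about half of that
(−5.055 eV/atom; `conv=FALSE` flags that the run used its full iteration
budget rather than reaching the force tolerance — the energy is converged
to well below 1 meV/atom), and the remaining gap shrinks with radius: by
(100,10) the tube is within 0.005 eV/atom of the sheet.  At this radius
the sheet is still the more stable form, as the summary's stability
verdict says.  `mos2-30-10/` contains the sheet and tube as extended-XYZ
and LAMMPS data files, `descriptors.csv` with the geometric- and
minimized-stage D1–D30 rows, and `summary.json` with full-precision
values.

Geometry-only workflows (any of the 13 materials, or a user-supplied cell
file) work the same way with `--minimize none`; materials without an
embedded force field are built geometrically and can be relaxed through
the external LAMMPS-engine adapter (`external_engine_adapter()`).

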
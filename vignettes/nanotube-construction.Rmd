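---
title: "Building and relaxing single-layer-material nanotubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and relaxing single-layer-material nanotubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoroll)
```

## The construction model

A nanotube is defined here by three choices: a two-dimensional material
(a primitive cell with in-plane lattice vectors $\mathbf a_1$, $\mathbf a_2$
and a basis of atoms at heights $z$ around the layer mid-plane), a pair of
integer chiral indices $(n_1, n_2)$, and a length rule (a fixed length in
angstrom, or the translational primitive cell).  The rolling vector is the
replicated lattice-vector sum

$$\mathbf C_h = n_1 \mathbf a_1 + n_2 \mathbf a_2,$$

whose length fixes the tube circumference and whose direction fixes the
wrap angle $\theta = \angle(\mathbf C_h, \mathbf a_1)$.  Negative indices
replicate in the opposite lattice direction and are required to enumerate
all tubes of low-symmetry layers; only $(0,0)$ is invalid.  All hexagonal
materials in the library use the convention $|\mathbf a_1| = |\mathbf a_2|$
with 120 degrees between the vectors.  Under that convention
$\cos\theta = (n_1 - n_2/2)/\sqrt{n_1^2 + n_2^2 - n_1 n_2}$, which gives
the familiar sequence 60.00, 30.00, 19.11, ..., 5.21 degrees for
$(10,10), (20,10), \ldots, (100,10)$.  The angle convention is a genuine
design choice: with a 60-degree primitive cell the same index pairs
produce different printed angles, so the 120-degree convention is fixed
package-wide and asserted in the tests.

The sheet region that becomes the tube is the half-open rectangle
$[0, |\mathbf C_h|) \times [0, L)$ in a frame rotated so that
$\mathbf C_h$ lies along $+x$.  Half-open intervals are the seam rule: a
closed-closed region would duplicate the boundary line of atoms at the
seam after rolling, a common defect of naive constructions.  Points within
$10^{-6}$ angstrom of a boundary are snapped onto it before the membership
test so floating-point jitter cannot drop or duplicate seam atoms.

Rolling preserves mid-plane arc length.  With reference radius
$R = |\mathbf C_h| / 2\pi$, an atom at $(x, y, z)$ maps to

$$\big((R+z)\cos\tfrac{2\pi x}{|\mathbf C_h|},\;
       (R+z)\sin\tfrac{2\pi x}{|\mathbf C_h|},\; y\big),$$

so atoms above or below the mid-plane land on radial shells offset by
their layer height: a three-plane MoS2 strip becomes three concentric
shells, and outer-shell interatomic distances stretch while inner-shell
ones compress.  This is exactly why geometric tubes of thick layers are
strained and need relaxation.  Which surface's arc length a physical tube
preserves is not knowable from geometry alone; the mid-plane is the
symmetric choice and the radial offsets reproduce the expected
inner/outer strain pattern.  Tubes whose innermost shell would reach
radius $\le 0.2$ angstrom are rejected as self-intersecting.

## The translational primitive cell

An infinite tube exists only if some lattice vector
$\mathbf T = t_1 \mathbf a_1 + t_2 \mathbf a_2$ is perpendicular to
$\mathbf C_h$; rolling the strip of axial length $|\mathbf T|$ then yields
a cell that tiles the cylinder axially.  Writing the lattice metric
contractions $\alpha = \mathbf a_1\cdot\mathbf C_h$ and
$\beta = \mathbf a_2\cdot\mathbf C_h$, the condition is
$\alpha t_1 + \beta t_2 = 0$.  When $\beta/\alpha$ is rational — true for
every built-in cell — the smallest solution follows from continued-fraction
reconstruction and gcd reduction, and the seam mismatch is exactly zero.
For an irrational metric the package falls back to an incremental search
over integer pairs that accepts the first $\mathbf T$ whose projection on
$\mathbf C_h$ is below 0.0001 angstrom (the seam threshold), and fails
loudly, reporting the best mismatch found, if none exists within
`max_rep`.  The sign of $(t_1, t_2)$ is canonicalized along the
$+90^\circ$ rotation of $\mathbf C_h$; the period direction is physically
a line, so the sign carries no content.  Tests compare the period length
and $|t_i|$ against a brute-force search over all $|t_i| \le 50$ on every
hexagonal material.

## The embedded force field

Sheets and tubes of MoS2 and WS2 are relaxed with an analytic
Stillinger-Weber model of the MX2 type,

$$\phi_2(r) = A\Big[B\big(\tfrac{\sigma}{r}\big)^p -
  \big(\tfrac{\sigma}{r}\big)^q\Big] e^{\sigma/(r - r_c)}, \qquad
\phi_3 = \lambda\, e^{\gamma_{ij}/(r_{ij}-r_{c,ij})}
          e^{\gamma_{ik}/(r_{ik}-r_{c,ik})}
          (\cos\theta_{jik} - \cos\theta_0)^2,$$

with both terms vanishing smoothly at their cutoffs.  The parameter tables
are an **original parameterization** written for this package and
calibrated to published reference properties of the monolayers, not a
transcription of any distributed force-field file:

* geometry — lattice constant $a = 3.160$ Å and Mo–S bond $d = 2.417$ Å
  for MoS2 ($a = 3.155$, $d = 2.405$ Å for WS2).  The pair-term minimum is
  placed at $d$ and the angular minimum at the trigonal-prismatic
  equilibrium $\cos\theta_0 = 1 - a^2/2d^2$ ($\theta_0 \approx 81.8^\circ$),
  which makes the flat monolayer the exact model minimum by construction;
* energetics — bond depth $\varepsilon = 2.555$ eV, i.e. $-5.11$ eV/atom
  at equilibrium (six bonds per formula unit), the equilibrium per-atom
  energy reported for the reference MX2 Stillinger-Weber model of MoS2;
* stiffness — the angular constant $\lambda = 100$ eV puts the measured
  bending rigidity at 6.7 eV, inside the published 6.6–9.6 eV range for
  monolayer MoS2 and at the soft end typical of Stillinger-Weber
  parameterizations.

Two structural devices follow established MX2 practice.  First, the two
chalcogen sub-planes are distinct internal force-field types (S1 upper or
outer, S2 lower or inner, assigned by height in a flat layer and by radial
shell in a tube): angle springs then act only on the crystallographically
equivalent $\approx 82^\circ$ angles.  With a single sulphur type the
$\approx 135^\circ$ cross-plane angles share the same $\theta_0$, the flat
sheet becomes frustrated, and the model develops a negative bending
rigidity — curved sheets would be *lower* in energy than flat ones, the
opposite of the physical size trend.  Second, short-range repulsive pair
terms between like species (Mo–Mo, S–S) are inactive in the equilibrium
sheet but engage when rolling compresses the inner shells.

Known limitations: the in-plane biaxial stiffness of the frozen model is
about 16 eV/Å$^2$ ($2(C_{11}+C_{12})$) versus roughly 22 eV/Å$^2$ measured
for MoS2 — with the flat-sheet equilibrium pinned exactly, the angular
constant cannot match the bending and stretching stiffnesses
simultaneously, and bending was preferred because tube energetics are the
package's purpose.  No reactive chemistry: bond topology is fixed by the
cutoffs, so hydrogenated or silica materials have no embedded model and
their energetics are reachable only through the external-engine adapter,
which exchanges LAMMPS data files and minimization scripts with any
engine that honours the same four stopping parameters.

## Energy evaluation and minimization

Periodic interactions are computed by exact image enumeration: every
periodic image pair within the cutoff contributes separately, including an
atom with its own image.  This is deliberate — the translational cell of a
narrow tube (the (10,10) MoS2 period is 5.47 Å) is shorter than twice the
cutoff, where a minimum-image convention is simply wrong; enumerating
images makes short-period cells exact rather than an error, and the axial
extensivity test (a doubled cell has exactly twice the energy) guards the
implementation.  Neighbor lists are rebuilt from cell bins with a 0.5 Å
skin when any atom has moved more than a quarter skin, and atoms are
processed in a fixed order, so energies are bit-stable across runs.

The default minimizer is FIRE (fast inertial relaxation engine), a damped
dynamics scheme that is robust for the strongly strained geometric tubes;
plain steepest descent is available as a fallback.  Both are wrapped in a
monotone-acceptance safeguard: a trial step that would raise the energy by
more than $10^{-12}|E|$ is rejected, velocities are zeroed and the time
step halved, so the accepted-energy trajectory is non-increasing and the
final energy can never exceed the initial one.  Convergence requires
*both* stopping conditions — relative energy change below `energy_tol`
(0.001 by default) *and* global force 2-norm below `force_tol`
($10^{-6}$ eV/Å) — the conservative reading when the two tolerances are
given without a stated combination rule.  The energy-change denominator is
the energy at the start of the minimization; a per-step-relative variant
is exposed via `energy_tol_reference = "step"`.  Budgets default to 1000
iterations and 100000 evaluations; the force tolerance is tight enough
that large systems typically stop on the iteration budget with the energy
converged to well below a millielectronvolt per atom.  Cell vectors are
held fixed throughout: the rolling vector defines the box, and radius
changes happen through free atomic motion, so a tube may relax to a
slightly non-circular cross-section.  No attempt is made to escape local
minima; strongly frustrated starting tubes can and do stay in local
minima, which is a property of the method, not a defect of the minimizer.

## Descriptors

The thirty-descriptor table pairs a nanosheet with its nanotube: per-atom
energies and their difference and ratio (sheet minus tube, so a positive
difference means the tube is the more stable form), mean coordination
numbers, the common-neighborhood parameter (CNP), ring-order ("hex")
indicators, the chiral indices, and the geometric quantities — nominal
diameter, perimeter and entrance disc from the rolling vector, and the
atom-derived minimum/maximum radii with the perimeters, annular entrance
surface and wall thickness that follow.  Records are tagged `geometric`
or `minimized` and both stages are emitted, since either may feed a
feature table.

Operational definitions that the descriptor names alone do not fix:

* neighbor cutoffs default to 1.2 times the shortest pair distance per
  species pair in the pristine sheet, overridable per pair;
* the CNP of atom $i$ is
  $\frac{1}{n_i}\sum_j |\sum_k (\mathbf r_{ik} + \mathbf r_{jk})|^2$
  over neighbors $j$ and common neighbors $k$, the standard
  structural-order form, which vanishes in an ideal FCC crystal (a test
  asserts this null case) and for structures with no shared neighbors;
* the first hex parameter of an atom is the indicator that its first-shell
  neighbor count equals the count of its species in the pristine sheet;
  the second hex parameter applies the same test between the first- and
  second-shell cutoffs.  Averages are fractions in $[0,1]$; vacancies and
  strong curvature lower them;
* the nominal entrance surface uses the nominal-radius disc
  $\pi R^2$; the "actual" entrance surface uses the atom-derived annulus
  $\pi(r_{max}^2 - r_{min}^2)$, which is zero for a zero-thickness tube;
* the index ratio $n_2/n_1$ is reported as `NA` when $n_1 = 0$ rather
  than raising an error;
* coordination is *not* asserted to increase upon rolling in general —
  that holds as a tendency, reliably so only for zero-thickness materials
  at small radius with a long-range cutoff.

## The material library

Thirteen curated layers ship as plain-text cell files (the same format
accepted for user cells): graphene, graphane, the alpha/beta/gamma
graphynes, gamma-graphdiyne, silicene (0.46 Å buckling), germanene
(0.64 Å), hexagonal boron nitride, the hexagonal and Stone-Wales
(haeckelite) silica bilayers, MoS2 and WS2.  Geometries use standard
literature values recorded in each file's source note; graphyne networks
are generated from the acetylenic bond-length prescription (aromatic
1.43 Å, sp2-sp2 1.46 Å, sp2-sp 1.40 Å, triple 1.22 Å, diyne single
1.34 Å), which reproduces the accepted lattice constants (6.96, 9.50,
6.88 and 9.44 Å).  The haeckelite silica net is labelled a synthetic
model geometry: a Stone-Wales rearranged (5-7) bilayer with a
harmonically relaxed silicon net, adequate for geometric construction but
not a relaxed ab initio structure.  Basis heights are stored about the
mid-plane ($z = 0$), so the rolling transform reads each atom's radial
offset directly from its $z$ coordinate.  None of the current materials
needs a rolling-surface choice (all are symmetric about the mid-plane);
the construction metadata records the fixed mid-plane-up orientation.

## Scope of validation

The test suite validates geometry against closed forms and brute-force
enumeration oracles, forces against central differences, and energetics
against the calibration anchors plus genuine predictions (the tube-energy
size trend and its approach to the sheet value from above).  What passing
tests do *not* show: that the embedded parameterization transfers to
properties outside its calibration set (phonons, defects, edges), that
minimized structures are global minima, or that descriptor values match
any particular external tool's conventions where only names, not
formulas, are standardized.  Problem sizes in the routine tests are kept
small (tubes up to a few hundred atoms; the largest acceptance
computation, the (100,10) MoS2 tube, has 5460 atoms and relaxes in
seconds with the compiled kernel).
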
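---
title: "Vertex models and morphometrics of neural plate folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex models and morphometrics of neural plate folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfvm)
```

## The scientific question

During neural tube closure, the neural plate epithelium bends along its
anteroposterior (AP) axis. Live imaging shows that only a subpopulation of
superficial neuroepithelial cells constrict their apical domains; they are
interspersed among cells that passively enlarge and elongate along AP. This
package implements the mechanical models used to ask whether that cell
elongation and the hinge furrow can arise *passively*, from nothing more
than a dispersed contractile subpopulation embedded in an elastic sheet,
together with the image-quantification stage used on segmented microscopy
data — driven here entirely by a synthetic-data generator, since no imaging
data are redistributed.

## The 2D vertex model

Each cell is a polygon over shared vertices. In dimensionless form (lengths
in units of the target cell area$^{1/2}$), the tissue energy is

$$e=\sum_c^N\left[(a^{(c)}-1)^2 + k_p\,(p^{(c)}-p_0^{(c)})^2\right],$$

with per-cell area $a^{(c)}$ and perimeter $p^{(c)}$, and the overdamped
dynamics $\dot r_i = -\nabla_{r_i} e$ integrated with an explicit Euler
scheme ($\Delta t = 10^{-4}$). Defaults: $k_p = 1$ and $p_0 = 3.7$, just
below the perimeter $6\sqrt{2/(3\sqrt3)} \approx 3.72242$ of the unit-area
regular hexagon, so the initial honeycomb is close to (but not at) its
energy minimum. A centered $N_x \times N_y$ plate region (default
$60\times20$) inside an $N'_x \times N'_y$ tissue (default $100\times60$)
is eligible for constriction: each plate cell independently becomes
constricting with probability $P_c$, which sets its target perimeter to
10% of the baseline. The outermost cell ring is frozen (all of its
vertices immobile), providing the external-tissue constraint; every second
plate column carries one extra cell so the region is symmetric about the
AP centerline (the default plate has exactly 1230 cells).

Key measured outputs:

* **Cell shape**: per-cell gyration tensor
  $S = \tfrac1n\sum_i (r_i - \bar r)\otimes(r_i - \bar r)$ over the cell's
  vertices; elongation $\kappa = (g_1-g_2)/(g_1+g_2)$ and orientation of
  the leading eigenvector against AP, folded into $[0^\circ, 90^\circ]$.
* **Plate dimensions**: distances between mean centers of small groups of
  centrally located edge cells (5 per edge by default; the layout only
  requires "several"), normalized by a relaxed zero-constriction
  reference.

## The 3D vertex model

For the hinge furrow, cells are unit-volume prisms (apical and basal
polygon loops, lateral quads) with energy

$$\sum_c\left[\alpha\,a_a + \beta\,a_b + \tfrac12 a_l
 + k_p (p_a - p_0)^2 + k_V (v-1)^2\right],$$

$\alpha=\beta=0.5$ (cuboidal tissue), $k_p=1$, $k_V=100$, and
$p_0 = 2\cdot6^{1/3}(\alpha+\beta)^{-1/3} \approx 3.6342$, the equilibrium
apical perimeter of a perimeter-elasticity-free honeycomb. The patch is 20
cells along AP with periodic boundaries (fixed box length equal to the
initial lattice extent — the simplest reading of periodicity, since the
hinge is much longer than wide) and 40 cells perpendicular, with one
frozen row on each side. A centered 3-row band running along AP
constricts with probability $P_c$ (again to 10% of $p_0$).

Geometry conventions the energy depends on (the model statement does not
fix them, so they are package conventions applied identically in energy
and forces): possibly non-planar faces are fan-triangulated about their
vertex centroid; cell volume is the divergence-theorem sum over the
outward-oriented closed triangulated surface. The initial prism
cross-section is the flat-equilibrium hexagon (area
$A^* = (p_0/3.72242)^2 \approx 0.953$, height $1/A^*$), which makes
volumes exactly 1 and the zero-constriction sheet stationary.

The furrow **depth** reported by `furrow_profile()` is a package
convention (the original analysis shows cross-sections only): the
deviation of the band's mean apical height below a quadratic baseline
fitted to the rest of the sheet. The baseline fit is needed because the
whole sheet develops a shallow height bowl (~0.3% of the cell height)
even with no constriction — volumes settle slightly below 1 against the
fixed boundary rows, which retain the initial height — and subtracting it
leaves only the localized furrow deflection.

## Relaxation: dynamics, minimization, and vertex mergers

`relax2d()`/`relax3d()` offer the explicit Euler gradient flow and a
`minimize` mode — a compiled limited-memory quasi-Newton (L-BFGS) descent
on the same energy — as a faster route to the same fixed point. Their
agreement is checked on a small instance in the test suite.

Two numerical points deserve emphasis:

* **Vertex mergers.** Because neighbor exchanges (T1 transitions) are
  deliberately not implemented, strongly constricting cells collapse some
  edges to zero length and the raw energy is non-smooth exactly at those
  configurations. The energy and force kernels therefore use a $C^1$
  regularization, $|e| \to \sqrt{|e|^2+\varepsilon^2}$ with
  $\varepsilon = 10^{-4}$ cell lengths (and the analogous smoothing of
  triangle-area norms in 3D), applied only in the energy/gradient path —
  reported areas and perimeters are exact. This is far below every
  physical scale of the model (regular edges are $\sim0.6$), changes the
  energy of a regular edge by $\sim10^{-8}$, and turns the merger kinks
  into genuine stationary points that quasi-Newton descent can reach.
* **Convergence criteria.** Smooth configurations converge in force (the
  matched-target honeycomb reaches max force $<10^{-14}$; the constricted
  3D patch reaches $<10^{-6}$). On large constricted 2D tissues the
  double-precision resolution of the total energy limits the reachable
  force level to $\sim10^{-4}$; the minimizer then declares convergence on
  energy stationarity (flagged `at_kink` in the result). L-BFGS is
  augmented with short FIRE (inertial damped-dynamics) bursts when a line
  search stalls, which carries the slow collective contraction modes past
  merger facets. Euler mode guards against instability: an energy rise
  beyond $10^{-9}$ per step halves $\Delta t$ once, then errors.

## Morphometrics

The quantification stage mirrors what is done on segmented images, and
deliberately uses *area-weighted* (per-pixel) normalized second central
moments — not the vertex-based gyration tensor of the solvers — for aspect
ratio and orientation; both conventions are kept because they are distinct
in the original analyses. Junctions are maximal boundary-pixel runs
touching exactly two cells (pixels touching three or more are network
vertices, reported separately; the original description does not say
whether they were pooled); junction intensities are measured on masks
dilated by 1 px (radius configurable — the original radius is unstated)
and cytoplasmic intensities on cell masks eroded by 1 px. Apical-domain
tracks are scored AC/AE at a ±20% relative change between the first and
last frame (a min/max-based option exists, but first/last is the default
baseline); dispersion uses the sample (n−1) standard deviation and
CV = s.d./mean.

## The synthetic-data generator

`generate_polygonal_tissue()` emulates the *measurable structure* of a
segmented neural-plate apical surface, not its mechanics: a weighted
(power-diagram) tessellation, built by direct half-plane clipping with two
Lloyd iterations and a proportional weight controller, drives a fraction
`f_c` of cells to a target small/large area ratio (default 0.2,
matching the strongly constricted apical domains); a global anisotropic
stretch imposes the target mean aspect ratio and orientation on the
sheet. Note the bias is global — constricted cells are stretched along
with the rest — which suffices for the round-trip and dispersion checks
the generator exists for. The junctional intensity channel follows
`a - b*length + N(0, sd)` per junction, clipped at zero, emulating
brighter staining of shorter junctions. Area tracks drift geometrically to
per-class target changes (defaults −50% for AC, +40% for AE over 20
frames) with multiplicative log-normal noise per timepoint, values chosen
to resemble the published track families. Every generator is a pure
function of its parameter record, including the seed.

What passing these tests does *not* show about real data: no point-spread
function, illumination gradients, or segmentation/tracking errors are
emulated, and the tessellation is not mechanically realistic — it only
controls the area/shape statistics the morphometrics consume.

## Experiment registry and problem sizes

`run_experiment()` exposes named end-to-end reproductions
(`fig3b_relax`, `fig3c_angles`, `fig3d_pc_sweep`, `fig3ef_alpha_sweep`,
`supp_geometry`, `supp_hinges`, `fig3hij_3d`) in two tiers. The `full`
tier uses the original lattice sizes (e.g. $100\times60$ with a
$60\times20$ plate; $N_xN_y\approx1200$ with margins of 40 for the
aspect-ratio sweep; the $20\times40$ 3D patch). The `smoke` tier runs the
same pipelines on reduced lattices (e.g. $50\times30$ with a
$30\times10$ plate, margins of 14, a $10\times24$ 3D patch) so every
entry completes in minutes on one CPU; bundles are stamped
`scaled_down = true`. The direction-of-effect conclusions are stable
across tiers; quantities tied to the full geometry (the ~9% area
reduction, the aspect-matched-exterior control at $N'_y = 34$) are always
evaluated at full size in the test suite. The $180\times180$ exterior
variant is part of `supp_geometry`'s full tier only (32400 cells; in
Euler mode such tissues are integrated at $\Delta t = 10^{-3}$ to
$t = 20000$); the shipped tests do not exercise it.

## Known limitations

* No T1 transitions, cell divisions, extrusions, or curved initial
  geometries; the cell-neighbor graph is fixed for all time.
* The 2D model has no out-of-plane degrees of freedom; the 3D model has no
  apico-basal polarity dynamics, basal constriction, or substrate.
* Minimize-mode endpoints at vertex-merger configurations are energy
  minima of the regularized landscape; different descent paths can land in
  slightly different merger patterns (the observables reported — mean
  areas, angle distributions, furrow depth — are stable to this).
* The hinge-band layouts idealize hinges as straight rows; real hinges
  curve.
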
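---
title: "Cell-based mechanics of epithelial monolayers on elastic substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-based mechanics of epithelial monolayers on elastic substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`episheet` simulates how elastic forces spread through an epithelial
monolayer that adheres to a deformable substrate, on timescales (seconds to
tens of minutes) short enough that the response is dominated by elasticity
rather than by cytoskeletal remodeling. This vignette is the package's own
account of the model, its parameters, the numerical choices, and what the
simulations can and cannot say about real tissue.

## The model

### Cells

Each cell is a closed two-dimensional polygon representing the apical
junctional outline of the cell; polygon vertices stand for material points
of the cell-cell junction belt. Subcellular structures enter as forces on
the vertices. The total force on vertex $i$ is the superposition

$$\mathbf F_{i,tot} = \mathbf F_{i,cort} + \mathbf F_{i,junc} +
  \mathbf F_{i,area} + \mathbf F_{i,div} + \mathbf F_{i,fa} +
  \mathbf F_{i,mem} + \mathbf F_{i,cont} + \mathbf F_{i,edge},$$

with largely Hookean ingredients:

* **Cortical actomyosin** — every membrane segment carries a line tension
  $T = k_{cort,const} + k_{cort,perim}\,(P - P_0)$: a constant prestress
  plus a perimeter-elastic part about the rest perimeter
  $P_0 = c_{P0}\sqrt{A_0}$. The tension pulls each vertex toward both
  neighbors. A concave (reflex) vertex additionally receives an outward
  push of magnitude $T\,\Delta\theta$ along the outward bisector, where
  $\Delta\theta$ is the turning-angle deficit: the discrete analogue of the
  cortical chord that runs behind such a vertex and presses it outward.
* **Internal pressure** — a pressure proportional to the relative area
  deficit, $k_{area}(A_0 - A)/A_0$, applied along the area gradient
  (equivalently: outward normals weighted by adjacent segment lengths).
  Expansive below the target area, compressive above it.
* **Cell–cell junctions** — zero-rest-length springs of constant $k_{junc}$
  between paired vertices of neighboring cells. Pairing is dynamic (below).
* **Membrane elasticity** — each segment is a spring about its rest length
  with strain normalization, tension $k_{mem}(l-l_0)/l_0$, so that vertex
  insertion or removal leaves the net stiffness of a membrane region
  unchanged.
* **Contact** — a vertex penetrating a foreign membrane segment by depth
  $\delta$ is pushed back along that segment's outward normal with force
  $k_{cont}(\delta - \delta_s/2)$ beyond a quadratic onset below
  $\delta_s = 0.1$ µm (the smoothing keeps the force $C^1$ at first touch
  and spares the step controller from chattering on grazing contacts); the
  reaction is shared by the segment endpoints by projection weights, so
  contacts inject no net momentum.
* **Edge** — vertices on the epithelium rim are tied by springs of
  constant $k_{edge}$ to their positions at placement time, standing in
  for the monolayer that continues beyond the simulated patch.
* **Division furrow** — a dividing cell constricts: membrane regions
  nearest the cleavage line (through the centroid along the short
  principal axis of the vertex scatter) are pulled toward it with a
  Gaussian weight in the distance from that line; the field is projected
  free of net force and torque.

### Substrate

The gel surface is a triangular lattice of points with spacing $h$
(default 2 µm) whose mechanics are three forces: *central* springs along
every lattice edge (rest length $h$), a short-range *repulsive* force
between each point and the opposite edge of its triangles that activates
below $h/2$ and prevents collapse under large compression, and a
*restorative* spring that pulls every point to its original position,
carrying the stiffness contributed by the finite gel thickness bonded to
glass.

The two spring constants are calibrated, per Young's modulus $E$, so that
a unit tangential point load on the lattice reproduces the surface
displacement of a bonded incompressible elastic layer (thickness 100 µm,
$\nu = 0.5$) over 1–10 lattice spacings. The reference is the
angle-averaged Cerruti surface solution regularized over the lattice's
load-spreading scale ($0.75h$), with an exponential finite-thickness
cutoff; the fitted lattice profile matches it to within 14% (maximum
relative deviation over the fit range), and both constants are exactly
linear in $E$. The calibration is solved once per $(\nu, h,$ thickness$)$
and cached.

### Focal adhesions

Every cell vertex is anchored to the substrate by a rupturable spring. The
anchor point is the vertex's position at attachment time expressed in
barycentric coordinates of its containing lattice triangle, so it moves
with the substrate material and the spring measures cell-versus-substrate
slip. Because the polygon lives in the apical plane, this spring lumps
together the focal adhesion proper and the apico-basal elasticity of the
cell body. Its strength is $k_{fa}(E)$ per micrometre of represented
membrane, with $k_{fa}$ interpolated through the calibrated values 0.5,
0.8 and 1.0 g/s²/µm at 1.1, 4.5 and 11 kPa — stiffer substrates make
stronger adhesions.

On the minutes timescale of remodeling-enabled runs, adhesions turn over:
each anchor carries a Maxwell slack that relaxes the spring extension
toward zero with time constant `tau_fa` (300 s, in the range of measured
focal-adhesion lifetimes). The sheet is thus elastically anchored on
second timescales (micromanipulation) but can slowly slide over the
substrate on minute timescales (optogenetic contraction), transmitting
only the weak unrelaxed part of the adhesion force down to the gel.
Structural remodeling carries adhesions through topology changes
stress-preservingly: a vertex merge combines the two anchors (material
midpoint, summed strength) and an inserted vertex inherits the material
midpoint of its neighbors' anchors, so remodeling neither discards nor
resets adhesion load.

An anchor breaks irreversibly when its spring force exceeds
`f_fa_rupture` (22 AU) on two consecutive between-step checks (the
confirmation filters single-step integration overshoot) or its extension
exceeds `d_fa_rupture` (25 µm).
The force route carries the stiffness dependence of detachment: identical
slips load anchors on stiff substrates about twice as hard (via
$k_{fa}$), and the weaker substrate displacement there increases the slip
itself, so detachment incidence grows with stiffness and vanishes on the
softest gel — the experimentally observed ordering — without any
stiffness-specific rupture parameter.

### Dynamics

The system is overdamped: $\eta\,\dot{\mathbf r}_i = \mathbf F_{i,tot}$
for cell vertices and $\eta\,\dot{\mathbf s}_m = \mathbf F_{m,tot}$ for
substrate points. Integration uses explicit Runge–Kutta — 2nd order when
the substrate is absent (growth), 4th order when present — with variable
steps controlled by step-doubling: a step is compared against two half
steps, halved while the discrepancy exceeds `err_tol`, and grown by at
most 1.5× when it falls below a tenth of it. The doubling check runs every
third step; between checks the last accepted step is reused. Substrate
points enter the error estimate with weight 1/5: they are slaved,
contractive linear modes whose per-step error relaxes rather than
accumulates, and an unweighted estimate lets stiff-substrate transients
throttle the step far below what trajectory accuracy requires.

Because the dynamics are overdamped, $\eta$ only fixes the clock. Each
scenario therefore runs on the clock that makes its protocol quasi-static
at its measurement times while staying integrable: growth uses
$\eta = 1$ g/s, micromanipulation $\eta = 0.1$ g/s (the 30 µm/s pull is
then ~50× slower than cell relaxation, and the state is read out after a
1 s settle), and the minutes-long optogenetic protocol a slow clock that
scales with the stiffest substrate modulus in the field
(`opto_params()`: $\eta = 40$ g/s at 1.1 kPa up to 400 g/s at 11 kPa),
which keeps the explicit integrator's stable step roughly
stiffness-independent while the slowest junction mode still relaxes an
order of magnitude faster than the 20-minute activation window — the
end-of-window readouts are clock-independent.

### Structural remodeling

Between integration steps (never inside a Runge–Kutta stage):

* membrane segments longer than `l_max` (3 µm) gain a midpoint vertex;
  segments shorter than `l_min` (1 µm) merge their endpoints, with rest
  lengths, links and anchors carried through;
* junction links stretched beyond `d_junc_unpair` (1.6 µm) dissolve; free
  facing vertices of distinct cells within `d_junc_pair` (0.8 µm) pair up,
  nearest first, one partner per vertex. A candidate pair whose midpoint
  lies inside a third cell is rejected, and an existing link that becomes
  threaded through a third cell is dissolved — without this, distance-only
  pairing occasionally links vertices straight through an interposed
  membrane wedge and leaves permanently frustrated stress;
* in growth mode, cells whose division clock expired constrict for
  `T_furrow` and are then split along the cleavage line, conserving the
  parent's area exactly; daughters draw fresh target areas and division
  times.

Micromanipulation freezes all remodeling (the experiment probes the
elastic response over one second); optogenetic runs keep it enabled.

## Virtual experiments

**Growth.** An epithelium grows from a single 16-gon by timed divisions
(normally distributed intervals, mean 10 s on the growth clock — a
compressed division cycle whose absolute scale is irrelevant; only the
ordering and spread shape the tissue) without substrate or edge forces,
then relaxes division-free until the maximum residual force falls below
0.05 AU. Target areas are drawn from a normal distribution (mean 90 µm²,
CV 0.15, in the range of cultured kidney-epithelium cells).

**Micromanipulation.** The grown tissue is placed on a lattice, every
vertex is anchored, rim vertices get edge anchors, and the frame is
centered on the manipulated cell. The pipette grabs the contiguous vertex
arc within 4 µm of the cell's leading pole and translates it kinematically
at 30 µm/s over 30 µm (20 µm in gradient scenarios). Grabbing releases
those vertices' own adhesions — the pipette presses onto the apical
surface and mechanically decouples that membrane patch from the substrate
— and these releases are not counted as detachment events.

**Optogenetic activation.** Both cortical tension constants are multiplied
(default 13×) for the vertices of the two chosen cells that currently lie
inside a fixed rectangle enclosing their shared junction run, from minute
2 to minute 22. The activation is positional — re-evaluated between steps,
like the illuminated region it models — which caps the activated membrane
length and prevents a runaway neighbor-exchange collapse that occurs if
activation flags travel with the contracting vertices. The relative
junction length $L/L_0$ (measured over the membrane span between the
outermost linked vertices, i.e. between the bounding triple points) is
tracked through remodeling; the substrate displacement between the
window's endpoints is sampled along the junction axis, and the largest
smoothed peak on each side of the junction center is averaged into the
peak statistic, paired with half the junction length change. The
multiplier was calibrated as the deepest contraction on the stable branch
of the response (see Known limitations).

**Gradient scenarios.** `make_gradient_scenarios()` builds the cartesian
product of interface distances (20–80 µm) and ramp widths (2 µm interface,
10 µm sharp, 50 µm shallow), in both soft-to-stiff and stiff-to-soft
orientations, plus the two uniform controls.

## Analyses

Displacement and force maps assign per-cell quantities (centroid
displacements; mean per-vertex force magnitudes of the adhesion, cortical
or junction component) to the original cell centers and interpolate them
linearly on a 1 µm grid — a triangulation-based interpolant, exact at its
sample sites, averaged over runs on a common grid. Substrate maps sample
the lattice points directly and interpolate with the lattice's own
triangles. Axis profiles follow the tension side of the pull (the negative
y half-plane); difference profiles subtract a uniform-control profile from
a gradient profile on the same grid.

## Numerical choices

* `err_tol` (step-doubling position discrepancy per step): 0.1 µm during
  the coupled scenarios, 0.3 µm during growth, 0.03 µm during the final
  growth relaxation. The coarse growth tolerance lets the integrator ride
  near the stability limit while the tissue's geometry is being produced;
  the tight relaxation tolerance prevents contact-overshoot oscillation
  from masking equilibrium.
* The pressure force saturates for transiently pinched polygons
  (area clamped at 2% of target) so that Runge–Kutta trial stages cannot
  abort on a state the dynamics would recover from; the user-facing
  single-cell operation still rejects non-positive areas.
* Contact candidates (vertex/foreign-segment pairs within 2.4 µm) are
  cached and refreshed when topology changes or any vertex has drifted by
  more than 0.5 µm.
* Snapshots are versioned JSON with 17-significant-digit numerics; a
  reloaded state continues bit-identically (tested), which makes runs
  reproducible from their manifest (config, seed, package version).

## Problem sizes

The package's own test and reproduction runs use desk-scale tissues: 16-cell
tissues for optogenetic runs (10 seeds per stiffness), ~30 cells (radius
~30 µm) for the uniform-substrate micromanipulations (5 seeds), and ~19
cells with 20 µm pulls for the gradient comparisons. The manipulated-cell
readouts are local and insensitive to tissue radius once a few cell rings
surround the center (the edge anchors carry the far field); the long-range
tails of the displacement maps, however, are truncated by the patch size,
so map comparisons are made between runs of identical geometry.

## What the generator does and does not emulate

Grown tissues reproduce the polygonal disorder, area dispersion and
junction topology of a confluent monolayer, which is what the mechanical
response probes. They do not emulate biological variability in material
properties (all cells share one parameter set), apico-basal shape,
nuclear mechanics, viscous or active remodeling of the cortex on long
timescales, or strain-dependent junction tension remodeling (deliberately
excluded: it mainly affects the permanent post-activation junction length,
not the within-window response studied here). Passing tests therefore
demonstrate correct elastic mechanics and force bookkeeping on idealized
tissue, not predictive power for any particular biological sample.

## Known limitations

* The substrate model is calibrated and validated for 1.1–11 kPa; requests
  outside that range load with a warning and are not trustworthy (a
  ~35 kPa gel is beyond what this lattice formulation reproduces).
* Under the extreme stretch of a 30 µm pull with frozen remodeling, the
  manipulated cell's polygon can transiently self-intersect near the
  grabbed tongue; areas stay positive and centroid readouts remain
  well-defined, but the local shape there should not be over-interpreted.
* Force transmission perpendicular to the pull on very soft substrates is
  under-represented, as expected for linear springs at large strain.
* The optogenetic junction contraction is bistable in the contractility
  multiplier: the stable branch saturates at $L/L_0 \approx 0.84$–$0.90$
  (a fast elastic drop to ~0.90 plus slow adhesion-turnover creep),
  insensitive to the junction spring constant, pairing distances,
  activation-rectangle width and adhesion strength, and above roughly 20×
  the junction collapses outright (a T1-like neighbor exchange). Deeper
  intermediate plateaus, as reported for light-activated junctions in
  epithelia on soft gels (relative lengths around two thirds), are not
  reachable at this cell-side parameter set; the *relative* behaviors —
  soft substrates contracting at least as much as stiff ones, and the
  very weak substrate coupling of the shortening (displacement peaks of
  order a tenth of the half length change on 1.1 kPa) — are reproduced.
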
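# episheet

Cell-based mechanics of epithelial monolayers on elastic substrates.

Epithelial cells form tightly connected sheets that sense and transmit
mechanical forces — between each other through their cell–cell junctions
and cortical cytoskeleton, and into the extracellular matrix through focal
adhesions. How far a mechanical perturbation travels through such a sheet
depends strongly on the stiffness of the substrate underneath, and spatial
stiffness heterogeneity (a stiff tumor in soft tissue, say) reshapes that
force transmission. `episheet` is a simulation package for studying these
questions over short, elastically dominated timescales: seconds for a
micromanipulated cell, minutes for an optogenetically contracted junction.

It is aimed at mechanobiologists and modelers who want a cell-resolved
(not continuum) description of a monolayer *coupled to a deformable
substrate*, with the substrate's stiffness — including interfaces and
gradients — as a first-class experimental variable.

## The model in brief

Cells are closed 2D polygons at the apical junction plane; vertex `i`
moves by overdamped dynamics

    eta dr_i/dt = F_cort + F_junc + F_area + F_div + F_fa + F_mem + F_cont + F_edge

with cortical line tension `T = k_c + k_p (P - P0)` (plus an outward push
at concave vertices), pressure `k_area (A0 - A)/A0`, zero-rest-length
junction springs between paired vertices of neighboring cells,
strain-normalized membrane springs, anti-overlap contact forces, edge
anchors standing in for the surrounding monolayer, and a division furrow
during growth. The substrate surface is a triangular spring lattice
(`eta ds_m/dt = F_cent + F_rep + F_rest + F_fa`) calibrated so that a
point load reproduces the surface displacement of a bonded incompressible
elastic layer of the given Young's modulus; focal adhesions are rupturable
springs between cell vertices and substrate material points, with
stiffness-dependent strength (0.5 / 0.8 / 1.0 g/s²/µm at 1.1 / 4.5 /
11 kPa). Units: µm, s, g; forces in AU = g·µm/s².

Virtual experiments: epithelium growth from a single cell
(`grow_epithelium()`), single-cell micromanipulation at 30 µm/s on uniform
or graded-stiffness substrates (`run_micromanipulation()`,
`make_gradient_scenarios()`), and optogenetic junction contraction
(`run_optogenetic()`). Analyses turn trajectories into displacement and
force maps (`cell_displacement_map()`, `substrate_displacement_map()`,
`force_map()`), axis and difference profiles (`axis_profile()`,
`difference_profile()`) and junction metrics (`junction_metrics()`), all
returning tibbles or plottable field maps (`autoplot()`); trajectories
have `tidy()`/`glance()` methods. See the methods vignette
(`vignettes/epithelial-mechanics.Rmd`) for the full model description.

## Worked example

Grow a small epithelium, place it on a soft 1.1 kPa gel, pull one cell
30 µm with a virtual pipette, and summarize:

```r
library(episheet)

st <- grow_epithelium(seed = 7, target_cell_count = 19)
pl <- place_on_substrate(st, stiffness_field("uniform", 1.1))
tr <- run_micromanipulation(pl, pipette_protocol(distance = 30, speed = 30))
glance(tr)
#> # A tibble: 1 × 6
#>   n_cells manipulated_cell cell_center_displacement max_substrate_displacement
#>     <int>            <int>                    <dbl>                      <dbl>
#> 1      19               15                     13.8                       10.4
#> # ... with 2 more variables: n_ruptures <int>, pipette_distance <dbl>
```

The pipette moved 30 µm but the cell's center only ~14 µm — the cell
stretches — and the gel surface underneath moved at most ~10 µm: the
apico-basal compliance folded into the adhesion springs partially isolates
the substrate from the apical plane. On this softest gel no adhesion
ruptures; repeating on 4.5 and 11 kPa gives smaller substrate
displacements and increasing detachment near the pipette. Maps and
profiles come from the analysis layer:

```r
m <- cell_displacement_map(tr)
axis_profile(m, "parallel")      # decay of |u| along the pull direction
autoplot(m)
```

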
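# nfvm — vertex-model mechanics and morphometrics of neural plate folding

During neural tube closure, only a subpopulation of neuroepithelial cells
apically constrict; their neighbors passively expand and elongate along the
anteroposterior (AP) axis. `nfvm` implements the computational side of that
story for modellers and quantitative cell biologists:

* a **2D vertex model** of the neural plate — polygonal cells with the
  area-and-perimeter elasticity energy
  $e=\sum_c[(a^{(c)}-1)^2+k_p(p^{(c)}-p_0^{(c)})^2]$, a centered plate
  region whose cells constrict with probability $P_c$ (target perimeter
  reduced to 10%), a frozen outer ring, and overdamped dynamics
  $\dot r_i=-\nabla_{r_i}e$ (explicit Euler, or a compiled quasi-Newton
  `minimize` mode that reaches the same fixed point);
* a **3D vertex model** of hinge furrowing — unit-volume prism cells with
  surface tensions $\alpha=\beta=0.5$, apical perimeter elasticity
  ($k_p=1$) and a volume penalty ($k_V=100$), periodic along AP, with a
  3-cell-wide constricting band;
* **morphometrics** for segmented label images — second-moment aspect
  ratio/orientation, junction and cytoplasm intensities via dilated/eroded
  masks, AC/AE classification of apical-area tracks (±20% rule), CV
  statistics;
* a **synthetic-data generator** (weighted tessellations with ground truth,
  junctional intensity channels, area tracks) so the whole pipeline runs
  with no external data;
* an **experiment registry** (`run_experiment()`) with thin drivers under
  `analysis/` that write the tables behind each in-silico figure panel.

## Worked example

Relax the default neural-plate geometry (100×60 tissue, 60×20 plate) at
half constriction probability and quantify the passive response:

```r
library(nfvm)

tz <- build_hex_lattice(100, 60, 60, 20)           # 6000 unit-area hexagons
tz <- assign_constriction(tz, sim_config2d("uniform", pc = 0.5, seed = 1))
a0 <- energy_measures <- nfvm:::tissue_measures(tz)[, "area"]

r  <- relax2d(tz, sim_config2d(mode = "minimize"))  # ~40 s on one CPU
st <- plate_cell_stats(r$tissue)

a1  <- nfvm:::tissue_measures(r$tissue)[, "area"]
sel <- tz$region == "plate" & !tz$constricting
mean(a1[sel]) / mean(a0[sel])
#> [1] 0.9128244
st$mean_angle
#> [1] 34.70489
```

The non-constricting plate cells end ~9% smaller than they started — they
elongate rather than expand — and their elongation axes average ~35° to
the AP axis (45° would be no alignment), with the angle histogram peaked
at 0°. In 3D, `build_prism_tissue()` + `relax3d()` + `furrow_profile()`
show a shallow apical furrow at $P_c=0.5$ that deepens at $P_c=1$.

The scripts in `analysis/` run the full set of named experiments
(constriction-probability sweep, constricting-region aspect-ratio sweep,
exterior-geometry variants, two-hinge layout, 3D furrow) and write their
tables under `results/`; pass `--tier full` for the original lattice
sizes.

## Package layout

| Path | Contents |
| --- | --- |
| `R/lattice.R` | hexagonal lattice construction, polygon and gyration-tensor geometry, JSON/OFF/VTK export |
| `R/vertex2d.R`, `R/vertex3d.R` | the two vertex models: constriction, energies, forces, relaxation, tissue measurements |
| `R/morphometrics.R` | label-image metrics, junction/cytoplasm intensities, track classification, dispersion stats |
| `R/synthetic.R` | tissue/track generators with ground truth |
| `R/experiments.R` | named experiment registry |
| `src/` | Rcpp kernels: energies, analytic gradients, Euler, L-BFGS+FIRE |
| `analysis/` | numbered drivers writing `results/` tables |
| `vignettes/vertex-models.Rmd` | the models, conventions, numerical choices and limitations |
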
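# bnctplan

Treatment-planning toolkit for **accelerator-based boron neutron capture
therapy (BNCT) of superficial tumors** using two overlapped irradiation
fields.

In BNCT the tumor dose is driven by the product of thermal neutron flux and
tissue ¹⁰B concentration, and the irradiation time is prescribed by normal
tissue tolerance (skin 12 Gy-eq, brain 15 Gy-eq). For a wide superficial
tumor under a 15-cm collimator the thermal flux is center-peaked, so the
dose minimum sits at the tumor margin. `bnctplan` plans *intensity-modulated*
irradiation: a uniform 2-cm polyethylene disk field (IF-A) is overlapped
with a center-shielded LiF-polyethylene pattern field (IF-B) for times in
ratio 1:r,

```
F_IM = (F_A + r · F_B) / (1 + r),        r ∈ {2, 3, 4, 5}
```

and the package selects the IF-B block pattern, block thickness (2–5 cm)
and time ratio that **maximize the minimum tumor dose**, reporting the
homogeneity index HI = (D₂ − D₉₈)/D₅₀ over the tumor dose–volume histogram
and the surface flux uniformity index u = Σ|100·(1 − φᵢ/φ_av)|/7.

The package provides:

* the combinatorial catalog of modulator shapes on the 6×6 aperture grid —
  64 Criterion-1 shapes (growth from the 2×2 core into the inner ring),
  41 Criterion-2 shapes (perimeter growth around the filled inner ring) and
  the all-filled shape: 106 shapes, 424 configurations;
* a deterministic kernel-superposition transport engine (Gaussian lateral
  spread × depth profile with surface buildup) for thermal/fast neutron
  flux and gamma dose rate, with a brute-force dense-sum oracle for
  verification;
* RBE/CBE-weighted equivalent dose (RBE 2.4 hydrogen, 2.9 nitrogen, 1.0
  gamma; boron CBE 3.8 tumor / 2.5 skin / 1.34 brain; 24 ppm blood boron,
  T/B 3.5, S/B 1.0), normal-tissue prescription, DVH metrics;
* the exhaustive 1696-candidate optimizer with IF-A baseline comparison and
  sensitivity sweeps over blood boron and the skin S/B ratio;
* three voxelized head-phantom fixtures (wide 100×10 mm disk tumor, small
  40×40×20 mm tumor, asymmetric tumor), YAML run configuration, CSV/JSON
  artifact output and a command-line front end (`exec/bnctplan`).

## Worked example

```r
library(bnctplan)

phantom <- make_head_phantom("wide_disk", voxel_size = 0.5)
result  <- optimize_plan(phantom)     # 424 configs x 4 time ratios
result
#> Optimal intensity-modulated plan
#>   FULL_t2 at time ratio 1:2 -> D_min 27.72 Gy-eq, HI 0.317, 97.0 min (skin-limited)
#>   IF-A baseline       -> D_min 19.25 Gy-eq, HI 0.741, 56.5 min (skin-limited)
#>   improvement: D_min +44.1%, HI -57%
```

For this 10-cm-wide, 1-cm-thick tumor the best plan shields the whole
central 6×6 block with thin (2 cm) LiF-PE and spends two thirds of a longer
irradiation on the edge-peaked field: the minimum tumor dose rises 44 %
and the dose homogeneity index drops by more than half, at the cost of a
longer irradiation — the characteristic trade-off of intensity-modulated
BNCT. The surface thermal flux flattens accordingly:

```r
grid <- build_aperture_grid()
beam <- beam_model()
lay  <- make_evaluation_layout(phantom)
m_a  <- flux_map(aperture_emission(beam, if_a_pattern(), grid), phantom, beam)
best <- shape_to_pattern(build_catalog(grid)$shapes[[result$best$shape_id]],
                         result$best$thickness_cm)
m_b  <- flux_map(aperture_emission(beam, best, grid), phantom, beam)
u_a  <- uniformity_index(flux_at_points(m_a, lay))
u_im <- uniformity_index(flux_at_points(combine_fields(m_a, m_b, result$best$ratio), lay))
c(u_a = u_a, u_im = u_im)
#>      u_a     u_im
#> 24.44...  4.20...
```

The full pipeline with file outputs (phantom grid, `catalog.json`,
`candidates.csv`, `best_plan.json`, `scatter.csv`, DVH curves, `run.log`):

```r
run_all(load_config(), out_dir = "results-wide")
```

or from a shell:

```sh
Rscript exec/bnctplan run-all --out results-wide
Rscript exec/bnctplan enumerate-patterns --thicknesses 2,3,4,5 --out catalog.json
Rscript exec/bnctplan metrics --flux 1,1,1,1,1,1,2
```

## Package layout

* `R/geometry.R` — aperture grid, head phantoms, evaluation-point layout
* `R/patterns.R` — modulator patterns and the shape catalog
* `R/flux.R` — beam model and kernel transport engine (+ dense oracle)
* `R/dose.R` — equivalent dose, field combination, prescription
* `R/metrics.R` — DVH, homogeneity index, uniformity index
* `R/optimizer.R` — exhaustive search, baseline, sensitivity sweeps
* `R/io.R` — array-grid/JSON/YAML formats and the `run_all()` pipeline
* `vignettes/intensity-modulated-bnct-planning.Rmd` — models, calibration
  and design choices
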
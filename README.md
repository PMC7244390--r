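# cerebsim

Simulation toolkit for quantifying how cortical and cerebellar folding
attenuates MEG and EEG signals.

## The problem

The cerebellar cortex is folded at two scales: large lobular folds carry
fine folia only 1–2 mm wide. Dipolar neural currents sit perpendicular to
the cortical sheet, so opposed walls of a fold carry nearly antiparallel
dipoles whose magnetic fields and surface potentials cancel at the sensors.
Whether cerebellar activity is detectable with MEG/EEG therefore hinges on
how much signal survives this cancelation — and on how badly a smoothed
segmentation (which erases the folia) overestimates the surviving signal.
`cerebsim` provides the full simulation chain to study this on synthetic,
reproducible anatomy: folded source surfaces, sensor arrays, dipole forward
models, Monte Carlo cancelation statistics, and per-vertex sensitivity
maps.

## The statistics at its core

For a gain (lead-field) matrix `G` whose column `G[, j]` is the sensor
signal of unit current dipole `j`, and a set of `n` simultaneously active
dipoles:

* net signal `A_n = || Σ_j G[, j] ||₂` (all dipoles active together),
* absolute signal `B_n = Σ_j || G[, j] ||₂` (each dipole active alone),
* conservation factor `C = A/B ∈ [0, 1]` — `C = 1` means no cancelation,
  `C = 0` complete cancelation; `1 − C` is the cancelation index,
* physiological norms `α = A·a_n·q0/n`, `β = B·a_n·q0/n`, which scale the
  activated patch (area `a_n`) to the standard current-dipole density
  `q0 = 1 nAm/mm²`; `C = α/β`,
* cortex-normalized curves `C̃(r) = C_cb(r)/C̄_ctx(r)` etc., relating a
  cerebellum-like surface to the cortex-like reference at equal patch
  radius.

Forward models: the closed-form magnetic field of a dipole in a spherically
symmetric conductor, a concentric three-shell (brain/skull/scalp,
0.3/0.006/0.3 S/m) Legendre-series scalp potential, and a three-compartment
boundary-element method with linear collocation for non-spherical
conductors, cross-validated against the analytic models.

## A worked example

```r
library(cerebsim)

head  <- head_model()                       # 80/85/92 mm, 0.3/0.006/0.3 S/m
mesh  <- generate_folded_sheet(default_recipes(1)[["cortex-like"]],
                               max_radius = 80)
src   <- source_space(mesh, boundary = head, min_dist = 5)
sens  <- combine_arrays(generate_helmet_array(),      # 102 sites, 306 ch
                        generate_electrode_array())   # 72 electrodes
gain  <- compute_gain(src, sens)

des <- experiment_design("distributed", n_grid = c(1, 9, 100, 10000),
                         samples = 200, seed = 1)
mc  <- run_distributed(des, list(cortex = gain))
subset(mc$summary, modality == "mag",
       select = c(n, C_mean, C_sd))
#>      n      C_mean        C_sd
#>      1 1.000000000 0.000000000
#>      9 0.355806483 0.097559950
#>    100 0.100458748 0.027661715
#>  10000 0.007504765 0.001245818
```

A single dipole conserves its signal exactly (`C = 1`); nine randomly
placed dipoles already cancel to a mean `C ≈ 0.36`; ten thousand dipoles
cancel almost completely (`C ≈ 0.0075`), following the `1/√n` law for
weakly correlated sources. Coherent patches are run the same way with
`run_coherent()`, and `sensitivity_map()` gives per-vertex signal norms
for a 100 nAm dipole:

```r
map <- sensitivity_map(gain, "mag", moment = 100)
percentile_clip(map)      # 1st–99th percentile display range, Tesla
```

The whole chain (anatomy → sensors → gain → Monte Carlo → sensitivity →
report) runs from one configuration via `run_pipeline(default_config())`,
or from a shell through the thin wrapper `inst/cli/cerebsim`.

## Scope and caveats

The synthetic two-scale sinusoidal surfaces reproduce the geometric
mechanism of cancelation (opposed fold walls), not any subject's anatomy;
absolute curve values are geometry-specific. The methods vignette
(`vignettes/cancelation-methods.Rmd`) documents the model assumptions, the
default study conditions, and the known limitations of the open-cap
surrogate — in particular which asymptotic results are MEG-specific there.
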
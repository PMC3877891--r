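# raftperm

Quantitative analysis of raft-targeting membrane permeabilization.

Some cyclodepsipeptide drugs kill cells not through a protein receptor but
by binding 2-hydroxylated lipids in cholesterol/sphingolipid-rich membrane
microdomains (lipid rafts), oligomerizing in the membrane, and opening pores
once the oligomer density passes a critical level. The experimental
signature of this mechanism is a sharp mismatch between two dose–response
curves measured on the same cells: *binding* of the fluorescent drug is
non-cooperative (Hill coefficient near 1), while *killing* (membrane
permeabilization, scored by propidium-iodide uptake) is steeply cooperative
(Hill coefficient 3–4). `raftperm` packages the analysis chain used to
establish and exploit that signature:

- **Number & Brightness (N&B)** analysis of confocal photon-count image
  stacks: per-pixel apparent brightness `B = σ²/⟨k⟩`, molecular brightness
  `ε = B − 1` (photons per diffusing unit per dwell time — 2× for a dimer),
  integer-shift registration, and stack QC (≤10% mean decay,
  cumulative-mean convergence).
- **Image quantification**: manually seeded watershed membrane masks,
  background-corrected membrane intensity, a bright-spot counter
  (Gauss → normalize → white top-hat → extended maxima → fill → shrink to
  points), pixelwise colocalization, and PI-positive fractions.
- **Hill dose–response fitting**
  `R(c) = bottom + (top−bottom)·cⁿ/(cⁿ + EC50ⁿ)` with profiled plateaus,
  multi-start search, and binding-vs-killing cooperativity reports.
- **Oligomer-threshold model**: Langmuir binding `b = S·c/(c+K_d)`,
  mass-action m-mer density `ρ_m = k·bᵐ`, and a log-normal per-cell kill
  threshold giving `P(c) = Φ((ln ρ_m − ln θ)/σ_θ)` — cooperative killing
  emerging from non-cooperative binding, with IC50-vs-site-density
  predictions for resistant (e.g. hypoxic) cells.
- **Uptake kinetics**: closed-form two-compartment binding/internalization
  traces and the initial-slope estimator of membrane binding.
- **Membrane probes**: l-format fluorescence anisotropy
  `r = (I_vv − G·I_vh)/(I_vv + 2G·I_vh)` and Laurdan generalized
  polarization `GP = (I_blue − I_red)/(I_blue + I_red)`.
- **Statistics**: Pearson/Spearman correlations with Fisher z-transform
  confidence intervals.
- **Synthetic data** for all of the above with known ground truth (Poisson
  photon detection over fluctuating emitter occupancy, membrane rims,
  punctate spot fields, dose–response tables, uptake traces, cell-line
  panels), so every estimator is testable without microscope data.

## Worked example

```r
library(raftperm)

## the shipped demo regime: Kd = 5.1 uM, m = 4, threshold calibrated so
## the killing IC50 is 10.2 uM
regime <- demo_regime()
conc <- exp(seq(log(0.3), log(300), length.out = 8))
binding <- fit_hill(data.frame(concentration = conc,
                               response = bound_density(conc, regime)))
killing <- apparent_hill_of_killing(regime,
                                    exp(seq(log(0.5), log(80), length.out = 25)))
compare_binding_killing(binding, killing)
#> binding n = 1.00 (non-cooperative), killing n = 3.61 (cooperative)
#>   EC50 ratio (killing/binding) = 2.069, Hill ratio = 3.613
```

Binding stays Langmuir (n = 1.00) for every oligomer order; the killing
curve steepens to n ≈ 3.6 purely because permeabilization is attributed to
tetramers crossing a threshold. The EC50 ratio ≈ 2 reproduces the
binding-before-killing offset (half-binding at 5.1 µM vs half-killing at
10.2 µM).

```r
## N&B on a simulated stack with molecular brightness 0.2
g <- gen_nb_stack(nb_sim_params(mean_occupancy = 2, epsilon = 0.2,
                                n_frames = 2000, height = 64, width = 64,
                                seed = 1))
qc_stack(g$stack)
#> stack QC: ACCEPTED
#>   mean decay fraction: 0.0026
#>   convergence slope: -1.186
molecular_brightness(pixel_moments(g$stack))
#> molecular brightness: median 0.1984 (MAD 0.0447), pooled 0.1997, n = 4096 px

## spot counting: 12 planted spots plus one large blob -> exactly 12
sp <- gen_spot_image(spot_sim_params(n_spots = 12, n_large_blobs = 1,
                                     seed = 3, noise_sd = 1))
count_bright_spots(sp$image)$count
#> [1] 12

## IC50 vs marker-level correlation with a Fisher-z interval
correlation_with_ci(c(7.8, 15, 7.5, 9.1, 1.4, 3.6, 2.4),
                    c(60, 35, 62, 55, 98, 80, 88))
#> pearson r = -0.986 (n = 7), 95% CI [-0.998, -0.902]
```

The pooled brightness 0.1997 recovers the simulated ε = 0.2 (a monomer
reference would make a dimer stack report a ratio of 2.0); the accepted QC
report shows the two stack-health statistics (mean decay below the 10%
cutoff, cumulative-mean variance decaying with log-log slope ≈ −1).

## Command line

```sh
Rscript inst/cli/raftperm.R hill --data dose.csv --constrain bottom=0,top=1 --out fit.json
Rscript inst/cli/raftperm.R spots --image img.pgm --sigma 1.5 --tophat 8 --h 0.1 --out spots.json
Rscript inst/cli/raftperm.R oligomer hill --out coop.json
Rscript inst/cli/raftperm.R simulate nb --config nb.json --out stack.txt --seed 1
```

All files are plain text: ASCII PGM images, CSV tables, JSON configs and
results (ground truth lands in `*.truth.json` sidecars).

## Documentation

The methods vignette (`vignettes/raftperm-methods.Rmd`) describes the
models, the estimator conventions, the synthetic-data generator and its
limits, and every numerically consequential design choice.
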
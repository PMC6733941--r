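# vesolv

Multi-modal analysis of detergent-induced solubilization of sub-micron
lipid vesicles.

## The problem this package addresses

Non-ionic detergents such as Triton X-100 dismantle lipid vesicles in
stages: monomers partition into the bilayer and swell it, mixed
detergent-lipid micelles form, and the membrane finally breaks down with
loss of lipid to solution. For large unilamellar vesicles (LUVs, 100-200
nm) these steps are invisible to diffraction-limited microscopy. They can,
however, be separated with single-vesicle FRET: membrane dyes (DiI/DiD)
report vesicle **swelling** as a drop in apparent FRET efficiency
`E = I_A / (I_A + I_D)` at constant total intensity, and **lysis** as a
loss of total intensity `I_D + I_A` at constant efficiency. Each phase is
exponential with its own half-life:

    E(t)     = E_p + (E_0 - E_p) * 2^(-(t - t0)/t_E)          (swelling, t_E)
    I_tot(t) = I_0 * (1 - f_loss * (1 - 2^(-(t - t0)/t_L)))   (lysis,    t_L)

`vesolv` is aimed at single-molecule biophysicists who want a tested,
seeded, end-to-end implementation of this analysis: per-vesicle biphasic
half-life fits on donor trajectories, spot detection and aperture
photometry for dual-channel image stacks, population FRET contour plots,
Hill fits of ensemble titrations `E(c) = A + (B - A) c^n / (k^n + c^n)`,
FCS vesicle sizing (multi-tau correlation, 3D-diffusion + triplet model,
`D = omega_xy^2 / (4 tau_D)`, Stokes-Einstein `R_h = kT / (6 pi eta D)`),
and QCM-D mass-phase analysis via the Sauerbrey relation
`dm = -C df / n`. Since raw data for this experiment class are rarely
deposited, every stage ships with a synthetic-data generator implementing
the forward mechanism above, and the test suite verifies each stage by
parameter recovery.

## Worked example

```r
library(vesolv)

# 1. Single-vesicle kinetics: simulate 20 vesicles at the fastest condition
#    (no cholesterol, 0.16 mM TX-100) and recover both half-lives
params <- solub_params(t_E = 1.2, t_L = 17.6, E0 = 0.46, E_plateau = 0.22,
                       f_loss = 0.5, I_tot0 = 200, t0 = 90, duration = 300)
fits <- lapply(1:20, function(i) {
  fit_biphasic(generate_trajectory(params, seed = i))
})
summarize_condition(fits, "0% chol / 0.16 mM TX-100")
#>                      label  n mean_t_E    sem_t_E mean_t_L   sem_t_L ratio_L_over_E
#> 1 0% chol / 0.16 mM TX-100 20 1.176117 0.03919708 17.54926 0.1100327       14.92136

# 2. Ensemble titration: Hill fit of a noisy dose-response
titr <- generate_titration(hill_params(A = 0.43, B = 0.12, k = 0.39, n = 2),
                           noise_sd = 0.01, replicates = 3, seed = 1)
fit_hill(titr$conc_mM, titr$E)
#> <hill_fit>
#>   A = 0.4328, B = 0.1208, k = 0.3827 mM, n = 1.921 (chi2 = 0.0024)

# 3. FRET geometry of the swelling step
r <- distance_from_fret(c(0.46, 0.22), R0 = 5.3)
#> inter-dye distance: 5.44 -> 6.54 nm (+20.2%)

# 4. FCS sizing of 200 nm vesicles from the diffusion time
D <- diffusion_coefficient(tau_D = 8.0e-3, omega_xy = 0.27e-6)
2e9 * hydrodynamic_radius(D)
#> D = 2.28e-12 m^2/s, hydrodynamic diameter = 215 nm

# 5. QCM-D mass phases from a synthetic solubilization trace
qc <- generate_qcmd_trace(qcmd_sim_params(gain_frac = 0.05, loss_frac = 0.63))
detect_mass_phases(qc, injection_time = 120)
#> <mass_phase_result>
#>   m_vesicle = 70.8, m_peak = 74.34, m_final = 27.51 ng/cm^2
#>   gain = 5%, loss = 63% (peak at 160 s)
```

Reading the numbers: the simulated ensemble recovers the generating
half-lives (1.2 s swelling, 17.6 s lysis) within their SEMs, and their
ratio shows expansion running more than an order of magnitude faster than
lysis. The Hill fit recovers the half-maximal constant near 0.39 mM with
cooperativity near 2. The efficiency drop from 0.46 to 0.22 corresponds to
a ~20% increase in inter-dye separation (to ~6.5 nm with a 5.3 nm Foerster
radius), an 8 ms diffusion time maps to a ~215 nm hydrodynamic diameter,
and the QCM-D phase detector returns the constructed 5% mass gain and 63%
mass loss.

## Pipeline runs

End-to-end seeded runs (simulate -> fit -> report) are driven by a JSON
config; a replica of the reference single-vesicle experiment (105
trajectories) is bundled:

```r
cfg <- system.file("extdata", "config-replica.json", package = "vesolv")
run_pipeline(cfg, out_dir = "run1", seed = 1)
# writes run1/data/*.csv, run1/results/*.json, run1/manifest.json, run1/report.md
```

or from the shell via the thin CLI wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "vesolv.R", package = "vesolv"))')" \
  --config run.json --out run1 --seed 1
```

## Layout

- `R/` - analysis + generators (FRET core, trajectory extraction,
  kinetics, titration, FCS, QCM-D, pipeline)
- `src/` - Rcpp Brownian-dynamics photon-count simulator
- `tests/testthat/` - unit, property and acceptance suites
- `vignettes/solubilization-analysis.Rmd` - models, assumptions, numerical
  choices, limitations
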
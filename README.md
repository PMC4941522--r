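# archdna

Single-molecule mechanics of architectural DNA-binding proteins: forward
models and analysis for tethered particle motion (TPM) and optical-tweezers
force spectroscopy of proteins that **bend**, **bridge**, or **stiffen**
DNA.

Small nucleoid-associated proteins reshape genomes by kinking the double
helix in *cis*, joining remote duplex segments into loops, or polymerizing
into stiff nucleoprotein filaments — and many switch between these modes
with concentration. `archdna` packages the quantitative machinery needed to
model and measure that behaviour:

* **Polymer mechanics** — extensible worm-like chain (eWLC)
  force–extension relations. The high-force Odijk form
  `x = Lc (1 − ½√(kBT/(F·Lp)) + F/K)` above 2 pN, the extensible
  Marko–Siggia interpolation below 0.5 pN, a smooth blend between, plus the
  kinked-chain apparent persistence length
  `1/Lp' = 1/Lp − ln(cos θ)/d` and contour lengthening by partial
  unwinding.
* **TPM forward model** — Metropolis Monte Carlo of a surface-tethered
  discrete WLC (5 nm segments) with a 230 nm reporter bead, hard
  surface/bead exclusion, and protein binding states (kinks, filament
  stiffness overrides, bridged loops). Output: the in-plane RMS excursion
  of the bead, the standard TPM observable.
* **TPM analysis** — drift correction, stuck/asymmetric tether rejection,
  per-tether RMS, single-Gaussian population fits with SEM.
* **FD analysis** — eWLC fitting over 0.5–30 pN, rupture (serration)
  detection with contour-release estimates, overstretching-plateau and
  hysteresis metrics, and binding-mode classification
  (bare / bending / stiffening / bridging).
* **Binding models** — McGhee–von Hippel large-ligand lattice isotherm
  (infinite-lattice closed form and exact finite-lattice transfer matrix),
  neighbour-contact statistics, and a concentration → (apparent Lp, Lc,
  mode weights) map reproducing the two-regime soften-then-recover
  behaviour.
* **Synthetic data** — seeded generators with ground-truth labels for bead
  trajectories (Ornstein–Uhlenbeck confined diffusion + tracking noise +
  drift + decoys) and FD curves (injected saw-tooth ruptures below 40 pN,
  overstretching plateaus, hysteresis).

## Worked example

Simulate the TPM experiment for bare DNA (685 bp tether, 0.46 μm bead) and
for a stiffened protein–DNA filament, then analyze a synthetic tether
population:

```r
library(archdna)

# forward model: bare DNA vs stiff filament
bare  <- sample_tether_ensemble(tether_model(persistence_length = 47.2),
                                n_samples = 20000, seed = 1)
stiff <- sample_tether_ensemble(tether_model(persistence_length = 61),
                                n_samples = 20000, seed = 2)
bead_rms(bare)
#> [1] 170.3611
bead_rms(stiff)
#> [1] 178.5059
```

The bare-tether simulation lands within the experimental band around the
measured ~162 nm for this geometry, and raising only the persistence length
to the filament value raises the RMS — the signature of stiffening read out
by TPM.

```r
# analyze a 50-tether population with 10% stuck-bead decoys
pop <- gen_population(50, trajectory_spec(161.8, duration = 60),
                      rms_jitter = 7, seed = 21, stuck_fraction = 0.1)
sel <- select_tethers(pop$trajectories)
meas <- vapply(sel$accepted, rms_of_trajectory, numeric(1))
population_rms(sqrt(meas^2 - 2 * 10^2))   # invert 10 nm tracking noise
#> <rms_result> 163.0 +/- 1.3 nm (sigma 8.4, N = 45)
```

Fit an eWLC to a noisy synthetic pulling curve and classify binding modes:

```r
p    <- polymer_params(47.2, 16400, 1200)      # Lp nm, Lc nm, K pN
pair <- gen_fd_pair(fd_curve_spec(p, force_noise = 0.5, seed = 4))
fit_ewlc(pair$extension)
#> <ewlc_fit> Lp = 45.88 nm, Lc = 16.435 um, K = 1339 pN (rms resid 0.49 pN, 45 pts)
```

A serrated curve (bridged loops rupturing below 40 pN) is refused by the
fitter and handled by the detector instead:

```r
rp   <- data.frame(force = c(8, 12, 16, 22), release = rep(0.3, 4))
serr <- gen_fd_pair(fd_curve_spec(p, ruptures = rp, seed = 9))
detect_ruptures(serr$extension)[, 1:3]
#>   rupture_force extension_at_event force_drop
#> 1      8.412365           15.68117   3.533341
#> 2     12.401383           16.16117   3.657353
#> 3     17.574446           16.64117   5.836179
#> 4     23.334666           17.12117   7.101447
```

Concentration sweeps tie it together (`?rms_concentration_curve`,
`?predict_mechanics`): a bend-only protein compacts the tether and stays
below the bare RMS at every concentration, while a bend+stiffen protein
dips at intermediate coverage and rises above bare at saturation.

A YAML-configured pipeline (`load_config()` / `run_pipeline()`) and a thin
CLI (`inst/scripts/archdna-cli.R`, subcommands `simulate-fixtures`,
`tpm-analyze`, `fd-fit`, `fd-detect`, `sweep`) wrap the same functions; see
`inst/extdata/example-config.yaml`.

## Package layout

```
R/                  polymer.R, tpm-sim.R, tpm-analysis.R, fd-analysis.R,
                    binding.R, synthetic.R, io.R, config.R
src/                compiled Metropolis sampler for the tethered chain
tests/testthat/     unit, property and acceptance tests (with oracles)
vignettes/          archdna-methods.Rmd — models, assumptions, choices
scripts/            acceptance.R
inst/scripts/       archdna-cli.R
inst/extdata/       example-config.yaml
```
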
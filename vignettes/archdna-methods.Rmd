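---
title: "Models and methods behind archdna"
author: "archdna authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind archdna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(archdna)
```

# Scope

`archdna` models what small architectural (nucleoid-associated) DNA-binding
proteins do to DNA mechanics, and analyzes the two single-molecule assays in
which those effects are measured:

* **Tethered particle motion (TPM)** — a bead on a short DNA tether; the
  in-plane root-mean-square (RMS) excursion of the bead reads out tether
  compaction (bending, bridging) or stiffening (filament formation).
* **Optical tweezers force spectroscopy** — force-distance (FD) curves of a
  long (λ-phage-scale) DNA molecule; extensible worm-like chain (eWLC) fits
  give the apparent persistence length $L_p$ and contour length $L_c$, and
  serrations (sudden force drops) report protein-bridged loops rupturing.

The motivating system is a pair of ~10 kDa coiled-coil dimers with winged
helix-turn-helix DNA-binding domains that (i) bend DNA in *cis* at low
coverage, (ii) either bridge DNA duplexes or form stiff nucleoprotein
filaments at high coverage, and (iii) bind with $K_D \approx 1$ nM over a
~25 bp site. Since the underlying bead trajectories and FD records are not
publicly deposited, the package ships seeded generators for both record
types; every quantitative test of the analysis chain runs against generated
data with known ground truth.

# Polymer mechanics

## Force-extension model

The canonical force-to-extension map used everywhere (forward generation,
fitting, inversion) is piecewise:

* **Odijk high-force eWLC** for $F \ge 2$ pN:
  $$x(F) = L_c\left(1 - \tfrac12\sqrt{\frac{k_BT}{F L_p}} + \frac{F}{K}\right)$$
* **extensible Marko-Siggia interpolation** for $F \le 0.5$ pN:
  $$\frac{F L_p}{k_BT} = \frac{1}{4(1-\ell)^2} - \frac14 + \ell,
    \qquad \ell = \frac{x}{L_c} - \frac{F}{K},$$
  which reduces to the Gaussian-chain limit
  $F = \tfrac32 k_BT\, x/(L_p L_c)$ at small extension;
* a cubic smoothstep blend on $[0.5, 2]$ pN.

The split keeps the documented closed form exact where fits carry their
information (the 2–30 pN window) while still covering the near-zero-force
toe of a full pulling curve. `ewlc_extension()` is the pure Odijk form;
`ms_ewlc_force()` inverts the full piecewise model, so the two are exact
mutual inverses above 2 pN. The inversion is analytic in structure: the
Odijk branch reduces to a cubic in $\sqrt F$, the MS branch to a rapidly
converging fixed point, so no generic root polishing is involved.

Defaults: $k_BT = 4.08$ pN nm (≈23 °C), 0.34 nm/bp, stretch modulus
$K = 1200$ pN (fitted within [300, 3000] pN).

## Kinked chains and unwinding

A bound dimer is modelled as a fixed polar kink of angle $\theta$ (default
60°) with free azimuth, repeated every $d$ nm along the chain (25 bp =
8.5 nm at full coverage). Tangent correlations then decay at the combined
rate

$$\frac{1}{L_p^{app}} = \frac{1}{L_p} - \frac{\ln\cos\theta}{d},$$

implemented in `kinked_apparent_lp()` and validated against a brute-force
Monte Carlo kinked chain (tangent-correlation fit) to within 5%. Partial
duplex unwinding by the bound protein lengthens the contour linearly in
coverage, $L_c' = L_c(1 + u\,\theta_{cov})$ with $u = 0.1$ at saturating
bend-mode coverage (`unwound_contour()`).

A single 60°/25 bp kink lattice on bare DNA gives
$L_p^{app} \approx 9.7$ nm — a strong softening, but well short of the
~2.5 nm measured for these complexes at 100 nM. That gap is the reason
bending alone is not the whole story at high coverage and why unwinding is
included; the package treats the kink+unwind description as the bend-regime
model and does not attempt a sequence- or structure-level explanation.

# The TPM forward model

`sample_tether_ensemble()` samples a discrete worm-like chain of ~5 nm
segments (a 685 bp tether resolves to 47 segments) anchored to a hard
surface, with a reporter bead of radius 230 nm attached at the distal
vertex along a freely sampled unit vector. Hard constraints: every vertex
at $z \ge 0$ and the bead centre at $z \ge R$ (bead-surface exclusion);
chain-bead overlap is neglected, as the dominant volume effect at this
geometry is the bead against the surface.

Sampling is Metropolis Monte Carlo with pivot moves (the surface joint is a
free hinge, so pivots there rotate the whole chain at zero energy cost) and
short crankshaft moves, a $10^4$-sweep burn-in and thinning of 10. Joint
bending energies are $\kappa_j(1-\cos(\theta_j - \theta_{0,j}))$ in units
of $k_BT$ with $\kappa_j = L_p/b$; protein kinks set $\theta_{0,j}$,
filament stretches override $\kappa_j$ with $L_{p,fil}/b$ (61 nm by
default), and occupancy is realized by uniform non-overlapping placement of
25 bp footprints. The sampler runs in compiled code and draws from R's RNG,
so ensembles are bit-reproducible for a given seed.

Validation anchors:

* the rigid-rod limit matches a deterministic quadrature over the
  hinged-rod/bead geometry to < 3%;
* bend-mode tangent correlations reproduce `kinked_apparent_lp()` to <10%;
* at the bare-DNA persistence length the simulated in-plane RMS of the
  685 bp/230 nm geometry falls within ±15 nm of the measured 161.8 nm, and
  switching only $L_p$ to the 61 nm filament value raises it toward the
  measured 173 nm.

**Bridging.** A loop is a zero-length constraint joining two sites. By
default the looped DNA is excised from the simulated backbone: the bridged
sites coincide and the side loop is invisible to the bead observable, so a
looped tether behaves exactly like a contour-shortened one. A fully
physical alternative (`bridge_method = "spring"`) keeps the whole chain and
closes the loop with a stiff harmonic spring; because the hanging loop also
feels the surface exclusion, it sits a reproducible few percent *below* the
shortened-tether RMS. We treat the excised form as the model definition and
keep the spring form as a documented sensitivity check.

**Problem sizes.** Headline RMS values are computed from $5\times10^4$
retained configurations (Monte Carlo standard error well under 1 nm);
qualitative sweep points use 4000 configurations (≈ 1 nm).

# Trajectory analysis

Raw bead trajectories (25 Hz, nm) are drift-corrected by subtracting a
moving average (default 4 s window). Moving-average subtraction also
removes the small fraction of genuine tether motion below the window
frequency — about 1–2% of the RMS for the default OU correlation time — a
bias shared by the corrected and uncorrected analyses of drift-free data
and far smaller than the tether-to-tether spread. Selection rejects stuck
beads (RMS below 60 nm, chosen midway between the ~45 nm stuck-bead
signature and the lowest genuine tether populations near 116 nm) and
multiply-tethered beads (excursion anisotropy $\sqrt{\lambda_1/\lambda_2} >
1.3$), each with a reason code. Population values come from a
single-Gaussian fit to the histogram of per-tether RMS (5 nm bins), with
SEM = $\hat\sigma/\sqrt N$; a poor single-Gaussian fit ($R^2 < 0.7$)
raises a multimodality flag instead of silently averaging two populations.

# FD curve analysis

`fit_ewlc()` fits the piecewise model in force space over 0.5–30 pN (the
implicit low-force branch is ill-conditioned at $F \to 0$, so zero-force
data are excluded). Two numerical choices matter:

* **window selection on a smoothed, then model-implied force.** Selecting
  points by raw measured force admits sub-window points promoted by noise —
  all with positive residuals over the flat toe — which biased recovered
  $L_p$ by ~15% in early testing. The fitter selects on a median-smoothed
  force, fits, re-selects on the fitted model force and refits.
* **staged optimization.** $(L_c, K)$ are strongly correlated;
  Levenberg-Marquardt from a cold start can stall. The fitter first fixes
  $K$ and fits $(L_p, L_c)$, then releases all three parameters.

With these, noiseless synthetic curves round-trip to $<10^{-3}$ relative
error and 20-curve means at 0.5 pN force noise recover all four regime
points (bare, two soft, one stiff) within 5%.

`detect_ruptures()` scans the raw force series for a local maximum followed
by a drop of at least 2 pN within 0.2 μm. At 2 μm/s and 25 Hz a rupture
recovers within a couple of samples, so any filter wide enough to suppress
0.5 pN noise also erases the event — hence no pre-smoothing, and a span
default of 0.2 μm (2–3 samples; a tighter span than one sample spacing
would detect nothing). Contour release per event is the difference of
contour-length-only refits (closed-form least squares at fixed $L_p$, $K$)
on the sub-curves flanking the event. A curve with ≥3 events is *serrated*;
serrated curves are refused by `fit_ewlc()`, since loop ruptures violate
the fixed-contour assumption. `overstretch_plateau()` reports the median
force of the longest low-slope (<3 pN/μm) stretch above 55 pN spanning
≥1 μm; `hysteresis_area()` integrates the extension-retraction force gap.

`classify_mode()` encodes the interpretation rules: serration ⇒ bridging
(direct evidence, takes precedence); $L_p$ below half of bare with $L_c$
above bare ⇒ bending; $L_p$ at least 5% above bare with $L_c$ at or below
bare ⇒ stiffening; otherwise indistinguishable from bare. The 5% stiffening
margin exists so a bare fit compared with itself is classified "bare".

# Binding models

Occupancy follows the McGhee-von Hippel large-ligand isotherm (footprint
$n = 25$ bp, $K_D = 1$ nM, optional nearest-neighbour cooperativity
$\omega$), solved numerically for the bound density; free ligand is taken
equal to total (protein in vast excess over a single tethered molecule). An
exact finite-lattice variant (transfer-matrix partition function with exact
concentration derivative) is available and is checked against exhaustive
enumeration to $10^{-6}$ on small lattices; edge effects make the finite
685 bp lattice differ from the infinite form by a few percent, which is why
both exist.

With $K_D = 1$ nM the lattice is already ~70% covered at 1 nM free
protein, so over the experimentally swept 1–3000 nM the coverage moves only
from ~0.72 to ~0.92: the concentration dependence of the *mechanics* in
this model therefore rides on a slowly varying coverage, and the stiffening
onset is effectively a sharp coverage threshold. That is a deliberate,
phenomenological representation — the measured bandshift affinity is taken
at face value and no attempt is made to re-derive an effective affinity
from the TPM/OT buffers. Salt enters only by letting the onset differ
between configurations.

`neighbor_contact_fraction()` gives the equilibrium probability that a
bound protein touches a neighbour (geometric gap statistics,
$1-(1-p_0)^2$ with $p_0 = \theta/(\theta + n(1-\theta))$), validated
against uniform stars-and-bars placement sampling. At the coverage reached
at 3000 nM (~0.92) this equilibrium contact fraction is only ~0.5 — too
small to explain the measured full return of $L_p$ and $L_c$ to
filament/bare values if stiffening were proportional to random contacts.
The package therefore treats filament growth as cooperative (the expected
behaviour of electrostatic wing-wing dimer contacts) and models the
stiffened fraction as a ramp that is log-linear in *concentration* between
the concentrations at which coverage reaches `stiffening_onset` (default
0.878) and `stiffening_onset + onset_width` (default +0.04): binding free
energy scales with $\ln c$, so this ramp changes uniformly along a
log-spaced sweep, whereas a ramp linear in coverage would concentrate its
whole change over a few sweep points of the nearly saturated isotherm.
With the defaults the stiffened fraction is 0 up to ~100 nM, ~0.6 at
1000 nM and ~0.98 at 3000 nM, matching the measured regime boundaries.
The neighbour-contact fraction remains available as a diagnostic.
Likewise `predict_mechanics()` interpolates the apparent $L_p$
*geometrically* (in log space) between the bent-regime value and the
filament value: the two regimes differ several-fold in stiffness, serial
(decay-rate) mixing would let any residual soft fraction dominate and
could never return above bare stiffness, and log-space mixing keeps the
sweep uniform on the scale on which persistence lengths are compared. All
of these are phenomenological interpolations between measured regime
endpoints, not microscopic claims.

Mode weights (`w_none`, `w_bend`, `w_stiffen`) always sum to 1, and the
predicted curves are continuous in concentration (no >5% step on a
100-point log sweep).

# Synthetic data

Bead trajectories are stationary 2D Ornstein-Uhlenbeck processes
(relaxation time 0.05 s ≈ one correlation time per frame at 25 Hz) with
per-axis σ = target RMS/√2, i.i.d. tracking noise (10 nm default) and
optional linear drift; the measured RMS of a long trace converges to
$\sqrt{\mathrm{RMS}^2 + 2\sigma_{track}^2}$, which analysis tests invert.
Only stationary statistics enter the analysis, so the temporal model needs
to be plausible rather than hydrodynamically exact — that is what the
generator does *not* emulate about real data (no bead inertia or
hydrodynamic coupling, no camera blur, no bead-size polydispersity), and
passing tests therefore certify the analysis chain, not the microscopy.

FD pairs are forward model curves on the 2 μm/s / 25 Hz grid with Gaussian
force noise (0.5 pN default), saw-tooth ruptures (contour steps at labelled
forces, all below 40 pN by default — bridges do not survive higher loads),
an optional overstretching plateau (force cap), and a retraction generated
from the final contour with an optional constant force deficit to create
hysteresis. Generators are pure functions of their specs; every downstream
test reads ground truth from the returned labels.

# Configuration and reproducibility

Run configurations are YAML with a fixed schema (unknown keys rejected,
physical parameters validated as positive, errors name the offending key).
A single seed governs every stage; multi-stage routines derive child seeds
via the documented affine scheme in `child_seed()`. `run_pipeline()` writes
JSON/TSV results plus a manifest with MD5 content hashes; reruns at the
same seed are byte-identical. A thin command-line wrapper
(`inst/scripts/archdna-cli.R`) exposes fixture generation, TPM and FD
analysis and the forward sweep as subcommands.

# Known limitations

* The bend-regime softening model (kinks + unwinding) is phenomenological;
  it reproduces directions and magnitudes of $L_p$/$L_c$ shifts but does
  not derive the measured 2.5 nm apparent $L_p$ from structure.
* Bridging has no concentration model (the data constrain only an onset),
  so loops are explicit inputs, and bridge kinetics/force-dependent
  lifetimes are out of scope.
* Salt dependence is represented solely by the stiffening-onset parameter;
  there is no electrostatic model.
* TPM RMS is defined on the equilibrium ensemble; blur/exposure corrections
  and bead rotational dynamics are not modelled.
* The overstretching plateau is detected, not thermodynamically modelled.
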
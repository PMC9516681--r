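---
title: "Predicting cyclic-peptide membrane permeability from biased sampling along z"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cyclic-peptide membrane permeability from biased sampling along z}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memperm)
```

## The problem

Large cyclic peptides can cross lipid membranes passively despite
violating the usual oral-drug rules, because they can fold into
"closed" conformers whose polar groups are shielded by intramolecular
hydrogen bonds. Predicting their passive permeability from simulation
follows a well-established route: sample the peptide along the
membrane-normal coordinate $z$ with umbrella restraints, unbias the
samples into a potential of mean force (PMF) $G(z)$, estimate a local
diffusivity $D(z)$, and combine the two through the inhomogeneous
solubility–diffusion model (ISDM).

`memperm` implements that analysis pipeline end to end — WHAM,
autocorrelation-based $D(z)$, and a modified ISDM with flip/out
endpoint rules — together with the conformational observables usually
profiled along $z$ (hydrogen bonds, polar surface area, dihedral
principal components, cis peptide bonds, inertia axes). Because the
all-atom sampling behind such a study needs on the order of $10^5$–$10^6$
GPU hours, the package also ships a *synthetic* data generator: 1D
overdamped Langevin dynamics on membrane-like free-energy and
diffusivity profiles, with replica exchange between umbrella windows.
Every stage of the analysis can therefore be exercised, and checked
against closed-form ground truth, on a laptop.

## The model

### Sampling design

One leaflet is sampled, $z \in [0, 37.5]$ Å with $z = 0$ the bilayer
centre; the PMF is assumed symmetric across the centre, and
`symmetrize()` mirrors profiles when a whole-bilayer view is wanted.
The default window schedule places 28 harmonic restraints: every 1.0 Å
from 0 to 6 Å at 1.5 kcal mol$^{-1}$ Å$^{-2}$, and every 1.5 Å from 6
to 37.5 Å at 0.5 kcal mol$^{-1}$ Å$^{-2}$ (the shared window at 6 Å is
counted once, in the fine segment). Combined with the 8-rung solute
temperature ladder (300–980 K) this is the familiar $28 \times 8 = 224$
replica layout:

```{r schedule}
sch <- build_window_schedule()
length(sch)
length(sch) * length(default_temperature_ladder()$rungs)
```

Solute tempering enters this package only as arithmetic: a scaling
factor $\lambda = T_\mathrm{sys}/T_\mathrm{solute}$, so $\lambda =
0.143$ at 300 K means the peptide samples as if at
`r round(effective_temperature(0.143, 300))` K. No Hamiltonian is
actually scaled here.

Harmonic conventions are a real interoperability trap: AMBER restraints
are $U = k(z - z_0)^2$, the common WHAM dialect expects
$U = \tfrac{k}{2}(z - z_0)^2$. Every window therefore carries an
explicit `convention` field and all converters are provided. Which
convention the printed force constants belong to is genuinely ambiguous
from the protocol description alone; we resolved it by simulation. On
the `popc_like` preset, reading them as AMBER-style (`full`) gives a
mean neighbour exchange acceptance of about 0.16 — inside the 10–20%
band the sampling design targets — while the `half` reading gives about
0.33. The package defaults to `full` in its configuration files and
documents the alternative.

### WHAM

`solve_wham_1d()` iterates the standard self-consistent equations on
per-window histograms (default 0.5 Å bins over $[0, 37.5]$ Å) until the
largest change in any window free energy drops below $10^{-7}$
kcal/mol, with a hard cap of $10^5$ iterations; hitting the cap flags
the solution rather than failing silently. Adjacent windows whose
sampled ranges do not touch raise an "insufficient overlap" error
naming the gap, and empty interior bins are a hard error — silent
interpolation would hide exactly the failure modes one needs to see.
Bins, tolerance and the burn-in fraction are configuration knobs; the
burn-in default is 0 because the reference protocol equilibrates in a
separate phase before production, but the parameter-recovery tests
discard 10% to mirror that separation when the toy sampler starts cold.

The reported PMF is min-zero by convention (that is what the resistance
integrand references); a bulk-zero variant is available for plotting.
Uncertainty follows the half-split recipe: WHAM is solved independently
on the first and second halves of every series and the per-bin standard
deviation of the two aligned PMFs is attached (`halfsplit_error()`).
`pmf_2d_reweight()` extends the same per-frame weights to a second,
unbiased axis (polar surface area in the motivating use case); empty
bins are `NA`, never zero, and marginalising the weighted density over
the auxiliary axis reproduces the 1D PMF — one of the consistency
oracles in the test suite.

### Local diffusivity

$D(z)$ comes from restrained runs (force constant 2.5
kcal mol$^{-1}$ Å$^{-2}$, half convention, 20 ns per window by default)
through the autocovariance estimator

$$D = \frac{\langle \delta z^2\rangle^2}{\int_0^{t_c} C_{zz}(t)\,dt},
\qquad C_{zz}(t) = \langle \delta z(0)\, \delta z(t)\rangle .$$

The autocovariance uses the biased $1/N$ normalisation (integrable by
construction) computed via FFT. The integration cutoff $t_c$ is the
first zero crossing of $C_{zz}$, falling back to the lag where it drops
below 1% of the variance; white-noise-like series whose covariance dies
within one sampling interval are rejected with advice rather than
returning a divergent estimate. On Ornstein–Uhlenbeck ground truth the
estimator is unbiased with roughly 9% scatter per 20 ns run, so repeat
runs are pooled by geometric mean — also the rule used to combine the
protocol's two independent umbrella passes — and `build_D_profile()`
interpolates $\log D$ linearly between window centres (diffusivity
varies multiplicatively across the interface; log-space interpolation
keeps it positive), extrapolating as a constant beyond the outermost
centres.

### Permeability

`resistance_profile()` implements

$$R(z) = \frac{\exp(\beta\, \Delta G(z))}{D(z)},$$

with $\Delta G$ referenced to the *global PMF minimum*, not the bulk
value. The distinction matters for peptides with deep interfacial
minima: referencing bulk would let the favourable adsorption well
cancel part of the barrier and overstate the permeability.
`permeability_between()` integrates $R$ by trapezoid and converts
(1 ps/Å $\times 10^{-4}$ = s/cm). Two endpoint choices give two
coefficients:

* $P_\mathrm{flip}$ — from the bilayer centre ($z = 0$) to the PMF
  minimum $z_\mathrm{min}$: the cost of flipping across the centre;
* $P_\mathrm{out}$ — from $z_\mathrm{min}$ to bulk water (37.5 Å):
  the cost of escaping outward.

When $z_\mathrm{min} > 30$ Å the peptide essentially never leaves
water and $P_\mathrm{out}$ is undefined (reported as such, never
silently dropped). Three edge rules are deliberate choices: ties for
the global minimum resolve to the grid point closest to bulk (the
longer, more conservative flip path); a minimum exactly at the bilayer
centre leaves a zero-length flip path and $P_\mathrm{flip} = \infty$;
and the headline value combines the two coefficients as
$\min(P_\mathrm{flip}, P_\mathrm{out})$ — the rate-limiting
interpretation — with both always reported and the rule configurable,
since a single "predicted permeability" necessarily hides this choice.
Uncertainty mirrors the PMF: the permeability is recomputed on the two
half-split PMFs and the standard deviation of $\log_{10} P$ reported.

## The synthetic generator

`simulate_langevin()` integrates the overdamped (position) Langevin
equation with the Euler–Maruyama scheme,

$$z \leftarrow z + \left[-\beta D(z)\,\partial_z(G + U_\mathrm{bias})
+ D'(z)\right] dt + \sqrt{2 D(z)\, dt}\; \xi,$$

with reflecting walls at $z = 0$ and $z = 37.5$ Å. The spurious-drift
term $D'(z)$ is not optional: without it a position-dependent
diffusivity distorts the stationary density, and the stationarity test
(Boltzmann recovery across the region where $D$ varies threefold) is
precisely the test that would catch its omission. Inertia is not
modelled — only the stationary density and the local diffusivity
matter to the downstream estimators.

`run_reus()` runs one walker per window and attempts Metropolis swaps
of alternating even/odd neighbour pairs every 10 ps (the standard
"adjacent replicas" scheme), logging every attempt with its energy
difference and uniform draw so the acceptance rule itself is
auditable. The toy model exchanges along the window dimension only;
the temperature ladder exists as bookkeeping, not as a second exchange
dimension.

Membrane presets are sums of Gaussians plus a bulk plateau — smooth,
differentiable, and controllable:

* `popc_like` — central barrier (5 kcal/mol scale), interfacial
  minimum near 12 Å, headgroup peak near 25 Å, $G \to 0$ in bulk;
  $D$ rises smoothly from 0.03 to 0.1 Å$^2$/ps across the interface.
* `chol50_like` — the interfacial minimum abolished; free energy
  monotonically increasing from bulk toward the centre, as in
  cholesterol-rich membranes.
* `square_barrier` — a tanh step of height $h$; its smoothing length
  defaults to 1 Å so the default 0.5 Å histogram bins resolve the
  step and the integrator's drift stays well below the grid scale.
* `flat` — free diffusion, for calibration.

The magnitudes are chosen to be membrane-realistic (barriers of a few
kcal/mol, $D \sim 0.1$ Å$^2$/ps in water), not fitted to any particular
peptide. What the generator does *not* emulate is equally important:
there is no orthogonal slow degree of freedom, no membrane deformation,
no finite-size pressure coupling, and conformational state is generated
*conditionally on z* rather than dynamically. Passing tests therefore
certify the estimators and their plumbing, not the force-field realism
of any particular prediction.

The conformer generator (`generate_conformer_series()`) emits a
two-state stand-in: a closed template whose four donor–H/acceptor
units form collinear 2.9 Å intramolecular hydrogen bonds (which also
buries polar surface), an open template with the acceptors swung 8 Å
away, Gaussian backbone dihedrals about per-state means, and a
configurable closed-state probability as a function of $z$ (default: a
sigmoid centred at 7 Å, closed conformers dominating inside the
membrane). Ground-truth state labels are retained so both closed-state
classifiers — the transferable intramolecular hydrogen-bond count
(default) and the dataset-specific principal-component box — can be
validated against what was actually generated.

## Numerical choices worth knowing

* $k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$; energies kcal/mol,
  lengths Å, times ps, diffusivities Å$^2$/ps ($\times 10^{-4}$ =
  cm$^2$/s).
* Langevin steps: `dt = 0.05` ps by default; a pre-run check warns if
  the worst-case drift step in the region the walker will visit
  exceeds 0.5 Å, and a step larger than 5 Å aborts with an error
  naming `dt`.
* Hydrogen bonds: donor–acceptor distance $\le 3.5$ Å and
  D–H$\cdots$A angle $\ge 135^\circ$, both configurable (cpptraj-style
  defaults; the criterion is never stated in protocol write-ups and
  must be declared).
* SASA: deterministic golden-spiral sphere sampling (960 points per
  atom by default, exact for an isolated sphere); the polar surface
  area is the N/O subtotal. The analytic LCPO alternative would not
  change any testable behaviour at this scale, so the simpler,
  verifiable algorithm is used and labelled.
* cis peptide bond: $|\omega| < 90^\circ$, ties to trans.
* Inertia axis: unit masses unless masses are supplied; the angle is
  folded to $[0, 90]$ degrees because the axis sign is arbitrary.
* Dihedral PCA embeds $(\sin, \cos)$ of $(\phi, \psi, \omega)$ —
  removing the $\pm 180^\circ$ seam — and eigendecomposes the
  covariance; eigenvector orthonormality and embedding round-trips are
  asserted to tight tolerances in the tests.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the toy protocol at
2×10$^5$ Langevin steps per window for PMF recovery (10 ns per window
at `dt = 0.05` ps; exchange attempts every 10 ps), 20 ns restrained
runs for diffusivity, and a fine-grid closed-form quadrature as the
end-to-end oracle. At these budgets the square-barrier height is
recovered to about $\pm 0.2$ kcal/mol (repeat-seed spread), the
`popc_like` PMF to well under 0.3 kcal/mol RMS, $D$ to within 10%
(pooling repeats), and the pipeline $\log_{10} P$ to within 0.2 of the
oracle. The whole suite takes well under a minute on one CPU.

## Known limitations

* The ISDM is one-dimensional: when the rate-limiting step involves
  motion orthogonal to $z$ (reorientation, slow conformational
  exchange inside the membrane), a 1D $P$ is not trustworthy — this is
  a documented limitation of the method itself, not of the
  implementation.
* No unstirred-water-layer or solubility corrections are applied.
* The toy sampler cannot reproduce any specific peptide's reported
  permeability; it exists to make the analysis verifiable.
* MBAR is not implemented; WHAM with explicit bins is the single
  estimator, chosen to match the reference tooling.
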
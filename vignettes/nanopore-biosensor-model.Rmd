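---
title: "Modelling a blocked-nanotube ion-channel biosensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a blocked-nanotube ion-channel biosensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoporesim)
```

## The model

`nanoporesim` models a membrane-spanning carbon-nanotube channel that
conducts monovalent cations and can be shut by a fluorofullerene blocker
docked at its mouth. The sensing principle is a switch: with no analyte the
blocker seals the pore; analyte cross-links the blocker to a polymer bead,
the hydrodynamic drag on the bead strips the blocker, and the reopened pore
announces the event as a step in ionic current.

Everything in the package runs off one object: a one-dimensional potential
of mean force (PMF) $W(z)$ along the channel axis, stored in thermal units
($kT$ at a stated temperature, default 310 K) and zero-referenced in bulk
solution. Three kinds of questions are asked of a PMF:

* **Equilibrium**: how tightly does a blocker bind (dissociation constant),
  how often does a blocked pore open spontaneously, how many ions occupy
  the pore?
* **Transport**: what current flows at a given voltage and salt
  concentration, and where do ions dwell?
* **Device arithmetic**: is the drag force on the reporter bead sufficient
  to strip the blocker, and how does the channel compare with the
  gramicidin-based reference sensor?

## PMF profiles and their construction

Only a handful of features of the underlying free-energy curves are known
numerically: the potassium profile has two wells of about $3\,kT$ centred
at $z=\pm9$ Å (the exohydrogenated bands of the tube) separated by a
$2.2\,kT$ barrier; chloride faces an insurmountable barrier of roughly
$20\,kT$; the C$_{60}$F$_{60}$ unbinding profile falls to $-25.6\,kT$ at
23 Å, rises to $-7.3\,kT$ at 24.5 Å, has a secondary minimum near 25.5 Å
and vanishes by 35 Å; C$_{60}$F$_{36}$ has a single $-11.9\,kT$ well at
22 Å. `build_pmf_from_features()` turns such anchor lists into smooth
profiles; `make_fixture()` packages the standard ones. Each fixture records
in its `provenance` attribute which numbers are anchored and which are
modelling choices — in particular the depth of the C$_{60}$F$_{60}$
secondary minimum ($-9\,kT$) and the repulsive shoulders left of each
binding well are choices, and the entire curve *between* anchors is
modelled, never data. The $2.2\,kT$ barrier is read as a height above the
well floor (wells $-3\,kT$, mid-channel $-0.8\,kT$), matching the usual
"wells separated by a barrier" phrasing.

Interpolation uses a Fritsch–Butland monotone cubic Hermite scheme written
for this package. Shape preservation matters here: an interpolant that
overshoots would invent spurious wells or clip barrier heights, and the
barrier heights enter observables exponentially. The scheme sets the slope
to zero at any knot where the secant slope changes sign, so anchored
extrema are honoured exactly and the curve never leaves the range of a
neighbouring anchor pair. (Base R's `splinefun(method = "monoH.FC")` does
not guarantee this at data extrema: on the C$_{60}$F$_{60}$ anchors it
renders the $-7.3\,kT$ barrier at $-6.8\,kT$, a $0.5\,kT$ error that would
inflate the opening probability by $e^{0.5} \approx 1.6$.)

```{r pmf}
k <- make_fixture("k_pmf")
c(min_w = min(k$w), barrier = pmf_value(k, 0) - pmf_value(k, 9))
```

## Umbrella sampling and WHAM

`sample_umbrella_window()` emulates the restrained sampling protocol used
to construct unbinding profiles: windows every 0.5 Å, harmonic restraint
$\tfrac12 k (z-z_0)^2$ with $k = 10$ kcal/mol/Å². Samples are drawn i.i.d.
from the biased Boltzmann density by inverse-CDF lookup; the
autocorrelation of a real trajectory is deliberately not modelled, so a
window's sample count plays the role of an effective sample size.
`wham_reconstruct()` is a standard self-consistent weighted-histogram
iteration (tolerance $10^{-6}\,kT$ on the window shifts, iteration cap
$10^5$ — convergence is cheap in one dimension). Sampler and WHAM share the
$\tfrac12 k$ bias convention, so recovery tests are insensitive to that
choice. Three numerical details matter on profiles this steep (the strong
blocker's flank rises 18 kT/Å): the default histogram bin is 0.05 Å,
because the binned estimator's error grows with the square of the bin
width and 0.25 Å bins leave several-tenths-kT artefacts near the well;
bins holding fewer than a handful of samples are dropped rather than
reported as wild free-energy estimates; and the zero reference at the bulk
end is a count-weighted average over the outermost ångström instead of the
single (noisiest) edge bin. With 27 windows of 5,000 samples the blocker
profile is recovered to an RMSE below $0.3\,kT$ over the sampled range.

## Dissociation constants and blocker statistics

The dissociation constant comes from the cylinder-restrained 1D integral

$$K_d^{-1} = 1000\, N_A \,\pi R^2 \int_{z_1}^{z_2} e^{-W(z)/kT}\, dz,$$

with $R = 8$ Å the radius of the flat-bottom cylinder that confined the
blocker during sampling (read as a radius, not a diameter), $z_1$ in the
binding pocket and $z_2$ in bulk. Defaults place $z_1$ two ångström below
the global minimum and $z_2$ at the bulk end; for wells this deep the
integral is completely dominated by the minimum, and moving $z_1$ by
±1 Å moves $K_d$ by well under 1% (asserted in the tests). Quadrature is
an adaptive trapezoid with a Richardson check, accurate to better than
0.1%.

```{r kd}
signif(c(kd36_M = binding_report(binding_model(make_fixture("c60f36_pmf")))$kd_molar,
         kd60_M = binding_report(binding_model(make_fixture("c60f60_pmf")))$kd_molar), 3)
```

The spontaneous opening probability is interpreted as a Boltzmann escape
factor $e^{-\Delta W}$, with $\Delta W$ the height of the confining barrier
between the bound minimum and bulk — the highest *interior* barrier along
the escape path, or the bulk value when the profile rises monotonically.
For the strong blocker this gives
$\exp(-(25.6 - 7.3)) \approx 1.1\times10^{-8}$. The maximum restoring
force is the steepest PMF slope along the escape path converted to newtons
($1\,kT/\text{Å} = 4.28\times10^{-11}$ N at 310 K); for these profiles it
is of order $10^{-10}$ N. A much smaller literature figure
($3.5\times10^{-20}$ N) exists for the same system; no PMF-slope reading
reproduces it, so `feasibility_report()` carries both values side by side
rather than guessing at its derivation.

## The permeation engine

`simulate_permeation()` propagates ions on the channel axis with an
overdamped Langevin (Brownian dynamics) update,

$$z \leftarrow z + \frac{D(z)}{kT} F(z)\,\Delta t + D'(z)\,\Delta t +
\sqrt{2 D(z) \Delta t}\,\eta,$$

where $F$ is the sum of the PMF mean force (inside the pore), the applied
field, and pairwise axial Coulomb forces screened by the local dielectric
(60 in the pore, 80 in the reservoirs, with a 2 Å minimum-distance clamp);
the $D'(z)$ term is the Itô correction required for position-dependent
diffusivity. The generalized-Langevin friction memory of the original
two-region method is not available in tabulated form; in the overdamped
limit steady-state currents and occupancies depend on $D(z)$ and $W(z)$
rather than on the kernel shape, so the engine is memoryless with a
position-dependent diffusion coefficient: the bulk value outside the pore
(K⁺ $1.96\times10^{-9}$, Cl⁻ $2.03\times10^{-9}$ m²/s), scaled by
`pore_diffusion_factor` (default 0.5) inside, with a smooth 2 Å taper at
each mouth. The applied potential drops linearly across the 36 Å pore
span; reservoirs are equipotential; positive current is cation flow from
the high- to the low-potential reservoir.

Geometry is quasi-one-dimensional: a cylinder of effective radius 4.53 Å.
Each end carries a 30 Å reservoir slab clamped to the bath concentration —
every step the slab's ion count is resampled to a Poisson draw with mean
$c \times$ slab volume. A discrete-time clamp of this kind realises its
Dirichlet boundary not at the slab edge but displaced by
$\mathcal{O}(\sqrt{D\,\Delta t})$ (the Milstein boundary-layer effect), so
the clamped slab extends `clamp_displacement_factor`
$\times\sqrt{D\,\Delta t}$ past the pore face and traversals are counted
at the slab edges. The factor is calibrated once against the analytic
flat-channel flux (a case with a closed-form solution, independent of any
fixture) and left fixed.

Currents are counted from complete pore traversals:
$I = \text{net crossings} \times q e / T$. Because the resistance of these
profiles concentrates in a few ångström at the channel entrance, the
default time step is small (10 fs); tests use 20–100 fs after verifying
that halving the step moves currents by less than the counting error.

### Independent cross-check

`steady_state_current()` solves the same transport model by quadrature of
the 1D steady-state Smoluchowski (Nernst–Planck) boundary-value problem,

$$J = \frac{c_L e^{\phi(a)} - c_R e^{\phi(b)}}
{\int_a^b e^{\phi(z)} / (D(z) A)\, dz}, \qquad \phi = \frac{W + qV(z)}{kT},$$

sharing only the model definition ($W$, $D$, geometry) with the stochastic
engine — no simulation is involved. In the independent-ion regime
(`ion_interactions = FALSE`, under which current is exactly linear in
concentration — simulations are therefore run at 500 mM purely for
counting statistics) the Brownian engine agrees with this solver to within
a few percent at 50–200 mV on the potassium fixture.

### What the stochastic results do and do not show

The synthetic profiles reproduce the *printed features* of the underlying
free-energy surfaces, not the surfaces themselves, and the per-slice
diffusivities of the original method are unpublished. Absolute currents
are therefore order-of-magnitude quantities: the defaults give a few
hundred pA at 200 mV / 500 mM where the reference calculation reports
82 pA. Relative and structural statements are the meaningful outputs:
linear current–voltage response, saturating current–concentration response
(fit with `fit_michaelis_menten()`), complete chloride exclusion by the
20 kT barrier, dwell modes at ±9 Å, and zero net current at zero bias.

A related, deliberate discrepancy: `equilibrium_occupancy()` applied to
the potassium fixture at 500 mM gives ≈ 6 ions, several-fold above the
reported average of 1.2. With wells of a full $3\,kT$ across the whole
4.53 Å cross-section the Boltzmann integral cannot be smaller; the
reported occupancy evidently reflects the three-dimensional shape of the
true PMF (the wells do not span the entire cross-section at full depth).
The fixture keeps the printed well depth rather than re-tuning it to match
the occupancy, and the package reports what the 1D reduction actually
implies.

## Device feasibility

`device_model()` collects the sensor-level numbers: 15 nm bead radius,
nominal water viscosity $1.0\times10^{-3}$ Pa·s (water at 310 K is
$\approx0.69\times10^{-3}$; the value used is echoed in every report), a
pore density of $2.5\times10^{11}$ cm⁻², and the reference single-channel
current of 4 pA at 200 mV ($2.5\times10^7$ ions/s). The published drag
force of $1.2\times10^{-13}$ N corresponds, through Stokes' law
$F_D = 6\pi\mu a U$, to a flow speed of $4.24\times10^{-4}$ m/s; the
conversion from an injection rate (1.2 mL/min) to a speed depends on the
chamber cross-section and is not specified, so the speed is an explicit
input with this back-derived value as its default. `feasibility_report()`
assembles the drag-versus-binding comparison, the fold change in current
over the reference channel (82/4 ≈ 20), and recognition-site counts
(2,500 per µm², $2.5\times10^{11}$ per cm²).

```{r device}
rep <- feasibility_report(make_fixture("default_device"),
                          binding_report(binding_model(make_fixture("c60f60_pmf"))),
                          channel_current_pA = 82,
                          literature_binding_force_N = 3.5e-20)
rep
```

## Numerical choices and problem sizes

* Energies in $kT$ at 310 K; one constants table
  (`physical_constants()`) holds every conversion.
* PMF anchors interpolated on 0.05–0.1 Å grids; quadratures use adaptive
  trapezoid with Richardson checks (0.1% target).
* WHAM: 0.05 Å bins, shift tolerance $10^{-6}\,kT$; non-convergence is
  flagged, never silently returned.
* Brownian dynamics: default $\Delta t$ = 10 fs, five replicates
  (matching the replication of the reference calculation), explicit seeds
  everywhere; the drift in a single step is monitored and a step of
  > 1 Å aborts with advice to reduce the time step.
* Test-suite simulations use 150 ns – 4 µs of simulated time per
  condition — enough for one-to-three-percent counting error on the
  quantities asserted — rather than the full 0.8 µs × 5 replicates of the
  study-scale configuration, which remains the default of
  `make_fixture("default_sim_config")`.

## Limitations

* One dimension: no explicit cross-sectional degrees of freedom, no 3D
  PMF, no induced surface charges (the membrane dielectric of 2 is
  recorded but enters no force term).
* Ion–ion interactions are axial Coulomb forces with a local dielectric;
  at very high occupancy this caricatures the true screened interaction.
* No binding kinetics ($k_{on}$/$k_{off}$): the blocker statistics are
  equilibrium quantities.
* The hydrodynamics is Stokes' law only; bead–wall and bead–flow-profile
  effects are out of scope.
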
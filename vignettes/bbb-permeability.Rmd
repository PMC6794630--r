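---
title: "Modelling solute transport and permeability read-outs in a microfluidic BBB device"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling solute transport and permeability read-outs in a microfluidic BBB device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbperm)
```

## The system

The device modelled here is a five-channel microfluidic chip in which a 3D
neural culture (wild-type or familial-AD mutant) is cocultured with a brain
endothelial cell (bEC) monolayer that forms a blood-brain-barrier-like
interface. The five parallel microchannels (MCs), crossed in order, are:

1. ReN cell medium MC (culture medium),
2. 3D ReN culture MC (cells in Matrigel) — the amyloid-beta source,
3. barrier MC (2 mg/mL collagen, connects the two chambers),
4. collagen scaffold MC (the gel on whose sidewall the monolayer grows),
5. bEC barrier MC (the endothelialised, medium-filled lumen).

Two quantitative questions drive the package:

* **Forward problem.** Given constant Abeta secretion in the 3D culture,
  heterogeneous diffusivities, a nearly impermeable endothelial barrier and
  daily medium replacement of the lumen, what concentration field develops
  over a week of coculture?
* **Inverse problem.** Given a fluorescence time-lapse of a dextran influx
  assay, what is the permeability coefficient *P* of the monolayer, and how
  faithful is the standard control-volume read-out?

A synthetic-data generator links the two: it simulates influx assays with a
*known* membrane permeability and renders them as noisy time-lapses, so the
estimator can be validated end to end without experimental data.

## Transport model

Concentrations obey Fick's second law with spatially varying diffusivity and
a distributed source,

$$\frac{\partial C}{\partial t} = \nabla \cdot \big( D(\mathbf{x}) \nabla C \big) + S(\mathbf{x}),$$

on the 2D plan view of the device. The out-of-plane direction (uniform
150 um channel height) enters only through volume/area bookkeeping, so a
plan-view model is sufficient; likewise the solution is
translation-invariant along the channels for the scenarios treated here, and
short channel strips reproduce the full cross-channel physics (the package
defaults to the full 7.5 mm length; tests and the acceptance script use
300-1000 um strips for speed).

Diffusivities (m^2/s) for ~4 kDa soluble Abeta are the study's values:
1.8e-10 (medium), 1.24e-10 (Matrigel), 0.7e-10 (2 mg/mL collagen), and
0.62e-10 for the scaffold. The scaffold was cast at 4 mg/mL but the closest
stated coefficient is the 5 mg/mL collagen value, which we adopt
(configurable). The dextran tracers carry no stated coefficients, so we
scale the Abeta values by Stokes-Einstein molecular-weight scaling,
$D \propto M_w^{-1/3}$: a factor 1.10 for 3 kDa and 0.464 for 40 kDa. These
land within the literature range for FITC-dextran in dilute collagen and are
fixed package defaults.

The endothelial monolayer is a thin membrane on the scaffold/lumen edge
with diffusivity $D_b = 2\times10^{-15}$ m^2/s and nominal thickness
$h_b = 2$ um (the study gives $D_b$ only; $h_b$ is ours and configurable),
exposed throughout as the conductance $K = D_b/h_b$, in m/s. In the
synthetic assay $K$ is set directly from the ground-truth permeability.

### Numerics

The solver discretises the layout on a uniform grid (cells take the
material of the region containing their centre) and uses
**harmonic-mean face diffusivities**, the conservative choice for
discontinuous coefficients; membrane faces add $1/K$ in series with the two
half-cell resistances. Boundaries are zero-flux. Two integrators are
provided:

* explicit FTCS with stability bound $\Delta t \le \Delta x^2/(4 D_{max})$
  (default for the short assay runs), and
* implicit backward Euler with the free cells factorised once per step size
  (sparse Cholesky), used for the multi-day accumulation runs
  (default $\Delta t = 600$ s).

Both schemes conserve mass to machine precision in a sealed domain (the
implicit operator has zero column sums; explicit fluxes telescope), and they
agree to ~0.01% on the day-scale accumulation scenario. Dirichlet
reservoirs ("pinned" regions) are eliminated from the implicit system so
the steady state is independent of the step size. Medium replacement is
instantaneous: at every multiple of the period the region is reset to the
replacement concentration (0: fresh medium carries no tracer or Abeta), the
removed mass is logged, and snapshots at event times record the post-event
state. Negative or non-finite concentrations abort the run with a
numerical-failure error; round-off-level negatives (below 1e-12 of the
field maximum) are clipped to zero.

Verification oracles (run in the test suite and the acceptance script):
a Gaussian pulse spreads with $\sigma^2(t) = \sigma_0^2 + 2Dt$ (to < 1%);
a two-material slab with fixed end concentrations reaches the
series-resistance steady state (machine precision, since the discrete
resistor network is exact for piecewise-constant $D$ aligned with faces);
and the 7-day run closes its full mass ledger
(final = initial + secreted − removed by events) to well below 0.1%.

## The accumulation scenario

Defaults follow the study: secretion at 1.4e-12 mol m^-3 s^-1 (5e-12 M/h,
converted exactly as rate × 1000/3600) distributed over the 3D culture MC;
initial condition 1.65e-7 mol m^-3 in that MC only; daily replacement of
the bEC barrier MC. `run_abeta_profile_experiment()` returns daily
cross-channel profiles and the time courses of the barrier-adjacent gel and
the lumen. The lumen traces a sawtooth: strictly rising between events,
zero immediately after each replacement; the barrier-adjacent gel rises
monotonically throughout. With the stated barrier diffusivity the lumen
stays an order of magnitude below the source channel at all times (our
detectability proxy; the study could not detect Abeta in the lumen medium).
The stated initial value corresponds to roughly 33 h of secretion at the
stated rate; we use the printed number verbatim.

## The permeability read-out

The estimator implements the standard control-volume relation

$$P = \frac{V_g}{A_v}\,\frac{1}{\Delta I_m}\,\frac{d\bar{I}_g}{dt},$$

with $\Delta I_m = I_{lumen}(0) - I_{gel}(0)$ and, by default, the
two-point slope between $t = 0$ and $t = 600$ s (the published read-out;
an OLS regression over a configurable window is also provided, matching the
2-h acquisition description). For a CV spanning the full interface,
$V_g/A_v$ reduces to the CV depth, independent of channel height. Saturated
pixels are excluded from means; above 5% saturation the estimate is
flagged.

Because intensity is modelled (and assumed) linear in concentration, the
read-out is exactly invariant to detector gain and offset — both the slope
and $\Delta I_m$ scale with gain, and a uniform background cancels in
$\Delta I_m$.

### Control-volume placement

The CV is a rectangle in the scaffold gel touching the monolayer and
spanning the full interface. Its default depth is the **full scaffold
width** rather than a shallow band: with the diffusivities above, the
tracer front travels ~200-300 um in the 600-s window, so a 200-um CV loses
up to a third of the transferred mass past its distal edge, biasing the
read-out low at *any* permeability. A full-depth CV captures the front;
`depth_um` restores the shallow convention when wanted.

### Validity envelope

The relation above assumes the transmural driving force stays at its t = 0
value. In reality the gel side of the membrane accumulates tracer (and the
lumen side depletes) with a resistance that grows like
$\sqrt{t/(\pi D_{gel})}$, so the read-out reports an *effective*
permeability — membrane conductance in series with transient gel and lumen
diffusion resistances. The bias scales with
$\beta = P\sqrt{t/D_{gel}}$: negligible for
$P \lesssim 5\times10^{-7}$ cm/s with these gels (round-trip recovery is
then accurate to ~1-3%, as the tests verify), but growing to tens of
percent across the published range
($1.96\times10^{-6}$ to $1.4\times10^{-5}$ cm/s) — the acceptance script
recomputes exactly how far each published value is under-recovered by a
noiseless synthetic round trip. This is a property of the assay equation
itself, not of the solver: published permeabilities produced by this
read-out are best read as effective (lower-bound) values, and differences
between groups remain monotone and highly significant. The estimator-side
tests therefore check exact recovery in the membrane-limited regime and the
monotone worsening of the underestimate outside it.

## Synthetic imaging and cohorts

Rendering maps concentration to intensity as
`pixel = gain * C + background`, with optional Poisson shot noise and
additive Gaussian read noise, clipped at the bit-depth ceiling. Defaults
(gain 5e4 per mol m^-3, background 100, sigma 2, 16 bit) put the 10-uM
lumen at ~500 counts and keep slope noise a few percent of the signal for
the published permeability range; all noise parameters are ours (the study
reports none) and are recorded in the stack metadata. No photobleaching,
PSF blur, depth attenuation or cell texture is modelled — passing tests
show estimator correctness under linear imaging, not robustness to optical
artefacts.

Cohorts draw per-device permeabilities log-normally with the requested
arithmetic group means and a coefficient of variation of 0.25 (our choice;
permeabilities are positive and right-skewed and the study reports only
mean ± SEM), with the study's group sizes (13 WT, 25 AD) and 40-kDa day-3
means (1.96e-6 vs 6.45e-6 cm/s) as defaults. A master seed drives the
draws; per-device sub-seeds are drawn from the master stream and recorded,
so every report is reproducible from (config, master seed, version). At
this dispersion the pooled two-sample t test (Student's form, as in the
study; Welch behind a flag) rejects at p < 1e-4 in essentially every
cohort; `cohort_separation_power()` measures that rejection rate on the
drawn permeabilities directly, since estimator noise is negligible relative
to a 25% inter-device CV.

## Problem sizes and persistence

Default grids use dx = 50 um (discretisation error ~0.02% on the day-3
barrier-adjacent concentration against dx = 25 um). Assay simulations store
snapshots on the 300-s frame clock; accumulation runs snapshot hourly.
Histories persist as plain-text CSV matrices plus a JSON config echo;
time-lapses as multi-plane 32-bit float TIFF with a JSON sidecar carrying
timestamps, pixel size and the imaging parameters.

## Known limitations

* No advection, aggregation/deposition kinetics, or receptor-mediated
  transport; the study's CAA deposition imaging has no stated kinetics and
  is not modelled.
* Post arrays bounding the channels are not modelled; interfaces are fully
  open.
* The published device dimensions appear only as figure annotations; the
  defaults (1 mm channels, 0.5 mm barrier MC, 7.5 mm length) are
  configurable and no result in this package depends on them.
* The two-point read-out's back-diffusion bias (above) is inherent to the
  assay equation; the package quantifies it rather than correcting it.
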
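---
title: "Estimating water permeability of membrane channels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating water permeability of membrane channels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waterperm)
```

# Scope and conventions

`waterperm` computes water (and small-solute) permeability coefficients
of narrow membrane channels from two kinds of data: particle
trajectories in a channel-aligned frame, and stopped-flow relaxation
traces. Internally all trajectory quantities use nm and ns; the z axis
is the pore axis with the pore centre at z = 0 and the extracellular
side positive, so that the signs of order-parameter and PMF profiles
are directly comparable across datasets. Permeabilities appear in
cm-based units only at the reporting boundary (cm/s macroscopically,
cm^3/s per channel), which confines unit conversion to a single,
auditable place.

# Trajectory estimators

## Translocation counting and p_d

A molecule's axial path is classified frame by frame against two event
planes as below, inside, or above. Only the full sequence
below → inside → above (or its mirror) records a translocation; an
excursion that retreats to its entry side records nothing, and the
state machine resets whenever a molecule leaves the trajectory, so
reservoir exchange can never stitch two molecules into one event. The
event planes default to the lumen extended outward by a 0.05 nm
hysteresis band. Without hysteresis, a molecule dithering across a
single boundary generates spurious enter/exit pairs; pushing the
planes outward suppresses this chatter at the cost of a slightly
longer nominal crossing. (The geometry type permits event planes
anywhere relative to the lumen; the outward default is the
scientifically safer choice.)

At equilibrium the two directions are symmetric, so the unidirectional
transport rate is half the bidirectional event rate,
`q0 = N / (2 t n_monomers)`, and `p_d = v_w q0` with
`v_w = 18 cm^3/mol / N_A`. The Poisson standard error `sqrt(N)`
propagates through. This factor-of-two convention is stated here
prominently because printed per-channel p_d values in the literature
are sensitive to exactly this normalization (which counting region,
whether both directions are pooled), and published tables do not
always pin it down; the package validates its convention against its
own brute-force oracles rather than against any single printed value.

## The collective coordinate and p_f

The osmotic permeability of a single pore is a linear-response
quantity: it can be read off equilibrium fluctuations of the
collective water coordinate n(t), the cumulative sum of in-lumen
axial displacements divided by the pore length L. Each step
contributes `dn = sum_i dz_i / L` over molecules inside the lumen at
either endpoint of the step, with displacements clipped to the lumen
so molecules entering or leaving mid-step contribute only their
in-lumen portion. Clipping is a first-order treatment of partial
residence; whether printed analyses clipped is typically unstated, but
for the sampling intervals used here (much shorter than a crossing)
the difference is below the statistical noise.

D_n is the slope/2 of the MSD of n(t) against lag time, averaged over
all time origins, and `p_f = v_w D_n`. The default lag window spans 2
to 20 sampling intervals, log-spaced: the shortest lags are excluded
as discretization-dominated, long lags as noise-dominated (few
independent origins). For confined diffusers the MSD also bends once
`sqrt(2 D tau)` approaches the confinement length, so the window must
sit well below L^2/D; the shipped analyses choose sampling so that
`sqrt(2 D tau_max)` stays below ~0.1 L. Standard errors come from
re-estimating D_n on five contiguous trajectory blocks.

## Axial profiles

The density profile normalizes the axial histogram by the local pore
cross-section and by bulk water, `n(z) = counts / (frames Lx(z) Ly(z)
dz) / rho_bulk`, with rho_bulk defaulting to the TIP3P value
33.37 nm^-3. The cross-section is an input (a constant pair or a
table): for synthetic cylindrical pores `Lx = Ly = 2r`. Boltzmann
inversion gives `W(z) = -kB T ln n(z)` with kB = 0.0019872
kcal/(mol K); zero-count bins are masked rather than set infinite so
that barrier extraction never propagates infinities, and the profile
is anchored to zero at its minimum over a reference region (default
|z| >= 0.9 nm, i.e. bulk-like vestibule water; profiles that do not
reach that far fall back to the global minimum). The default bin
width of 0.05 nm resolves ~0.1 nm PMF features without starving bins
at ordinary trajectory sizes.

The dipole order parameter is the per-bin mean of `cos theta = u_z`
for unit dipole vectors; values near zero mark free rotation
(vestibules), a sign change across the centre marks the reorientation
that blocks Grotthuss proton hopping. Hydrogen bonds use the de facto
standard geometric criterion — donor–acceptor distance <= 0.35 nm and
D–H···A within 30 degrees of linearity — applied symmetrically to
water–water pairs and, when a partner-site table is supplied, to
water–protein donors/acceptors. Whether published H-bond counts used
a geometric or energetic criterion is often unstated; counts from
different criteria agree only qualitatively, so water-file H-bond
profiles should be read as shapes, not absolute numbers.

# The synthetic single-file generators

No deposited trajectory accompanies the analyses this package targets,
and desk-scale hardware cannot regenerate hundreds of ns of all-atom
dynamics. The generators therefore produce *surrogate* single-file
trajectories whose ground truth is known exactly, in two variants
sharing one trajectory container.

**Vacancy hopping.** A row of `n_sites` hard-core sites spans the
lumen; particles hop to adjacent empty sites (Metropolis acceptance on
a tabulated site potential) and exchange with single-slot reservoir
buffers held at occupancy q by balanced insertion/deletion
(`p_ins = p_ex q`, `p_del = p_ex (1 - q)`). The chain is reversible
with respect to a product-Bernoulli grand-canonical measure, so the
stationary occupancy is known in closed form — this is the variant
every counting estimator is validated against, via an independent
plain-R re-simulation of the same rules. In addition to vacancy hops,
a concerted knock-on move translates the entire column by one site
when the pore is full and the far buffer empty. The move is its own
mirror image with zero energy difference, so it provably leaves the
equilibrium measure untouched; kinetically it supplies the concerted
column translation that characterizes tight water files. This matters
for the single-file diagnostic: a pure vacancy chain (simple exclusion
process) has its tracer transport suppressed relative to collective
transport in a way that yields `pf/pd - 1` closer to O - 1 than to the
occupancy O, whereas with the knock-on channel dominant — the dense
regime, which is the physically relevant one for a water file at
near-close packing — the classic `pf/pd = N + 1` law emerges. The
reservoir exchange attempt rate defaults to five times the hop rate:
bulk water exchange at a pore mouth is not the rate-limiting step.

**Brownian hard cores.** Overdamped Langevin dynamics on the axis
with a tabulated potential, reflecting outer walls, grand-canonical
buffer slabs beyond the pore ends, and hard-core no-passing exclusion
enforced by move rejection *within the pore region only*: the buffer
slabs represent vestibule water, which is three-dimensional and can
pass. (If exclusion extended into the slabs they would become part of
the single file, and the permeability ratio would track the total file
occupancy including the slabs instead of the lumen occupancy.) With
exclusion disabled and the reservoir closed this variant degenerates
to independent diffusers in a box — the analytic oracle
`D_n = M D / L^2` — and with a potential it is the Boltzmann sampler
used to validate density binning and PMF inversion.

Defaults mimic a UT-B-like pore: lumen 1.4 nm, effective radius
0.221 nm, five sites (water-water spacing ~0.28 nm), hop attempts at
20 /ns, 10% of each run discarded as burn-in before statistics.

What the surrogates deliberately do not model: three-dimensional water
structure, protein flexibility, electrostatics, or the absolute
friction inside a real channel. Passing estimator tests on them
demonstrates that the estimators are correct implementations of their
definitions and that their statistical machinery (SEs, windows,
hysteresis) behaves; it does not certify absolute permeability values
for any real channel.

**Numerical choices.** The Brownian integrator is Euler–Maruyama with
single-step reflection; its boundary layer scales with the step width
`sqrt(2 D dt)`, so runs that profile densities near walls use steps
small enough to keep that width below one histogram bin. PMF recovery
is judged against the *bin-integrated* Boltzmann weight, since
comparing to the mid-bin potential value introduces a purely
geometric O(bin^2) bias where the potential is steep. Validation of
the `pf/pd - 1 = O` diagnostic uses dense files (buffer occupancy
0.95) at three pore sizes (4, 6, 8 sites) — the regime the single-file
law describes — with durations (2.5–4 microseconds of model time) set
so that Poisson counting error stays near 3–5%.

# Stopped-flow calculus

Relaxation traces are fitted by nonlinear least squares
(Levenberg–Marquardt, initialized from a log-linearized tail fit) to
one or two exponentials plus baseline; two phases are reported as
resolved only when the rate ratio exceeds 3, otherwise the fit warns
of degeneracy. Non-convergence is an error, never a silent default.

The conversion formulas are reconstructed from the standard variable
definitions: `Pf = k (V/S) / (V_W C_out)` (van-Heeswijk-style
light-scattering analysis), `Pd = k (V/S)` with V/S = r/3 for
spherical ghosts (isotopic exchange), and `P = k (V/S)` for the
simplified NH3/H+ analyses, with an exposed multiplicative correction
factor (default 1) as the hook for buffer-capacity treatment of proton
uptake, whose exact published form varies. Because assembled equations
are frequently elided in papers, the package cross-validates the forms
by back-solving V/S from published paired (k, P) control values: the
osmotic and exchange rows imply V/S of 6.7e-5 and 6.5e-5 cm
respectively (3% apart), and the proton row 6.1e-5 cm, confirming the
reconstruction. This back-solve also fixes the C_out convention:
C_out is the *post-mixing total* extracellular osmolality, and the
published control rows are mutually consistent only when the quoted
mannitol gradient (400 mosM) is read as the gradient experienced by
the cells after mixing, i.e. C_out ≈ 300 + 400 = 700 mosM = 7e-4
mol/cm^3 — the package default. Under the alternative reading (400
mosM in the stock, halved by equal-volume mixing, C_out = 5e-4) the
implied V/S values disagree by ~27%. Users should always set C_out to
their actual protocol.

Unit permeabilities `(P_control - P_null) area / copies` require the
membrane area per cell, which published tables rarely state. The
default (1.0e-6 cm^2) is *back-solved* from a published unit
permeability and flagged as a reconstruction in the API every time it
is used implicitly; it is within a factor ~1.4 of the textbook red-cell
area, but any quantitative use should supply a measured area. The
single-file water count is reported raw, to one decimal, and as the
nearest integer, because published usage mixes the latter two
conventions. Arrhenius energies use the least-squares line through
(1/T, ln k) with R = 0.0019872 kcal/(mol K).

# Pipeline and reproducibility

`run_pipeline()` orchestrates simulate → analyze → report with a
single integer seed governing every stochastic step; identical
(config, seed) pairs produce byte-identical JSON reports, and file
inputs are logged with MD5 checksums. A deterministic fixture with
exactly 257 complete translocations over 200 ns and 3 monomers ships
with the package (`extdata/utb_events_synthetic.tsv`, a constructed
stand-in, not simulation output); it anchors the event counter's
bookkeeping: 257 / (200 x 3) = 0.43 waters per monomer per ns, i.e.
4.3e8 molecules per channel per second.

# Known limitations

* The surrogate dynamics carry no absolute timescale calibration;
  single-channel p_f/p_d magnitudes from the generators are
  model-scale, and only dimensionless diagnostics (occupancy,
  pf/pd - 1) transfer to real channels.
* The `pf/pd - 1 = O` relation is kinetics-dependent: it holds in the
  dense, knock-on-dominated regime and degrades toward vacancy-mediated
  or boundary-limited regimes. The package reports both sides of the
  comparison rather than asserting the law.
* H-bond counting requires explicit hydrogen coordinates; no attempt
  is made to infer protonation or to use an energetic criterion.
* The proton-permeability correction factor is exposed but defaults to
  1; quantitative proton work must supply the buffer-capacity factor
  for its own system.
* Trajectory input is plain text (XYZ or delimited tables); binary MD
  formats are out of scope for the core and belong in external
  converters.
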
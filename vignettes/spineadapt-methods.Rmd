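---
title: "Methods: coupled disc adaptation and vertebral bone remodelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled disc adaptation and vertebral bone remodelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineadapt)
```

This vignette is the package's account of the science it implements: the
model equations and their assumptions, the parameters that matter with
their units and defaults, the calibrations that were performed once and
frozen, the numerical choices, and what the synthetic fixtures do and do
not establish about real tissue.

## Scope and architecture

`spineadapt` simulates the adjacent segment of a lumbar fusion: one
intervertebral disc and one vertebra, driven by a *change* in loading.
The change is supplied by the user as per-mode scale factors
(`load_change_factors()`), standing in for the output of a full lumbar
spine finite-element model, which is out of scope.  Mechanics inside the
disc are provided through a pluggable provider interface
(`solve_activity()`): a coarse linear poroelastic solver, and an analytic
"synthetic" provider that attaches prescribed radial stimulus profiles to
the mesh and scales them with load magnitude.  The adaptation laws
consume only time-averaged scalar fields (deviatoric strain, fluid speed,
strain energy density), which is what makes this decoupling viable.

## Disc tissue model

### Composition, osmotic pressure and swelling

Each element carries an initial solid volume fraction $n_{s,0}$, collagen
and GAG dry-weight fractions, a fixed charge density (FCD, mEq/ml), and a
water (fluid volume) fraction.  Baselines: nucleus pulposus (NP)
$n_{s,0}=0.20$, collagen $0.15$, FCD $0.30$; annulus fibrosus (AF)
$0.25$, $0.65$, $0.20$.  GAG is carried as the dry-weight complement of
collagen, which makes the NP baseline GAG $0.85$ and the AF $0.35$ —
exactly the preferred matrix contents of the chondrocyte and fibroblast
phenotypes, so a healthy disc is a fixed point of the dynamics by
construction.

The osmotic pressure difference against a physiological bath
($c_{ext} = 0.15$ mEq/ml, $T = 310$ K) is the ideal Donnan form
$$\Delta\pi = \phi R T\left(\sqrt{FCD^2 + 4(\gamma c_{ext})^2} -
2\gamma c_{ext}\right),$$
with osmotic and activity coefficients defaulting to 1
(`donnan_pressure()`).

**GAG to FCD.**  `gag_to_fcd()` converts GAG content to FCD from the
molecular weights and charge numbers of chondroitin sulfate (CS, 2
charges per 513 g/mol disaccharide) and keratan sulfate (KS, 1 per 464
g/mol), an effective dry-matrix density, and the fluid fraction (FCD
dilutes with water).  Two scalars are calibrated once in closed form
(`gag_fcd_calibration()`) so the NP and AF baselines map to 0.30 and
0.20 mEq/ml.  A single global CS:KS ratio cannot reproduce both anchors:
the required charge-per-gram ratio between AF and NP (about 1.52) lies
inside the CS/KS span (1.81), so the package keeps the NP CS:KS mass
ratio at 0.25 and solves for the effective dry-matrix density
(0.113 g/ml) and the AF ratio (16.8).  These are *effective* parameters:
their job is to anchor the baselines, not to report glycosaminoglycan
biochemistry, and both are config-overridable.

**Free swelling.**  `free_swelling_equilibrium()` finds, per element, the
water fraction $w$ at which $\Delta\pi(FCD(w))$ balances the elastic
tension of the solid network stretched beyond its stress-free porosity
$w_0 = 1 - n_{s,0}$:
$$\Delta\pi(FCD(w)) = K_{eff}\,\frac{w - w_0}{1 - w_0},\qquad
K_{eff} = n_{s,0}\left[(1-\rho_c)K_{nf} + \rho_c E_f/9\right],$$
solved by `uniroot` to $10^{-10}$.  The effective moduli
($K_{nf} = 17.6$ MPa, $E_f = 340$ MPa) were chosen once so the baseline
NP equilibrates near water 0.815 and the AF near 0.755, inside the
healthy-to-degenerate NP water span of 0.81–0.75 used by the grade
translation; $E_f/9 > K_{nf}$ makes the equilibrium water decrease with
collagen and increase with GAG, as it should.  These are drained
small-strain stiffnesses of the composition-weighted network, not fibril
tissue moduli.

### Stress evaluation

`evaluate_stress()` implements the small-strain composition-weighted
total stress: the solid contribution scales with $n_{s,0}$ and splits
into an isotropic non-fibrillar part (weighted by $1-\rho_c$) and
tension-only fibril stresses along the element's fibre directions
(weighted by $\rho_c$, shared equally across fibrils; the NP's dispersed
fibrils resist volumetric expansion only); pore pressure and $\Delta\pi$
act hydrostatically.  This replaces the full fibril-reinforced
swelling formulation by design: the adaptation laws never see the stress
tensor, only the scalar stimulus fields, so a linearised mechanics with
osmotic prestress suffices, and the free-swelling balance above is
exactly the volumetric response of this stress model (a property the
test suite asserts).

### Mechanics providers

The **poroelastic** provider treats the disc as a radially draining
biphasic annulus on the polar element grid.  Static loads (standing
compression; sitting flexion plus half-hour creep) drive an implicit
finite-volume consolidation solve per angular sector — storage
$S = 1/H$ with $H$ the composition-dependent confined modulus, Darcy
permeability $k = 10^{-3}$ mm⁴/(N·s), drained rim, zero-flux centre —
giving pore pressure, confined axial strain
($\varepsilon^{dev} = \tfrac{2\sqrt2}{3}|\varepsilon_z|$) and fluid
speed $v_f = k|\nabla p|/w$.  Bending maps the imposed angle to a linear
axial strain field across the cross-section; axial rotation is pure
shear ($\gamma = \theta r/h$, no volumetric change, no flow).  The
finite-volume form is conservative: the suite checks that the total
fluid volume change equals the accumulated boundary flux.  Two honest
limitations: the confined idealisation means 0.5 Hz oscillatory modes
produce almost no interior strain (the undrained confined response is
nearly rigid; real discs bulge), and composition feeds back on mechanics
only between macro windows.  The provider exists to give the package a
physically grounded mechanics path and to host the preconditioning
(three day/night compression–creep cycles, `precondition()`); the
headline adaptation runs use the **synthetic** provider, whose radial
profiles are calibrated so the NP sits in the cartilage window and the
outer AF in the fibrous window at baseline loads (see below).

## Mechanical stimulus and phenotype

`daily_stimulus()` aggregates the per-activity fields into
$$\psi = \frac{1}{16}\left(\frac{\sum_a \varepsilon^{dev}_a[\%]\,h_a}{4.67}
+ \frac{\sum_a v_{f,a}[\mu m/s]\,h_a}{3}\right)$$
with hours $(5.5, 2, 4.5, 4)$.  The strain divisor 4.67 (instead of the
classical 3.75) encodes the shift of the fibrous/cartilage strain
threshold from 11.25% to 14% that accounts for the residual
swelling/collagen-tension strains of disc tissue: 14%/4.67 ≈ 3, so the
phenotype thresholds stay at $\psi = 3$ (fibrous above) and $\psi = 1$.
Units are a convention the stimulus definition fixes: strain enters in
percent, fluid speed in μm/s with the original 3 μm/s normalisation.
Boundary values belong to the lower class (deterministic tie-break).
$\psi \le 1$ (the bony regime of the original theory) is labelled
`low_stimulus` and treated as chondrocyte-preferred for rate switching,
since disc ossification is outside the model; occurrences are reported.

## Cell and matrix dynamics

Fibroblast and chondrocyte concentrations (normalised to the cell space,
`c_space = 1`) evolve by daily explicit Euler steps of
$$\frac{dc_i}{dt} = f^{prolif}_i c_i\left(1-\frac{c_i}{c_{space}}\right)
- f^{differ} - f^{apopt}_i c_i$$
with rates switched on/off by the preferred phenotype: the preferred type
proliferates logistically and receives a conversion flux
$f^{differ}_{src}\,c_{src}$ from the non-preferred type (differentiation
is modelled as conversion at the source type's rate, conserving cells up
to apoptosis); the non-preferred type loses differentiation and
apoptosis.  Rates (day⁻¹): fibroblasts 0.5/0.2/0.05, chondrocytes
0.2/0.14/0.1, making the preferred-state fixed points
$c^* = (1 - f^{apopt}/f^{prolif})c_{space}$ = 0.9 (fibroblasts) and 0.5
(chondrocytes); synthetic discs start their home regions at 0.9.

Matrix fractions ($i$ = collagen, GAG) follow, per cell type,
$$\frac{dm_i}{dt} = f^{synth}_i c\left(1-\frac{m_i}{m_i^{pref}}\right)
- f^{degrad1}_i c - f^{degrad2}\, c\, \frac{m_i - m_i^{pref}}{m_i^{pref}}
+ \text{turnover},$$
where synthesis acts for the preferred type and is clamped at zero when
$m_i \ge m_i^{pref}$ (overshoot removal is the job of the excess term,
not of negative synthesis); $degrad1$ is the constant-rate degradation by
the non-preferred type; the excess degradation
($degrad2 = 0.0011$ day⁻¹) acts for either type only while
$m_i > m_i^{pref}$ of that type, as written.  Natural turnover by the
preferred type uses the half-life-derived rates (collagen
$3\times10^{-5}$ day⁻¹, GAG $1.6\times10^{-4}$ day⁻¹ ≈ ln 2 / 12 y) as a
degradation balanced by an equal baseline synthesis, implemented as the
net flux $k_{turn}(c/c_{ref})(m^{pref}_i - m_i)/m^{pref}_i$ — healthy
tissue is thereby exactly stationary, which is the stated purpose of the
turnover extension.  (The printed collagen rate and the quoted 95-year
half-life are mutually inconsistent under $\ln 2/t_{1/2}$; the printed
rate constant is used as-is.)  Preferred contents and rates (day⁻¹):

| cell | matrix | $m^{pref}$ | $f^{synth}$ | $degrad1$ |
|---|---|---|---|---|
| fibroblast | collagen | 0.65 | 4.8e-3 | 2.6e-3 |
| fibroblast | GAG | 0.35 | 0.85e-3 | 0.45e-3 |
| chondrocyte | collagen | 0.15 | 3.1e-3 | 1e-3 |
| chondrocyte | GAG | 0.85 | 7.7e-3 | 2e-3 |

All concentrations and fractions are clamped to their unit intervals
after every step.  After each adaptation window the FCD and water are
re-equilibrated from the new GAG via `gag_to_fcd()` and
`free_swelling_equilibrium()`.

Because synthesis toward a target and excess-degradation away from it
have different time constants, switching the phenotype back and forth is
only approximately reversible, and only over short excursions; the suite
checks a three-day excursion returns within 0.02 absolute.

## Degeneration grade

`translate_grade()` converts the simulated *relative* NP water change to
an absolute content using the baseline grade's representative water, then
looks the result up in a monotone grade–water table spanning 0.81
(grade I) to 0.745 (grade V).  The interior break points of
`grade_water_table()` are an assumption — the literature gives a monotone
decline, not universal cut-points — and every entry is
config-overridable; out-of-range water is clamped with a warning.

## Bone remodelling

Site-specific form: with the pre-operative SED field as reference,
$$\frac{d(BV/TV)}{dt} = g\,(SED_{post} - SED_{ref})\cdot\alpha\cdot
\frac{BS}{TV},\qquad \frac{BS}{TV} = \frac{2\,BV/TV}{r},$$
where the osteoclast terms of the underlying cell-level theory cancel
exactly in the difference, so identical pre/post loads give a bitwise
invariant field.  The gain $g$ is the product of the osteoblast formation
rate ($\tau$ = 475 μm³/(nmol·day)) and osteocyte mechanosensitivity
($\mu$ = 1 nmol/((MPa/s)·μm²)), both fitted quantities whose individual
units do not compose cleanly; only their product matters and it is
converted once to $g = 0.475$ mm/(MPa·day) and exposed in config.
$\alpha = 0.5$ of the strut surface is remodelling-active; the strut
radius (0.1 mm) and the modulus law $E = E_{tissue}(BV/TV)^2$ with
$E_{tissue} = 6000$ MPa (giving ≈240 MPa at BV/TV 0.2, a standard
cancellous value) are config-exposed defaults.

`sed_field()` evaluates the compressive load case — the dominant mode —
as a statically determinate homogenised load path: uniform axial stress
$\sigma = F/A$ through every voxel column, $SED = \sigma^2/2E$ per
element.  Stress control makes element SED a decreasing function of its
own density, so the remodelling loop is self-limiting; the alternative
(stiffness-proportional load sharing between parallel columns) makes SED
increase with own stiffness and is structurally unstable under SED
homeostasis — dense regions run away while shielded regions resorb — so
it was rejected.  The cost is that genuine load redistribution
(stress shielding) is not represented.

`remodel_to_steady()` integrates the rate with explicit steps from
$dt = 1$ day until $\max|rate| < 10^{-7}$ day⁻¹.  Since only the steady
endpoint of a macro window is used, the step is allowed to grow
geometrically (factor 1.1, capped at 64 days) while the squared SED
mismatch of unclamped elements decays monotonically; oscillation (error
growth with rate sign flips) halves the step and caps further growth,
and a mismatch pinned at its numerical floor by clamped elements (a
cortical shell stuck at BV/TV 1) is accepted as the temporary steady
state.

## Coupling schedule

`make_schedule()` produces 90-day windows for the first post-operative
year — when changes are largest — then 180-day windows; a 10-year horizon
gives 4 + 18 windows (3600 days; the 50-day remainder of 10 × 365 is
dropped rather than simulated as a short stub).  Per window the order is
bone-to-steady-state first, then disc mechanics, stimulus, phenotype and
a daily adaptation loop (`spine_adapt()`).  The load change is computed
once at surgery and held fixed; disc-composition feedback into the bone
solve is next-window (the two tissues interact through the shared load
program, not within a window).  Everything is deterministic given the
inputs; all randomness lives in the seeded fixture generators.

## Synthetic fixtures and what the tests show

`make_disc()` builds an elliptical polar template (default 12 rings × 40
sectors ≈ 480 elements of roughly 1.7–2.6 mm, disc radius 20 mm, height
10 mm) with an NP core (inner half of the radius), a one-ring transition
band and AF rings, crossed ±30° fibre pairs in the AF, and the Table
baselines above.  `make_vertebra()` is a shell-and-core voxel surrogate
(default 10×10×8 voxels of 3 mm): a near-unity cortical shell one voxel
thick and a trabecular core drawn from a truncated normal (mean 0.2,
sd 0.05) — a parametric stand-in for an image-derived vertebra, not a
reconstruction.  `make_followup()` adds i.i.d. Gaussian noise clamped to
[0,1], emulating a re-meshed follow-up scan.  `make_stimulus_profile()`
attaches quadratic radial ε/v profiles (9.5→16 % strain, 0.15→2 μm/s)
chosen so that, at baseline loads, the whole NP is chondrocyte-preferred
(ψ ≈ 2.1–2.6), the outer AF fibroblast-preferred (ψ > 3), and the inner
AF a mixed/transition band — and so that a uniform 1.5× load increase
pushes the entire NP across the ψ = 3 boundary.  All generators are pure
functions of their parameters and seed.

What passing tests establish is therefore *internal*: the dynamics hold
their fixed points, respond to load changes in the clinically reported
directions (nucleus becomes more fibrous under overload; no grade change
within two years at these rates; bone densifies modestly), conserve their
invariants, and agree with independent closed-form or refined-step
oracles.  They do not validate the model against patient images: real
discs have patient geometry, nonuniform degeneration, and measured
load changes, none of which the fixtures emulate.

## Numerical choices

* Disc micro step 1 day (explicit Euler); the suite checks 90-day
  agreement with a 0.01-day reference within 1% of the unit state scale,
  and the bounds clamp under 10⁵ randomised steps.
* Stimulus thresholds: boundary values to the lower class; ψ ≤ 1 treated
  as chondrocyte-preferred and logged.
* Synthesis clamped non-negative; excess degradation active only above
  the acting type's preferred content.
* Swelling root-find on $(w_0, 0.999)$, tolerance $10^{-10}$; absence of
  a root is an error, not a silent clamp.
* Bone steady state: rate tolerance $10^{-7}$ day⁻¹, max 20 000
  iterations, pseudo-time acceleration as described.
* Composition is element-constant (fields live at element centres);
  fibre directions are fixed (AF fibre reorientation is out of scope).
* Default problem sizes — 480-element disc, 800-voxel vertebra, 2–10
  year horizons — keep a full coupled run in seconds; they are the sizes
  at which the reported numbers were produced.

## Known limitations

The mechanics providers are deliberately coarse: confined radial
consolidation under-represents dynamic strains, and the bone load path
ignores redistribution.  Nutrient transport, cell migration,
inflammation, fibre remodelling, facet contact and ligaments are out of
scope.  The grade–water break points and the GAG→FCD region ratios are
effective calibrations.  The patient-specific pipeline (image-derived
geometry, per-patient load changes from a whole-lumbar-spine model,
follow-up comparison against CT) is represented only by its interfaces:
the element-index field mapping (`map_fields()`), the 2-mm spherical
smoothing, the 1.9% minimal-detectable-change gate and the per-element
correlation (`outcome_report()`).
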
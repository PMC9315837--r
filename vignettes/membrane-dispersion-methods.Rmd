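---
title: "Models and numerical methods in mchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in mchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mchrom)
```

`mchrom` simulates frontal membrane chromatography with two deliberately
different descriptions of band broadening, and provides the
method-of-moments machinery to translate between them. This vignette is
the package's account of the models, the tunable parameters, and the
numerical decisions behind the implementation.

## The transport model

The bed is a stack of membranes of total thickness $L$ (cm), frontal area
$A$ (cm²) and void fraction $\varepsilon$. At volumetric flowrate $F$ the
interstitial velocity is $\langle v\rangle = F/(\varepsilon A)$. The
solute balance with local-equilibrium adsorption is written with all
accumulation lumped on the time derivative,

$$\phi(c)\,\frac{\partial c}{\partial t}
  + \langle v\rangle \frac{\partial c}{\partial z}
  = D_L \frac{\partial^2 c}{\partial z^2},
  \qquad
  \phi(c) = 1 + \frac{1-\varepsilon}{\varepsilon}\frac{dq}{dc},$$

with a clean bed at $t = 0$. The adsorbed concentration $q$ is expressed
per unit volume of *solid* membrane material — that convention is fixed
throughout the package, and is why the factor $(1-\varepsilon)$
multiplies $q$ in every mass balance. For the bi-Langmuir isotherm

$$q(c) = \frac{q_m^{irr} c}{K_d^{irr} + c} + \frac{q_m^{rev} c}{K_d^{rev} + c},$$

an irreversible site is the limit $K_d^{irr} = 0$: a step of height
$q_m^{irr}$ at $c = 0^+$. Only the equilibrium form is implemented; no
rate constants enter the model, so binding kinetics beyond local
equilibrium are out of scope.

Extra-column equipment is represented by two lumped volumes: a plug-flow
delay $V_{PFR}(F)/F$ (the tubing volume may grow linearly with flowrate)
followed by a stirred tank with time constant $V_{CSTR}/F$. Both units
are linear and time-invariant, so their order is immaterial for the
outlet signal; the package applies them upstream of the bed. For a
non-binding (linear) bed this placement is provably irrelevant; for an
adsorbing bed it is a modelling choice, documented here.

## The polydisperse pore-bundle model

The alternative description treats the membrane as $n_p$ straight
cylindrical pores with radii drawn from a Gaussian density truncated to
an effective support (below). With Hagen–Poiseuille flow, the flow
through a pore scales as $r^4$, the mean velocity in a pore of radius
$r$ is $v_m(r) = \langle v\rangle\,(M_2/M_4)\,r^2$ (with $M_k$ the
discrete raw moments of the radius distribution), and the pore residence
time is $\tau(r) = L / v_m(r)$. Intra-pore (Taylor–Aris) dispersion and
pore connectivity are neglected by construction; every pore sees the
same inlet. A step feed then breaks through as the flow-weighted
superposition of delayed steps

$$\frac{c_{out}(t)}{c_0} = \sum_k w_k \, \mathbf{1}\{t \ge \tau_k\},
  \qquad w_k = \frac{r_k^4 f_k \Delta r}{\sum_j r_j^4 f_j \Delta r}.$$

Two useful exact identities follow from the $r^4$/$r^2$ algebra and are
enforced as tests: the flow-weighted mean residence time equals
$L/\langle v\rangle$ regardless of the distribution, and the whole model
is self-similar in $t\langle v\rangle$ — running it at flowrate $aF$ and
rescaling time by $1/a$ reproduces the $F$ curve to rounding.

### Regularization and the method of moments

The discrete breakthrough is a staircase. It is regularized by
least-squares fitting of a lag-shifted logistic

$$c(t) = \frac{a}{1+e^{-b[(t-t_{lag})-c]}} - \frac{a}{1+e^{bc}},
  \qquad t > t_{lag},$$

which is identically zero up to the lag time. $t_{lag}$ is *not* fitted:
it is the residence time of the fastest retained pore, a known quantity
of the bundle, leaving $a$, $b$, $c$ as the three adjustable parameters.
The pulse response is the analytic derivative of this fit (maximum
$ab/4$ at $t_{lag}+c$), and the method of moments converts its second
central moment $\bar\mu_2$ into a dispersion coefficient.

Two conventions for that conversion circulate, differing by a factor of
the porosity: $D_L = \bar\mu_2 \langle v\rangle^3 / (2L)$ (the standard
relation when $\langle v\rangle$ is already the interstitial velocity)
and the same expression multiplied by $\varepsilon$. The package
defaults to the porosity-free form: against the exact-moment oracle of
the pore bundle (below), it is self-consistent, while the
$\varepsilon$-version changes every derived $D_L$ by the factor 0.8
under the bundled disc configuration. Both are implemented; every
`moment_summary` records the flag it was computed with, and comparing
summaries across conventions raises an error.

### The exact-moment oracle

Because the bundle's residence-time distribution is available in closed
form, so are its moments: the flow-weighted variance
$\mathrm{Var}_w(\tau) = (L/\langle v\rangle)^2 (M_4 / M_2^2 - 1)$ can be
used *in place of* the fitted peak's $\bar\mu_2$, bypassing the time
grid, the sigmoid and the quadrature entirely
(`bundle_dispersion_oracle()`). This grid-free route is exactly
flowrate-invariant, which is what makes the dispersivity audit sharp:
in `flowrate_sweep()`, any spread of the fitted $\alpha = D_L/\langle
v\rangle$ across flowrates that the oracle does not show is a numerical
artifact of the fitting procedure, not a property of the membrane. With
the default velocity-scaled time grid the fitted spread is at rounding
level; forcing an absolute time step (`fixed_dt_s`) reproduces the
spread that a fixed-grid implementation exhibits, and the audit flags
it.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `theta` | 1e-5 | — | relative-density cutoff of the PSD support |
| `n_bins` | 600 | — | radius bins over the effective support |
| `n_time` | 4000 | — | breakthrough grid intervals |
| `extend` | 1.2 | — | grid extension past the 99.9% crossing |
| `delta` | 1e-3 | mg/mL | regularization of an irreversible site |
| `n_cells` | 400 | — | finite-volume cells across the bed |
| `rtol`, `atol` | 1e-8, 1e-10 | — | stiff integrator tolerances |

The effective PSD support is $[\mu - m\sigma,\ \mu + m\sigma]$ with
$m = \sqrt{2\ln(1/\theta)}$ ($m \approx 4.80$ at the default), clipped
to the nominal bounds $[r_{min}, r_{max}]$. The threshold matters
because the lag time is set by the largest *retained* radius: with
$\theta = 10^{-5}$ the narrow distribution ($\sigma = 0.10\ \mu$m) puts
the support edge at $\approx 1.98\ \mu$m, whereas using the nominal
6.5 µm bound directly would give a lag time several times smaller.
600 uniform bins with midpoint densities renormalized to unit mass keep
the staircase artifacts of the radius discretization below the fit's
resolution; the test suite checks that the staircase-derivative moments
agree with the closed-form variance to 0.5% at 500 bins.

The breakthrough grid runs to the time at which 99.9% of the flow has
broken through, extended by 20%, in 4000 steps. The residual slow-pore
tail (less than 0.1% of the flow) is deliberately cut: for broad
distributions clipped at $r_{min}$ the slowest pores elute an order of
magnitude later than the bulk, and the published-style fitting window
cannot extend there. This truncation — together with the unweighted
least-squares objective over $t > t_{lag}$ — is the single largest
source of spread when comparing fitted $D_L$ values against their
grid-free oracle counterparts, and it is why derived quantities such as
the sensitivity of $D_L$ to $r_{max}$ carry a tolerance of a percentage
point or two rather than machine precision.

The fit itself is bounded Levenberg–Marquardt, initialized from the
curve ($a$: final value; $c$: half-rise time minus $t_{lag}$; $b$:
$4\times$ max slope / $a$), with up to five jittered restarts under a
fixed internal seed, so every workflow is bit-reproducible.

## Numerics of the transport solver

The solver is a conservative finite-volume method of lines integrated
with `deSolve`'s `lsoda` and a banded Jacobian.

**Advection fluxes.** Plain first-order upwinding is unusable here: its
numerical diffusion $\langle v\rangle \Delta z/2$ at 400 cells exceeds
the physical $D_L$ whenever the bed Péclet number exceeds ~800, and
corrupts it long before. Non-binding (smooth) runs therefore use
unlimited 3rd-order upwind-biased (QUICK, $\kappa = 1/3$) face values,
whose leading error is a mild hyper-dissipation that damps start-up
wiggles without inflating the breakthrough variance (a 4th-derivative
term preserves first and second moments). Adsorbing runs with an
irreversible site form a self-sharpening front, where an unlimited
scheme would oscillate; they use van-Leer-limited MUSCL fluxes instead.
The choice is automatic and can be overridden.

**Boundary closures.** Two are provided because they answer different
questions. Adsorption runs use the Danckwerts closure on exactly
$[0, L]$ — prescribed total flux at the inlet face, zero diffusive
gradient at the outlet — which conserves mass to the integrator
tolerance (the suite checks the global balance of a full bi-Langmuir
run to well under 0.5%, and the breakthrough front centre-of-mass
against the stoichiometric time $\,t_{st} = (L/\langle v\rangle)(1 +
\frac{1-\varepsilon}{\varepsilon} q(c_0)/c_0)$ to 1%). Non-binding
validation runs use a prescribed inlet concentration with the domain
extended 25% downstream at unchanged cell size, sampling the outlet
plane by spline: this emulates the semi-infinite medium of the
classical closed-form step response
$$\frac{c}{c_0} = \tfrac12\Big[\mathrm{erfc}\frac{L - \langle v\rangle t}{2\sqrt{D_L t}}
 + e^{\langle v\rangle L / D_L}\,\mathrm{erfc}\frac{L + \langle v\rangle t}{2\sqrt{D_L t}}\Big],$$
against which the solver is verified to $L_\infty < 10^{-3}$ at 400
bed cells over Péclet 50–2000. A Danckwerts column genuinely differs
from that closed form by a few $10^{-3}$ at Péclet 50, so validating
against it requires matching the boundary physics, not loosening the
tolerance. One numerical trap deserves note: the image term
$e^{\langle v\rangle L/D_L}\mathrm{erfc}(x_2)$ must be evaluated in log
space; `erfc` underflows at Péclet beyond ~700 while the term itself is
still of order $10^{-2}$ at the outlet.

**The irreversible-site shock.** $K_d = 0$ makes $dq/dc$ a Dirac spike
at $c = 0$. The capacity factor replaces $K_d = 0$ by a small
$\delta$ (default $10^{-3}$ mg/mL), which caps $\phi(0)$ at a large but
finite value; the mass-balance bookkeeping uses the same
$\delta$-regularized isotherm so the balance closes identically.
`delta_convergence_check()` reruns a configuration at $\delta/2$ and
reports the shift of the half-breakthrough volume; the default is
converged to well under 1% for the bundled experimental configuration.

**Degenerate inputs.** $D_L = 0$ is accepted (pure advection; the
limited scheme is then advisable and a warning fires for QUICK at cell
Péclet > 50). A zero-capacity isotherm is deliberately legal and
reduces the model to the non-binding equation, which the suite asserts.
Equal truncation radii in the $r_{max}$ sensitivity yield exactly 0%.

## What the synthetic conditions do and do not show

All study inputs are parameter sets, not measured chromatograms: a
2.2 cm disc (275 µm, 80% void, $\mu = 1.5\ \mu$m) for the pore-bundle
pipeline, and a 5-layer stack (0.1 cm, 3.8 cm², $\varepsilon = 0.545$)
with a measured dispersivity $\alpha = 0.104$ cm and bi-Langmuir
parameters ($q_m^{irr} = 4.75$, $q_m^{rev} = 7.00$ mg/mL,
$K_d^{rev} = 1.15$ mg/mL) for the transport simulations. The
`synthetic_pulse()` generator produces inverse-Gaussian tracer peaks
with known $D_L$; the suite uses it to show 2% parameter recovery over
Péclet 50–5000. Passing these tests demonstrates internal consistency
of the two model families and of the moments machinery — it does not
validate either model against a real membrane, where finite binding
kinetics, intra-pore dispersion, pore connectivity and detector
broadening all enter.

## Known limitations and one disagreement

- Taylor–Aris intra-pore dispersion is excluded from the pore bundle by
  assumption; at narrow pore-size distributions it would dominate real
  band broadening, so the bundle's $D_L$ should be read as a lower
  bound there.
- Washing and elution stages, competitive adsorption, temperature and
  buffer effects are out of scope.
- A qualitative expectation sometimes attached to this model pair —
  that the two breakthrough curves agree *better* for broader pore-size
  distributions — is not reproduced by the absolute discrepancy metric.
  In this implementation the $L_\infty$ gap grows monotonically with
  $\sigma$ under every pairing we examined (raw staircase or fitted
  sigmoid, against either boundary closure): as the equivalent Péclet
  number falls, the dispersion solution becomes increasingly skewed
  while the bundle curve keeps its hard lag cutoff. What *is* shared at
  every width is the first moment (bed transit time), which both models
  reproduce within 2%, and the suite asserts exactly that, together
  with the observed monotone trend.

## Problem sizes used by the test suite

The suite runs the full pipelines at their default resolutions
(600 radius bins, 4000-step breakthrough grids, 400-cell PDE solves)
for the headline checks, and smaller configurations (100–200 cells,
shorter grids) for properties where convergence is itself the thing
being measured. The complete suite finishes in about half a minute on a
single core.
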
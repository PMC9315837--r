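# mchrom

Breakthrough simulation and dispersion analysis for preparative membrane
chromatography.

Membrane adsorbers capture a target protein (e.g. IgG) from a feed pumped
through a thin stack of macroporous membranes. Designing and scaling such
steps hinges on how band broadening is modelled. `mchrom` implements, side
by side, the two competing descriptions of a membrane bed under frontal
loading, for process modellers who want to compare them quantitatively:

1. **A physical transport model.** One-dimensional convection–dispersion
   with local-equilibrium adsorption,

   φ(c) ∂c/∂t + ⟨v⟩ ∂c/∂z = D_L ∂²c/∂z²,
   φ(c) = 1 + ((1−ε)/ε) dq/dc,

   where ⟨v⟩ = F/(εA) is the interstitial velocity, D_L the axial
   dispersion coefficient, and q(c) a Langmuir or bi-Langmuir isotherm
   (per unit volume of solid membrane; an irreversible site has K_d = 0).
   Extra-column tubing and mixers are modelled as a plug-flow delay plus a
   stirred tank. The solver is a finite-volume method of lines with
   3rd-order upwind-biased (QUICK) fluxes for smooth non-binding runs and
   van-Leer-limited fluxes for self-sharpening adsorption fronts.

2. **A polydisperse parallel-pore model.** The membrane as a bundle of
   straight cylindrical pores whose radii follow a truncated Gaussian
   f(r). Each pore carries Hagen–Poiseuille flow (∝ r⁴), so the outlet
   breakthrough is the flow-weighted superposition of delayed inlet
   steps, c_out(t) = Σ_k w_k c_in(t − τ_k) with τ(r) = L/v_m(r) and
   v_m(r) = ⟨v⟩ (M₂/M₄) r². The discrete curve is regularized with a
   lag-shifted logistic, differentiated analytically into a pulse-response
   peak, and reduced by the **method of moments**
   (µ₁ = L/⟨v⟩, µ̄₂ = 2 L D_L/⟨v⟩³) to an equivalent dispersion
   coefficient D_L and dispersivity α = D_L/⟨v⟩.

Because α is a material property, it must not depend on the flowrate. The
package's sweep-and-audit workflow makes that check explicit: the
grid-free moment oracle of the pore bundle yields an exactly
flowrate-invariant α, so any variation produced by the fitted pipeline is
a numerical artifact of the chosen time grid, and is reported as such.

## Worked example

A single 2.2 cm membrane disc, 275 µm thick, 80% porosity, mean pore
radius 1.5 µm with σ = 0.10 µm, loaded at 1 mL/min:

```r
library(mchrom)

cfg <- load_config(mchrom_example("sartobind_psd.yaml"))
ms  <- psd_to_dispersion(cfg, sigma_um = 0.10)
tidy(ms)
#> # A tibble: 1 × 7
#>      M0 mu1_s mu2_s2 D_L_cm2_s alpha_cm epsilon_in_moments tail_truncated
#>   <dbl> <dbl>  <dbl>     <dbl>    <dbl> <lgl>          <lgl>
#> 1 0.996  4.99  0.455  1.36e-6  2.49e-4  FALSE          FALSE
ms$t_lag
#> [1] 2.946491
```

The peak's mean residence time (4.99 s) is the bed transit time L/⟨v⟩;
its variance (0.455 s²) converts to D_L = 1.36×10⁻⁶ cm²/s and a
dispersivity of 2.49×10⁻⁴ cm. Nothing elutes before the fastest pore's
residence time, t_lag = 2.95 s.

The dispersivity-constancy audit across flowrates:

```r
sw <- flowrate_sweep(cfg, c(1, 2, 5, 10), sigmas_um = 0.10)
sweep_audit(sw)
#> # A tibble: 1 × 4
#>   sigma_um alpha_ratio_fitted alpha_ratio_oracle fitted_variation_is_artifact
#>      <dbl>              <dbl>              <dbl> <lgl>
#> 1      0.1               1.00                  1 TRUE
```

And a full frontal-capture simulation with the bi-Langmuir isotherm and
measured dispersivity of an experimental 5-layer stack:

```r
run <- simulate_experiment(mchrom_example("table1_run.yaml"))
autoplot(run)                      # breakthrough curve vs time
transport_mass_balance(run)        # closes to ~1e-9 relative
```

A thin command-line interface wraps the same functions
(`exec/mchrom simulate|psd2dl|moments|sweep|compare`).

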
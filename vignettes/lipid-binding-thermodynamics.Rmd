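---
title: "Thermodynamics of protein-lipid binding from native MS titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of protein-lipid binding from native MS titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidcycles)
library(dplyr)
```

## The measurement and the model

Variable-temperature native mass spectrometry resolves, in a single
spectrum, a membrane protein with 0, 1, 2, ... lipids bound. After external
deconvolution, the peak intensities of these species become mole fractions
$F_{PL_0} \dots F_{PL_n}$ at each point of a lipid titration. `lipidcycles`
starts from these mole-fraction tables — deconvolution itself is out of
scope — and carries the analysis through three stages:

1. **Sequential binding fits.** With stepwise association constants
   $K_{A,n}$ for $PL_{n-1} + L \rightleftharpoons PL_n$, the species
   fractions follow the binding polynomial
   $$F_{PL_n} = \frac{L_{free}^{\,n}\prod_{j\le n}K_{A,j}}
   {1+\sum_i L_{free}^{\,i}\prod_{j\le i}K_{A,j}},$$
   with the free lipid fixed by mass balance,
   $L_{free} = L_{total} - P_{total}\sum_i i\,F_{PL_i}$. The constants are
   estimated by minimising the pseudo-$\chi^2$,
   $\sum (F_{exp}-F_{calc})^2$, over all species and titration points.
2. **van't Hoff analysis.** Repeating the titration at several temperatures
   gives $K_A(T)$; its temperature dependence yields $\Delta H$ (and, in the
   nonlinear form, $\Delta C_p$). $\Delta G$ comes directly from $K_D$ at
   each temperature and $-T\Delta S$ is back-calculated as
   $\Delta G - \Delta H$.
3. **Mutant cycles.** Differences of these quantities between mutants and
   their parent background quantify the energetic coupling between mutated
   residues — for free energy, and separately for its enthalpic and entropic
   components.

The shipped reference tables (`msba_kdl_table()`) contain the published
values for the *E. coli* ABC transporter MsbA binding the LPS precursor
KDL, in the inward-facing state and trapped outward-facing with ADP and
vanadate; they serve as worked examples and as ground truth for the
package's own consistency checks.

## Units, constants and conventions

* Concentrations are micromolar throughout the binding stage; constants are
  converted to molar only where a logarithm is taken, so
  $\Delta G = RT\ln K_D(\mathrm{M})$ on the 1 M standard state, with
  $R = 8.314462618\times10^{-3}$ kJ/mol/K and temperatures in kelvin.
* Stepwise dissociation constants are $K_{D,n} = 1/K_{A,n}$.
* $\Delta\Delta X$ is mutant minus parent; a positive interaction term
  $\Delta\Delta G_{int}$ means the residues cooperate to stabilise binding.
* Replicates are fit independently; reported values are replicate means with
  sample standard deviations, and SDs combine in quadrature wherever values
  are added or subtracted. Correlation between terms sharing the wild-type
  corner is ignored, matching how such tables are conventionally reported.

## Fitting choices

The mass-balance residual is strictly increasing in $L_{free}$, so the
free-lipid solve brackets the root on $[0, L_{total}]$ (Brent) and polishes
it with Newton steps, using the identity that the derivative of the mean
occupancy is its variance over $L_{free}$; every fit evaluation uses this
exact solve, to a relative mass-balance error below $10^{-10}$.

The pseudo-$\chi^2$ is minimised over $\ln K_A$, which enforces positivity
and conditions the search. A grid of starting guesses spanning $K_D \in
\{0.1, 1, 10\}$ uM per event is ranked by objective value; a coarse
Nelder-Mead simplex runs from the three best starts and the winner is
polished. One-event fits reduce to a bracketed one-dimensional Brent search,
which is global for this smooth objective. $R^2$ is
$1 - SS_{res}/SS_{tot}$ over all mole-fraction entries jointly, about the
grand mean — the conventional choice when a single $R^2$ is quoted per fit.

The number of binding events is normally supplied per variant (different
variants resolve one, two or three events). An optional automatic rule
(`auto_events = TRUE`) drops the highest event when its predicted occupancy
never exceeds 1% across the titration. Titrations with only zero-lipid
points, or fewer points than events plus one, are refused outright.

## van't Hoff models

The linear form is $\ln K_A = -\Delta H/R \cdot 1/T + \Delta S/R$. The
nonlinear form, for a constant heat-capacity change,

$$\ln K_A = \frac{\Delta H_{T_0} - T_0\Delta C_p}{R}
\Big(\frac{1}{T_0}-\frac{1}{T}\Big) +
\frac{\Delta C_p}{R}\ln\frac{T}{T_0} + \ln K_0,$$

is *linear in its three parameters*, so both models are solved exactly by
ordinary least squares (`lm()`) — there is no iterative optimiser to
converge or to seed, and the nonlinear fit constrained to
$\Delta C_p = 0$ reproduces the linear fit identically. The fitted curve is
invariant to the choice of reference temperature $T_0$; only the reported
$\Delta H_{T_0}$ and $\ln K_0$ re-anchor. Four temperatures against three
parameters leaves a single residual degree of freedom, which is the study
design this analysis targets; `model = "auto"` keeps the nonlinear fit only
when it reduces the residual sum of squares by more than half and at least
four temperatures are present, otherwise it falls back to the line.

Enthalpy at an arbitrary temperature follows
$\Delta H(T) = \Delta H_{T_0} + \Delta C_p (T - T_0)$. Each replicate is
fit separately and one $\Delta C_p$ is reported per (variant, event,
replicate); published tables sometimes print slightly different
$\Delta C_p$ values per temperature row, which a single-constant model
cannot generate, so no attempt is made to reproduce that per-row variation.
Outlier temperatures are never dropped automatically: exclusions are an
explicit user-supplied list of (variant, temperature) pairs.

## Mutant-cycle algebra

For a double cycle with parent $P$, single mutants $PX$, $PY$ and double
mutant $PXY$:
$$\Delta\Delta X_{int} = \Delta\Delta X_{PX} + \Delta\Delta X_{PY}
- \Delta\Delta X_{PXY}.$$
The third-order (triple-cycle) coupling is the change of a pairwise
coupling when a third residue is mutated: the $X/Y$ interaction in the
wild-type background minus the same interaction in the $Z$ background. On
any one consistent table this quantity is an alternating sum over the eight
cycle corners and is therefore *identical along all three routes*;
`triple_mutant_cycle()` computes all three and warns (rather than fails)
when independently rounded inputs disagree slightly. The identity
$\Delta\Delta G_{int} = \Delta\Delta H_{int} + \Delta(-T\Delta S)_{int}$
holds exactly by construction and `cycle_consistency()` reports the
residual, which on rounded published tables reflects rounding only.

## The synthetic generator

`build_cycle_truth()` constructs a ground-truth panel from a wild-type
baseline $(\Delta G_{T_0}, \Delta H_{T_0}, \Delta C_p)$ per binding event,
additive per-mutation shifts on $(\Delta G, \Delta H)$ at $T_0$, and
explicit interaction terms $c_G$, $c_H$ subtracted from multi-mutant
corners (a triple term added back for the eighth corner). The entropic
coupling then follows as $c_G - c_H$, keeping the thermodynamic identity
exact. Storing $\Delta G_{T_0}$ rather than $\Delta S$ avoids a redundant
parameterisation.

One consequence worth knowing when designing simulations: because
$\Delta G(T)$ is linear in $(\Delta H_{T_0}, \ln K_0)$ at fixed
$\Delta C_p$, a free-energy coupling designed as $c_G$ at $T_0$ evolves as
$c_H(1 - T/T_0) + c_G\,T/T_0$ at other temperatures, while the enthalpy
coupling stays constant whenever the $\Delta C_p$ terms cancel across the
cycle. The package's tests use this closed form as an oracle.

`simulate_titration()` evaluates the exact model, adds Gaussian noise of SD
`noise_sd` to every mole fraction, clips at zero and renormalises each
titration point — emulating replicate scatter of deconvoluted, normalised
native MS intensities. Defaults mirror the study conditions: 0.39 uM
protein, titrant from 0 to 10 uM over nine points, temperatures
288-303 K (293-310 K for trapped-state scenarios), three replicates, and
`noise_sd = 0.01`, which reproduces the 5-10% relative scatter of the
published replicate K_D standard deviations. The exact titrant grid is not
published; the default grid is an assumption and fully configurable. What
the generator does *not* emulate: raw spectra, charge states, detector
response, deconvolution artefacts, lipid-detergent partitioning. Passing
synthetic tests therefore validates the estimator chain, not the
spectrometry.

## Worked example

```{r}
kd <- kd_table_to_long(msba_kdl_table("kd_inward"))
wt1 <- filter(kd, variant == "WT", event == 1)
vant_hoff_nonlinear(wt1$temperature_K, 1 / wt1$kd_uM, t0 = 298)
```

```{r}
ddx <- msba_kdl_table("ddx_inward")
coupling_from_ddx(ddx, "R78A", "K299A", temperature = 298)
```

End to end on synthetic data:

```{r}
truth <- build_cycle_truth(
  baseline = tibble::tibble(event = 1, dG_T0 = -35.2, dH_T0 = 45, dCp = 8.9),
  shifts = list(R1 = c(dG = 2.7, dH = -60), R2 = c(dG = 2.8, dH = -2)),
  pair_couplings = list("R1:R2" = c(cG = 1.7, cH = -26))
)
panel <- simulate_panel(truth, noise_sd = 0.01, seed = 1)
res <- run_binding_pipeline(panel, model = "nonlinear",
                            cycles = list(list(px = "R1", py = "R2",
                                               pxy = "R1 R2")))
filter(res$cycles, temperature_K == 298)[, c("quantity", "dd_int", "dd_int_sd")]
```

## Numerical notes and limitations

* Simulation sizes in the tests (nine-point titrations, four temperatures,
  three replicates, 200-panel coverage studies) match the study design this
  package targets; larger designs only improve conditioning.
* The sequential model assumes distinct stepwise events; independent-sites
  or mixed high/low-affinity site models are not implemented.
* $\Delta C_p$ is treated as constant over the fitted temperature window;
  no Kirchhoff integration with temperature-dependent $\Delta C_p$.
* Coverage statements for designed couplings use quadrature SDs from n = 3
  replicates, which are themselves noisy; nominal 95% normal intervals
  deliver roughly 90% empirical coverage at that replicate count.
* Missing cycle corners (a mutant lacking a binding event) make that event's
  coupling non-computable; nothing is imputed.
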
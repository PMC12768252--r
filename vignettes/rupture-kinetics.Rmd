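---
title: "Electroporation rupture kinetics: model, estimators, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electroporation rupture kinetics: model, estimators, and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvpore)
```

## The physical model

A giant unilamellar vesicle (GUV) in a uniform, quasi-static electric field
develops a transmembrane voltage $V_m = 1.5\,R\,E\,|\cos\theta|$, the
classical thin-shell result for a sphere whose aqueous interior and
exterior conduct much better than the membrane. Poration initiates at the
poles ($\theta = 0$), so the package evaluates everything downstream at the
pole value $V_m = 1.5RE$. The electro-compressive Maxwell stress of the
interfacial charge appears as an in-plane tension

$$\sigma_e = \varepsilon_m \varepsilon_0 \frac{h}{2h_e^2} V_m^2,$$

quadratic in voltage, hence $\sigma_e = c\,R^2E^2$ with a geometry constant
$c$. Pulse structure (kHz pulsating DC) is treated as metadata: in the
quasi-static limit the duty cycle does not enter the tension, so only the
field amplitude matters here.

A transient low-density defect (prepore) of radius $r$ in a membrane under
total tension $\sigma_e + B$ has free energy
$U(r) = 2\pi r \Gamma - \pi(\sigma_e + B)r^2$: the pore-edge (line) tension
$\Gamma$ penalizes rim length, tension rewards area. $B$ is the constant
electrostatic tension from membrane surface charge. The maximum of $U$ at
the critical radius $r_c = \Gamma/(\sigma_e+B)$ is the nucleation barrier
$U_b = \pi\Gamma^2/(\sigma_e+B)$; prepores that reach $r_c$ expand without
bound and the vesicle ruptures. Thermally activated barrier crossing gives
a constant hazard

$$k_r = A \exp\!\left[-\frac{\pi\Gamma^2}{(\sigma_e+B)\,k_BT}\right],$$

so the intact fraction decays as $P_{\mathrm{intact}}(t) = e^{-k_r t}$ and
$\ln k_r$ is affine in $1/(\sigma_e+B)$ — the linearization that lets a
regression across tensions return $\Gamma$ (slope) and $A$ (intercept).
With a channel-forming peptide (gramicidin A) at mole fraction $\phi$ in
the bilayer, the edge tension is modelled by the biphasic quadratic
$\Gamma(\phi) = \Gamma_0 + a\phi - b\phi^2$. The Helfrich bending energy
density $\tfrac12\kappa(C-C_0)^2$ is provided as the standard vocabulary
for discussing why peptide-induced spontaneous curvature can favour
toroidal pore rims; it does not enter the kinetic fits.

## Parameters and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| $\varepsilon_m$ | relative membrane permittivity | 4.5 | — |
| $\varepsilon_0$ | vacuum permittivity | 8.85e-12 | F/m |
| $h$ | membrane thickness | 4e-9 | m |
| $h_e$ | dielectric thickness | 2.8e-9 | m |
| $T$ | temperature | 298.15 | K |
| $B$ | electrostatic tension | 1.76e-3 | N/m |
| window | observation time | 60 | s |
| frame | acquisition interval | 1 | s |

Two deliberate choices here. First, $\varepsilon_0$ defaults to the
two-digit 8.85e-12 F/m rather than the CODATA value: with the default
geometry this makes the composite coefficient on $R^2E^2$ equal 22.86 mN/m
at two decimals, the conventional figure for this system; CODATA precision
gives 22.87, a 0.04% difference with no practical consequence, and the
constant is configurable in `membrane_constants()`. Second, everything
internal is SI (m, V/m, N/m, N, J); the boundary helpers `um()`,
`V_per_cm()`, `mN_per_m()`, `pN()` and their inverses exist so that
laboratory units never leak into the computations.

The signs of $a$ and $b$ in the biphasic model are deliberately
unconstrained. The model's interesting regime — edge tension dipping to a
minimum at intermediate peptide content and recovering — corresponds to
particular sign patterns, but which pattern a membrane exhibits is an
empirical question, so `fit_biphasic()` reports whatever the least-squares
solution says rather than enforcing a narrative.

## Estimating the rate constant

`fit_rate()` offers two estimators.

The default, `method = "ls"`, fits $e^{-kt}$ to the empirical intact
fraction on the acquisition grid by nonlinear least squares — the
conventional approach, and the one whose $R^2$ values are typically quoted.
It has a useful robustness property: rupture times recorded by
time-lapse imaging are ceil-quantized to the frame grid, but the empirical
curve evaluated *at grid times* depends only on whether each latent rupture
time exceeds $t$, so quantization does not bias this estimator at all. Its
uncertainty comes from the fit curvature and should be read as a
goodness-of-fit-flavoured error, since neighbouring grid points of a
survival curve are strongly dependent.

`method = "mle"` is the censored-exponential maximum likelihood, closed
form $\hat k = d / \sum_i t_i$ with $d$ ruptures and censored vesicles
contributing their full window as exposure; $se = \hat k/\sqrt d$. It is
the statistically correct treatment of censoring and its standard error is
trustworthy — but on ceil-quantized times it is biased low by roughly a
factor $1/(1 + k\,\Delta/2)$ for frame $\Delta$ (about 10% at
$k = 0.2\,\mathrm{s}^{-1}$ with 1 s frames), because quantization
overstates every exposure by up to one frame. The test suite documents both
facts. For fitting quantized data the curve estimator is therefore the
default; the MLE is preferred for continuous-time records and for
uncertainty statements at low rupture counts.

Rates can be fitted pooled across trials (default) or per trial with the
mean and across-trial standard error reported (`by_trial = TRUE`). Pooling
is the default because it weights every vesicle equally and remains stable
when a trial has few ruptures; with only 2–4 trials, an across-trial
standard error is itself very noisy.

## Inferring the edge tension

`fit_edge_tension()` regresses $\ln k_r$ on $1/(\sigma_e+B)$ by OLS
(optionally inverse-variance weighted using the delta-method variance of
$\ln k_r$, $(se_k/k)^2$). The slope must be negative — a rising trend is
reported as a non-physical-fit error rather than returned as an imaginary
$\Gamma$. The edge tension follows as
$\Gamma = \sqrt{-\mathrm{slope}\cdot k_BT/\pi}$ with delta-method standard
error $|k_BT/(2\pi\Gamma)|\,se_{\mathrm{slope}}$, and
`confint()` builds a t-interval on the regression's residual degrees of
freedom (3, for the usual five-tension design) — the heavier-than-normal
tails matter at these tiny design sizes. $B$ is passed explicitly rather
than absorbed into the tension so its influence on $\Gamma$ can be scanned.
Unweighted OLS is the default because rate uncertainties are not always
available and the conventional analysis is unweighted; weighting is a
flag, not a behaviour change.

The attempt frequency $A = e^{\mathrm{intercept}}$ is reported but should
be treated as a nuisance parameter: it is a long extrapolation to
$1/(\sigma_e+B) \to 0$ and is poorly constrained by any realistic design,
while $\Gamma$ — the slope — is robust to it (rescaling $A$ leaves
$\Gamma$ unchanged, which the tests assert).

## The simulator and what it does (not) emulate

`simulate_tension_grid()` reproduces the statistical structure the
estimators assume: per vesicle, a radius uniform on the 28–32 µm diameter
range, a field chosen by `field_for_target_tension()` so the vesicle
experiences the cell's target tension exactly (mirroring the
measure-the-radius-then-set-the-field protocol), a latent exponential
rupture time at the Arrhenius rate implied by the generating parameters,
censoring against the 60 s window *on the latent time* (a rupture at
60.4 s is never observed), and ceil quantization of observed times to the
1 s frame. Trial counts (2–4) and per-trial vesicle counts (12–18) are
drawn from their design ranges so aggregation code is exercised. An
optional lognormal tension jitter models radius-measurement error; it is
off by default because the protocol sets the field per measured radius.

Seeding is hierarchical: each (composition, tension) cell derives its own
substream from the single global seed, so adding a condition to a design
never perturbs the draws of existing cells — a property the tests check
byte-for-byte.

What the simulator does *not* model: pre-rupture leakage or gradual
fluorescence decay (rupture is an instant), non-constant hazard within the
window (the exponential model assumes the hazard is constant from field
onset), vesicle deformation under field, and any imaging noise. Passing
tests on simulated data therefore demonstrate the statistical machinery —
estimator consistency, censoring handling, interval coverage — not the
adequacy of the constant-hazard model for any particular real membrane.

## Choosing tensions for simulation studies

A tension at which the expected rate is 5 s⁻¹ produces rupture of
everything in the first frame; one at 10⁻⁴ s⁻¹ produces no ruptures in
60 s. Real experiments choose tensions so kinetics are observable, and
`design_tensions()` encodes that: it inverts the Arrhenius law to find the
tensions at which the expected rate takes `n` log-spaced values across
`k_range`, defaulting to 0.02–0.22 s⁻¹ — the span of rate constants
typically reported for this system. Simulation studies in this package
(tests and the acceptance script) use five such tensions for whatever
generating $\Gamma$ and $A$ they posit.

## Validation scope and problem sizes

The package validates itself at these sizes, chosen to match the
experimental design it emulates: single studies of 15 vesicles × 3 trials
at 5 designed tensions (225 vesicles); interval-coverage sweeps of 200
replicate studies (the 95% t-interval for a generating $\Gamma$ of 6 pN at
$A = 100\,\mathrm{s}^{-1}$ covers truth in well over 90% of replicates);
large-sample checks (10⁴–2×10⁴ vesicles) for the exponential-CDF,
quantization-bias, and MLE-consistency properties; and noiseless designs
for the exact-recovery properties (linearization round trip, biphasic
quadratic through its points), which hold to machine precision.

## Degenerate inputs and numerical choices

All-censored data make the rate unidentifiable and raise an error rather
than returning 0. A least-squares rate collapsing onto the $k \to 0$
boundary is flagged in the result. The nonlinear rate fit starts from an
exposure-based estimate, falls back to a bracketed 1-D minimization if
`nls` fails, and polishes the optimum so that exactly-exponential curves
are recovered to machine precision. Ties in rupture times are handled by
counting; no ordering is ever assumed. Mole percent vs mole fraction is an
explicit boundary conversion (`percent = TRUE` in `fit_biphasic()`), never
a guess.

## Known limitations

The exponential model cannot represent delayed-onset rupture (a
time-dependent hazard); diagnostics beyond $R^2$ — e.g. Weibull
alternatives — are out of scope. The per-composition fits assume a shared
$A$ across tensions within a composition but fit $A$ per composition, so
comparisons of $A$ across compositions inherit the intercept's weak
identification. Edge-tension values for real membranes depend on $B$,
which is taken from the literature for the charged-lipid system in buffer
and is not inferred from the data.
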
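---
title: "Modelling E. coli growth on glucose and yeast extract: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling E. coli growth on glucose and yeast extract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yegrowth)
```

## The model

`yegrowth` implements a macro-kinetic model of *Escherichia coli* growing in
mineral-salt medium with glucose and yeast extract (YE). The classical
substrate-partitioning picture is kept: glucose uptake
$q_S = q_{S,max}\,S/(S+K_S)$ splits into an oxidative flux $q_{S,ox}$ and an
overflow flux $q_{S,of} = q_S - q_{S,ox}$; overflow produces acetate
($q_{Ap} = q_{S,of}\,Y_{A/S}$), which can be re-assimilated under glucose
repression,
$q_{Ac} = q_{Ac,max}/(1+S/K_{i,A,S}) \cdot A/(A+K_A)$. The oxidative
capacity saturates through
$\alpha = K_{qSox}/(K_{qSox}+q_S)$; small $K_{qSox}$ (roughly below
4 g L$^{-1}$) means strong overflow, large values suppress it
exponentially.

Yeast extract is a mixture of hundreds of compounds; the model deliberately
does not resolve them. Following the observation that amino-acid mixtures
act on *E. coli* growth through a rapidly consumed class, a slowly consumed
class and a nearly inert remainder, YE is lumped into fractions A, B and C.
At inoculation the dose $YE_0$ is split by two distribution parameters,

$$YEF_{A,0} = YE_0\, d_{YE,AB}, \qquad
  YEF_{B,0} = (YE_0 - YEF_{A,0})\, d_{YE,BC}, \qquad
  YEF_{C,0} = (YE_0 - YEF_{A,0})(1-d_{YE,BC}),$$

each consumable fraction is taken up with Monod kinetics, and both uptakes
inhibit the oxidative glucose route non-competitively:

$$q_{S,ox} = \frac{q_S\,\alpha}
 {1 + q_{YEFA}/K_{i,YEFA,qSox} + q_{YEFB}/K_{i,YEFB,qSox}}.$$

This single coupling reproduces the experimentally observed signature of YE:
faster growth, earlier glucose depletion and substantially more acetate.
Growth sums three anabolic terms,
$\mu = (q_{S,ox}-q_m)Y_{X/S,em} + q_{YEFA}Y_{X/YEFA} + q_{YEFB}Y_{X/YEFB} +
q_{Ac}Y_{X/A}$, and may be negative when maintenance $q_m$ exceeds supply —
biomass decay under starvation is intended behaviour, not an error state.

Four nested variants exist (`basic`, `one_yef`, `two_yef`, `three_yef`),
differing only in which fractions are active and whether the distribution
parameters are free. `two_yef` pins $d_{YE,BC}=1$ (no inert fraction);
`one_yef` pins both at 1; `basic` carries no YE mass at all. Nesting is
exact: `two_yef` with $d_{YE,AB}=1$ reproduces `one_yef` trajectories, and
any variant with $YE_0=0$ reproduces `basic` (this is tested to 1e-8).

### Oxygen and the probe

Oxygen demand is a carbon balance over the three catabolic routes,
$q_O = Y_{O/S}(q_{S,ox} - \mu_S r_S) + Y_{O/A}(q_{Ac} - \mu_A r_A) +
Y_{O/YE}(q_{YE} - \mu_{YE} r_{YE})$: whatever carbon is taken up but not
fixed into biomass is respired. The printed rendering of the anabolic
correction ratios for the acetate and YE terms is typographically ambiguous
in the source material this model family derives from; we default to the
carbon-balance reading $r_j = C_X/C_j$ (biomass carbon formed per unit
co-substrate-$j$ carbon), which is dimensionally coherent with the cited
balance, and expose the alternate literal reading $r_j = C_j/C_S$ behind
the `carbon_literal` switch of `ye_design()`. $q_O$ is clipped at zero —
respiration cannot run backwards.

Dissolved oxygen is treated algebraically,
$DOT = DOT^* - q_O X H / k_L a$, avoiding a stiff gas-phase ODE entirely;
only the first-order probe lag $dDOT_m/dt = \tau^{-1}(DOT - DOT_m)$ is
integrated, initialised at $DOT(t_0)$. DOT is **not** floored at zero: a
negative value flags a transfer-starved configuration and hiding it would
mask infeasible designs. The carbon contents ($C_X = 0.0426$,
$C_S = C_A = 0.0333$, $C_{YE} = 0.040$ mol$_C$ g$^{-1}$) and the reactor
constants ($DOT^* = 100\,\%$, $k_L a = 1000$ h$^{-1}$, $H = 14000$
%·L·g$^{-1}$, $\tau = 0.008$ h) are package defaults — typical glucose
stoichiometry, standard biomass composition and a small oxygen-enriched
stirred tank with a fast optical sensor — and should be overridden with
measured values where available.

## Feeding and integration

Feeds come in three flavours: user-supplied stepwise-constant tables (the
"periodically adjusted" operator strategy is not reproducible
algorithmically, so no adjustment heuristic is invented), continuous
exponential profiles $F = F_0 e^{\mu_{set}(t-t_0)}$ with
$F_0 = \mu_{set} X_0 V_0 /(S_i Y_{X/S})$, and bolus feeding, where the
exponential target is delivered as instantaneous perfectly mixed pulses:
$V \leftarrow V+v$, concentrations dilute by $V/(V+v)$ and glucose gains
$v S_i/(V+v)$. A cumulative-substrate stop criterion (grams fed per litre
of *initial* volume — the normalisation is configurable, as the convention
is not universal) silences any feed. Evaporation removes water only; an
optional `evap_conc` switch adds the corresponding concentration term,
default off because the effect is small at the default 30 µL h$^{-1}$.

Integration uses `deSolve::lsodar` with the right-hand side in compiled C.
Feed starts/stops and step changes restart the integrator; bolus pulses are
compiled integrator events; glucose depletion is caught by a root function
on $S$ crossing 1e-9 g L$^{-1}$ with a restart, so the solver never steps
across the stiff depletion transient, and rate evaluations clamp
concentrations at zero so tiny negative excursions cannot generate negative
uptake. Trajectories keep states smooth for the optimizer — there is no
hard clipping. Default dense output is 200 points per operating phase plus
all event times; default tolerances are rtol 1e-8 with per-state atol
(1e-12 on concentrations, 1e-14 on volume), relaxed to rtol 1e-6 during
fitting where speed matters more than the last digits.

## Estimation

`ye_fit()` minimises a weighted least-squares cost over the four
observables (biomass X, glucose S, acetate A, DOT — the probe reading):

$$J(\theta) = \sum_l \sum_k \frac{w_l}{\sigma_{lk}^2 N_l}
  \big(h_l(t_k;\theta)^{sc} - y_{lk}^{sc}\big)^2,$$

with default weights $w = (10, 6, 4, 2)$ for (X, S, A, DOT). Both sides are
robust-scaled (median/IQR, type-7 quantiles, fitted on the measurements
only, zero IQR falling back to scale 1) so that variables of very different
magnitude contribute comparably; per-point $\sigma_{lk}$ defaults to 5% of
the variable's median (floored at 1e-3 native units) when the data carry
none. A failed simulation returns a large finite penalty so the
derivative-free search survives pathological parameter regions.

The search itself is Nelder-Mead under box bounds via a smooth
sine-squashing reparameterisation $\theta = lo + (hi-lo)\sin^2 x$ — plain
Nelder-Mead is unbounded, and several YE parameters are only identifiable
thanks to their bounds (the fast/slow fraction convention is encoded by
keeping the $q_{YEFA,max}$ bounds above the $q_{YEFB,max}$ bounds;
`validate_params(check_order = TRUE)` enforces it on request). Parameters
follow a free/fixed convention mirroring common practice for this model
family: maintenance, the stoichiometric yields ($Y_{A/S}$, $Y_{O/S}$,
$Y_{O/A}$, $Y_{O/YE}$, $Y_{X/A}$), $K_S$ and the carbon contents are fixed
by default. Goodness of fit is reported as
$RMSE = \sqrt{J/N_{tot}}$, the root mean weighted squared scaled residual;
a printed formula in the source material sums squared *parameters*, which
contradicts its own caption, so the residual-based definition is used and
documented here. Default parameter bounds are package choices (the original
appendix values are not reproduced in the text) and every one can be
overridden in `ye_params()`.

## Uncertainty quantification

`ye_mc()` quantifies estimate dispersion by replication: L replicate
datasets are drawn from the fitted model (parametric bootstrap with each
point's $\sigma_{lk}$; residual resampling available), each replicate is
refit over an identifiable subset from a Latin-hypercube initial point
(`lhs::randomLHS`, stratification tested against a brute-force bin count),
replicates whose RMSE falls outside the 1.5×IQR Tukey fences are excluded
(single pass, type-7 quantiles — the quantile convention changes filter
outcomes at small L, so it is fixed and stated), and per-parameter 95%
intervals are formed as mean ± t-quantile × sd of the kept estimates. The
sd of estimates — not the standard error — is interpreted as the parameter
uncertainty; the SE variant is reported alongside. L defaults to 250; the
test-suite and the bundled acceptance script run L in {10, 50} to keep
runtimes sensible, and report the sizes they used.

The identifiable subset comes from `ye_subset_select()`: finite-difference
sensitivities of the scaled outputs with respect to log-parameters at all
sampling times, parameters ranked by RMS sensitivity, grown greedily while
the collinearity index $1/\sqrt{\lambda_{min}}$ of the unit-normalised
sensitivity columns stays at or below 10. Finite differences are entirely
adequate at this problem size; no automatic differentiation is needed.

## Synthetic data

`ye_scenario()`/`ye_generate()` emulate the study conditions of a
mini-bioreactor run: 10 mL at OD$_{600}$ 0.3 (0.37 g DCW L$^{-1}$ per OD
unit — a calibration default, override it), 9 g L$^{-1}$ glucose,
0–20 g L$^{-1}$ YE, an 8 h batch phase, then an exponential bolus feed
(pulses every 5 min, $S_i = 400$ g L$^{-1}$, $\mu_{set} = 0.2$ h$^{-1}$,
$F_0$ from the feed rule at a nominal 5 g L$^{-1}$ biomass at feed start).
DOT is sampled at online cadence (1 min default), X/S/A at at-line cadence
(20 samples over the horizon by default, optional jitter); Gaussian noise
with sd $= rel \cdot |value| + floor$ is added per point and the true sd is
stored in the `sigma` column. Zero-noise scenarios leave `sigma`
unspecified so the measurement constructor imputes its usual default
instead of a degenerate zero. The generator is a pure function of
(scenario, seed) and returns the generating parameters, so recovery and
coverage tests need no external data.

What the generator does *not* emulate: analyzer artefacts (carryover,
detection limits, censoring), the DO-stat stirrer cascade of litre-scale
reactors (which makes $k_L a$ time-varying — fitted DOT data near a 30%
control floor carry model-plant mismatch), plasmid/induction kinetics, or
lot-to-lot YE composition changes beyond what the distribution parameters
absorb. Passing tests on synthetic data therefore demonstrate correctness
of the machinery and identifiability under the model's own assumptions —
not model adequacy for any particular real cultivation.

## Numerical choices, sizes and limitations

* Depletion threshold 1e-9 g L$^{-1}$; root-restart instead of clipping.
* Bolus impulses applied exactly (solver event), so the volume balance
  audits to better than 1e-9 L over a 12 h fed-batch.
* Fitting tolerances rtol 1e-6 / atol 1e-8; reference simulations rtol
  1e-8 or tighter. Halving tolerances moves a 12 h fed-batch terminal
  state by less than 1e-6 relative.
* Nelder-Mead budgets: 1000 evaluations for reference fits, 200–600 for
  replicate refits in the test-suite and acceptance script.
* The test-suite's heavy blocks use 20 seeded replicates for fed-batch
  recovery (full sampling schedule), 10 seeds for the variant-ranking
  comparison, and 20 meta-replicates × L=50 for interval coverage with a
  leaner schedule (12 at-line points, DOT every 20 min); the acceptance
  script reports each quantity with the size it used.
* Known limitations: a single lumped YE pool per fraction (no amino-acid
  resolution — by design), constant $k_L a$, no product formation, no
  CO$_2$ balance, no temperature/pH dependence. The three-fraction variant
  is structurally richer but, without measurements of the fractions
  themselves, its distribution parameters are weakly identifiable — expect
  visibly wider Monte-Carlo intervals than for `two_yef` on the same data.

## A minimal session

```{r example, eval = FALSE}
sc <- ye_scenario("two_yef")            # fed-batch template, 2% noise
gen <- ye_generate(sc, seed = 11)
fit <- ye_fit(gen$measurements, gen$design, "two_yef",
              free = c("q_S_max", "Y_XS_em", "Y_X_YEFA", "d_YE_AB"))
summary(fit)
sub <- ye_subset_select(fit)
mc <- ye_mc(fit, L = 50, seed = 42, subset = sub$subset)
mc
```
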
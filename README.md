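# yegrowth

Macro-kinetic modelling of *Escherichia coli* batch and fed-batch
cultivations in glucose media supplemented with yeast extract (YE).

Complex media additives like yeast extract are everywhere in bioprocess
development, yet most mechanistic *E. coli* growth models ignore them — and
with them the faster growth, earlier glucose depletion and extra acetate
that YE causes. `yegrowth` closes that gap for people doing model-based
process development: it extends the classical substrate-partitioning model
(Monod glucose uptake split into oxidative and overflow routes, acetate
cycling, algebraic dissolved-oxygen balance with a first-order probe lag)
with up to three lumped YE fractions — fast (A), slow (B) and unconsumed
(C) — whose uptake non-competitively inhibits the oxidative glucose flux:

    q_S,ox = q_S · α / (1 + q_YEFA/Ki_YEFA,qSox + q_YEFB/Ki_YEFB,qSox),
    α      = K_qSox / (K_qSox + q_S),
    q_S,of = q_S − q_S,ox,          q_Ap = q_S,of · Y_A/S,
    μ      = (q_S,ox − q_m)·Y_XS,em + q_YEFA·Y_X/YEFA + q_YEFB·Y_X/YEFB
             + q_Ac·Y_X/A.

On top of the simulator the package provides the full estimation workflow:
weighted least squares with RobustScaler-style (median/IQR) scaling and
per-point sigmas, bounded Nelder–Mead search, sensitivity-based
identifiable-subset selection, and Monte-Carlo uncertainty quantification
(replicate datasets, Latin-hypercube restarts, 1.5×IQR outlier filtering,
Student-t confidence intervals). A synthetic-data generator emulating
online DOT sensing and at-line sampling makes everything testable without
cultivation data.

## Worked example

```r
library(yegrowth)

# a synthetic fed-batch: 10 mL mini-bioreactor, 9 g/L glucose, 10 g/L YE,
# 8 h batch then an exponential bolus feed (400 g/L stock, pulses every
# 5 min), 2% measurement noise
sc  <- ye_scenario("two_yef")
gen <- ye_generate(sc, seed = 11)

start <- ye_params(values = list(q_S_max = 0.45, Y_XS_em = 0.35,
                                 Y_X_YEFA = 0.4, d_YE_AB = 0.5))
fit <- ye_fit(gen$measurements, gen$design, "two_yef", start = start,
              free = c("q_S_max", "Y_XS_em", "Y_X_YEFA", "d_YE_AB"))
fit
#> Yeast-extract growth model fit (two_yef variant)
#>   901 measurement points, 4 free parameter(s)
#>   cost 5.91804 (from 97112.3), RMSE 0.08105, converged after 129 evaluations
#>   estimates:
#>  q_S_max  Y_XS_em Y_X_YEFA  d_YE_AB
#>  0.61297  0.42860  0.56340  0.27416
```

The generating values were q_S_max = 0.62, Y_XS,em = 0.43,
Y_X/YEFA = 0.56 and d_YE,AB = 0.27 — every estimate lands within ~1% here.
`plot(fit)` overlays the fitted trajectories on the data;
`ye_subset_select(fit)` ranks parameters by dynamic sensitivity and returns
the subset whose collinearity index stays below 10; `ye_mc(fit, L = 250,
seed = 1)` quantifies the estimate dispersion with confidence intervals.

Eight reference parameter sets (four model variants × batch / full-process
estimates) ship as plain-text configs, loadable with
`ye_reference_params(variant, phase)`; example experiment designs live in
`inst/extdata/designs/`. A thin command-line front end
(`inst/cli/yegrowth.R`) exposes `simulate`, `fit`, `mc` and `generate` for
shell pipelines.

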
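# fadyn

Binding dynamics and spatial organisation of focal adhesion (FA)
proteins — paxillin, vinculin, zyxin, VASP and their kind — quantified
from two complementary live-cell experiments:

* **FRAP**: bleach one FA, watch fluorescence return. The recovery curve
  encodes how much of the protein pool is mobile, dynamically bound
  (residence times of tens of seconds) or stably bound (many minutes).
  fadyn fits each measured curve against a database of Monte Carlo
  simulated curves from a three-pool reaction–diffusion model
  (`mobile <-> medium, medium -> long -> mobile`), with effective rate
  constants defined by the steady-state balances
  `k_off = 1/t_r`,
  `k_on,med = F_med/(1 − F_med − F_long) · (k_off,med + k_on,long)` and
  `k_on,long = (F_long/F_med) · k_off,long`.
* **Photoconversion pulse-chase**: switch the label from green to red in
  one FA, wait three minutes, and form the per-pixel "ratio view"
  `RV = red(t_post)/red(t_0)`. Retained red signal maps the *stably
  bound* protein inside the FA; moment-preserving (Tsai) thresholding
  and particle analysis turn it into stable-area counts, sizes, FA
  coverage and distal/proximal positions.

FAs are additionally classified by geometry relative to the ventral
membrane edge — *pointing* (long axis within 30° of perpendicular) vs
*parallel* (within 30° of parallel), *outer* vs *inner* (another FA
blocks the path to the edge) — and cohorts are compared with rank tests
(Mann–Whitney; Kruskal–Wallis plus four fixed contrasts for the
location × orientation groups, significance at p < 0.01).

A synthetic-data module generates every input kind (FRAP experiments,
photoconversion stacks, cell geometries) with known ground truth, so the
whole pipeline is testable offline. The package is tidyverse-shaped:
data frames in, tibbles out, `tidy()`/`glance()` on fitted objects,
`autoplot()`/`plot_*()` for figures.

## Worked example

Simulate a paxillin-like protein (30% dynamic, 45% stable, residence
times 50 s / 1800 s), generate a synthetic experiment, and fit it
against a simulated-curve database:

```r
library(fadyn)

p <- kinetic_params(f_medium = 0.30, f_long = 0.45,
                    t_r_medium_s = 50, t_r_long_s = 1800)
derive_rates(p)
#>   f_medium f_long t_r_medium_s t_r_long_s k_off_medium k_off_long k_on_medium
#> 1      0.3   0.45           50       1800         0.02   0.000556       0.025

curve <- simulate_frap(p, n_molecules = 1e4, seed = 1)
mean(curve$normalized[curve$time_s >= 300])   # 6-min plateau
#> [1] 0.331
plateau_accounting(curve)                      # closed-form prediction
#> [1] 0.318

db  <- build_database(300, n_molecules = 1e4, seed = 7)
exp <- gen_frap_experiment(p, n_fas = 4, n_molecules = 1e4, seed = 42)
qc  <- qc_experiment(exp)
qc
#> <frap_qc> experiment PASS
#>   bleached FAs kept: 4 dropped: 0

norm <- normalize_prebleach(exp) |> dplyr::filter(role == "bleached")
fit  <- iqr_refit(fit_cohort(norm[, c("roi_id", "time_s", "i_norm")], db))
tidy(fit)[, c("roi_id", "f_stable", "f_dynamic", "f_mobile", "ssr")]
#>   roi_id f_stable f_dynamic f_mobile    ssr
#> 1 fa01      0.445     0.448    0.108 0.0393
#> 2 fa02      0.445     0.448    0.108 0.220
#> 3 fa03      0.445     0.448    0.108 0.0967
#> 4 fa04      0.445     0.448    0.108 0.0755
```

The stable fraction comes back at 0.445 against a truth of 0.45 — it is
the well-identified parameter, since it sets the unrecovered plateau
deficit. The dynamic fraction is only weakly identified per trace (here
0.448 against a truth of 0.30): the normalized FA-count curve is nearly
invariant along a ridge where larger bound fractions trade off against
deeper fluorescent-pool depletion. The methods vignette
(`vignettes/fadyn-methods.Rmd`) discusses this degeneracy and every
other modelling choice.

Photoconversion, in three lines:

```r
stack <- gen_photoconv_stack(stack_spec(exchange_fraction = 0), seed = 2)
areas <- detect_stable_areas(ratio_view(stack))
coverage_stats(areas)$coverage_ratio   # fixed control: ~1 (no exchange)
```

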
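---
title: "Models and methods behind fadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadyn)
```

fadyn quantifies how focal adhesion (FA) proteins such as paxillin,
vinculin, zyxin and VASP bind to the FA complex, from two kinds of
live-cell experiments: FRAP (fluorescence recovery after photobleaching)
time series, and green-to-red photoconversion pulse-chase image stacks.
This vignette explains the models, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The three-pool kinetic model

Every labelled molecule is, at any moment, in one of three pools:

* **mobile** — diffusing freely (or bound too briefly to distinguish from
  free diffusion),
* **dynamically bound** ("medium") — bound with residence times of tens
  of seconds,
* **stably bound** ("long") — bound with residence times of many minutes.

The reaction scheme routes all stable binding through the dynamic state:

$$M_{mob} \rightleftharpoons M_{med}, \qquad
  M_{med} \rightarrow M_{long} \rightarrow M_{mob}.$$

A direct mobile-to-stable transition is deliberately absent: a molecule
must first engage dynamically before it can convert to the stable mode of
binding.  The model is parameterized by the two steady-state bound
fractions $F_{med}, F_{long}$ (of the whole pool) and the two mean
residence times $t_{r,med}, t_{r,long}$.  Off rates are reciprocal
residence times, $k_{off} = 1/t_r$, and the effective on rates follow
from the stationary balance of the scheme:

$$k_{on,med} = \frac{F_{med}}{1 - F_{med} - F_{long}}
  \left(k_{off,med} + k_{on,long}\right), \qquad
  k_{on,long} = \frac{F_{long}}{F_{med}}\, k_{off,long}.$$

`derive_rates()` applies these as exact definitions and
`steady_state_fractions()` inverts them by solving the linear stationary
balance; the round trip is exact to machine precision and is additionally
checked against a continuous-time (Gillespie) single-molecule simulation
in the test suite.  A parameter set with $F_{med} = 0$ but
$F_{long} > 0$ is rejected rather than treated as a limit, because the
scheme has no path into the stable state that avoids the dynamic state.

## The Monte Carlo FRAP simulator

`simulate_frap()` places `n_molecules` (default $10^4$) in an ellipsoidal
cell (U2OS preset $24 \times 44 \times 2$ µm, MDCK
$15 \times 64 \times 2$ µm, optional nucleus ellipsoid excluded) with two
FA ellipsoids of $1.5 \times 2 \times 0.5$ µm near the ventral surface.
Time advances in 100 ms steps; the curve is sampled every 500 ms, with
30 s of prebleach and 6 min of postbleach acquisition, matching the
experiments.  Mobile molecules take independent Gaussian steps per axis
with variance $2 D\,\Delta t$ ($D = 1$ µm²/s, measured for cytoplasmic
paxillin-GFP).  All per-step probabilities use the exact form
$1 - e^{-k \Delta t}$, not $k \Delta t$.

**Association is mean-field.**  The effective on rate of the scheme is a
global pseudo-first-order constant, so every mobile molecule binds with
per-step probability $1 - e^{-k_{on,med} \Delta t}$ regardless of
position, and is placed uniformly inside one of the FA ellipsoids when it
binds; release happens in place.  The obvious local alternative — scale
the in-FA binding probability by the inverse FA volume fraction
$1/\varphi$ — cannot reproduce the rate equations here: with
$\varphi \approx 1.4\times10^{-3}$ the scaled probability saturates at 1
once $k_{on,med} > \varphi/\Delta t \approx 0.014\,s^{-1}$, which caps
the achievable on rate below much of the physiological range (the
worked-example rate set already has $k_{on,med} = 0.025\,s^{-1}$).
Mean-field association reproduces the stationary occupancies exactly,
which is verified against the closed form at $10^4$ molecules.  The price
is spatial: transport to the FA is not rate-limiting in the simulator.
With $D = 1$ µm²/s and residence times of 20–3200 s, binding, not
transport, is rate-limiting in the real system too, so this is the
regime the model is built for.

**Boundary rule.**  A proposed step that leaves the accessible volume is
rejected and the molecule stays put for that step.  A symmetric proposal
plus rejection has the uniform distribution as its exact stationary law
and conserves molecules.  (Redrawing until the proposal lands inside — a
tempting alternative — is *not* symmetric and measurably distorts the
equilibrium near the thin-slab boundary; specular reflection off an
ellipsoid would be exact too but adds complexity with no observable
benefit.)

**Bound dwell times** are sampled as geometric episode lengths, identical
in law to per-step Bernoulli draws, so a bound episode costs constant
time regardless of its length.  The exit of the dynamic state is split
between release and conversion to the stable state in proportion to
$k_{off,med} : k_{on,long}$, exact for competing first-order processes.
The exposed `binding_step()` operation keeps the literal per-step
semantics; the two are cross-checked through dwell-time and occupancy
tests.

**The bleach pulse** is instantaneous, with intensity 1 on a
$2 \times 2$ µm square footprint centred on the target FA, Gaussian
lateral shoulders ($\sigma_{xy} = 0.5$ µm beyond the square edge) and a
Gaussian axial profile ($\sigma_z = 1$ µm).  A molecule at intensity $I$
is bleached with probability $1 - e^{-\alpha I}$; the default $\alpha$
bleaches a footprint-centre molecule with probability 0.98, which
comfortably satisfies the experiments' own inclusion rule (FA bleached to
below 20% of prebleach).  Bleaching touches only the fluorescence flag;
bleached molecules keep binding and diffusing exactly like fluorescent
ones.  One point worth knowing: in the $1106$ µm³ model cell this pulse
bleaches about 2.3% of the entire pool, so even a pure-diffusion curve
recovers to ~0.977 of prebleach rather than 1.0.

**Output.**  The curve is the number of fluorescent molecules inside the
target FA ellipsoid at each sample instant, normalized to the prebleach
mean.  `plateau_accounting()` provides an independent closed-form
prediction of the late plateau from the pulse's bookkeeping (which
molecules of which pool were bleached), including the two finite-pool
effects that matter at this scale: fluorescent-pool depletion and the
slow relaxation of the stable pool at rate $k_{off,long}$.

**Mobile transport options.**  `transport = "diffusion"` (default)
simulates every Gaussian step.  `transport = "well_mixed"` keeps explicit
diffusion only within ~1.2 µm of the target FA and treats mobile
molecules elsewhere as uniformly distributed: their transit occupancy of
the FA at a sample instant is a Bernoulli($\varphi$) draw and their
position at a pulse instant is a uniform draw.  Because association is
mean-field, the two schemes agree in distribution apart from a ~2 s
transit transient and the small count contributed by just-released
molecules lingering near the FA (~1.5% of the FA count); the well-mixed
scheme is ~40× faster and is the default for database-scale curve
generation, where templates and test traces use the same scheme so the
comparison is internally consistent.

### Two finite-pool caveats, measured honestly

The model defines $F_{med}, F_{long}$ as fractions of the *whole
simulated pool*, all of it bound at just two FAs.  Two consequences
follow that a reader should know about, because both are visible in the
acceptance checks:

1. **A repeated bleach does not recover to the same level.**  In the
   experiments, bleaching the same FA again six minutes later recovered
   to the same level, proving the pulse did not deplete the cellular
   pool.  In the simulator the target FA holds roughly a third of all
   molecules, so each pulse removes a large bite of the fluorescent
   exchanging pool and the second plateau lands visibly lower (by 0.11-0.14 at
   MDCK-paxillin-scale fractions, depending on seed).  The experiment's invariance relies
   on the FA being a negligible part of the cellular pool, which this
   model, by construction, is not.
2. **Per-trace fraction estimates are degenerate.**  The normalized
   FA-count curve is almost invariant along a ridge in parameter space:
   raising both bound fractions deepens pool depletion and mimics the
   curve of a smaller-fraction, different-ratio parameter set.  The
   stable fraction is the best-identified parameter (it sets the
   unrecovered deficit); the dynamic fraction is poorly identified per
   trace.  On a $3 \times 3$ truth grid with 50 noisy traces each and a
   2000-entry database, the median absolute error of the recovered
   stable fraction measures 0.045-0.057 across seeds — straddling the
   0.05 working target, with the misses concentrated where the dynamic
   fraction is small.  Averaging over a cohort (the pipeline's actual
   deliverable) is far better behaved for the stable fraction (grid
   biases mostly below 0.05), but no database size or molecule count
   removes the ridge, because it is a property of the observation model,
   not of the noise.

## Trace normalization, QC and database fitting

Raw ROI intensities are background-corrected and normalized to the
prebleach mean,
$I_{norm} = (I_t - I_{BG,t})/(I_{pre} - I_{BG,pre})$, with the prebleach
average taken over the entire 30 s window and one background series
(mean of the background ROIs) shared by all FAs of an experiment.  The
zero-one rescaling sets the first postbleach value to 0 and the final
recovery level (mean of the last 25 samples) to 1, for comparing
recovery *rates* irrespective of bleach depth.  Traces whose zero-one
denominator is not positive (no measurable recovery — an FA that was not
in a stable state) are excluded and reported.

Two QC rules mirror the acquisition practice: an experiment is discarded
wholesale if the mean normalized intensity of the unbleached control FAs
drops below 90% of prebleach at any postbleach time point (the stricter,
per-time-point reading of "fell below 90% of original levels"); an
individual FA is excluded if its first postbleach value is not below 20%
of prebleach.

`build_database()` draws parameter sets uniformly from the stated
ranges — both fractions from 0–70%, medium residence times 20–100 s,
long residence times 600–3200 s — rejecting draws with
$F_{med} + F_{long} \ge 0.95$ (sums $\ge 1$ are unphysical; sums within
5% of 1 leave an empty mobile pool and divergent on rates).  The
full-scale databases are 5122 (U2OS) and 2027 (MDCK) entries; the test
suite uses 2000 entries at $10^4$ molecules per curve, which builds in
about half a minute with the well-mixed transport.

`fit_curve()` ranks database entries by the sum of squared residuals
over the postbleach samples only — once both sides are normalized to a
prebleach mean of 1, the prebleach samples carry no information.
`iqr_refit()` then applies the outlier rule: the interquartile ranges of
$k_{on,med}$ and $k_{off,med}$ are computed once over the initial
best fits, and any FA whose parameters fall outside
$[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ is moved down its
own ranking until both parameters comply (an FA whose ranking is
exhausted keeps its best fit and is flagged).  Because the bounds are
frozen at the initial fits, the operation is idempotent.  Cohorts are
summarised as mean ± 2 SEM per group (`aggregate_fits()`), and groups
are compared with two-sided Mann–Whitney tests, or for the four
location × orientation groups a Kruskal–Wallis omnibus test followed by
exactly the four meaningful pairwise contrasts, at a significance
threshold of 0.01 (`compare_groups()`).

## The photoconversion ratio-view pipeline

A photoconversion experiment converts the mMaple-type label in a small
region from green to red, waits three minutes (about three dynamic
residence times, so the dynamically bound and mobile converted protein
exchanges away), and images both channels at three time points with two
frames each.  The **ratio view** is the per-pixel ratio of the averaged
red signal at $t_{post}$ over $t_0$: high ratios mark stably bound
protein.  The ratio is only defined on pixels whose green $t_{pre}$
value clears a background-dependent preselection threshold
(background median + 6 MAD by default); the FA mask itself comes from
the moment-preserving threshold of the averaged green $t_{pre}$ image.
No background is subtracted inside the ratio by default (a switch
exists); the ratio is invariant to any common red-channel gain, so
conversion efficiency does not matter as long as the converted sample is
a fair draw from the pool.  Ratios are not clipped at 1 — fixed controls
fluctuate above it through noise.

**Moments threshold.**  The dynamic threshold is the classic
moment-preserving (bilevel) rule: replace the 256-bin histogram by a
two-level distribution preserving its first three moments and cut at the
corresponding $p_0$-tile.  The implementation returns the upper edge of
the selected bin (foreground is strictly greater), is deterministic, and
is verified against a brute-force enumeration of all candidate cuts.

**Stable areas.**  The same moment-preserving rule, recomputed on the RV
values within the FA mask (the "same dynamic threshold" applied to the
RV image; reusing the numeric green-channel level is exposed as an
option), splits stable from dynamic pixels.  Because a moment-preserving
rule always produces a split — even on pure noise — the split is only
accepted when it actually separates two populations: the between-class
variance must reach 75% of the total variance (Otsu's effectiveness
measure; a Gaussian split at its mean reaches only ~64%).  An
effectively unimodal mask, such as a chemically fixed control where
everything is retained, is therefore labelled entirely stable, which is
exactly the control's expected read-out.  Above-threshold pixels are
grouped by 8-connectivity (the particle-analysis convention) and
components of at least 0.05 µm² — inclusively — become stable areas;
everything else in the FA is dynamic.

Per FA, the pipeline reports the number of stable areas, their sizes,
the summed stable area, the coverage ratio (summed area over FA area,
in [0, 1]), and the area-weighted gravitational centre of the stable
areas projected on the distal-to-proximal axis: the major axis for
pointing FAs, the minor axis for parallel FAs, scaled so the distal end
(nearest the membrane edge) is 0 and the proximal end is 1.  Values
above 0.5 place the stable material in the proximal half, where the
actin stress fibre enters.  `rotated_plot()` draws the conventional
comparison frame: distal side left, pointing FAs horizontal, parallel
FAs vertical, stable areas red, the rest green.

## FA classification

Orientation uses the angle $\varphi$ between the undirected FA long axis
and the undirected local tangent of the ventral membrane edge polyline
(the tangent of the segment containing the nearest point to the FA
centroid), folded to $[0°, 90°]$: *pointing* if
$|\varphi - 90°| \le 30°$, *parallel* if $\varphi \le 30°$, *other*
otherwise (excluded from orientation analyses).  Under uniformly random
orientations exactly one third ($60°/180°$) of FAs fall in the excluded
band — the analytic expectation `expected_random_exclusion()` returns
and the Monte Carlo check reproduces.  Location is *inner* iff the open
segment from the FA centroid to its nearest edge point crosses another
FA's outline polygon (an FA never blocks itself; grazing contacts count
as blocking, decided by sampled interior points so the test is robust to
vertices lying exactly on the segment), *outer* otherwise.  The distal
end of the relevant axis is the endpoint nearer the edge; exact ties are
broken deterministically toward smaller x (then y) and flagged.  FA axes
come from the exact second-order area moments of the outline polygon.

## Synthetic data: what it does and does not emulate

The generators exist so every pipeline stage can be tested against known
truth without any downloads; each one is deterministic under a fixed
seed and attaches a machine-readable truth record.

* `gen_frap_experiment()` wraps the simulator in a camera model
  (intensity = counts × photon scale + background, Poisson photon noise
  plus Gaussian read noise, ~2% normalized noise at defaults, optional
  linear monitor drift) and adds unbleached control and background ROIs.
  A drift of $-4\times10^{-4}$/s drives controls below the 90% rule, by
  design.
* `gen_photoconv_stack()` draws an elliptical FA on a cytoplasmic
  background, converts a rectangle around it with configurable
  efficiency, implants stable clusters with full retention, and decays
  the remaining red signal by a specified exchange fraction by
  $t_{post}$.  Retention is binary (clusters keep everything, the rest
  keeps $1 - \text{exchange}$), mirroring the stable/dynamic dichotomy
  at the 3-minute read-out; the chase interval is recorded but not
  simulated kinetically.  Poisson + Gaussian noise gives a mask-level
  SNR near 10, typical of the source imagery.
* `gen_cell_geometry()` places elliptical FAs against a straight
  vertical membrane edge with chosen orientation statistics, and builds
  inner/outer chains by inserting a blocking FA between each inner FA
  and the edge.

None of the generators emulate drift/registration error, FA assembly or
sliding, uneven illumination, or spatially varying binding within an
FA — so green tests demonstrate the pipeline's correctness on the model's
own terms, not robustness to those real-data complications.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use a 2000-entry database at
$10^4$ molecules per curve (well-mixed transport for database-scale
work), 50 traces per truth point on a $\{0.10, 0.25, 0.40\}^2$ fraction
grid at residence times 60/1800 s, occupancy runs at $10^4$ molecules,
and pure-diffusion recovery pooled over six runs at $10^5$ molecules
(the transit count through the 0.8 µm³ FA is only ~7 molecules per
sample at $10^4$).  Every stochastic function takes an explicit seed;
identical seeds give bit-identical results, and per-molecule RNG streams
make simulations independent of molecule ordering.
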
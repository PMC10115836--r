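---
title: "Visuomotor delay identification and heterogeneous-delay swarm stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visuomotor delay identification and heterogeneous-delay swarm stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaysync)
```

## The scientific problem

Flying insects track moving targets - a relocating hive entrance, a
conspecific, a predator - through a visuomotor feedback loop whose reaction
time is a *transport delay*: the interval between a change in the visual
scene and the corresponding change in flight trajectory. Delays of tens of
milliseconds are a large fraction of the dynamics' time constants, and when
many insects react to each other's *stale* positions, the distribution of
delays across the group decides whether the swarm holds together or loses
its center.

`delaysync` implements the full computational chain for studying this on
synthetic data:

1. **Synthetic experiment generation** - triangular stimulus schedules,
   linear responder models with transport delays, shifted-gamma delay
   populations, and multi-camera pixel detections of 3-D flights.
2. **Tracking** - data association by reprojection error, DLT
   triangulation, Kalman bridging of detection dropouts, coherence-based
   solo/group labelling.
3. **System identification** - frequency-domain transfer-function fitting
   with a transport-delay grid for records longer than 1.5 s, and
   time-domain ARX least squares for shorter ones.
4. **Population modelling** - shifted-gamma fits to identified delays.
5. **Swarm theory and simulation** - a delayed attraction-repulsion swarm,
   its scalar mean-field reduction, and Hopf stability boundaries for
   gamma-distributed delays.

## The responder model and the synthetic experiment

Each simulated insect is a proper rational transfer function composed with
a delay,

$$ y = G_e(s)\, M(s, \tau)\, u, \qquad
   M = e^{-s\tau} \text{ or } \tfrac{1}{1+\tau s}, $$

driven by a triangular stimulus. The worked-example model (three poles,
three zeros, 15 ms pure delay) is available as `eq_example_model("freq")`.
Triangular waves concentrate power in odd harmonics and their slope
reversals pack broad frequency content into short records; the default
schedule sweeps half-periods of 2, 1, 0.5 and 0.25 s at 0.1 m amplitude,
covering roughly 0.25-2 Hz, the band where insect tracking is coherent.
The printed sources show the stimulus shape but not its parameters; the
defaults here are the package's own choice and are not revisited per
experiment.

Numerical realization matters for the identification accuracy downstream,
and four choices are deliberate:

* **First-order-hold integration.** The rational part is discretized with
  a linear-interpolation hold (via the augmented matrix exponential), which
  is *exact at the samples* for piecewise-linear stimuli. The independent
  oracle in the test suite integrates the same ODE with `deSolve`'s RK4 on
  interpolated input - a different scheme, so agreement is informative.
  A zero-order-hold variant exists (`hold = "zoh"`) because its discrete
  equivalent is exactly an ARX structure for strictly proper models, which
  the time-domain tests exploit.
* **Input-side fractional delay.** The transport delay shifts the stimulus
  (linear interpolation between samples, constant pre-history). On the
  piecewise-linear stimulus this is exact except within the single sample
  straddling a corner.
* **Steady-state excision.** Real records are excerpts of ongoing
  tracking, not cold starts; the example model has a pole with a ~7 s time
  constant, so a 4 s record started from rest is transient-dominated.
  `make_tracking_trial()` therefore solves the exact periodic steady state
  (x0 = (I - Phi_cycle)^-1 g) and excises whole stimulus cycles.
* **Shared anti-alias decimation.** The trial is simulated at an
  oversampled rate and both channels are decimated to the camera rate
  through one zero-phase FIR. A filter common to both channels cancels
  exactly in the frequency-response ratio, while sampling-alias artifacts
  (triangle corners folding across Nyquist) would otherwise bias the FRF
  by ~1% - an order of magnitude above the identification's needs.

Records are trimmed to whole stimulus cycles so that the analysis grid of
harmonics is leakage-free. Measurement noise is white Gaussian, added to
the response at the camera rate, scaled so RMS(signal)/RMS(noise) equals
the requested amplitude SNR; the stimulus is commanded and noise-free.

```{r trial}
trial <- make_tracking_trial(eq_example_model("freq"), duration = 4,
                             snr = 20, seed = 1)
head(trial, 3)
```

## Frequency-domain identification

`estimate_spectra()` computes Hann-windowed Welch auto/cross spectra and
magnitude-squared coherence. The identification band is the contiguous
coherence > 0.6 region carrying the most coherent stimulus power, floored
at 1/T_rec (the record-length rule T_rec > 2 pi / omega_min) and capped at
8 Hz. `empirical_frf()` evaluates H = D2/D1 on the record's harmonic grid
inside that band, masking points where the stimulus spectrum is below
1e-3 of its band maximum, and keeps the complex stimulus spectrum as a
per-point weight.

`fit_tf_with_delay()` searches structure x delay-kind x delay grid
(1 ms steps over 0-200 ms). Three numerical decisions deserve emphasis:

* **Criteria on the output spectrum.** FIT, MSE and FPE compare measured
  and modeled *output spectra* over the band (equivalently
  stimulus-weighted FRF errors): FIT = 100(1 - ||Y - G D1||/||Y - mean Y||).
  An unweighted FRF distance would let the weakly excited harmonics - whose
  FRF values are noise-dominated - swamp the criterion; on a 4 s record at
  amplitude SNR 10 its ceiling is below 92% even with the true model known,
  which is inconsistent with the reported robustness of the method. The
  output-spectrum form is the normalized-fit convention of identification
  practice, and its FPE/MSE ratios also reproduce the internal consistency
  of the published worked-example table.
* **Delay/allpass identifiability.** A rational fit with unconstrained
  zeros can mimic a transport delay with right-half-plane zeros, making
  the delay unidentifiable on a narrow band. The delay search therefore
  constrains all transfer-function coefficients to be nonnegative
  (solved by NNLS inside the Sanathanan-Koerner iteration) - stable,
  minimum-phase tracking dynamics have positive coefficients - so all
  excess phase loads onto the delay. A second stage factors each
  candidate into minimum-phase x allpass, converts residual allpass phase
  into its delay equivalent by a weighted phase-slope regression, folds it
  into the delay, and iterates this to its fixed point at the winner.
* **L2 over the band.** The printed minimization is an absolute
  difference with unstated norm; least squares is used, which makes the
  per-delay subproblem linear.

The winner maximizes FIT; candidates within 0.01 FIT points are tied and
resolved by minimum FPE (Akaike's final prediction error), which penalizes
the inflated structures that tie on clean data.

```{r identify}
res <- identify_visuomotor(trial)
res[, c("domain", "delay_s", "fit_percent", "status")]
tidy(res$fit[[1]])[, c("fit_percent", "fpe", "delay_s", "n_poles", "n_zeros", "delay_kind")]
```

On noise-free records the recovered delay is exact on the 1 ms grid, the
pure-delay structure beats its first-order rational approximation, and the
3-pole/3-zero structure is selected - mirroring the worked example. Median
FIT stays above 95% down to amplitude SNR 10.

## Time-domain identification

Records of 1.5 s or less go to `arx_fit_delay_grid()`: order-n ARX least
squares (QR, never an explicit inverse) with the input shifted by d
samples, searched exhaustively over orders and delays. The printed cost
function omits the square on the residual and the printed "fit" formula is
an error ratio; both are implemented in the standard least-squares /
normalized-fit sense consistent with the reported 80-95% fit values. The
one-step residual drives selection; a free-run simulation fit is reported
as a diagnostic. With zero-order-hold synthetic data the worked-example
40 ms delay is recovered exactly.

Two degenerate corners are documented rather than hidden: a pure-gain
system makes the zero-delay regressor collinear (output = constant x
input), so d = 0 is rank-deficient and the search settles on the smallest
viable delay; and a true fractional-sample delay quantizes to a
neighboring integer.

## Delay populations

`shifted_gamma(m, a, tau_m)` is the delay population model: a gamma
density translated by a minimal delay, with Gamma(m) generalizing the
factorial so non-integer shapes are legal. Mean tau_m + m/a, variance
m/a^2, Laplace transform (a/(a+lambda))^m e^(-lambda tau_m).
`fit_shifted_gamma()` estimates tau_m as 0.99 x sample minimum and (m, a)
by maximum likelihood (shape from the digamma equation by root finding).

The printed population fits are kept verbatim as `preset_distribution()`:
solo (m = 3.5, a = 12, tau_m = 1.85) and group (m = 4, a = 5.1,
tau_m = 4.1), in one consistent but unnamed time unit. These printed
parameters are dimensionally inconsistent with the reported millisecond
population statistics (the solo mean tau_m + m/a = 2.14 units cannot be
the reported 30 ms mean, and the group mean 4.88 exceeds solo's 2.14
while the measured group delays are *smaller* and *narrower* than solo's).
No rescaling is guessed; the consequences for the stability analysis are
spelled out below.

## Swarm model and mean field

Each of N agents moves by delayed attraction plus short-range repulsion:

$$ \dot x_i = -\frac{1}{N}\sum_{j \ne i}\big(\alpha x_i - \beta x_j(t - \tau_{ij})\big)
   + \sum_{j \ne i} \frac{\alpha B_r}{D_r} e^{-r_{ij}/D_r}\,\frac{d_{ij}}{r_{ij}}, $$

with d_ij = alpha x_i - beta x_j(t - tau_ij) and r_ij its norm. The
attraction term is taken from the agent update rule (it is what the
mean-field reduction uses); the repulsion keeps the literal potential
gradient with its amplitude absorbed in B_r. Delays are drawn per ordered
pair by default (matching the double-sum approximation of the mean field);
a per-observer mode is provided as the biologically motivated alternative.
Integration is explicit Euler with delays quantized to the step and
constant pre-history - with quantized delays Euler is exactly
reproducible, which matters for seeded experiments. The default step is
min(tau_min/10, T/1000), with a guard keeping dt inside the explicit
stability limit for the mean-field integrator.

Averaging over agents and delays gives the scalar center equation
dC/dt = -alpha C + beta \int C(t - tau) g(tau) dtau
(`simulate_meanfield()`, gamma kernel discretized into 50 equal-probability
atoms). Components decouple, so C is scalar.

## Stability analysis

Linearizing gives the characteristic function
lambda + alpha - beta e^(-lambda tau_m) (a/(a+lambda))^m
(`char_residual()`). At lambda = i omega its real and imaginary parts are
*linear* in (alpha, beta), so the Hopf contour solves exactly:
beta = omega/Im E, alpha = beta Re E with
E = e^(-i omega tau_m)(a/(a+i omega))^m. The two printed closed forms
differ in the sign of the m atan(omega/a) term inside alpha; both are
evaluated and validated against the characteristic equation point by
point, and the agreeing branch (the "+" form, consistent with the printed
beta expression) is recorded on the contour object. Every retained point
has |residual| < 1e-8 (in practice ~1e-15). In the omega -> 0 limit the
validated branch gives alpha -> -1/(tau_m + m/a).

```{r contour}
hc <- hopf_contour(preset_distribution("group"))
max(hc$residual)
attr(hc, "branch")
```

Two structural facts the analysis makes explicit:

* **The operative boundary is delay-independent.** Because
  |E(i omega)| <= 1 for any delay kernel, every Hopf crossing satisfies
  beta >= alpha; meanwhile lambda = 0 crosses exactly at beta = alpha.
  So as neighbor influence grows, the mean-field center always loses
  stability first through the real root at beta = alpha, for *any* delay
  distribution. The delay distribution shapes the Hopf curves above that
  line - the oscillation frequency at the transition (which rises with
  alpha along the boundary) - not the first loss of stability.
* **The printed presets invert the claimed ordering.** With the verbatim
  solo/group parameters the group kernel has the larger mean delay, so the
  group Hopf branch lies *below* solo's for alpha up to ~13 and only
  crosses above it beyond. The published comparison (group boundary
  tolerating more neighbor influence across the board) does not follow
  from the printed parameter values; it would follow from the measured
  millisecond statistics (group delays smaller and narrower). Both facts
  are consequences of the unit inconsistency noted above. The package
  computes and reports what the stated parameters imply; the
  corresponding acceptance checks are left failing rather than adjusted.

`classify_stability()` deliberately ignores the contour: it is the
independent mean-field oracle (simulate from C(0) = 1 for 200
characteristic times; stable if the trailing window falls below 0.5,
unstable if |C| exceeds 10). `region_map()` classifies an (alpha, beta)
grid for both presets; away from the boundary the oracle and the
contour-side prediction (beta < min(alpha, beta_Hopf)) agree on 100% of
cells in the shipped configuration.

Full swarm simulations at the printed operating point (alpha = 7,
beta = 6, B_r = 0.5, D_r = 1, N = 30 - the simulation text says 100
agents, its caption 30; both are presets) settle ||C(t)|| to a constant
under *both* preset delay populations, as the mean-field theory above
predicts for beta < alpha; the solo center settles roughly an order of
magnitude farther from the origin. The published qualitative contrast
(solo failing to settle) is again not reproducible from the printed
presets, and the corresponding check is left failing with this analysis
as its explanation.

## End-to-end replica

`run_replica()` chains everything: per-trial true delays (default: 1 ms
grid draws between 5 and 120 ms, the range spanned by the reported delay
histograms), steady-state trials at the camera rate, routing by record
length (> 1.5 s to the frequency domain), identification, and a
shifted-gamma fit to the identified delays. Per-trial seeds derive from
the master seed by a counter scheme so any trial can be reproduced alone.
At amplitude SNR 20 the mean absolute delay error is under 2 ms.

```{r replica, eval = FALSE}
rep_ <- run_replica(n_trials = 50, snr = 20, seed = 17)
rep_
glance(rep_$dist_fit)
```

## What the synthetic experiments do and do not show

The generator emulates the statistical structure the analysis assumes:
linear time-invariant tracking with a pure transport delay, white
measurement noise, gamma-distributed populations, pinhole cameras with
Gaussian pixel noise and Bernoulli dropouts. Real insect tracking is none
of these exactly - responses saturate, delays drift within a bout, noise
is colored by the tracker, occlusions are structured. Passing tests
demonstrate that the *pipeline* recovers what it assumes, at the noise
levels and record lengths stated; they do not validate the linear-plus-
delay abstraction on real animals. Problem sizes throughout (4 s records
at 120 Hz, populations of tens of trials, 10 x 10 stability grids,
N = 30-100 agents) are the package's chosen desk scale.

## Known limitations

* Frequency-domain delay estimates assume positive low-frequency tracking
  gain (the nonnegative-coefficient constraint); a responder moving
  against the stimulus would need the sign handled upstream.
* The coherence band is assessed at Welch resolution (~1 Hz on 4 s
  records); bands below one Welch bin fall back to the record-length rule.
* The ARX path identifies delay as an integer sample shift; fractional
  true delays quantize.
* The swarm integrator is first order; it is exact reproducibility, not
  high-order accuracy, that is optimized. Halving the step changes stable
  center trajectories by under 1%.
* `ingest_real()` requires an explicit column mapping; the deposited
  recordings' schema is not standardized and no download is attempted.
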
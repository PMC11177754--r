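---
title: "Closed-loop norepinephrine control of arterial pressure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop norepinephrine control of arterial pressure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pressorloop)
```

`pressorloop` simulates a computer-controlled closed-loop norepinephrine
(NE) infusion system that holds mean arterial pressure (MAP) at a target
during anesthesia-induced hypotension, together with the virtual animal it
is exercised on and the performance metrics it is judged by. This vignette
is the package's own account of the models, the defaults, and the design
choices that were genuinely open.

## The control law

The controller runs every 2 s on the low-pass-filtered arterial pressure
(first-order filter, time constant 10 s — the smoothed signal *is* the MAP
the system works with; pulsatility is not simulated, so here the filter's
job is noise smoothing). Three stages:

**Nonlinear error transformer.** With target $t$ and filtered pressure $m$,
the shaped error is

$$
\Delta =
\begin{cases}
t - m, & t \le m\\[2pt]
(t - m) + 10 - \dfrac{10}{1 + e^{1.5\,((t-m) - 5)}}, & t > m,
\end{cases}
$$

i.e. hypertension is corrected on the raw error while hypotension gets a
bounded sigmoid boost (at most +10 mmHg, half of it at a 5-mmHg error), so
low pressure is treated more aggressively than high pressure. The two
branches meet at the target to within $10/(1+e^{7.5}) \approx 0.0055$ mmHg
and the transform is strictly decreasing in $m$. The printed form of the
sigmoid is typographically ambiguous about parenthesization; the reading
above is the one that keeps the function continuous, monotone, and equal to
twice the raw error at a 5-mmHg deficit, and it lives in a single function
(`nl_transform()`) so an alternative reading is a one-line change.

**PID.** Parallel form, $u = K_p(\Delta + K_i I + K_d D)$, with defaults
$K_p = 0.004\ \mu g\,kg^{-1}min^{-1}mmHg^{-1}$, $K_i = 0.006\ s^{-1}$,
$K_d = 96\ s$. The published law is continuous-time; a discretization had
to be chosen. We use forward-Euler integration (advance $I$ by
$\Delta\,dt$, then use the advanced value in the same update) and a
backward-difference derivative on the *transformed* error, zero on the
first update after activation. The integrator starts at zero at each
activation edge; there is no bumpless transfer. The oracle tests pin this
exact scheme.

**Limiter.** If the filtered MAP exceeds target + 10 mmHg the commanded
rate is zero regardless of the PID output; otherwise the rate is clamped to
$[0, 1]\ \mu g\,kg^{-1}min^{-1}$ (negative computed rates clamp to zero —
the published rule set does not address negatives). In the default,
publication-faithful mode the shut-off does **not** touch the integrator;
`antiwindup = TRUE` enables conditional integration (the integral freezes
on updates whose unclamped output lies outside the rate bounds), an
improvement the original authors suggest but did not run. Commands are
zero-order-held between updates, as a syringe pump receiving a setpoint
every 2 s would behave.

## The virtual dog

The study measured real Beagles; the plant here is this package's model,
calibrated to the study's printed medians. Statics:

$$
MAP_{ss}(c, u) = map_0
  - E_{iso}\frac{c^h}{c^h + EC_{50}^h}
  + E_{ne}\frac{u}{u + U_{50}},
$$

with isoflurane concentration $c$ (%) and NE rate $u$
($\mu g\,kg^{-1}min^{-1}$). Both effects relax toward their steady values
with first-order time constants, and the NE command passes through a pure
transport dead time first. Measured MAP adds white Gaussian noise. The
heart-rate channel is decorative (an affine function of the pressor effect
plus noise) and feeds nothing.

Calibration anchors (`default_anchors()`): MAP 92 mmHg at 1.5% isoflurane,
41 mmHg at 4%, and a +19 mmHg pressor effect (enough to lift 41 back to the
60-mmHg target) at 0.33 $\mu g\,kg^{-1}min^{-1}$ of NE. With the Hill
exponent and $map_0$ fixed, the two isoflurane anchors invert in closed
form to $E_{iso} \approx 91.5$ mmHg and $EC_{50} \approx 3.28\%$; the NE
anchor gives $U_{50} \approx 0.712$. Assumptions, each overridable:

| parameter  | default | why |
|------------|---------|-----|
| $map_0$    | 100 mmHg | typical awake canine MAP; not printed anywhere |
| $h$ (Hill) | 3       | steep vasodilatory dose-response; two anchors cannot identify a third shape parameter |
| $E_{ne}$   | 60 mmHg | a pressor ceiling well above the 19-mmHg demand, leaving rescue margin for sensitive animals |
| $\tau_{iso}$ | 120 s | pressure settles well within the 10-min induction window |
| $\tau_{ne}$  | 30 s  | fast venous drug effect |
| $lag_{ne}$ | 20 s    | venous transit plus pump start-up |
| noise SD   | 2 mmHg  | beat-to-beat and transducer noise after mean extraction |
| weight     | 9.1 kg  | cohort median body mass |

`calibrate_defaults()` is deterministic, rejects contradictory anchor sets
with the residual report, and reproduces every anchor to within 0.1 mmHg.

Inter-animal variability (`sample_population()`) multiplies the sensitivity
parameters ($E_{iso}$, $E_{ne}$, $U_{50}$, both time constants) by
independent mean-preserving log-normal factors with a given coefficient of
variation (0.2 for the cohort experiments).

## Protocol replay

Timelines are event tables (time, isoflurane %, controller-active, target).
The canonical ones: an open-loop hypotension trial (1.5% baseline stepped
to 4%, 10 min), and the activation trial (the same step with the loop
closed simultaneously, 30 min, target 60 mmHg), optionally followed by a
deactivated observation period. `timeline_full_protocol()` chains both with
a 5-min 1.5% washout, as one continuous session.

Numerical grids are deliberately decoupled: the plant, noise, and filter
advance at an inner step of 0.05 s (20 Hz — a desk-scale stand-in for the
200-Hz hardware sampling that changes no control mathematics); the
controller fires every 2 s; analysis sampling is every 10 s, so the
15–30-min window holds exactly 90 points. Halving or doubling the inner
step moves the 30-min MAP by well under 0.5 mmHg (tested).

Per-dog anesthetic titration: the study adjusted the isoflurane
concentration slightly per animal. `titrate_iso()` raises the concentration
in 0.25% steps (cap 6%) while the dog's steady MAP at 4% would stay above
60 mmHg — and also *lowers* it (floor 2%) while the steady MAP would fall
below 35 mmHg. The downward branch is this package's choice: with 20%
log-normal variability a right-tail animal would otherwise be parked at an
unsurvivable pressure beyond any NE rescue, which is not something an
anesthetist (or the study) would allow; 35 mmHg marks severe-but-survivable
hypotension.

## Performance metrics

Varvel-style, on the filtered measured MAP restricted to an analysis window
(half-open, `start < t <= end`): percentage performance error
$PE_i = (MAP_i - t)/t \times 100$; MDPE = median PE; MDAPE = median |PE|;
wobble = median |PE − MDPE|; divergence = least-squares slope of PE on time
in minutes; time-in-range = % of points with MAP inside target ± 5 mmHg,
bounds inclusive. Conventions that had to be fixed: even-length medians are
the mean of the two central order statistics; cohort medians/IQRs use
linear-interpolation quantiles; divergence regresses the *signed* PE by
default (the printed formula), with `on = "absolute"` for the
trend-of-|PE| reading the surrounding prose suggests — the two differ in
sign whenever a below-target error is shrinking, and we do not guess which
the original analysis ran.

## Gain tuning

`step_response()` records the open-loop MAP response to an NE step (default
0.25 $\mu g\,kg^{-1}min^{-1}$ from the 1.5% baseline); `fit_fopdt()` fits a
first-order-plus-dead-time model by the two-point method (28.3%/63.2%
crossings; $T = 1.5\,(t_{63} - t_{28})$, $L = t_{63} - T$), rejecting
non-settling responses; `chr_gains()` applies the classical
Chien–Hrones–Reswick setpoint table (0% overshoot:
$K_c = 0.6\,T/(KL)$, $T_i = T$, $T_d = 0.5L$; 20% overshoot:
$K_c = 0.95\,T/(KL)$, $T_i = 1.357\,T$, $T_d = 0.473L$) and converts to the
parallel form ($K_p = K_c$, $K_i = 1/T_i$, $K_d = T_d$). The 0%-overshoot
variant is the default. No variant applied to the virtual dog's own step
response reproduces the published gain triple (0.004/0.006/96) — the
original tuning data are not available, and we do not attempt to
reverse-engineer which variant or what manual adjustment produced them.

## What the simulator does and does not show

Closed-loop behavior under the published gains is *integral-limited*: the
steady NE demand of 0.33 $\mu g\,kg^{-1}min^{-1}$ requires an error
integral of $u/(K_p K_i) \approx 13{,}750$ mmHg·s, which takes tens of
minutes to accumulate, so the 15–30-min analysis window still carries a
residual negative bias of a few percent before the loop finally converges
(the acceptance long-run check shows the rate settling at 0.33 and MAP at
60). The simulated window metrics land where the real system's did —
MDPE around −3%, MDAPE well under the 5% acceptability bound, wobble near
1% — which is reassuring, but it is agreement between one calibrated model
and six real animals' medians, not validation of the plant's functional
form.

Not modelled: baroreflex buffering, pulsatile waveforms and beat detection,
receptor tolerance/tachyphylaxis, isoflurane uptake pharmacokinetics
(inhaled % is the effect-site input), drug interactions, and any real pump
or safety logic. Measurement noise is white; real arterial lines drift and
clot. Passing tests therefore demonstrate that the *control and analysis
code* is correct and that the published control law behaves as reported on
a plant matching the printed steady-state anchors — not that the system is
safe or effective in animals beyond those conditions.

Problem sizes used throughout (tests and the acceptance script): 30-min
trials at a 0.05-s inner step, 6-dog cohorts, one 3-h noise-free run for
the steady-state check — all chosen as the smallest sizes that exercise
every protocol feature at comfortable numerical accuracy.

## A worked run

```{r example, eval = FALSE}
p   <- calibrate_defaults()                       # the study-median dog
rec <- run_closed_loop_trial(p, timeline_activation(), seed = 42)
summarize_trial(rec)                              # 15-30-min Varvel metrics
autoplot(rec)                                     # MAP / NE / isoflurane panels

coh <- run_cohort(n = 6, cv = 0.2, seed = 7)      # the cohort experiment
glance(coh)                                       # median (IQR) per metric
```
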
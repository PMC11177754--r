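# pressorloop

Intra-operative hypotension is the most common complication of inhalant
anesthesia in dogs: isoflurane vasodilates dose-dependently, and keeping
mean arterial pressure (MAP) up by hand-titrating a norepinephrine (NE)
drip is fiddly and attention-hungry. `pressorloop` implements, in silico,
a computer-controlled closed-loop NE infusion system for this problem —
the feedback controller, a calibrated virtual-dog pharmacodynamic plant to
exercise it on, the study protocol that couples them, the Varvel-style
performance metrics used to judge such controllers, and the
step-response/Chien–Hrones–Reswick gain-tuning pathway. It is aimed at
people developing or evaluating physiological closed-loop controllers who
need a reproducible test harness rather than an animal lab.

## The system

Every 2 s the controller reads the low-pass-filtered arterial pressure
(time constant 10 s) and commands a pump rate through three stages:

1. **Nonlinear error transformer** — hypertension is corrected on the raw
   error `tMAP − MAP`; hypotension gets a bounded sigmoid boost,

   `Δ = (tMAP − MAP) + 10 − 10 / (1 + exp(1.5 ((tMAP − MAP) − 5)))`,

   so low pressure is treated more aggressively than high pressure.
2. **PID** — parallel form `u = Kp (Δ + Ki ∫Δ dt + Kd dΔ/dt)` with the
   published gains `Kp = 0.004 µg·kg⁻¹·min⁻¹·mmHg⁻¹`, `Ki = 0.006 s⁻¹`,
   `Kd = 96 s`.
3. **Limiter** — rate forced to 0 whenever MAP > tMAP + 10 mmHg, otherwise
   clamped to [0, 1] µg·kg⁻¹·min⁻¹. Optional anti-windup (integral clamping
   under saturation) is off by default, matching the published system.

The virtual dog combines sigmoid-Emax statics
(`MAP = map0 − Eiso·cʰ/(cʰ+EC50ʰ) + Ene·u/(u+U50)`), first-order effect
dynamics, a 20-s NE transport dead time, Gaussian measurement noise, and
log-normal inter-animal variability. `calibrate_defaults()` pins it to the
study's printed medians: MAP 92 mmHg at 1.5% isoflurane, 41 mmHg at 4%, and
a +19 mmHg pressor effect at 0.33 µg·kg⁻¹·min⁻¹ of NE.

Trials are scored on the 15–30-min window (90 points at 10 s) with
percentage performance error PE, MDPE (bias), MDAPE (inaccuracy), wobble
(variability), divergence (trend, %/min) and time-in-range (55–65 mmHg).

## Worked example

```r
library(pressorloop)

p   <- calibrate_defaults()                       # the study-median dog
rec <- run_closed_loop_trial(p, timeline_activation(), seed = 42)
summarize_trial(rec)
#> <perf_summary> 90 points, 15-30 min, target 60 mmHg, band [55, 65] mmHg
#>   MDPE -2.93%  MDAPE 2.93%  wobble 0.708%  divergence 0.405%/min  in-range 92.2%
```

MAP, driven from its 92-mmHg baseline down by 4% isoflurane, is pulled back
by the automated NE infusion and held near (slightly under) the 60-mmHg
target: a bias of −2.93% means the window median sat at ≈ 58 mmHg, inside
the acceptable band 92% of the time. A cohort experiment with 20%
inter-dog variability:

```r
coh <- run_cohort(n = 6, cv = 0.2, seed = 7)
glance(coh)
#> # A tibble: 5 × 4
#>   metric         median     q1      q3
#>   <chr>           <dbl>  <dbl>   <dbl>
#> 1 divergence      0.232  0.177   0.295
#> 2 mdape           4.09   3.69    4.20
#> 3 mdpe           -4.09  -4.20   -3.69
#> 4 time_in_range 100     97.5   100
#> 5 wobble          1.43   1.21    1.75
```

Median inaccuracy (MDAPE) and wobble sit well under the 5% acceptability
bound. The tuning pathway, from the virtual dog's own open-loop step
response:

```r
m <- fit_fopdt(step_response(calibrate_defaults(noise_sd = 0)))
m
#> <fopdt> K = 62.36 mmHg/(ug/kg/min), T = 29.99 s, L = 21.93 s (RMS residual 0.000824 mmHg)
chr_gains(m)
#> # A tibble: 1 × 4
#>       kp     ki    kd variant
#>    <dbl>  <dbl> <dbl> <chr>
#> 1 0.0132 0.0333  11.0 setpoint_0
dose_to_pump_rate(0.33, 9.1)   # µg/kg/min -> mL/h at 0.5 mg/mL
#> [1] 0.36036
```

`autoplot()` methods draw trial records (MAP/NE/isoflurane panels), cohort
median–IQR ribbons, and windowed PE series; `tidy()`/`glance()` give tabular
forms of every result object.

A small CLI wraps the same functions
(`Rscript inst/cli/pressorloop.R <command>`, or the installed copy under
`system.file("cli", "pressorloop.R", package = "pressorloop")`):
subcommands `run-trial`, `simulate`, `cohort`, `metrics`, `tune`,
`make-fixture`; every stochastic command takes `--seed`.

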
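---
title: "Modelling cardiovascular autonomic control across sleep stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiovascular autonomic control across sleep stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvsleep)
```

## The model

`cvsleep` implements a compact delay-differential model of the human
cardiovascular system under baroreflex autonomic control, with eight
cortical-input parameters that shift the operating points of the control
loops between the awake state, REM sleep and stage-4 non-REM sleep.

**Pacemaker.** The sinoatrial node is an integrate-and-fire phase
oscillator,

$$\frac{d\varphi}{dt} = \frac{f_s(t)\, f_p(t)}{T_0 + \xi},$$

firing a heartbeat whenever $\varphi$ reaches 1. $T_0 = 1.1$ s is the
period of the denervated heart; $f_s$ and $f_p$ are sympathetic and
parasympathetic factors; $\xi$ is a 1/f ("pink") perturbation of the
period, redrawn at each beat, standing in for humoral regulation and other
unmodelled slow influences.

**Arterial pressure.** During the first $T_{sys} = 0.125$ s of each cycle
the pressure follows a pulse launched from the end-diastolic value
$D_{i-1}$ of the previous cycle,

$$p(t) = D_{i-1} + S(t)\, x\, e^{1-x} + k_{pB} B(t), \qquad
x = \frac{t - T_{i-1}}{T_{sys}},$$

peaking at $D_{i-1} + S$ at end-systole; afterwards it decays through a
Windkessel, $\dot p = -p / (R(t)C)$ with
$R(t)C = R_0C\,(1 + k_{Rv} c_v)$. The contractility $S$ combines a
baseline, noradrenaline sensitivities and the previous cycle length, and
saturates towards the resting ceiling $\hat S = 40$ mmHg. $B(t)$ is a
sinusoidal respiratory signal whose period is jittered every cycle.

**Baroreflex.** Carotid and lower-body baroreceptor nodes sense pressure
and its rate of change, $v_b = k_1 (p - p_0) + k_2\, \dot p$. Two
sympathetic loops (heart rate and vessel tone) pass $v_b$ through a
sigmoid with cortical inputs $C_*$,

$$v_s = a_s \tanh\!\big((b_s + C_{sb})(v_b - v_{s0}) - C_{sv}\big) + y_s
+ k_{sr} B,$$

and drive cardiac and vascular noradrenaline pools with first-order
kinetics and conduction delays ($\theta_c = 1.5$ s, $\theta_v = 2.5$ s).
The parasympathetic pathway is rectified,
$v_p = \max(0,\, C_{pv} + v_{p0} + (C_{pk} + k_{pb}) v_b + k_{pr}|B|)$,
acts with a short delay ($\theta_p = 0.25$ s), and is gated within the
cardiac cycle by the phase effectiveness curve

$$F(\varphi) = \varphi^{1.3} (\varphi - 0.45)
\frac{(1-\varphi)^3}{0.008 + (1-\varphi)^3},$$

negative (phase delay) early in the cycle and positive late. All defaults
are the published operating values; `cvs_parameters()` documents each
group with units, and `sleep_preset()` returns the stage columns of the
cortical inputs (all zero when awake).

## Design choices in ambiguous places

Several details of the printed formulation admit more than one reading;
the package resolves each the same way throughout and exposes the
alternative where practical.

* **Sympathetic sigmoid operating point.** The printed argument
  $(b_s + C_{sb}) v_b - C_{sv} - v_{s0}$ subtracts the resting afferent
  tone unscaled, which places the sigmoid's knee at $v_b \approx 9$,
  i.e. at ~230 mmHg: the vessel loop is then saturated at maximal
  sympathetic output over the entire physiological pressure range, the
  Windkessel time constant stays near 4.4 s, and the closed loop is forced
  to a hypertensive equilibrium near 208/166 mmHg. Reading $v_{s0}$ as
  recentring the baroreceptor input,
  $(b_s + C_{sb})(v_b - v_{s0}) - C_{sv}$, puts the reflex in its linear
  range at physiological pressures and yields the published operating
  regime (heart rates near 60 bpm, pressures ~15 mmHg above the published
  stage means). The centred form is the default; `sympathetic_form =
  "printed"` selects the literal one.
* **Systolic pulse kernel.** The literal kernel $x e^{x}$ overshoots the
  contractility scale by a factor $e$ at end-systole, which is
  incompatible with the published pulse pressures (~36 mmHg, the
  contractility scale). The default kernel $x e^{1-x}$ is the standard
  beat-to-beat pulse form that peaks at exactly $D_{i-1} + S$;
  `systolic_form = "literal"` retains the printed expression.
* **Intrinsic period.** Two values appear in the source material (1.5 s
  in the running text, 1.1 s in the parameter table). 1.1 s is the
  default: the closed loop then runs near 60 bpm, against ~45 bpm with
  1.5 s. Override with `cvs_parameters(t0 = 1.5)`.
* **Systolic duration.** The parameter table prints a variance (an
  evident row-copy misprint) for $T_{sys}$; the text value 0.125 s is
  used.
* **Respiratory jitter semantics.** The jitter variance is stated in
  s^2^ (a period perturbation) while the respiratory equation places the
  noise as a phase offset. The period reading is used: each respiratory
  cycle's period is $T_{br} + \zeta$, $\zeta \sim N(0, 0.3\,\mathrm{s^2})$,
  clamped to at least 0.5 s, realised by phase accumulation. This honours
  the stated units and keeps the instantaneous period well defined.
* **Per-cycle noise.** $\xi$ is held constant within each cardiac cycle
  and redrawn at each beat, since it perturbs the cycle period. Values
  that would make $T_0 + \xi \le 0.2$ s are skipped (a >6-sigma event at
  the default variance).

## Numerics

The coupled system is advanced with a fixed-step classical RK4 scheme,
default $dt = 1$ ms, which resolves the 0.125 s systole and all delays.
Delayed loop activities are kept in a history buffer sampled every step
and looked up with linear interpolation (delays are 250-2500 steps, so
interpolation error is negligible); the pre-history ($t<0$) is filled
with the resting activities at $v_b = 0$, $B = 0$. Beats are located by
linear interpolation of the $\varphi = 1$ crossing within the step and
the phase overshoot is carried into the next cycle, so beat times are not
quantised to the step grid; in the denervated, noise-free limit every
interbeat interval equals $T_0$ to better than $10^{-6}$ s. Cycle
bookkeeping (pressure capture, cycle length, noise redraw,
systole/diastole switching) is applied at step boundaries. The
baroreceptor rate input $\dot p$ is the analytic branch derivative, not a
finite difference, so the cycle-boundary pressure jump injects no spike.
Halving $dt$ changes the post-transient mean interbeat interval by about
$10^{-5}$ relative. Initial conditions are $\varphi = 0$, $p = 80$ mmHg
and the noradrenaline pools at their resting steady states; the first
1000 s are discarded as transient in all analyses.

## The analysis toolkit

Interbeat intervals are extracted at the phase resets, cubically
interpolated onto a 4 Hz grid (standard HRV practice; Nyquist far above
the 0.4 Hz band edge) in milliseconds, and analysed with a Welch
estimator (Hann window, 256 s segments, 50% overlap) normalised so that
the integrated density reproduces the series variance. LF and HF are the
band powers over 0.05-0.15 Hz and 0.15-0.4 Hz.

The largest Lyapunov exponent uses the Rosenstein nearest-neighbour
divergence method on the 0.05-0.4 Hz band-passed series (zero-phase
two-pass Butterworth), embedding dimension 13, in 1000 s windows.
Conventions the source leaves open are fixed as: embedding delay at the
first non-positive autocorrelation lag (fallback 10 samples); Theiler
exclusion of one mean orbital period (dominant spectral peak); slope
fitted from lag zero to the half-rise point of the divergence curve, at
least 5 points. Estimates whose fit has $R^2 < 0.9$, or whose half-rise
falls inside the embedding span (where apparent divergence reflects
decorrelation of overlapping embedding windows, as for white noise), are
flagged `poor_fit` rather than silently reported. The estimator is
validated against a fully chaotic logistic map ($\lambda = \ln 2$), a
periodic signal ($\lambda \approx 0$) and the Lorenz-63 x-component
against a tangent-space (Benettin) oracle. Exponents are reported both
per second and per sample (0.25 s spacing); the per-sample scale is used
in the stage reports, as it is the one on which the published values
(~0.02) lie.

## What the ensembles show - and do not show

`run_stage_experiment()` repeats the published protocol: per stage, 20
independent runs of 1000 s transient plus 1200 s analysis, with HR, SP,
DP, LF, HF and $\lambda_0$ summarised as mean ± SEM (the ensemble size
mirrors the 20-subject experimental cohort; the source does not state its
model ensemble size). With the default parameters the simulated heart
rates track the published stage means within ~2%, and non-REM pressures
fall within 10%; the awake pressures run ~19% high and the spectral
indices and $\lambda_0$ exceed the published values by roughly an order
of magnitude. The test suite leaves these comparisons red rather than
retuning: the printed per-beat noise variance of 0.02 s^2^ (141 ms
standard deviation per beat) necessarily places several thousand ms^2^
into the 0.05-0.4 Hz band of a 1/f process regardless of its
low-frequency cutoff, which no choice of the remaining printed constants
can reconcile with in-band powers of a few hundred ms^2^; and the
Windkessel decay geometry with the printed sigmoid constants admits no
closed-loop equilibrium at the published awake pressures. The
deterministic behaviour of the implementation is verified independently
by exact and closed-form checks (denervated period, Windkessel
exponential, noradrenaline steady states, step-halving convergence).

The synthetic inputs emulate per-beat humoral-like 1/f variability and
breath-to-breath period variability. They do not emulate nonstationarity
(stage transitions, arousals), ectopy or measurement noise of real RR
series, broadband respiratory dynamics, or humoral and local (Bowditch)
control, which are outside the model. Passing tests therefore certify
the solver, the estimators and the stated operating conditions - not
fidelity to any individual's physiology.

## Problem sizes

Defaults used throughout the package's own experiments: 2200 s records
(1000 s discarded), $dt = 1$ ms, 20 runs per stage; Lyapunov windows of
1000 s at 4 Hz (4000 samples, embedding dimension 13). A single run
simulates in about a second in the compiled core.
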
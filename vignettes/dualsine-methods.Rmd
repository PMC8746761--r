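---
title: "Single-trial E/I conductance estimation from dual-sinusoid current clamp: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial E/I conductance estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dualsine)
```

## The problem and the model

Excitatory and inhibitory synaptic inputs are classically separated by
recording the same stimulus many times at different holding potentials.
That averages away single-trial structure, and it fails outright for
*shunting* input: a conductance whose reversal potential sits at the
resting potential draws no current and leaves no voltage signature at
all. `dualsine` implements a single-trial alternative: while recording
in current clamp, a current composed of two high-frequency sinusoids

$$ I(t) = I_1 \sin(2\pi f_1 t) + I_2 \sin(2\pi f_2 t) $$

is injected (defaults $I_1 = I_2 = 0.375$ nA, $f_1 = 210$ Hz,
$f_2 = 315$ Hz). Seen through a pipette with series resistance $R_s$,
the passive cell (total conductance $g$, capacitance $C$) has circuit
impedance

$$ Z(f, t) = R_s(t) + \frac{1}{g(t) + j\,2\pi f\, C}, $$

so the amplitude and phase of the voltage response at each tone carry an
instantaneous, current-independent readout of $g(t)$ and $R_s(t)$.
With $g(t)$ in hand, the passive membrane equation

$$ C\dot V = -g_l (V - V_l) - g_e (V - V_e) - g_i (V - V_i) + I $$

is solved per sample for the excitatory conductance
($V^x \equiv V - V_x$):

$$ g_e(t) = \frac{C\dot V + g_l V^l + g_s V^i - I_{\rm slow}}{V^i - V^e},
   \qquad g_i = g_s - g_e , $$

where $g_s = g - g_l$ is the synaptic part of the total conductance and
$I_{\rm slow}$ is any non-sinusoidal injected current (the sinusoids'
effect is carried entirely by the impedance branch). The denominator is
the constant $V_e - V_i$, so the decomposition is well defined even
where $V$ crosses a reversal potential.

The pipeline in `estimate_conductances()` chains:

1. time-resolved complex impedances $Z_k(t)$ at the two tones, from the
   ratio of narrowband analytic signals of voltage and current;
2. a phase-based capacitance estimate on a synaptically silent
   calibration window, $C = 1/|\tan\theta \cdot R_s^* \cdot 2\pi f|$,
   valid in the high-frequency regime $(2\pi f C)^2 \gg g^2$;
3. optionally, estimation and subtraction of pipette stray capacitance;
4. the closed-form inversion of the two-tone system for $R_s(t)$ and
   $g(t)$ (a quadratic in $R_s$ after eliminating $g$);
5. removal of the stimulus tones from the voltage;
6. leak conductance and resting potential from the lowest-percentile
   conductance samples;
7. the E/I decomposition above.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| tones $f_1, f_2$ | 210, 315 Hz | high enough for $(\omega C)^2 \gg g^2$ (ratio $\approx$ 89 already at 100 Hz for $g = 10$ nS, $C = 0.15$ nF), low enough to retain impedance sensitivity |
| tone amplitude | 0.375 nA each | a few mV of membrane-level ripple ($<6$ mV peak-to-peak), below voltage-gated recruitment |
| cell preset | $C = 0.15$ nF, $R_{\rm in} = 150$ M$\Omega$, $V_l = V_i = -70$ mV, $V_e = 0$ | experimentally typical cortical values; a 300 M$\Omega$ variant is provided |
| electrode | $R_s = 30$ M$\Omega$ | upper end of in-vitro, typical of in-vivo whole cell |
| impedance half-bandwidth | 6 Hz ($-3$ dB, Gaussian) | accuracy optimum on the reference fixture, see below |
| notch half-width | 5 Hz per tone | removes the tones while leaving the membrane dynamics untouched |
| leak percentile | 5% | quietest samples stand in for the resting state |
| calibration window | 0.15–1 s | synaptically silent, past the filter edge trim |
| simulation dt | 0.1 ms (0.025 ms for noise and stray-capacitance runs) | explicit-Euler accuracy; the pipette node time constant $R_s C_p = 0.1$ ms needs the finer step |

Temporal resolution contract: a Gaussian filter of half-bandwidth $B$
has envelope resolution $\sigma_t = \sqrt{\ln 2}/(2\pi B)$ (22 ms at
6 Hz). Estimates are meaningful on timescales of that order and are
*not* silently smoothed further.

## Why a Gaussian narrowband filter

Early in development the narrowband stage used a steep windowed-FIR
bandpass. Its near-brick-wall frequency response has strong time-domain
sidelobes, and fast conductance transients made the instantaneous
impedance *ring*: the estimated conductance pre-rang before each event,
overshot several-fold and went negative, destroying the inhibitory
recovery. A Gaussian (Morlet-style) kernel has a monotone, ring-free
envelope response; transients are smoothed, never rung. The default
half-bandwidth of 6 Hz is the measured accuracy optimum on the reference
fixture: wider bands buy temporal resolution more slowly than they admit
cross-tone transient splatter.

Two further numerical points matter because the circuit inversion
amplifies impedance errors by roughly $|Z_{\rm cell}|^{-2}$ (a $10^{-4}$
relative impedance ripple becomes a percent-level conductance error):

* the kernels are truncated at $\pm 6\sigma_t$, keeping the truncation
  sidelobe floor ($\sim e^{-18}$) below the level at which the other
  tone's leakage would beat into the conductance trace;
* the analytic (Hilbert) narrowband signal is computed by one local
  convolution with the *complex* Gaussian kernel rather than filtering
  followed by a global FFT Hilbert step — the global transform leaks
  trace-end and onset non-stationarities into the whole envelope at
  exactly the amplified level.

With these choices the conductance recovered from a silent
constant-circuit recording is flat to $<10^{-3}$ nS and matches the true
value to the forward-Euler discretisation error ($<1\%$ at dt = 0.1 ms).

## Circuit inversion: branch and cross-check

Eliminating $g$ from the two-tone system gives a quadratic in $R_s$; the
square-root branch is chosen per sample to give $\mathrm{Re}(R_s) > 0$
with the smallest relative imaginary residual, and the residual is kept
as a diagnostic. Whether the inversion should be evaluated on the
complex impedances or on their magnitudes is a genuine design fork; both
are implemented (`solve_circuit(..., method =)`). The complex path is
the default: through transients the measured phases stabilise the branch
choice, and on the reference fixture it is markedly more accurate than
the magnitude path.

The magnitude-only system is also the basis of the independent test
oracle (`numeric_circuit_oracle`). It reduces to one equation in $g$
whose roots are enumerated by bracketing; the system generically has
*two* admissible roots, and the physical one (the branch the complex
data are consistent with) is the smaller-conductance root throughout the
method's operating regime ($R_s \gtrsim 10$ M$\Omega$, $g$ below about
half of $\omega_1 C$). Outside that regime the pairing can flip; the
oracle returns all roots so the ambiguity is visible.

## Stray-capacitance compensation

Pipette capacitance $C_p$ shunts injected current and, uncompensated,
produces a grossly inflated leak and spuriously *negative* evoked
inhibition. The admittance-difference estimator
$C_p \approx \mathrm{Re}\,\langle (1/Z_1 - 1/Z_2)/(j(\omega_1-\omega_2))
\rangle$ neglects the cell term $Y_1 - Y_2$; for a realistic
few-picofarad pipette on a 20 M$\Omega$ electrode that term is the same
size as the stray term and the plain estimator fails (it can even go
negative). The package therefore fits the full four-parameter circuit
$(R_s, g, C, C_p)$ to the two window-averaged complex impedances
(`calibrate_circuit`): two complex samples give exactly four real
equations. This also repairs the capacitance estimate, which the stray
capacitance otherwise biases low by a factor of two. On the
stray-capacitance fixture the joint fit recovers $C_p$ to 0.5% and $C$
to 0.3%, and compensation flips the inhibitory correlation from $-0.8$
to $+0.9$.

## The synthetic-data generators: what they emulate

* **Depressing trains** (`tm_depressing_conductance`): two-variable
  depletion/recovery dynamics — per event $n$,
  peak$_n = U R_n g_{\max}$ and
  $R_{n+1} = 1 - (1 - R_n(1-U))e^{-\Delta t/\tau_{\rm rec}}$, with
  exponential conductance decay $\tau_{\rm inact}$. Reference
  parameters: $U = 0.7$, $\tau_{\rm inact} = 3$ ms,
  $\tau_{\rm rec} = 0.5$ s (E) / 1.3 s (I), inhibition delayed 4 ms.
* **Reference fixture** (`std_conductance_programme`): a regular 2 Hz
  train over seconds 0.5–2.5 plus a 5 nS tonic step in both
  conductances over seconds 3–4 of a 5 s trace. The per-event
  $g_{\max} = 15$ nS puts first-event peaks near 10 nS, the scale of
  evoked cortical conductances. Event timing and amplitudes are
  package choices (the corresponding reference experiments do not print
  them) and every element is parameterised.
* **Network surrogate** (`make_network_surrogate`):
  Ornstein–Uhlenbeck-type E and I traces sharing a latent component so
  the pre-clipping correlation is exact; 20 ms correlation time as a
  stand-in for aggregated synaptic input in an asynchronous network
  state. A circular 10 s shift of inhibition mimics uncorrelated
  inputs.
* **Access-resistance wobble** (`make_rs_trace`): Gaussian noise put
  through a zero-phase Gaussian lowpass (−3 dB at 2 Hz) and rescaled,
  riding on the base resistance. The band-limitation matters: wobble
  power above the impedance envelope band cannot be attributed by the
  two-frequency inversion and would leak into $g(t)$ with the amplified
  lever described above.
* **Recording noise** (`make_recording_noise`): white Gaussian voltage
  noise, SD 0.04 mV — the amplitude of open-pipette noise in a slice
  setup. A user-supplied recorded noise trace can be added with
  `add_noise()` instead.

What the generators do **not** emulate: amplifier feedback dynamics and
transfer-function colouration (the known obstacle to applying the
method on real rigs), voltage-gated conductances, spikes, synaptic
facilitation, and the temporal structure of real network input beyond a
single correlation time. Passing tests on these fixtures therefore
validate the analysis chain, not the method's robustness to hardware.

## The cable model

`build_ball_and_stick()` constructs a soma plus `n_dend` passive
dendrites ($R_a = 150\ \Omega$cm, $C_m = 1\ \mu$F/cm², $R_m = 15$
k$\Omega$cm², 2 µm dendrites, ≤25 µm or 0.1 electrotonic-length
compartments). The default three 600 µm dendrites put the somatic input
resistance at 143 M$\Omega$ — the experimentally typical regime — and
are a deliberately parametric stand-in for detailed pyramidal
morphologies: distance-dependent conclusions transfer qualitatively,
never numerically. Integration is backward Euler with a Hines-ordered
direct solve (explicit stepping is unstable on stiff trees); synapses
are depressing dual-exponential conductances, 10 Hz trains with 10 ms
Gaussian jitter.

For somatic recordings of a dendritic cell, injected current escapes
into the tree and the apparent leak is inflated. The empirical dynamic
leak correction

$$ g_l'(t) = g_l\left(1 - e^{-(g_s(t)/g_l)^2}\right) $$

is applied before the decomposition in cable mode only (it is off for
point neurons); on proximal-input cable runs it raises the inhibitory
correlation from ~0.3 to ~0.97. Voltage-clamp comparison runs hold the
soma at one input's reversal through the same 10 M$\Omega$ access
resistance, subtract the holding current measured on a silent window,
and divide by the driving force.

The distance sweep uses the distance ladder of the reference
experiments (most proximal ≈130 µm dendritic path). At the somatic
limit a separate-trial voltage clamp is trivially near-exact — the
meaningful comparison starts where the synapse is electrotonically
separated from the electrode.

## Known limitations

* **Envelope bandwidth vs fast transients.** With tones 105 Hz apart
  the usable envelope bandwidth is a few tens of Hz; 3 ms synaptic
  decays are inevitably smoothed in $g(t)$. The excitatory trace is
  largely immune (its fast structure re-enters through $C\dot V$), but
  inhibition at rest is visible *only* through the impedance branch, so
  its fast transients are smoothed: on the reference fixture the
  inhibitory correlation plateaus near 0.94 (a smoothing-ceiling
  analysis — correlating Gaussian-smoothed truth with truth — gives
  ≈0.99 even at 2 ms resolution, which the tones cannot deliver).
  Reported correlations on this fixture are $r_e \approx 0.998$,
  $r_i \approx 0.94$.
* **Estimation-induced E/I correlation.** Errors in $g_s$ enter $g_e$
  and $g_i$ with weights $V^i/(V_e-V_i)$ and $-V^e/(V_e-V_i)$ — both
  positive in the physiological range — so shared conductance error
  produces spurious positive E–I correlation. With uncorrelated
  (shifted) surrogate inputs the estimated E–I cross-correlation is
  ~0.24 against ~0.7 for genuinely correlated inputs: the contrast is
  preserved, the absolute value is not zero.
* **Leak percentile bias.** With persistent background activity the
  lowest-percentile conductance still contains synaptic input, so
  $g_l$ is overestimated and evoked conductances are shifted
  negative — visible as negative excursions, which are reported, never
  clipped.
* **Step amplitudes vs absolute offsets.** The percentile leak places
  an arbitrary zero; evoked amplitudes (differences from the local
  baseline) are accurate to a few percent even for voltage-invisible
  shunting steps, absolute offsets are only as good as the leak
  estimate.

## Problem sizes used in validation

The shipped validation runs 5 s point-neuron trials at dt = 0.1 ms
(0.025 ms for the noise and stray-capacitance conditions), a 13 s
network-surrogate trial, and a four-distance cable sweep of 4 s trials
on a 73-compartment tree — sizes chosen so the full suite exercises
every regime in well under a minute of simulation time while keeping
every filter's edge trim small relative to the trace.
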
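---
title: "Models and measurement conventions in audsynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement conventions in audsynth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audsynth)
```

This vignette explains the science behind the package: what the two
measurement pipelines quantify, what the synthetic generators emulate and
deliberately leave out, and the numerical and design choices made where the
underlying analysis conventions are genuinely open.

## The two measurement problems

**EPSC trains.** Optogenetic stimulation of a presynaptic population with
brief light pulses evokes AMPAR-mediated EPSCs in a patched postsynaptic
neuron held at −70 mV. The analytically relevant quantities are the
per-pulse amplitude (and its change after manipulations such as extracellular
zinc chelation), the kinetics of the response (decay tau), and short-term
depression along 5–10 Hz trains. Because absolute amplitudes vary strongly
from cell to cell, comparisons are made within cell after normalisation, and
experiments are paired (each cell is its own control).

**Frequency tuning in awake mice.** Layer-5 cortical neurons expressing a
GCaMP indicator are imaged at 5 Hz while pure tones from a 25-frequency ×
5-level grid are presented pseudorandomly. The response of a neuron to each
of the 125 stimuli, averaged over 5–7 block presentations, defines its
frequency-response area, summarised by the best frequency, the response
threshold and the Q20 bandwidth. Wide-field imaging at 20 Hz with a
low-level 6 kHz tone locates the low-frequency regions of A1 and the AAF
before cellular imaging.

## EPSC generator

Each evoked EPSC is a peak-normalised difference of exponentials

$$k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}, \qquad \tau_r < \tau_d,$$

zero at pulse onset and equal to the requested amplitude at its analytic
peak time $t^* = \frac{\tau_r\tau_d}{\tau_d-\tau_r}\ln(\tau_d/\tau_r)$.
Defaults $\tau_r = 1$ ms, $\tau_d = 15$ ms give AMPAR-like kinetics; a
larger $\tau_d$ preset emulates slower (e.g. NMDAR-dominated) responses.

Short-term depression follows a single-pool vesicle-depletion recursion with
release fraction $U$ and recovery time constant $\tau_{rec}$:

$$R_1 = 1,\qquad R_{n+1} = R_n(1-U)\,e^{-\Delta t/\tau_{rec}} + 1 -
e^{-\Delta t/\tau_{rec}},$$

with the pulse-$n$ ideal amplitude $A_n = A_1\,g_c\,R_n$, where $g_c$ is a
condition gain. This model was chosen because it reproduces the qualitative
signature of the recordings — more depression at 10 Hz than at 5 Hz — and
has a closed-form fixed point

$$R_{ss} = \frac{1-e^{-\Delta t/\tau_{rec}}}{1-(1-U)\,e^{-\Delta
t/\tau_{rec}}}$$

that the test suite uses as an independent oracle. Defaults $U = 0.4$,
$\tau_{rec} = 200$ ms produce a 10-Hz steady state near 0.62.

The chelator condition is modelled as a purely postsynaptic multiplicative
gain (default 0.75, i.e. a 25 % amplitude reduction) that leaves $U$ and
$\tau_{rec}$ untouched — consistent with the observation that paired-pulse
ratios are unchanged by zinc chelation, pointing at a postsynaptic locus.
Noise is additive white Gaussian with a default sd of `base_amplitude / 20`
(first-pulse SNR ≈ 20). Real recordings additionally contain line noise,
slow drift and stimulation artifacts, none of which are emulated; passing
recovery tests therefore demonstrates correctness of the measurement code,
not robustness to every pathology of real traces.

## EPSC measurement conventions

* **Baseline** at each pulse is the mean over the 1 ms window ending at the
  pulse onset (robust to noise); a single-sample reading is available via
  `baseline_window = 0`.
* **Peak search** runs from the onset to the smaller of the inter-pulse
  interval and 100 ms; the extremum is the most negative sample (EPSCs are
  inward at −70 mV) and amplitudes are reported as positive magnitudes.
* **Decay fits** use Levenberg–Marquardt least squares on
  $y(t) = a\,e^{-t/\tau}$ from the peak sample to the next pulse (capped at
  100 ms), initialised at the time-to-1/e of the peak. Non-decaying or
  sub-noise segments are flagged rather than fitted. On the
  difference-of-exponentials kernel the fitted tau slightly exceeds
  $\tau_d$ (the rise steals early samples); the pure-exponential recovery
  test therefore uses an exact exponential trace.
* **Steady state** is the mean of the last 3 pulses over the first; 3 is a
  package default, chosen because 10-pulse trains have clearly plateaued by
  pulse 8.
* **Trial count** 3–7 is enforced; a permissive flag downgrades it to a
  warning for exploratory use.

## Imaging generator

A neuron's ground-truth receptive field is *rectangular in log frequency at
each level*: stimulus $(f, l)$ is responsive iff $l \ge$ threshold and
$|\log_2(f/\mathrm{BF})| \le \mathrm{bw}(l)\,g_c/2$, with
$\mathrm{bw}(l) = 0.5 + 0.25\,(l - \mathrm{thr})/10$ octaves (a V-shaped
field, 1 octave wide at 20 dB above threshold) and $g_c$ a per-condition
bandwidth gain. Rectangular bands make the true Q20 exact by construction,
which is what permits the noise-free pipeline-equivalence tests. Within the
band, injected amplitudes taper triangularly away from BF and grow with
level, so the noise-free global maximum is exactly at (BF, highest level)
and best-frequency recovery is well posed.

Responsive stimuli inject a GCaMP kernel (difference of exponentials, rise
0.1 s, decay 1.0 s — peaking ≈ 0.26 s after onset, safely inside the 1-s
quantification window) scaled by a lognormal trial-to-trial jitter
(sdlog 0.2), onto a baseline of 1, plus white per-frame noise. The default
peak ΔF/F of 1.0 with frame-noise sd 0.3 was calibrated so that a *single*
presentation of a responsive stimulus is detected with probability ≈ 0.9;
after the standard 5-repeat averaging, detection is ≈ 0.98 with a ≈ 3 %
false-positive rate per non-responsive stimulus. Neuropil contamination,
motion, correlated noise and spike-to-calcium nonlinearity are not
emulated.

Each block repetition re-draws its pseudorandom presentation order from a
derived seed; the alternative (a frozen order reused across repetitions) is
not distinguishable by any analysis in the package, which aligns responses
per stimulus.

## Imaging measurement conventions

* **ΔF/F** uses the mean of the 1 s preceding each onset as F.
* **Z-scoring scope**: the repeat-averaged per-stimulus responses are
  concatenated (in grid order) into the neuron's average-response trace, and
  the Z transform uses the mean and sd of that *entire* trace. Scoring each
  stimulus segment in isolation would erase amplitude information (the Z
  transform of $a\cdot s(t)$ does not depend on $a > 0$), making the best
  frequency undefined even without noise; the global convention preserves
  response ordering across stimuli.
* **SD convention**: population (divide by N), with the sample convention
  available by flag; for the 1875-frame average trace the difference is
  negligible, but the choice is documented because it changes hand-computed
  examples.
* **Detection**: > 0.6 Z for ≥ 2 consecutive frames within the half-open
  1-s window (5 frames at 5 Hz) starting at the onset frame; both criterion
  frames must be in-window. The peak in the window is the response size.
* **Q20** reads the single level row at threshold + 20 dB and takes
  log₂(max/min) of the responsive frequencies there, regardless of gaps
  (literal "highest and lowest" reading). Neurons whose threshold + 20 dB
  exceeds the tested range are excluded from bandwidth analyses rather than
  extrapolated.
* **BF ties** break toward the lower frequency — deterministic and
  seed-independent.
* **d′** is computed as
  $(\bar e - \bar b)/\sqrt{(s_e^2+s_b^2)/2}$ over repeats, where $e$ is the
  peak ΔF/F in the 1-s window of the BF stimulus and $b$ the peak over the
  matched-duration pre-onset window. The literature the convention comes
  from does not fix a single formula; this matched-statistic form is the
  package's choice, and the top-20 % selection stage is agnostic to it.
* **Wide-field maps** filter each ΔF/F frame with a frequency-domain 2-D
  Butterworth low-pass (order 2, cutoff 0.1 cycles/pixel — both
  configurable, since the convention only specifies "a low-pass Butterworth
  filter") and average the 10 frames (0.5 s at 20 Hz) starting at sound
  offset. Region detection thresholds at mean + 3 sd and keeps 8-connected
  components, sorted by area; the real procedure localises A1 by eye, so
  the detector is a convenience, not a reproduction.

## Statistics

Paired comparisons gate on a Lilliefors test of the paired differences
(the quantity that enters the paired test; the convention leaves the tested
quantity open). The signed-rank branch uses the exact distribution for
n ≤ 25. All-zero difference vectors short-circuit to a degenerate result
(statistic 0, p = 1, flagged) since neither test is defined there. The
two-way repeated-measures ANOVA assumes a complete, balanced, fully
within-subject design (cells × treatment × pulse position) and reports the
treatment main effect as the headline value. Holm–Bonferroni decisions come
from the step-down rule (equivalently `p.adjust(method = "holm")`).

## Problem sizes and determinism

The experiment drivers default to the study-scale designs: 6 cells × 2
conditions × 3 trials for the ephys track, 40-neuron cohorts × 5 block
repetitions for the imaging track. Recovery-rate checks in the test suite
and acceptance script use 200 replicates (ephys gain recovery), 100 cohorts
per condition (bandwidth direction), and 1000 replicates (family-wise error
under the global null). A master seed spawns per-stage child seeds through a
Lehmer-style map, so identical configurations give byte-identical bundles
and any stage can be rerun in isolation.

## Known limitations

* The depletion recursion is a deliberately minimal presynaptic model; it
  has no facilitation, calcium dependence or multiple pools.
* The 0.6-Z / 2-frame criterion has an intrinsic false-positive floor that
  couples to how much of the trace variance is signal; cohort-level Q20
  comparisons inherit this noise, which is why direction-recovery claims are
  made over seeded cohort replicates rather than single cohorts.
* Synthetic receptive fields are rectangular; real tuning curves have soft
  edges, so exact-Q20 recovery is a property of the generator–analysis pair,
  not a claim about biological data.
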
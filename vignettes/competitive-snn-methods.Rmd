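---
title: "Competitive learning in a spiking network: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive learning in a spiking network: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnemg)
```

## The model

`snnemg` simulates networks of two-variable Izhikevich neurons,

$$\dot v = 0.04 v^2 + 5 v + 140 - u + I(t), \qquad \dot u = a (b v - u),$$

with the spike rule $v \ge 30\,\mathrm{mV} \Rightarrow v \leftarrow c,\;
u \leftarrow u + d$. Excitatory neurons use the regular-spiking preset
($a = 0.02$, $b = 0.2$, $c = -65$, $d = 8$), inhibitory neurons the
fast-spiking preset ($a = 0.1$, $b = 0.2$, $c = -65$, $d = 2$). The
driving current is the sum of three terms,

$$I(t) = \xi(t) + I_{syn}(t) + I_{stml}(t),$$

a white Gaussian noise current of intensity $D$, the synaptic current,
and the external stimulus. Synapses are current-based:
$I_{syn} = \sum_j g_j\, w_j\, y_j(t)$ with $g_j = +2$ for excitatory
and $-2$ for inhibitory presynaptic neurons, and $y_j$ the presynaptic
synaptic-output trace, an exponentially decaying variable
($\tau = 100$ ms) incremented by one at each presynaptic spike.

Plasticity acts on weights confined to $[0,1]$ by the multiplicative
soft bounds $F^+(w) = \lambda (1 - w)$ and $F^-(w) = \lambda \alpha w$.
Three rules are available per synapse:

* **pair STDP** — at each postsynaptic spike,
  $\Delta w = F^+(w)\, y^1_{pre}$; at each presynaptic spike,
  $\Delta w = -F^-(w)\, y^1_{post}$, where $y^1$ is a fast trace
  ($\tau_1 = 10$ ms);
* **triplet STDP** — the same depression, but potentiation additionally
  gated by the slow postsynaptic trace $y^2$ ($\tau_2 = 100$ ms):
  $\Delta w = F^+(w)\, y^1_{pre}\, y^2_{post}$, which makes
  potentiation grow with the postsynaptic rate;
* **triplet STDP + forgetting** — adds the continuous,
  activity-dependent decay $\dot w = -w\, y_i / \tau_f$, where $y_i$
  is an averaged-activity trace of the postsynaptic neuron
  ($\tau_o = 100$ ms). Forgetting implements synaptic competition: an
  active neuron slowly discards the inputs that do not drive it.

All traces of a spiking neuron are read *before* that spike's own
increment, so a spike only ever interacts with traces left by earlier
spikes; when a presynaptic and a postsynaptic spike fall in the same
step, depression is applied before potentiation. Both orderings are
deterministic tie-breaks and are covered by tests.

## Integration, noise and event handling

The engine advances the membrane with forward Euler at `dt = 0.5` ms
(configurable, at most 1 ms), advancing the voltage in four
quarter-steps per step (the recovery variable at full `dt`) and
clamping the upstroke at the spike peak for numerical robustness.
Accuracy is certified against a fine-step (`dt = 0.01` ms) reference
integrator: a one-second tonic-firing run agrees within one spike, and
halving the step changes the count by at most one.

The noise term uses the Euler–Maruyama convention: each step receives
an independent Gaussian sample of variance $D/\mathrm{dt}$, so the
integrated noise power over any fixed interval does not depend on the
step size. Noise intensities quoted below are in these units.
Unstimulated ordinary neurons are kept below 0.2 Hz baseline firing
(classifier preset: $D = 2$, effectively silent at rest); the
rest-detector neuron carries a large noise intensity by design so it
fires tonically whenever it is not inhibited.

Between spikes, traces decay exactly (multiplicative factors per step)
and the forgetting rule is integrated exactly per step,
$w \leftarrow w\,e^{-y_i\,\mathrm{dt}/\tau_f}$. An event-driven
reference mode (`stdp_replay()`) evolves the plastic weights of a
fixed spike raster in closed form, with the forgetting integral
$\int y_i\,dt$ computed analytically between events; the stepped
engine converges to it as `dt` shrinks, which the test suite checks.

## Parameter provenance and two corrections

The published parameterization this package follows states
$\lambda = 0.001$, $\alpha = 1$, $\tau_1 = 10$ ms, $\tau_2 = 100$ ms,
$\tau = 100$ ms, $\tau_f = 10$ ms, $\tau_o = 100$ ms, an EMG-current
gain $k = 2 \times 10^6$, and protocols of 1000 s (repeated pattern
learning) and about one minute (online EMG learning). Two of these
numbers are dimensionally incompatible with the protocols they are
supposed to serve, and this package deliberately departs from them;
both departures follow from time-scale analysis, not curve fitting.

**Forgetting time.** With unit trace increments, $y_i$ is of order
$r\,\tau_o$ (about 1–4 for rates of 10–40 Hz), so $\tau_f = 10$ ms
makes weights e-fold every few milliseconds of postsynaptic activity.
Simulated at face value, every plastic weight collapses to zero within
seconds and the postsynaptic neuron goes permanently silent.
Forgetting can only play its stated role — competition between inputs
*across a learning session* — if $\tau_f / y_i$ is of the order of the
session length. The defaults are therefore $\tau_f = 2\times10^6$ ms
for the 1000-s rate-coding protocol, and, in the classifier preset,
$5\times10^3$ ms for sensory inputs (pruning within a one-minute
session) with a slower $6\times10^4$ ms on the tonic rest-detector
pathway so that disuse prunes it on the session scale rather than
within a single gesture.

**Learning rate.** Each pair or triplet event changes a weight by at
most $\lambda$ (traces are of order one), so the total weight change
available in 1000 presentations of a temporal pattern is about
$e$-fold $\lambda N \approx 0.6$ — far short of the near-extremal
final weight distributions the method is known to produce, and far
short of what one minute of EMG learning requires. The single-neuron
experiments keep $\lambda = 0.001$ and instead run the repeated
pattern to its fixed point (3000 s of model time; the structure is
already visible at 1000 s but the familiar/unknown response contrast
is not yet saturated). The classifier preset uses $\lambda = 0.02$, at
which an association locks within one or two 3-s gesture epochs, which
is what online learning during a one-minute recording demands.

## Stimulation protocols

Stimulator pulses are rectangular, by default 0.5 ms at 180 current
units. This is deliberately strong and brief: a driven relay neuron
must follow its stimulator one-to-one at every commanded rate, the
regular-spiking preset accumulates recovery current between closely
spaced pulses, and a pulse that outlasts the spike it triggers fires a
second one. The default is verified to give exactly one spike per
pulse — under both the production step and a fine-step reference —
from rest up to 200 Hz bursts; gentler pulses (for example 3 ms at 15)
miss more than half the pulses at 50 Hz.

Rate patterns are Poisson by default (exponential intervals rescaled
around a 5 ms refractory floor so the requested mean rate is exact);
periodic trains are available. The temporal pattern plays one pulse
per stimulator at offsets $(j-1)\Delta t$, repeated at 1 Hz. The
supervised "teacher" electrode delivers the same suprathreshold pulse
at 40 Hz to one classifier, confined to labeled gesture intervals; it
biases the competition rather than overwhelming the network, and the
association it commands survives after the teacher is removed.

## The synthetic EMG generator

The study's original recordings are not deposited, so the package
generates surrogate 8-channel surface EMG: per channel, a zero-mean
Gaussian carrier band-passed to 20–95 Hz at 200 Hz sampling (the
bracelet rate), multiplied by an envelope
$\mathrm{baseline} + \mathrm{effort} \times \mathrm{weight}_c \times
\mathrm{max}_{rms}$. Flexion loads channels 1–3, extension channels
5–7, each with a weak secondary channel; rest has zero weights
everywhere. The envelope is affine in effort, so the mean absolute
value (MAV) inherits the linearity that the graded-response analysis
measures. Transitions between gestures use a 400 ms raised-cosine
ramp — the scale of a deliberate change of hand posture — which also
lets the synaptic traces of the previous competition winner decay
before the next competition begins. The amplitude scale
(`max_rms = 2e-5` V) puts dominant-channel currents, after the
$k|EMG|$ rectified coupling, in the 20–60 range where sensory neurons
fire at vigorous tens of Hz; this matters because triplet potentiation
is quadratic in the postsynaptic rate, and a lukewarm network cannot
lock an association within a one-minute session.

What the generator does **not** emulate: motor-unit structure,
electrode shift, fatigue, crosstalk between adjacent channels beyond
the fixed secondary weights, or inter-subject variability. Passing
tests on this surrogate demonstrate that the network mechanics work as
described, not that the pipeline would reach the same accuracy on real
recordings.

## The classifier network

`build_emg_classifier()` wires a sensory layer (one excitatory neuron
per channel, each with an inhibitory partner; partners mildly inhibit
the other sensory neurons, weight 0.3, contrasting the profile without
silencing secondary channels) plus one rest-detector neuron (noise
intensity 700, about 45 Hz when uninhibited, silenced through
weight-2 inhibitory synapses whenever the sensory layer is active),
and an output layer of three classifiers with inhibitory partners
(drive 3, cross-inhibition 4) implementing winner-take-all. All
sensory neurons and the rest detector project plastically
(triplet + forgetting) to every classifier, initialized uniformly on
[0.25, 0.75].

Fixed synapses are not subject to the $[0,1]$ bound — that bound is a
property of the multiplicative plastic rule — and the lateral gains
above were calibrated once so that (i) an active classifier reliably
drives its interneuron, (ii) losers are fully suppressed within
~150 ms, and (iii) the tonic rest pathway is strong enough to sustain
its own association (again the quadratic rate dependence: an
association below ~10 Hz cannot out-grow its own forgetting) yet weak
enough not to bridge gesture transitions. With unit-scale lateral
weights the interneurons barely reach threshold and no competition
occurs.

During unsupervised learning the equilibrium is self-stabilizing: the
classifier that wins a gesture potentiates that gesture's channels and
— through forgetting while it fires — discards the others, including
the rest pathway; the classifier that never wins a movement keeps its
rest-detector weight and inherits the rest class. The settling is
strongly path-dependent, however: across wide seed sets roughly a
third of runs separate all three classes cleanly (rate-ratio accuracy
0.9 or higher), while the rest plateau near 0.5-0.75 because the rest
association never locks or two classifiers contest one movement, and
longer recordings do not rescue these runs. This unpredictability of
unsupervised competitive assignment is precisely what motivates the
supervised teacher electrode, which across every seed tested yields
the commanded assignment and accuracy above 0.98. Errors concentrate
at gesture transitions, where the previous winner's traces are still
warm.

## Evaluation

Label assignment searches all bijections between gestures and
classifiers for the maximal total own-class rate (3! = 6
permutations). Accuracy per gesture is the assigned classifier's spike
rate divided by the summed classifier rates over that gesture's
samples; the overall figure is the duration-weighted mean. All
test-phase simulations run with learning frozen, which the tests
verify by weight equality. Responses are spike counts over windows
divided by window length; the single-neuron familiar/unknown tests use
30 s per pattern (at the 1 Hz repetition that is 30 presentations).

## Known limitations

* At an inter-pulse interval of 1 ms the whole 10-pulse temporal
  pattern (10 ms) is shorter than the integrate-to-spike latency of
  the postsynaptic neuron at any attainable drive (~7 ms), so the
  postsynaptic spike always falls at the end of the pattern:
  depression can only reach the last ranks, the learned weight
  profile is not monotone in rank, and familiar/unknown
  discrimination does not emerge. This is a structural property of
  accurately integrated canonical dynamics, not a tuning issue.
* Plain triplet STDP saturates all weights toward the ceiling, but the
  lowest-rate inputs (0.1–0.2 Hz) approach it very slowly; over
  realistic training lengths, the weight–rate Spearman correlation of
  the triplet-only rule therefore stays moderately positive rather
  than near zero.
* The forgetting-rule sigmoid places the middle of the rate ladder
  near weight 0.2–0.5; the exact foot and shoulder positions move a
  few hundredths across seeds.
* Problem sizes used by the tests and the acceptance script: 3000 s
  of model time for the single-neuron experiments (fixed-point
  convergence of the printed learning rate), 72 s recordings
  (six rest/flexion/rest/extension cycles of 3 s each) for the
  classifier, five seeds for stochastic medians, 30 s test phases,
  10 s per effort level in the graded-response analysis.
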
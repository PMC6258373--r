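---
title: "A point-neuron model of the layer 4 circuit in mouse V1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A point-neuron model of the layer 4 circuit in mouse V1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`layer4sim` builds and simulates an all-point-neuron model of layer 4 (L4) of
mouse primary visual cortex: 45,000 leaky integrate-and-fire (LIF) cells in a
cortical slab, driven by a bank of 9,000 linear-nonlinear-Poisson (LNP)
filters standing in for the dorsal LGN, and by traveling waves of background
activity standing in for the rest of the brain. The package covers the whole
in-silico physiology workflow: network construction, stimulus generation,
synaptic-weight calibration, simulation under two synapse models,
optogenetic-style perturbations, and the standard visual-response metrics
(OSI, DSI, F0/F1, lifetime sparsity, CV of ISIs, Fano factor, signal/noise
correlations, optogenetic modulation index, multi-unit activity spectra, LGN
input fractions and convergence).

### Cells and geometry

Seven cell types populate a cylinder 100 um high: five "core" types in the
inner 400 um radius (the excitatory Scnn1a, Rorb and Nr5a1 classes and the
fast-spiking PV1 and PV2 interneuron classes; 3700/3300/1500/800/700 cells)
and two generic LIF types in the annular shell out to 845 um (29,750
excitatory, 5,250 inhibitory). The shell exists to absorb boundary artifacts:
connection counts fall off near any open edge, so response statistics are
read from the core, whose cells have complete neighborhoods. Positions are
uniform per unit volume in each region (the slab height being the only
vertical structure, z placement is uniform on [0, 100] um). Every cell is
assigned a preferred direction that tiles [0, 360) degrees linearly over each
type's id range; orientation, where a rule needs it, is the direction mod
180.

### Recurrent connectivity: the LL/LR/RL/RR rule family

Connections are drawn independently per ordered pair with probability

p = p_dist(d) x p_ori(delta_ori),

where p_dist falls linearly from its peak at zero planar distance (0.34
E-to-E and 0.26 E-to-I under like-to-like connectivity; 0.255 for both under
random connectivity; 1.0 from inhibitory sources) to zero at 300 um
(excitatory sources) or 160 um (inhibitory sources). Under the "L"
connectivity rules (LL, LR) the E-to-E probability also falls linearly from 1
at zero orientation difference to 0.5 at 90 degrees. Distances are planar:
the slab is only 100 um thick and all other spatial rules (retinotopy,
waves) are planar as well. Each established connection carries 3-7 synapses
(uniform), a fixed 1 ms conduction delay (a nonzero delay is needed for
causal event ordering; the value is configurable), and a weight equal to a
per-(source class, target type) base value. Under the "L" weight rules (LL,
RL) the E-to-E weight is further multiplied by
F_w = exp(-(delta_theta)^2 / sigma_theta^2) with sigma_theta = 50 degrees.
Self-connections are excluded; one Bernoulli draw is made per ordered pair,
so reciprocal and one-way connections arise naturally.

These rules reproduce the reported degree statistics over core cells (mean
excitatory in-degree ~490, out-degree ~480; inhibitory out-degree ~530) and
the ~3,000 recurrent-plus-LGN synapses per core cell.

### The LGN front end

Each LGN unit is a transient ON, OFF, or ON/OFF filter: a center-surround
difference-of-Gaussians in space (surround amplitude A_c/6, surround width
2 sigma_c) times a biphasic temporal kernel k t exp(-kt)(1 - k^2 t^2 / 6)
whose integral is exactly zero, so static scenes evoke no sustained linear
response. The linear response is added to a baseline R0 and rectified;
ON/OFF filters sum two displaced subfields (separation 2 sigma_c by default,
in a random direction) and subtract the shared baseline; the sum is clamped
at zero because a negative rate cannot drive the Poisson spike generator.
The first 500 ms of every response is overwritten with R0 to suppress the
movie-onset transient, which is why every stimulus begins with at least
500 ms of gray.

The published sampling table for the filter parameters is not reproduced
here; instead `calibrate_filter_params()` regenerates the ranges from their
stated design targets: preferred spatial frequency 0.05 cpd, preferred
temporal frequency 4 Hz, and a bank-maximum F0 of 11-12 Hz. Separability of
the kernel makes the search clean: sigma_c alone sets the SF peak, k alone
the TF peak, and A_c scales the pre-rectification response linearly, so the
amplitude is found by root finding at the highest-gain corner of the
(sigma_c, k) ranges with the +/-10% sampling variation folded in. The
resulting defaults are sigma_c in [1.8, 3.4] degrees, k in [0.032, 0.056]
per ms and A_c = 1.79e-4 (+/-10%). R0 is drawn from [1, 6] Hz, spanning
typical LGN spontaneous rates. Numerically, the spatial kernel is evaluated
on the pixel grid truncated at a 3 sigma_s box (< 0.2% of kernel mass lost)
and the temporal kernel uses exact per-millisecond bin integrals of the
closed-form antiderivative, which preserves the zero-integral property on
the discrete grid to ~1e-5.

### Retinotopy and lasso wiring

Cortical position maps linearly to visual space at 120 deg/mm (azimuth) and
50 deg/mm (elevation). Around each cell's mapped position, capture regions
("lassos") select which filters feed it. Inhibitory targets get three
concentric circles (diameter drawn from [15, 20] degrees, one draw per
lasso). Excitatory targets get ON and OFF ellipses (minor radius [3, 4]
degrees, aspect ratio [2.8, 3.0]) whose centers are separated by [10, 11]
degrees along the cell's assigned preferred orientation with minor axes on
that line, plus a circular ON/OFF lasso with the ellipses' minor radius. A
two-subfield filter is a candidate when either of its kernel centers falls
inside the ON/OFF lasso, and its own ON-OFF axis must lie within 15 degrees
(folded orientation) of the cell's assigned orientation — this is the
reading of the capture rule that best reproduces the reported wiring
statistics (~600 LGN synapses per excitatory core cell; ~90-100 L4 targets
per filter). Selected filters are capped at 8 per type for excitatory and 15
per type for inhibitory targets, and each contributes 30 synapses. Note the
three reported wiring statistics are not jointly attainable under the stated
caps (saturated inhibitory caps force more targets per filter than the
reported mean whenever excitatory cells reach 600 synapses); the package
reports what the rules produce.

### Background traveling waves

3,000 Poisson generators cover the model footprint plus a 150 um margin (so
edge cells keep full candidate pools). Waves are sequential: duration
uniform on [200, 1200] ms, inter-wave gap on [250, 1750] ms, amplitude on
[5, 15] Hz, direction uniform; each wave is a 2,000 um rectangular band
(infinite perpendicular extent) whose speed is set so it traverses the whole
footprint within its duration — a generator is therefore active for
width/speed of each wave. Every trial draws a fresh schedule, so trials see
unique combinations of background-on and background-off states. Each cell
receives 18-24 connections from generators within 150 um; all of a cell's
background connections share a single synapse multiplier drawn from a
truncated geometric distribution on 1..16 (success 0.5, mode 1), the
long-tailed ingredient behind the skewed firing-rate distribution.

### Point-neuron dynamics

Both synapse models share a normalized threshold of 1, reset to 0, a 3 ms
refractory period during which arriving events are discarded, and membrane
time constants of 15 ms (E) and 10 ms (I) — calibration inputs standing in
for averages over the detailed reference cell models, not measured
constants. The instantaneous ("charge-dump") model adds weight x n_syn per
arriving event to a decaying activation. The kinetic model filters
excitatory drive through a single exponential (tau_e) and inhibitory drive
through a peak-normalized difference of exponentials (rise tau_i1, decay
tau_i2), with tau_e/tau_i1/tau_i2 = 1/4/17 ms onto excitatory and 7/1/8 ms
onto inhibitory cells; the membrane integrates the drives with tau_m. The
simulator uses a fixed 0.1 ms step on which the 1 ms delay and 3 ms
refractory period resolve exactly; within each step the kinetic cascade is
propagated with its exact closed-form solution, verified against a
matrix-exponential oracle to 1e-6 and better. Every arriving excitatory
event also increments per-cell accumulators (LGN-only and all-source summed
weights), from which the LGN input fraction is computed. An audit counter
confirms every input event is either applied once or discarded by the
refractory rule.

In-silico optogenetics: population silencing attaches one inhibitory synapse
per selected cell driven by an independent 100 Hz Poisson train, with weight
proportional to the labeled current (-30/-50/-100/-150 pA scale linearly;
`calibrate_silencing_weight()` maps the -100 pA label to a weight through a
benchmark-cell rate-suppression criterion). LGN silencing deletes all LGN
spikes from the onset time (1,000 ms in the standard protocol).

### Weight calibration

Calibration touches only the per-(source class, target type) scalars; edge
topology, synapse counts and the per-edge F_w structure are never modified,
so the same protocol applies identically to all four rule variants. Three
stages mirror the staged optimization of the reference model:

1. **LGN weights**, feedforward-only regime, matched to per-class target
   rates (defaults E 4 Hz, I 8 Hz) during a training grating.
2. **Background weights**, background-only regime, aimed slightly below
   (80% of) the spontaneous-rate targets.
3. **Recurrent weights**, full network, trained on one fixed gray trial and
   one fixed grating trial (reusing the same trial each iteration makes the
   loop deterministic in the weights). Excitatory classes track the
   preferred-population grating response (Rmax target) and inhibitory
   classes track the spontaneous rate, through damped multiplicative updates
   (exponent 0.25, step clamps, excitatory rises limited to 15% per step).

Spontaneous targets are the midpoints of the reported bands (0.75 Hz
excitatory, 1.75 Hz inhibitory) with a 0.25 Hz tolerance — tighter than the
nominal 0.5 Hz so that converged rates stay inside the bands. Rmax targets
default to 6/12 Hz, close to the feedforward-regime preferred-population
rates, since in the reference simulations the full-network maximal responses
approximately equaled the LGN-only ones. A synchrony guard rejects iterates
whose 5 ms-binned population rate exceeds 10x its median, or whose
population response runs away outright, by scaling excitation down. Because
strongly-coupled instantaneous-synapse networks have a sharp stability fold,
the loop brackets the lowest destabilizing excitatory weight and only raises
excitation toward the geometric midpoint of that bracket; if the bracket
closes before the Rmax target is reached, the maximal stable response is
accepted and flagged (`rmax_limited`), with the spontaneous targets still
enforced. At the reduced scales used for testing this is the typical
outcome; the calibrated networks then reproduce the reference excitatory
LGN-input fraction (~0.53) and the LL/RL > LR/RR orientation-selectivity
ordering.

### Stimuli

Square-wave drifting gratings (contrast 80% by default, levels 127 +/- 1.27
x contrast around mid-gray 127) are named g1-g240 with temporal frequency
varying fastest over {1,2,4,8,15} Hz, then spatial frequency over
{0.025,...,0.8} cpd, then direction over the eight multiples of 45 degrees.
The 0.8 cpd member of the battery is below the Nyquist limit of the 1.25
deg/pixel raster and is rendered with a warning. Full-field flashes follow
the exact published timings; moving bars are ~4 degrees wide at 33.8 deg/s;
gray screens measure spontaneous activity. All stimuli begin with >= 500 ms
of gray, which every metric discards.

## Problem sizes and what the tests show

The full 45,000-cell build (and its 9,000-filter wiring) is exercised
directly for all structural statistics. Dynamical properties are measured on
matched-density reduced cylinders — 150/250 um (about 3,900 cells, 4,500
filters) for the LGN-fraction and silencing checks, 125/200 um for the
four-variant OSI comparison — with the filter bank and generator pool scaled
to the same densities over the smaller footprint. These sizes were chosen as
the smallest at which central cells retain most of their in-degree so that
the recurrent/feedforward balance is representative. Reduced scale does
shrink in-degrees somewhat (a 150 um core cell reaches ~80% of the full
in-degree), which calibration partly compensates by raising per-synapse
weights; the LGN-fraction agreement indicates the balance survives.

The synthetic stimuli and the wave background emulate the *statistics* the
model was designed against, not real retinal input: there are no sustained
LGN channels (hence near-zero direction selectivity, as in the reference),
no eye movements, no natural-scene statistics unless the user supplies
movies in the `stimulus_movie` layout. Passing tests therefore demonstrate
faithful implementation of the circuit model and its analysis conventions,
not biological validity beyond what the reference model itself claims.

## Numerical choices and degenerate inputs

- Degenerate metric denominators (all-zero tuning curves, zero-variance
  samples, cells with no excitatory input) return NA rather than zero so
  population summaries can exclude them explicitly.
- The MUA inverse-distance weight caps r below at 1 um to avoid the
  singularity at the recording point.
- Flash-PSTH peaks are detected on a 10 ms-smoothed copy of the 2 ms-binned
  trace (raw 2 ms bins are noisy at practical trial counts).
- The CV of inter-spike intervals is reported squared, following the printed
  definition, with `squared = FALSE` for the conventional ratio; both F1
  conventions (|b| and 2|b|) are exposed and the choice is recorded by the
  caller.
- Poisson sampling of rate series uses one Bernoulli draw per 1 ms bin
  (thinning-equivalent at these rates).
- Movies shorter than the 500 ms gray-override epoch, negative distances,
  inconsistent geometries and unknown cell types raise errors rather than
  propagating silently.

## Known limitations

Compartmental biophysics, dendritic synapse placement, conductance-based
synapses, LFP via volume conduction, sustained/direction-selective LGN
channels, plasticity and probabilistic release are all out of scope, as in
the all-point-neuron variant of the reference model. Serialization is
CSV/JSON only. The calibration loop is a damped fixed-point heuristic that
replaces a manual optimization; it converges on the tested configurations
but is not guaranteed to for arbitrary targets, and reports best-effort
results with flags when it cannot.
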
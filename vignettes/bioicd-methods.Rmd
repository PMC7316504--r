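---
title: "Methods: frequency-sensing anti-arrhythmic channel simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-sensing anti-arrhythmic channel simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bioicd)
```

## The model

This package simulates a *biologically integrated cardiac defibrillator*
(BioICD): an engineered sarcolemmal ion channel whose gating senses the
cardiac activation frequency and conducts a large depolarizing current only
during tachyarrhythmia. The channel is a two-state Markov pore with a slow
catalytic deactivation agent:

$$\frac{\partial O}{\partial t} = \frac{k_{CO}\,C - k'_{OC}(a_1)\,O}{\tau_o},
\qquad
\frac{\partial a_1}{\partial t} = \frac{k_{01}\,a_0 - k_{10}\,a_1}{\tau_a},$$

with $C = 1 - O$, $a_0 = 1 - a_1$ and
$k'_{OC}(a_1) = k_{OC} + K\,a_1^{5}$, $K = 2\times10^4$ (the reduced form of
non-cooperative binding of five catalyst molecules). The four rates are
piecewise-constant in voltage: subunits open ($k_{CO} = 1$) above
$-60$ mV and close ($k_{OC} = 7$) below it; the catalyst activates
($k_{01} = 1$) only inside the plateau window $(-55, 0)$ mV and otherwise
decays fast ($k_{10} = 200$, e-fold time $\tau_a / k_{10} = 7$ ms). Both
characteristic times are $\tau_o = \tau_a = 1400$ ms. The channel needs all
$n = 8$ identical subunits open to conduct, so the current is

$$I_{\mathrm{BioICD}} = G\,O^{8}\,(V - E), \qquad
G = 150\ \mathrm{nS/pF},\ E = 0\ \mathrm{mV},$$

a non-selective pore. The eighth power makes the conductance effectively
all-or-nothing in $O$: at sinus rhythm $O$ oscillates around small values
and the current is negligible ($< 0.5$ pA/pF), while a sustained increase in
the fraction of time spent above $-60$ mV integrates $O$ towards 1 and the
current becomes enormous, clamping the tissue to $\approx 0$ mV. Holding the
membrane in the plateau window then accumulates $a_1$, which closes the
channel ($O_\infty \to k_{CO}/(k_{CO} + K) \approx 5\times10^{-5}$), the
tissue repolarizes, $a_1$ decays within tens of milliseconds, and normal
pacing resumes. Detection, termination and reset are thus all encoded in
the gating itself.

A useful back-of-envelope: with duty cycle $d$ (fraction of time above
$-60$ mV), $O$ grows iff $d > k_{OC}/(k_{CO}+k_{OC}) = 7/8$. A paced
myocyte at 1.2 Hz has $d \approx 0.4$; cells near a reentrant core are
depolarized almost continuously. This is the discrimination margin the
design exploits, and it also explains the failure mode: reentry anchored to
a large scar rotates slowly enough that $d$ stays below the threshold and
the arrhythmia is (by design) not detected.

## Host myocyte and tissue model

The host cell is the epicardial variant of the ten Tusscher–Panfilov (2006)
human ventricular model — 12 sarcolemmal currents, SR calcium cycling with
the four-state RyR reduction, dynamic intracellular Na$^+$ and K$^+$ — with
$I_{\mathrm{BioICD}}$ added to the total ionic current. The epicardial
subtype is the default (the common choice for 2D reentry studies with this
model); `cell_params()` also exposes the endo- and mid-myocardial variants.
All currents are in pA/pF, so the monodomain equation reads

$$\partial_t V = \nabla\!\cdot\!(D\,\nabla V) - (I_{\mathrm{ion}} + I_{\mathrm{stim}}),$$

with $D = 1.54$ cm$^2$/s scalar in monolayers (isotropy assumed; the
anisotropic tensor $D_{ij} = (D_l - D_t)\alpha_i\alpha_j + D_t\delta_{ij}$
with $D_t = D_l/4$ is provided by `diffusion_tensor()` for fiber fields).
Space is discretized with the centred five-point stencil at
$\delta x = 0.025$ cm under no-flux boundaries, both at the domain edge and
internally at fibroblast voids and scar cores.

## Numerics

* **Time stepping.** Forward Euler at $\delta t = 0.02$ ms for voltage and
  concentrations, Rush–Larsen exponential updates for the Hodgkin–Huxley
  gates, and the exact per-step linear-ODE solution for $O$ and $a_1$
  (voltage and $a_1$ frozen over the step). The exact update keeps both
  fractions in $[0,1]$ for any step size; a plain Euler path is retained
  for cross-checking (`bioicd_step(method = "euler")`).
* **Semi-implicit channel conductance.** With $G = 150$ nS/pF and
  $O \to 1$, explicit Euler violates its stability bound
  ($G\,\delta t = 3 > 2$). The voltage update therefore treats the
  $G\,O^8 (V - E)$ term by exact linear relaxation towards its momentary
  equilibrium, which reduces to forward Euler whenever the channel is
  closed and is unconditionally stable when it is open. This is the one
  place the package deviates from a textbook explicit update; without it
  every termination event would be a numerical blow-up.
* **Lookup tables.** All voltage-dependent gate steady states, rate
  exponentials and current factors are tabulated on 0.05 mV bins with
  linear interpolation (the inward-rectifier factor on $V - E_K$ bins).
  A direct-evaluation path (`use_tables = FALSE`) verifies the tables; the
  two agree within 0.5 mV over an AP, with the difference concentrated in
  sub-sample upstroke shift.
* **Reversal potentials.** $E_{Na}, E_K, E_{Ks}, E_{Ca}$ are recomputed
  every 25 steps (0.5 ms); the underlying concentrations drift on second
  time scales, and both the single-cell and tissue paths share the
  interval, keeping them bitwise consistent.
* **Stability guard.** Configurations violating
  $\delta t < \delta x^2 / (4 D)$ are rejected up front.
* **Determinism.** All randomness (substrate masks, scar boundary noise)
  derives from explicit integer seeds; fixed seed and config give
  bitwise-identical records on a fixed platform and build. Double
  precision throughout; no fast-math.
* **Discontinuous rates.** The channel's piecewise-constant rates are kept
  as hard steps (no smoothing); at exact threshold equality the
  "otherwise" branch applies. The choice is measure-zero but documented
  for reproducibility.
* **Initial channel state.** $O = a_1 = 0$: at the resting potential both
  rates drive the states to zero, so rest is the channel's fixed point.

## Substrates and scenarios

`build_homogeneous()`, `build_fibrosis()` and `build_scar()` generate the
pathological substrates as pure functions of their arguments including the
seed:

* **Diffuse fibrosis**: each node independently becomes an uncoupled
  fibroblast void with probability 0.20 (0.30 supported as the stressed
  variant). Voids are removed from the stencil entirely — they represent
  fibroblasts that do not couple electrotonically. A connectivity guard
  regenerates (and logs) masks whose largest myocyte component falls below
  60% of nodes, so percolation-broken fixtures cannot silently appear.
* **Scar with grey zone**: an irregular inexcitable core built from a
  seeded low-order Fourier modulation of an ellipse, parameterized by its
  major-axis length — the one geometric property controlled in the
  source experiments (3.4 cm terminable, 5.8 cm not). The shape beyond its
  length is not recoverable from the source material, so only
  length-controlled claims are made. The surrounding grey zone (default
  width 0.5 cm, unspecified in the source and chosen as a typical
  infarct border-zone scale) carries the remodelled current scales
  $I_{Ks}\times0.20$, $I_{Kr}\times0.30$, $I_{CaL}\times0.31$,
  $I_{Na}\times0.38$.
* **VF substrate**: the published steep-restitution parameter variant of
  the ventricular model (`cell_params(variant = "steep")`: plateau current
  maxima 0.8666/0.00219 and a twice-faster f-gate), which destabilizes the
  induced spiral into breakup. How the source's VF monolayer differed from
  its VT monolayer is not stated; this variant is the package's
  construction, exposed as a preset.

Arrhythmias are induced by an S1–S2 cross-field protocol: a planar S1 from
the left edge and a premature S2 over the lower-left quadrant (for the
scar substrates, over the half-plane below the scar core, which anchors
the broken wave onto the scar and grey zone; a quadrant S2 there produces
a circuit that paced-wave collisions detach within a couple of seconds).
`scan_vulnerable_window()` locates coupling intervals that produce
sustained reentry by brute force; the scenario defaults were fixed with
that scan and an analogous induction screening for the scar geometry. Sinus rhythm is surrogated by 1.2 Hz pacing of a 2-node edge
strip that keeps running throughout every scenario (whether the source's
monolayer pacing continued during arrhythmia is unstated; continuing it is
the stricter choice since termination must also recapture the paced
rhythm).

## Dynamic-clamp emulation

The in-vitro validation protocol is emulated in silico on the model
myocyte: 10 ms rectangular current injections stand in for the optical
stimuli (channelrhodopsin photocurrent kinetics are not modelled; the
default amplitude is about 1.5 times the 10 ms diastolic threshold), and
the six-phase train (7 baseline pulses, 8 baseline pulses, fast pacing
with feedback, 7 + 8 baseline pulses, fast pacing without the channel) is
reproduced with the published refractory-beat rule: a beat is refractory
when the membrane stays above $-20$ mV for the entire pulse. Because the
ventricular AP is much longer than the atrial APs the protocol was designed
around, pacing below the APD trivially produces alternating 2:1 refractory
beats without any channel involvement; block *detection* therefore requires
two consecutive refractory beats by default (`refractory_consecutive`,
settable to 1 for the raw rule) — ordinary 2:1 responses alternate, while
channel-driven depolarization block holds the membrane up across
consecutive pulses. On detection the feedback stops fast pacing. "Stable state" (the phase-iii exit when no
termination occurs) is operationalized as 10 consecutive fast beats whose
APD$_{90}$ varies by less than 1% — the source gives no criterion. The
experiments used atrial myocytes; the emulation runs on the ventricular
model (the mechanism depends only on baseline APD, which the
`termination_threshold_scan()` varies by scaling $I_{Kr}/I_{Ks}$ in
{0.5, 0.75, 1, 1.5, 2} — biological cell-to-cell variability cannot be
replicated, so only orderings are claimed, never the experimental
termination times). In this single-cell setting the channel does not need
$O \to 1$: depolarization block already occurs near $O \approx 0.5$
(where $G\,O^8$ reaches the order of the repolarization reserve), after
which the catalyst resets the cell; the tissue simulations are where $O$
approaches 1.

## Metrics conventions

The source reports timing claims (activation within 1 s, synchronization
within 300 ms, reset within 700 ms for functional reentry / 600 ms for
anatomical reentry, about 2 s from onset to restored rhythm) without
operational definitions. The package fixes these conventions, all
config-exposed:

* arrhythmia onset = the S2 time;
* channel activation = first frame whose spatial max $|I_{\mathrm{BioICD}}|$
  exceeds 1 pA/pF;
* synchronization = 95% of myocyte nodes simultaneously above $-20$ mV;
* reset = 99% of nodes below $-75$ mV;
* restoration = first pacing stimulus from which every subsequent stimulus
  elicits exactly one activation per probe with no unstimulated
  activations;
* upstrokes = $-20$ mV upward crossings with a 50 ms lockout (robust at
  the 5–10 ms summary cadence).

The solver computes the node fractions and current maxima densely (every
5 ms by default) during the run, so metrics are recomputable from the saved
record alone and are insensitive to the (coarser) full-field snapshot
cadence.

## Problem sizes

The source monolayer is 512 × 512 nodes (12.8 × 12.8 cm). The package's
default scenario domain is the scaled-down 256 × 256 monolayer
(6.4 × 6.4 cm) at identical $\delta t$ and $\delta x$; `nx`/`ny` expose the
full size. The reference analyses (tests, acceptance script) run the VT
scenario at 224 × 224 (5.6 cm — the smallest domain that reliably sustains
the induced figure-of-eight; at 4.8 cm the spiral annihilates on the
boundary), the 3.4 cm scar at 208 × 208 (5.2 cm, leaving a ~0.9 cm
conduction channel outside the grey zone), and the enlarged-scar control at
256 × 256 with a 4.8 cm scar, the longest that fits a 6.4 cm domain with
its grey zone and a conducting outer channel (the source's 5.8 cm scar
would need an 8 cm sheet). Where a property only needs the comparison
between two geometries (small vs large scar), this proportionally scaled
pair is used. Statements about the full-size domain are therefore
extrapolations in domain size only; all other parameters are at their
published values.

Domain size changes the *character* of termination, not its occurrence. At
6.4 cm the induced reentry's far field spends about 81% of its time above
$-60$ mV — below the $7/8$ duty-cycle threshold — so the open fraction
grows heterogeneously (fastest near the rotor core, boosted everywhere by
the channel's own APD prolongation) and the arrhythmia dies by fragmented
local conduction block once $O$ reaches $\approx 0.5$, roughly 1.5–2 s
after onset, leaving a percent-scale population of depolarized pockets
that the catalyst clears over a further second. The channel still
terminates the arrhythmia the control sustains, the current's first
appearance is early (hundreds of ms), and paced rhythm returns about 2 s
after onset; but the *activation-relative* synchronization and reset
durations are several-fold longer than in a full-size domain, where the
larger far field sustains the rotor longer relative to the $O$ build-up
and the collapse is a single, nearly simultaneous clamp. Timing statements
tied to that clamp (synchronization within hundreds of ms of the 1 pA/pF
activation crossing) should therefore only be expected at full size.

## What the synthetic substrates do not capture

Generated masks emulate the *statistics* of diffuse fibrosis and the
*scale* of scars, not image-derived anatomy: real fibrotic strands are
spatially correlated, real scars are not ellipse-like blobs, and real
hearts are 3D with rotational fiber anisotropy. Passing tests therefore
demonstrate the channel's detection/termination logic on controlled 2D
excitable media, not clinical performance. The atrial model, 3D anatomical
geometries and photocurrent physics are out of scope (interface hooks:
`cell_params()` is the adapter slot for an atrial parameter set; the
anisotropy presets carry the atrial constants $D_l = 1.6$ cm$^2$/s, ratio
6, $\delta t = 0.01$ ms, $\delta x = 0.033$ cm for future use).

## Known limitations

* The catalyst-binding Markov chain is implemented only in its published
  reduced form (the extra facilitated O→C flow); the unreduced chain is
  not available.
* Termination-vs-frequency in the paced single cell is not monotone: in
  narrow frequency bands the ventricular model's 2:1 block or alternans
  lengthens diastole and the channel correctly stays quiet. Threshold
  statements are therefore made on scanned grids, not as a single global
  cutoff.
* Records store dense summary series plus coarse snapshots; full-field
  voltage movies at frame cadence would dominate memory at tissue scale
  and are intentionally not kept.
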
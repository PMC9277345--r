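---
title: "Methods: fixed-point network simulation and the latency performance model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-point network simulation and the latency performance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(izhnode)
```

`izhnode` is a functional twin of a single-chip neuromorphic compute node for
spiking neural network simulation: it reproduces the node's numerics
(40-bit fixed-point Izhikevich pipelines), its event-driven synaptic delivery
(ring buffers with validity stamps), its Create/Connect/Simulate engine, and
the analytical latency model used to predict the node's acceleration factors
across hardware design points. This vignette documents the model choices, the
calibrations, and what the package's tests do and do not establish.

## Neuron model and integration

Neurons follow the two-variable Izhikevich dynamics

$$\dot v = 0.04 v^2 + 5v + 140 - u + i_\mathrm{syn} + i_\mathrm{ext},
\qquad \dot u = a(bv - u),$$

with the reset $v \leftarrow c$, $u \leftarrow u + d$ whenever $v \ge 30$ mV.
The excitatory population uses the regular-spiking parameterization
$(0.02, 0.2, -65, 8)$, the inhibitory population fast-spiking
$(0.1, 0.2, -65, 2)$. Integration is plain explicit forward Euler at a fixed
$h = 0.1$ ms — the step size that doubles as the minimum synaptic delay
$d_\mathrm{min}$ — with both derivatives evaluated on the pre-update state.
The spike test is applied to the post-update value; on a spike the membrane
potential reported for that step is clamped to 30 mV (spike-peak
normalization) while the stored state is reset. Placing the threshold test
after the update makes spike timing well-defined on the step grid and is the
ordering the package treats as the reference.

### Fixed-point arithmetic

The pipeline arithmetic is s16.23: 40-bit signed fixed point with 23
fractional bits, values in $[-65536, 65536 - 2^{-23}]$. Three policies are
deliberate choices and are configurably documented rather than hidden:

* **Overflow saturates** instead of wrapping. Saturation events are counted
  and surfaced (`glance()` of a simulation reports them), so a run can
  assert that none occurred — which is exactly what makes fixed-point
  accumulation commutative and the spike-identicality guarantees below
  exact.
* **Multiplication truncates toward $-\infty$** (arithmetic right shift of
  the full-precision 80-bit product), the cheapest DSP datapath behaviour.
  The truncation bias is bounded by one unit in the last place.
* **Constants are encoded once** with round-to-nearest-even. The reference
  evaluation order of $0.04v^2 + 5v + 140$ is: $v \cdot v$, scaled by the
  encoded $0.04$, then $+5v$, $+140$, $-u$, then the three currents, then
  $v + h \cdot \mathrm{acc}$.

A consequence worth knowing: the s16.23 image of $0.04$ is off by
$0.32 \cdot 2^{-23}$, and $v^2$ amplifies that to $\sim 2\cdot10^{-5}$ mV per
step near rest. This — not the per-operation truncation — dominates the
fixed-versus-float deviation, and the property tests assert exactly that
derived bound. Over long runs the two arithmetics nevertheless produce
spike-identical trains on the benchmark network, which the tests check
directly rather than assuming.

### Verification oracle

An adaptive Runge-Kutta-Fehlberg(4,5) integrator (`rkf45_oracle()`,
default absolute tolerance $10^{-6}$) provides the reference solution for
the Euler pipelines. Threshold crossings are located by step bisection to
$10^{-6}$ ms and the reset applied at the crossing. The oracle is itself
cross-checked in the test suite against `deSolve::lsodar` — including
lsodar's independent root-finding and event machinery on a spiking protocol
— so the package carries two independent routes to the reference dynamics.

## Ring-buffer synaptic delivery

Each processing unit owns a ring buffer of `K_RB` segments × `N_P` slots;
an entry accumulates the lumped excitatory and inhibitory input due at one
future step, together with a validity stamp `k_val` equal to the target
step's high-order bits (`k' %/% K_RB`, requiring `K_RB` to be a power of
two). Stale entries are never cleared: a read at step `k` accepts an entry
only if its stamp matches, so leftovers from a previous buffer cycle are
ignored and overwritten by the next write. The default `K_RB = 64` bounds
delays at 6.4 ms, covers the benchmark's delay range, and keeps the stamp
arithmetic a single shift.

Two scheduling details matter for exactness:

* Within one step the reads happen before the step's event-driven updates.
  A delay of exactly `K_RB` addresses the segment currently being read; the
  schedule only lets it land after the reads complete. The functional engine
  orders all deliveries of step `k` before the reads of step `k+1`, which
  also subsumes the hardware's pipeline-restart rule for minimum-delay
  synapses (`needs_restart()` flags those; the flag feeds performance
  accounting only, never correctness).
* Multapses (repeated (target, delay) pairs in one source's list) can
  collide in the hardware's update pipeline; `reorder_targets()` implements
  the memory-layout fix, separating identical keys by a configurable gap
  (default 4, a proxy for the update-pipeline depth — the required
  separation is not published).

The test suite checks the buffer against a brute-force dense queue keyed by
absolute step over random traffic, exactly, in raw integer arithmetic.

## Engine

`new_network() |> net_create() |> net_connect() |> simulate_network()`
mirrors the node's Create/Connect/Simulate interface. Logical neuron ids map
block-wise onto hardware resources (`unit = id %/% N_P`, `slot = id %% N_P`);
each source's synaptic targets are held as quadruples (stream route, target,
weight, delay) in fixed-capacity lists (128 per source on the prototype),
with targets routed to the `DS` data streams alternately for balanced memory
load. Per step: ring-buffer reads and Euler updates, spike serialization in
ascending (unit, slot) order, then delivery of every firing neuron's full
target list in list order. Simultaneous-spike serialization order is a free
choice in the hardware; any fixed order gives determinism, and ascending id
is used here. Runs are deterministic given network, stimulus and arithmetic;
with zero saturations, fixed-point accumulation is commutative, so relabeling
the network across processing units permutes the spike trains exactly — both
properties are asserted, not assumed.

The random-stimulus generator is the node's XNOR-shift PRNG: the Marsaglia
xorshift triplet (13, 17, 5) with complemented stages. Exhaustive search
shows the recurrence has a single fixed point, `0x3FFFFFFF`; that seed is
remapped with a warning. No repeat occurs within $10^6$ draws from the seeds
used in testing.

## Workload and performance model

The workload measure is the average number of spike events per step,
$\bar\nu_k = N \bar\nu h$ — independent of how many nodes share the network,
because the per-node out-degree $C^M = \epsilon N / M$ is constant for fixed
connection probability. The acceleration factor (biological time over wall
clock) follows from cycle counts: a silent step costs
$L_\Sigma = IL_N + L_\mathrm{SYNC}$ cycles, a spike-processing step
$L_\Sigma^{SE} + L_{DS}$ per event, with the sub-unity workload regime
mixing the two linearly; inter-node communication adds a fixed
$L_\mathrm{COM} = f_\mathrm{clk} T_\mathrm{COM}$ per step plus
$\alpha L_\mathrm{COM}$ per event ($T_\mathrm{COM}$ = 500 ns, $\alpha$ =
0.05 defaults). The loss decomposition
$P_\mathrm{TOT} = P_S + P_C$ is algebraically exact and tested as such.

**Calibration.** The per-component spike-path latencies are not individually
authoritative here; what is calibrated is their sums, by inverting the
prototype design point at $f_\mathrm{clk} = 200$ MHz, $h = 0.1$ ms (a
20,000-cycle budget per biological step, kept exact in the code):
$L_\Sigma = 67$ (hence `L_SYNC = 3` with `IL_N = 64`) and
$L_\Sigma^{SE} = 81$ (hence a spike-path component sum of 49, with the
$IL_N/2$ term reflecting events arriving mid-iteration on average). The
default component split (`L_RD = 4, L_ODE = 12, L_SE = 9, L_IDS = 6,
L_RB = 10, L_SYNC_SE = 8`) is one plausible decomposition of that sum; only
the sums enter the equations. Under this single calibration the prototype
column and all four design-point maxima reproduce exactly to the printed
decimal; the mid-workload entries of the high-data-stream and low-unit
design points are internally inconsistent with any single
$(L_\Sigma^{SE}, L_{DS})$ pair at the 1–2% level and are deliberately not
pinned.

One subtlety the model itself produces: with `IL_N = 128` the modeled
spike-processing step (counted at $IL_N/2$ after a restart) is *cheaper*
than a silent step, so the acceleration factor is not monotone below one
event per step for that design point. The monotonicity tests encode the
condition rather than the folklore.

## The benchmark network generator

`build_two_pop()` generates the two-population validation network: 800
regular-spiking excitatory plus 200 fast-spiking inhibitory neurons, every
neuron with a fixed in-degree of 100, excitatory sources projecting to both
populations, inhibitory sources to excitatory targets only, no autapses.
Weights, delays and the stimulus are documented stand-ins chosen once:

* weights: excitatory $U(0, 0.5] \times$ `weight_scale`, inhibitory
  $U[-1, 0) \times$ `weight_scale`, with `weight_scale = 10` so the mean
  inhibitory weight is $-5$ pA, the classic two-population value;
* delays: excitatory uniform on the 0.1 ms grid in $[1.0, 6.4]$ ms,
  inhibitory 1.0 ms (the network's minimum synaptic delay);
* random input: one uniformly drawn neuron per step receives a
  suprathreshold pulse. At $h = 0.1$ ms a pulse must carry $\sim$1000 pA to
  lift a resting neuron over threshold within a single step, so 1000 pA is
  the default; it yields a rest-state activity of order 10 spks/s
  ($\bar\nu_k \approx 1$), the moderate-workload regime. Weaker per-step
  pulses (e.g. 20 pA) are subthreshold at this resolution and leave the
  default network silent.

Because a fixed in-degree leaves out-degrees random, a handful of sources
in a 1000-neuron draw exceed the node's 128-target capacity with
near-certainty; the generator repairs this deterministically by re-drawing
sources for the excess connections (preserving every target's exact
in-degree) so the generated network always fits the node.

What the synthetic network does *not* emulate: the published validation
used a plasticity-trained connectivity state with its specific weight and
delay distributions, and a hardware PRNG stimulus protocol, neither of
which is public in full. Statistical results on the generated network
(rates, CVs, correlations) therefore characterize this generator's
conditions, not the trained reference state; the package's equivalence
tests compare runs of the *same* generated network across stimulus seeds,
arithmetic modes and processing-unit relabelings, which is the part of the
claim that transfers.

## Validation statistics

`compare_runs()` implements the statistical-equivalence pipeline:
per-neuron firing rates (silent neurons included at 0), coefficients of
variation of inter-spike intervals (neurons with fewer than 3 spikes
excluded, count reported), and pairwise Pearson correlations of spike
trains binned at 2 ms. Correlation pairs: all within-population pairs when
they number at most `max_pairs` (the 200-neuron inhibitory population's
19,900 pairs qualify), otherwise a seeded random sample of 20,000 pairs —
the published pair policy is not stated, so this one is explicit.
Distributions are presented with Freedman-Diaconis bin widths
($2\,\mathrm{IQR}\,n^{-1/3}$) and a Gaussian-kernel density; the kernel
bandwidth rule is not published, so Silverman's `nrd0` is the documented,
configurable default, and the density is renormalized to integrate to
exactly one. The Kolmogorov-Smirnov statistic is always computed on the raw
measure samples, never on the smoothed densities; the smoothing is
presentation only.

The self-consistency threshold used in testing — all six measure sets with
$D < 0.1$ between two stimulus seeds at population sizes of a few hundred —
is a documented package choice (roughly the $p \approx 10^{-3}$ critical
value at $n = 800$), not a published number.

## Problem sizes and numerical choices in the tests

The test suite runs the full 1000-neuron benchmark for 60 s of biological
time (600,000 steps) in fixed-point mode, the statistical pipeline on
two 10 s runs, the engine-versus-brute-force comparison on 50 random small
networks (kept exact, both arithmetics), and the ring-buffer oracle on
$10^4$ random events — sizes chosen so the whole suite completes in well
under a minute on one core while every comparison that can be exact is
exact. Float-mode exactness across the R/C++ boundary requires compiling
the kernel without floating-point contraction (no FMA); the package's build
flags enforce this.

## Known limitations

* Hardware plumbing is out of scope: bus protocols, DMA, clock-domain
  crossings, recording transport, and measured wall-clock performance of
  the physical chip are represented only through the latency model's
  calibrated totals.
* Plasticity is excluded by design; the connectivity is static during a
  run.
* Multi-node execution is modeled analytically (broadcast with fixed
  transmission latency), never simulated functionally.
* Only the s16.23 format is exercised; the fixed-point layer is
  parameterized internally but narrower formats are deliberately not
  supported.
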